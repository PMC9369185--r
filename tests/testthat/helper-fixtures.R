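# Published per-spot measured colocalization percentages (transcribed from
# the study's results text), in canonical category order for each spot.
# For a CD9 spot the order is (capture_only, capture+CD63, capture+CD81,
# triple); for a CD63 spot (capture_only, capture+CD9, capture+CD81, triple).
published_measured <- function() {
  list(
    msc_hpl_cd63 = list(spot = "CD63", pct = c(63.1, 11.1, 10.3, 15.5)),
    msc_hpl_cd9  = list(spot = "CD9",  pct = c(78.1, 2.8, 7.6, 11.6)),
    msc_fcs_cd63 = list(spot = "CD63", pct = c(32.4, 9.1, 35.6, 23.0)),
    msc_fcs_cd9  = list(spot = "CD9",  pct = c(49.2, 3.2, 18.4, 29.2)),
    hela_cd9     = list(spot = "CD9",  pct = c(56.7, 8.5, 17.3, 17.6)),
    hela_cd63    = list(spot = "CD63", pct = c(17.1, 50.7, 16.3, 15.8)),
    hfl1_cd9     = list(spot = "CD9",  pct = c(25.4, 3.8, 18.6, 52.2)),
    hfl1_cd63    = list(spot = "CD63", pct = c(42.0, 7.0, 18.1, 32.9)),
    a4_cd63      = list(spot = "CD63", pct = c(11.3, 15.8, 11.6, 61.4)),
    co2_cd63     = list(spot = "CD63", pct = c(21.0, 23.6, 13.5, 41.8)),
    hmec1_cd63   = list(spot = "CD63", pct = c(21.6, 16.4, 2.8, 59.2)),
    huvec_cd63   = list(spot = "CD63", pct = c(39.0, 10.8, 4.2, 46.1)))
}

published_table <- function(name) {
  spec <- published_measured()[[name]]
  coloc_table(spec$spot, fractions = spec$pct / 100, sample_label = name)
}

# predicted percentage (1 dp) of one category from a published table
predicted_pct <- function(name, category) {
  tb <- published_table(name)
  pred <- predict_random(marker_marginals(tb))
  round_half_up(100 * pred$fractions[[category]], 1)
}

# minimal well-formed experiment: one particle per spot including IgG
tiny_experiment <- function() {
  chip_experiment(tibble::tibble(
    chip_id = "C1", bio_rep = 1L, tech_rep = 1L,
    particle_id = sprintf("p%d", 1:4),
    spot = c("CD9", "CD63", "CD81", "IgG"),
    cd9_pos = c(TRUE, FALSE, TRUE, FALSE),
    cd63_pos = c(FALSE, TRUE, FALSE, FALSE),
    cd81_pos = c(FALSE, FALSE, TRUE, FALSE),
    size_nm = c(55, 60, NA, 70)),
    sample_label = "tiny")
}

# hand-built experiment with known counts on one spot
spot_experiment <- function(spot, a_flags, b_flags, sample_label = "manual") {
  others <- setdiff(TETRASPANINS, spot)
  n <- length(a_flags)
  flags <- list(CD9 = rep(FALSE, n), CD63 = rep(FALSE, n),
                CD81 = rep(FALSE, n))
  flags[[spot]] <- rep(TRUE, n)
  flags[[others[1]]] <- a_flags
  flags[[others[2]]] <- b_flags
  chip_experiment(tibble::tibble(
    chip_id = "C1", bio_rep = 1L, tech_rep = 1L,
    particle_id = sprintf("p%d", seq_len(n)),
    spot = spot,
    cd9_pos = flags$CD9, cd63_pos = flags$CD63, cd81_pos = flags$CD81,
    size_nm = NA_real_), sample_label = sample_label)
}
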