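test_that("tabulate_spot classifies the four categories exhaustively", {
  exp <- spot_experiment("CD63",
                         a_flags = c(FALSE, TRUE, FALSE, TRUE),   # CD9
                         b_flags = c(FALSE, FALSE, TRUE, TRUE))   # CD81
  tb <- tabulate_spot(exp, "CD63")
  expect_equal(unname(tb$counts), c(1, 1, 1, 1))
  expect_equal(unname(tb$fractions), rep(0.25, 4))
  expect_equal(tb$total, 4)
})

test_that("capture-channel fluorescence is ignored under the export convention", {
  # particle on the CD9 spot with cd9_pos = FALSE but cd81_pos = TRUE:
  # classified capture+CD81, not dropped
  exp <- chip_experiment(tibble::tibble(
    chip_id = "C1", bio_rep = 1L, tech_rep = 1L, particle_id = "p1",
    spot = "CD9", cd9_pos = FALSE, cd63_pos = FALSE, cd81_pos = TRUE,
    size_nm = NA_real_))
  tb <- tabulate_spot(exp, "CD9")
  expect_equal(tb$counts[["capture+CD81"]], 1)
  expect_equal(tb$total, 1)
  # strict mode instead requires the capture channel and drops it
  expect_error(tabulate_spot(exp, "CD9", strict_capture = TRUE))
})

test_that("non-fluorescent particles are excluded by default, countable on request", {
  exp <- chip_experiment(tibble::tibble(
    chip_id = "C1", bio_rep = 1L, tech_rep = 1L,
    particle_id = c("p1", "p2"),
    spot = "CD63",
    cd9_pos = c(FALSE, TRUE), cd63_pos = FALSE, cd81_pos = FALSE,
    size_nm = NA_real_))
  expect_equal(tabulate_spot(exp, "CD63")$total, 1)
  with_dark <- tabulate_spot(exp, "CD63", include_nonfluorescent = TRUE)
  expect_equal(with_dark$total, 2)
  # the dark particle counts as capture-only; the CD9+ one keeps its category
  expect_equal(with_dark$counts[["capture_only"]], 1)
  expect_equal(with_dark$counts[["capture+CD9"]], 1)
})

test_that("tabulation is invariant to particle order and id relabelling", {
  exp <- simulate_chip(sim_config(n_vesicles = 2000, seed = 31))
  ref <- tabulate_spot(exp, "CD81")
  shuf <- exp
  perm <- withr::with_seed(1, sample.int(nrow(exp$particles)))
  shuf$particles <- exp$particles[perm, ]
  shuf$particles$particle_id <- sprintf("q%06d", seq_len(nrow(shuf$particles)))
  expect_equal(tabulate_spot(shuf, "CD81")$counts, ref$counts)
})

test_that("noiseless simulated fractions equal the generator's conditional truth", {
  cfg <- sim_config(n_vesicles = 8000, fn_rate = 0, fp_rate = 0, seed = 32)
  exp <- simulate_chip(cfg)
  truth <- attr(exp, "truth")
  for (spot in TETRASPANINS) {
    tb <- tabulate_spot(exp, spot)
    tr <- truth[truth$spot == spot, ]
    others <- setdiff(TETRASPANINS, spot)
    a <- tr[[paste0("true_", tolower(others[1]))]]
    b <- tr[[paste0("true_", tolower(others[2]))]]
    expect_equal(unname(tb$counts),
                 c(sum(!a & !b), sum(a & !b), sum(!a & b), sum(a & b)))
  }
})

test_that("empty spots raise an explicit error, never a zero division", {
  exp <- spot_experiment("CD63", a_flags = TRUE, b_flags = FALSE)
  expect_error(tabulate_spot(exp, "CD9"),
               class = "tetraspot_empty_spot_error")
})

test_that("capture distribution reports spot shares with IgG outside the 100%", {
  counts <- c(CD9 = 345, CD63 = 330, CD81 = 326)
  rows <- do.call(rbind, lapply(names(counts), function(s) {
    data.frame(spot = s, n = counts[[s]])
  }))
  particles <- tibble::tibble(
    chip_id = "C1", bio_rep = 1L, tech_rep = 1L,
    particle_id = sprintf("p%d", seq_len(sum(counts) + 10)),
    spot = c(rep(rows$spot, rows$n), rep("IgG", 10)),
    cd9_pos = TRUE, cd63_pos = FALSE, cd81_pos = FALSE,
    size_nm = NA_real_)
  cd <- capture_distribution(chip_experiment(particles))
  expect_equal(round_half_up(100 * unname(cd$fractions), 1),
               c(34.5, 33.0, 32.6))
  expect_equal(sum(cd$fractions), 1, tolerance = 1e-12)
  expect_equal(cd$igg_count, 10)
  expect_equal(cd$igg_ratio, 10 / mean(counts))

  # all particles on one spot
  solo <- spot_experiment("CD9", a_flags = c(TRUE, TRUE), b_flags = FALSE)
  expect_equal(unname(capture_distribution(solo)$fractions), c(1, 0, 0))

  # simulated equal-affinity all-triple run: shares within 4 multinomial SE
  probs <- stats::setNames(rep(0, 8), phenotype_levels())
  probs["CD9+CD63+CD81+"] <- 1
  exp <- simulate_chip(sim_config(n_vesicles = 20000, phenotype_probs = probs,
                                  background_rate = 0, seed = 33))
  cd2 <- capture_distribution(exp)
  n <- sum(cd2$counts)
  expect_true(all(abs(cd2$fractions - 1 / 3) <=
                    4 * sqrt((1 / 3) * (2 / 3) / n)))
})

test_that("background assessment flags spots near the IgG control level", {
  mk <- function(n_spot, n_igg) {
    chip_experiment(tibble::tibble(
      chip_id = "C1", bio_rep = 1L, tech_rep = 1L,
      particle_id = sprintf("p%d", seq_len(n_spot + n_igg)),
      spot = c(rep("CD81", n_spot), rep("IgG", n_igg)),
      cd9_pos = FALSE, cd63_pos = FALSE, cd81_pos = TRUE,
      size_nm = NA_real_))
  }
  flags <- assess_background(mk(80, 75), threshold = 1.5,
                             fluorescent_only = FALSE)
  expect_true(flags$background_level[flags$spot == "CD81"])
  flags2 <- assess_background(mk(1000, 10), threshold = 1.5,
                              fluorescent_only = FALSE)
  expect_false(flags2$background_level[flags2$spot == "CD81"])

  # missing IgG spot: warning, flags undetermined
  no_igg <- spot_experiment("CD9", a_flags = TRUE, b_flags = FALSE)
  expect_warning(flags3 <- assess_background(no_igg))
  expect_true(all(is.na(flags3$background_level)))

  # heavy simulated background pushes every spot to background level
  cfg <- sim_config(n_vesicles = 4000, background_rate = 2, seed = 34)
  flags4 <- assess_background(simulate_chip(cfg))
  expect_true(all(flags4$background_level))
})

test_that("replicate summary averages per-replicate fractions unweighted", {
  # two technical replicates with different totals but known fractions
  p1 <- tibble::tibble(
    chip_id = "C1", bio_rep = 1L, tech_rep = 1L,
    particle_id = sprintf("a%d", 1:4),
    spot = "CD63",
    cd9_pos = c(TRUE, TRUE, FALSE, FALSE),
    cd63_pos = TRUE,
    cd81_pos = c(FALSE, FALSE, FALSE, TRUE),
    size_nm = NA_real_)
  p2 <- tibble::tibble(
    chip_id = "C1", bio_rep = 1L, tech_rep = 2L,
    particle_id = sprintf("b%d", 1:8),
    spot = "CD63",
    cd9_pos = FALSE, cd63_pos = TRUE, cd81_pos = FALSE,
    size_nm = NA_real_)
  exp <- chip_experiment(dplyr::bind_rows(p1, p2))
  sm <- coloc_summary(exp)
  row <- sm[sm$spot == "CD63" & sm$category == "capture+CD9", ]
  # replicate fractions 0.5 and 0: unweighted mean 0.25, not pooled 2/12
  expect_equal(row$mean_fraction, 0.25)
  expect_equal(row$pooled_count, 2L)
  expect_equal(row$n_replicates, 2L)
})
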