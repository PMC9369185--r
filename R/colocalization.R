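#' Particles of one spot, with the default fluorescence policy applied
#'
#' Default policy: particles with no fluorescence in any channel are
#' interferometric-only detections and are excluded from colocalization
#' tabulation (they are retained in the particle table). `strict_capture`
#' additionally requires fluorescence in the capture marker's own channel.
#' @noRd
.spot_particles <- function(experiment, spot, strict_capture = FALSE,
                            include_nonfluorescent = FALSE) {
  p <- experiment$particles[experiment$particles$spot == spot, ]
  if (nrow(p) == 0) {
    rlang::abort(paste0("no particles on the ", spot, " spot"),
                 class = "tetraspot_empty_spot_error")
  }
  flags <- cbind(CD9 = p$cd9_pos, CD63 = p$cd63_pos, CD81 = p$cd81_pos)
  if (strict_capture && spot %in% TETRASPANINS) {
    p <- p[flags[, spot], ]
  } else if (!include_nonfluorescent) {
    p <- p[rowSums(flags) > 0, ]
  }
  if (nrow(p) == 0) {
    rlang::abort(paste0("no particles left on the ", spot,
                        " spot under the current fluorescence policy"),
                 class = "tetraspot_empty_spot_error")
  }
  p
}

#' Tabulate colocalization categories on one capture spot
#'
#' Classifies every particle captured on an anti-tetraspanin spot into the
#' four observable categories using only its two non-capture channel flags;
#' the capture channel flag is ignored because a captured particle is scored
#' positive for the capture tetraspanin regardless of fluorescence (the
#' platform's export convention). `strict_capture = TRUE` switches to the
#' alternative reading in which capture-channel fluorescence is required.
#'
#' @param experiment A [chip_experiment()].
#' @param spot `"CD9"`, `"CD63"` or `"CD81"` (the IgG control has no
#'   colocalization categories).
#' @param strict_capture Require fluorescence in the capture channel
#'   (particles without it are dropped before classification).
#' @param include_nonfluorescent Count particles with no fluorescence in any
#'   channel as capture-only instead of excluding them (default `FALSE`).
#' @return A count-backed [coloc_table()].
#' @export
#' @examples
#' exp <- simulate_chip(sim_config(n_vesicles = 2000, seed = 11))
#' tabulate_spot(exp, "CD63")
tabulate_spot <- function(experiment, spot, strict_capture = FALSE,
                          include_nonfluorescent = FALSE) {
  stopifnot(inherits(experiment, "chip_experiment"))
  spot <- match_spot(spot, allow_igg = FALSE)
  p <- .spot_particles(experiment, spot, strict_capture,
                       include_nonfluorescent)
  others <- other_markers(spot)
  flag_of <- function(marker) {
    switch(marker, CD9 = p$cd9_pos, CD63 = p$cd63_pos, CD81 = p$cd81_pos)
  }
  a <- flag_of(others[1])
  b <- flag_of(others[2])
  counts <- c(sum(!a & !b), sum(a & !b), sum(!a & b), sum(a & b))
  coloc_table(spot, counts = counts, sample_label = experiment$sample_label)
}

#' Tabulate all three tetraspanin spots
#'
#' @inheritParams tabulate_spot
#' @param spots Spots to tabulate (default all three tetraspanin spots).
#' @return Named list of [coloc_table()] objects.
#' @export
tabulate_experiment <- function(experiment, spots = TETRASPANINS,
                                strict_capture = FALSE,
                                include_nonfluorescent = FALSE) {
  out <- lapply(spots, tabulate_spot, experiment = experiment,
                strict_capture = strict_capture,
                include_nonfluorescent = include_nonfluorescent)
  stats::setNames(out, spots)
}

#' Capture-spot particle distribution
#'
#' Fraction of all fluorescent tetraspanin-spot particles found on each of
#' the CD9, CD63 and CD81 spots (summing to 1), with the IgG isotype-control
#' spot reported alongside as a count and as a ratio to the mean
#' tetraspanin-spot count — never inside the 100%.
#'
#' @param experiment A [chip_experiment()].
#' @param fluorescent_only Count only particles with fluorescence in at
#'   least one channel (default `TRUE`, matching fluorescent-count
#'   reporting).
#' @return An object of class `capture_distribution`: `counts` and
#'   `fractions` over the three tetraspanin spots, `igg_count`, `igg_ratio`.
#' @export
capture_distribution <- function(experiment, fluorescent_only = TRUE) {
  stopifnot(inherits(experiment, "chip_experiment"))
  p <- experiment$particles
  if (fluorescent_only) {
    p <- p[p$cd9_pos | p$cd63_pos | p$cd81_pos, ]
  }
  counts <- vapply(TETRASPANINS, function(s) sum(p$spot == s), numeric(1))
  if (sum(counts) == 0) {
    rlang::abort("no particles on any tetraspanin spot",
                 class = "tetraspot_empty_spot_error")
  }
  igg_count <- sum(p$spot == IGG_CONTROL)
  structure(
    list(counts = counts, fractions = counts / sum(counts),
         igg_count = igg_count, igg_ratio = igg_count / mean(counts)),
    class = "capture_distribution")
}

#' @export
print.capture_distribution <- function(x, ...) {
  pct <- round_half_up(100 * x$fractions, 1)
  cat("<capture_distribution>",
      paste0(TETRASPANINS, " ", pct, "%", collapse = "  "), "\n")
  cat("  IgG control:", x$igg_count, "particles (ratio to mean spot:",
      round_half_up(x$igg_ratio, 2), ")\n")
  invisible(x)
}

#' Flag capture spots whose signal is at background level
#'
#' A tetraspanin spot whose particle count does not clearly exceed the IgG
#' isotype-control count is indistinguishable from nonspecific adhesion;
#' such spots are flagged so downstream colocalization results can be
#' discounted. The IgG count is only compared, never subtracted.
#'
#' @param experiment A [chip_experiment()].
#' @param threshold A spot is flagged when its count is at most `threshold`
#'   times the IgG count (default 1.5).
#' @param fluorescent_only Count only fluorescent particles; the default
#'   (`FALSE`) compares total detected event counts, since nonspecifically
#'   adhered background particles need not fluoresce.
#' @return A tibble with one row per tetraspanin spot: `spot`, `count`,
#'   `igg_count`, `ratio` and logical `background_level` (`NA` with a
#'   warning when the chip has no IgG spot).
#' @export
assess_background <- function(experiment, threshold = 1.5,
                              fluorescent_only = FALSE) {
  stopifnot(inherits(experiment, "chip_experiment"), threshold > 0)
  p <- experiment$particles
  if (fluorescent_only) {
    p <- p[p$cd9_pos | p$cd63_pos | p$cd81_pos, ]
  }
  counts <- vapply(TETRASPANINS, function(s) sum(p$spot == s), numeric(1))
  has_igg <- any(experiment$particles$spot == IGG_CONTROL)
  igg <- sum(p$spot == IGG_CONTROL)
  if (!has_igg) {
    rlang::warn("experiment has no IgG control spot; background flags undetermined")
    flag <- rep(NA, 3L)
    ratio <- rep(NA_real_, 3L)
  } else {
    flag <- counts <= threshold * igg
    ratio <- if (igg > 0) counts / igg else rep(Inf, 3L)
  }
  tibble::tibble(spot = TETRASPANINS, count = as.integer(counts),
                 igg_count = if (has_igg) as.integer(igg) else NA_integer_,
                 ratio = ratio, background_level = flag)
}

#' Replicate-averaged colocalization summary
#'
#' Computes colocalization fractions within each (biological, technical)
#' replicate, then averages them unweighted across replicates and reports
#' the standard error of that mean — the convention of reporting the mean of
#' independent biological experiments with technical replicates. Pooled
#' counts are carried alongside.
#'
#' @inheritParams tabulate_spot
#' @return A tibble with one row per spot x category: `spot`, `category`,
#'   `pooled_count`, `mean_fraction`, `sem`, `n_replicates`.
#' @export
coloc_summary <- function(experiment, strict_capture = FALSE,
                          include_nonfluorescent = FALSE) {
  stopifnot(inherits(experiment, "chip_experiment"))
  reps <- unique(experiment$particles[c("chip_id", "bio_rep", "tech_rep")])
  rows <- list()
  for (spot in TETRASPANINS) {
    cats <- coloc_categories(spot)
    per_rep <- matrix(NA_real_, nrow = nrow(reps), ncol = 4L,
                      dimnames = list(NULL, cats))
    pooled <- stats::setNames(numeric(4), cats)
    for (i in seq_len(nrow(reps))) {
      sub <- experiment$particles[
        experiment$particles$chip_id == reps$chip_id[i] &
          experiment$particles$bio_rep == reps$bio_rep[i] &
          experiment$particles$tech_rep == reps$tech_rep[i], ]
      if (!any(sub$spot == spot)) next
      sub_exp <- experiment
      sub_exp$particles <- sub
      tb <- tryCatch(
        tabulate_spot(sub_exp, spot, strict_capture, include_nonfluorescent),
        tetraspot_empty_spot_error = function(e) NULL)
      if (is.null(tb) || tb$total == 0) next
      per_rep[i, ] <- tb$fractions
      pooled <- pooled + tb$counts
    }
    ok <- stats::complete.cases(per_rep)
    n_rep <- sum(ok)
    mean_f <- if (n_rep > 0) colMeans(per_rep[ok, , drop = FALSE]) else
      rep(NA_real_, 4)
    sem <- if (n_rep > 1) {
      apply(per_rep[ok, , drop = FALSE], 2, stats::sd) / sqrt(n_rep)
    } else rep(NA_real_, 4)
    rows[[spot]] <- tibble::tibble(
      spot = spot, category = cats,
      pooled_count = as.integer(pooled),
      mean_fraction = unname(mean_f), sem = unname(sem),
      n_replicates = n_rep)
  }
  dplyr::bind_rows(rows)
}
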