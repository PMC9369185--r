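#' Per-spot interferometric size summary
#'
#' Percentile summary (5/25/50/75/95) of the interferometric diameters of
#' particles captured on one spot, matching box-and-whisker reporting
#' (box = interquartile range, whiskers = 5th to 95th percentile).
#' Percentiles use linear interpolation between closest ranks. Fluorescent
#' particles below the sizing floor carry no size; they are counted
#' separately and never imputed.
#'
#' @param experiment A [chip_experiment()].
#' @param spot Any capture spot, including the IgG control.
#' @return An object of class `size_summary`: `spot`, `p5`, `p25`, `p50`,
#'   `p75`, `p95` (nm), `n_sized`, `n_fluorescent_unsized`.
#' @export
size_percentiles <- function(experiment, spot) {
  stopifnot(inherits(experiment, "chip_experiment"))
  spot <- match_spot(spot)
  p <- experiment$particles[experiment$particles$spot == spot, ]
  if (nrow(p) == 0) {
    rlang::abort(paste0("no particles on the ", spot, " spot"),
                 class = "tetraspot_empty_spot_error")
  }
  sized <- p$size_nm[!is.na(p$size_nm)]
  if (length(sized) == 0) {
    rlang::abort(paste0("no sized particles on the ", spot,
                        " spot (all below the sizing floor)"),
                 class = "tetraspot_no_sized_error")
  }
  fluorescent <- p$cd9_pos | p$cd63_pos | p$cd81_pos
  q <- stats::quantile(sized, c(0.05, 0.25, 0.5, 0.75, 0.95), type = 7,
                       names = FALSE)
  structure(
    list(spot = spot, p5 = q[1], p25 = q[2], p50 = q[3], p75 = q[4],
         p95 = q[5], n_sized = length(sized),
         n_fluorescent_unsized = sum(fluorescent & is.na(p$size_nm))),
    class = "size_summary")
}

#' @export
print.size_summary <- function(x, ...) {
  cat(sprintf(
    "<size_summary> %s: p5 %.1f | p25 %.1f | median %.1f | p75 %.1f | p95 %.1f nm\n",
    x$spot, x$p5, x$p25, x$p50, x$p75, x$p95))
  cat("  sized:", x$n_sized, "| fluorescent unsized:",
      x$n_fluorescent_unsized, "\n")
  invisible(x)
}

#' Size summaries for every occupied spot
#'
#' @param experiment A [chip_experiment()].
#' @param spots Spots to summarize; defaults to every spot present with at
#'   least one sized particle.
#' @return A tibble, one row per spot, with the [size_percentiles()] fields.
#' @export
size_summary_table <- function(experiment, spots = NULL) {
  stopifnot(inherits(experiment, "chip_experiment"))
  if (is.null(spots)) {
    present <- unique(experiment$particles$spot)
    spots <- CAPTURE_SPOTS[CAPTURE_SPOTS %in% present]
  }
  rows <- lapply(spots, function(s) {
    ss <- tryCatch(size_percentiles(experiment, s),
                   tetraspot_no_sized_error = function(e) NULL,
                   tetraspot_empty_spot_error = function(e) NULL)
    if (is.null(ss)) return(NULL)
    tibble::tibble(spot = ss$spot, p5 = ss$p5, p25 = ss$p25, p50 = ss$p50,
                   p75 = ss$p75, p95 = ss$p95, n_sized = ss$n_sized,
                   n_fluorescent_unsized = ss$n_fluorescent_unsized)
  })
  dplyr::bind_rows(rows)
}
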