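#' Per-spot marker marginals
#'
#' Extracts, from a per-spot colocalization table, the marginal probability
#' that a captured particle is positive for each tetraspanin. The capture
#' marker's marginal is 1 by the capture-positivity convention; each
#' non-capture marker's marginal is the sum of the categories containing it
#' (its double positive plus the triple positive). Counts are carried when
#' the table is count-backed.
#'
#' @param table A [coloc_table()].
#' @return An object of class `marker_marginals`: `spot`, `p` (named over
#'   CD9/CD63/CD81), `n_total` and `n_pos` (`NULL` in fraction-only mode),
#'   and `estimated = TRUE` flagging that the marginals were estimated from
#'   the observed table itself (this matters for test degrees of freedom,
#'   see [test_randomness()]).
#' @export
#' @examples
#' tb <- coloc_table("CD63", fractions = c(0.631, 0.111, 0.103, 0.155))
#' marker_marginals(tb)
marker_marginals <- function(table) {
  stopifnot(inherits(table, "coloc_table"))
  others <- table$markers
  f <- table$fractions
  p <- stats::setNames(rep(1, 3), TETRASPANINS)
  p[others[1]] <- f[[paste0("capture+", others[1])]] + f[["triple"]]
  p[others[2]] <- f[[paste0("capture+", others[2])]] + f[["triple"]]
  n_pos <- NULL
  if (!is.null(table$counts)) {
    cnt <- table$counts
    n_pos <- stats::setNames(rep(table$total, 3), TETRASPANINS)
    n_pos[others[1]] <- cnt[[paste0("capture+", others[1])]] + cnt[["triple"]]
    n_pos[others[2]] <- cnt[[paste0("capture+", others[2])]] + cnt[["triple"]]
  }
  structure(
    list(spot = table$spot, p = p, n_total = table$total, n_pos = n_pos,
         sample_label = table$sample_label, estimated = TRUE),
    class = "marker_marginals")
}

#' Construct marker marginals by hand
#'
#' For marginals that come from an external source rather than from the
#' observed table under test (so the goodness-of-fit test keeps its full
#' 3 degrees of freedom).
#'
#' @param spot Capture spot (`"CD9"`, `"CD63"` or `"CD81"`).
#' @param p Named probabilities for the two non-capture markers (the capture
#'   marker is fixed at 1; supplying it is allowed only as exactly 1).
#' @param n_total Optional particle count behind the marginals.
#' @param sample_label Optional label.
#' @return A `marker_marginals` object with `estimated = FALSE`.
#' @export
manual_marginals <- function(spot, p, n_total = NULL,
                             sample_label = NA_character_) {
  spot <- match_spot(spot, allow_igg = FALSE)
  full <- stats::setNames(rep(1, 3), TETRASPANINS)
  bad <- setdiff(names(p), TETRASPANINS)
  if (length(bad) > 0 || is.null(names(p))) {
    rlang::abort("p must be named with tetraspanin names",
                 class = "tetraspot_validation_error")
  }
  full[names(p)] <- p
  if (any(full < 0) || any(full > 1)) {
    rlang::abort("marginal probabilities must lie in [0, 1]",
                 class = "tetraspot_validation_error")
  }
  if (full[[spot]] != 1) {
    rlang::abort("the capture marker's marginal is 1 by convention",
                 class = "tetraspot_validation_error")
  }
  structure(
    list(spot = spot, p = full, n_total = n_total, n_pos = NULL,
         sample_label = as.character(sample_label), estimated = FALSE),
    class = "marker_marginals")
}

#' @export
print.marker_marginals <- function(x, ...) {
  cat("<marker_marginals> spot:", x$spot,
      if (!is.null(x$n_total)) paste0("n=", x$n_total) else "(fraction-only)",
      "\n")
  cat(" ", paste0("p(", names(x$p), ")=", signif(x$p, 4), collapse = "  "),
      "\n")
  invisible(x)
}

#' Closed-form random-model prediction
#'
#' The random-assignment null model: channel signals are assigned to
#' captured particles independently, each tetraspanin with its per-spot
#' marginal frequency, so the probability of any marker combination is the
#' product of the per-marker probabilities (the complement probability for
#' absent markers). Conditioned on the capture marker (probability 1), with
#' A and B the two non-capture markers:
#' `P(capture-only) = (1-p_A)(1-p_B)`, `P(capture+A) = p_A (1-p_B)`,
#' `P(capture+B) = (1-p_A) p_B`, `P(triple) = p_A p_B`.
#' Deviations of the measured fractions from this prediction indicate
#' non-random (coordinated or exclusive) tetraspanin sorting into vesicles.
#'
#' @param marginals A [marker_marginals()] or [manual_marginals()] object.
#' @return An object of class `random_prediction` with exact `fractions`
#'   over the spot's four categories (`method = "closed_form"`).
#' @export
#' @examples
#' m <- manual_marginals("CD63", c(CD9 = 0.266, CD81 = 0.258))
#' predict_random(m)
predict_random <- function(marginals) {
  stopifnot(inherits(marginals, "marker_marginals"))
  spot <- marginals$spot
  others <- other_markers(spot)
  pa <- marginals$p[[others[1]]]
  pb <- marginals$p[[others[2]]]
  fractions <- stats::setNames(
    c((1 - pa) * (1 - pb), pa * (1 - pb), (1 - pa) * pb, pa * pb),
    coloc_categories(spot))
  structure(
    list(spot = spot, fractions = fractions, method = "closed_form",
         n_draws = NULL, seed = NULL, se = NULL,
         marginals = marginals,
         estimated_params = if (isTRUE(marginals$estimated)) 2L else 0L,
         sample_label = marginals$sample_label),
    class = "random_prediction")
}

#' @export
print.random_prediction <- function(x, ...) {
  cat("<random_prediction>", x$method, "spot:", x$spot, "\n")
  pct <- round_half_up(100 * x$fractions, 1)
  for (i in seq_along(x$fractions)) {
    cat(sprintf("  %-14s %6.1f%%", names(x$fractions)[i], pct[i]))
    if (!is.null(x$se)) cat(sprintf("  (MC SE %.4f)", x$se[i]))
    cat("\n")
  }
  invisible(x)
}

#' Monte-Carlo random reassignment
#'
#' Simulates the random reassignment of channel signals to particles: draws
#' `n_draws` particles, each non-capture marker present independently with
#' its marginal probability, and returns the empirical category fractions
#' with per-category binomial standard errors. Converges to
#' [predict_random()] as `n_draws` grows; useful as a simulation cross-check
#' of the closed form.
#'
#' @param marginals A [marker_marginals()] object.
#' @param n_draws Number of simulated particles (>= 1).
#' @param seed Integer seed; the result is reproducible given the seed.
#' @return A `random_prediction` with `method = "monte_carlo"`, `n_draws`,
#'   `seed` and per-category `se`.
#' @export
simulate_random_reassignment <- function(marginals, n_draws = 10000,
                                         seed = 1L) {
  stopifnot(inherits(marginals, "marker_marginals"), n_draws >= 1)
  spot <- marginals$spot
  others <- other_markers(spot)
  pa <- marginals$p[[others[1]]]
  pb <- marginals$p[[others[2]]]
  counts <- withr::with_seed(seed, {
    a <- stats::runif(n_draws) < pa
    b <- stats::runif(n_draws) < pb
    c(sum(!a & !b), sum(a & !b), sum(!a & b), sum(a & b))
  })
  fractions <- stats::setNames(counts / n_draws, coloc_categories(spot))
  se <- sqrt(fractions * (1 - fractions) / n_draws)
  structure(
    list(spot = spot, fractions = fractions, method = "monte_carlo",
         n_draws = as.integer(n_draws), seed = as.integer(seed), se = se,
         marginals = marginals,
         estimated_params = if (isTRUE(marginals$estimated)) 2L else 0L,
         sample_label = marginals$sample_label),
    class = "random_prediction")
}

#' Measured-versus-predicted deviation report
#'
#' Compares a measured colocalization table with a random-model prediction
#' category by category: fold change (measured / predicted; flagged
#' undefined when the prediction is 0) and direction of deviation. Folds are
#' reported rounded half-away-from-zero to one decimal; full precision is
#' kept in the `fold` column.
#'
#' @param measured A [coloc_table()].
#' @param predicted A `random_prediction` for the same spot.
#' @return A tibble of class `deviation_report` with one row per category:
#'   `spot`, `category`, `measured`, `predicted`, `fold`, `fold_1dp`,
#'   `fold_defined`, `direction` (`"over"`, `"under"`, `"none"`).
#' @export
deviation_fold <- function(measured, predicted) {
  stopifnot(inherits(measured, "coloc_table"),
            inherits(predicted, "random_prediction"))
  if (!identical(measured$spot, predicted$spot)) {
    rlang::abort("measured table and prediction are for different spots",
                 class = "tetraspot_validation_error")
  }
  m <- unname(measured$fractions)
  p <- unname(predicted$fractions[measured$categories])
  eps <- 1e-12
  fold <- ifelse(p > 0, m / p, NA_real_)
  direction <- dplyr::case_when(
    m > p + eps ~ "over",
    m < p - eps ~ "under",
    .default = "none")
  out <- tibble::tibble(
    spot = measured$spot, category = measured$categories,
    measured = m, predicted = p,
    fold = fold, fold_1dp = round_half_up(fold, 1),
    fold_defined = p > 0,
    direction = direction)
  class(out) <- c("deviation_report", class(out))
  out
}

# all 4-category compositions of n; exact multinomial tail probability
.exact_multinomial_p <- function(counts, prob) {
  n <- sum(counts)
  na <- 0:n
  reps_b <- n - na + 1L
  a1 <- rep.int(na, reps_b)
  b1 <- sequence(reps_b) - 1L
  m <- n - a1 - b1
  a <- rep.int(a1, m + 1L)
  b <- rep.int(b1, m + 1L)
  cc <- sequence(m + 1L) - 1L
  d <- n - a - b - cc
  lp <- function(k, p) ifelse(k == 0L, 0, k * log(p))
  logp <- lgamma(n + 1) - lgamma(a + 1) - lgamma(b + 1) - lgamma(cc + 1) -
    lgamma(d + 1) + lp(a, prob[1]) + lp(b, prob[2]) + lp(cc, prob[3]) +
    lp(d, prob[4])
  obs <- lgamma(n + 1) - sum(lgamma(counts + 1)) +
    sum(ifelse(counts == 0L, 0, counts * log(prob)))
  sum(exp(logp[logp <= obs + 1e-7]))
}

.chisq_stat <- function(obs, expected) {
  bad <- expected <= 0
  if (any(bad & obs > 0)) return(Inf)
  sum(((obs - expected)^2 / expected)[!bad])
}

#' Goodness-of-fit test of the random-assignment null
#'
#' Tests whether the observed category counts of one capture spot are
#' consistent with the random-model predicted fractions.
#'
#' Degrees of freedom: when the prediction's marginals were estimated from
#' the observed table itself (the default pipeline,
#' [marker_marginals()] of the same table), the null hypothesis is exactly
#' independence of the two non-capture markers in a 2x2 layout, so the
#' chi-square statistic has `3 - 2 = 1` degrees of freedom; for externally
#' supplied marginals ([manual_marginals()]) all 3 degrees of freedom
#' remain. The exact method likewise switches between Fisher's conditional
#' exact test (self-estimated marginals) and full multinomial enumeration
#' (external marginals, `n <= 200`); the Monte-Carlo method is a parametric
#' bootstrap that re-estimates marginals per draw when they were
#' self-estimated. Any expected count below 5 triggers an automatic fallback
#' from chi-square to the Monte-Carlo method, with a note.
#'
#' @param table A count-backed [coloc_table()], or a fraction-only table
#'   plus `nominal_n` (results are then flagged approximate).
#' @param predicted A `random_prediction` for the same spot; default is
#'   `predict_random(marker_marginals(table))`.
#' @param method `"chi_square"` (default), `"exact_multinomial"` or
#'   `"monte_carlo"`.
#' @param alpha Significance level used for the `reject` flag (default
#'   0.05).
#' @param nominal_n Assumed total count for fraction-only tables.
#' @param n_sims Monte-Carlo draws for the bootstrap method (default 2000).
#' @param seed Seed for the Monte-Carlo method.
#' @return An object of class `randomness_test`: `spot`, `statistic`, `df`,
#'   `p_value`, `method` (the method actually used), `reject`, `alpha`,
#'   `approximate` (fraction-only mode), `notes`, and `deviations` (the
#'   [deviation_fold()] tibble).
#' @export
test_randomness <- function(table, predicted = NULL,
                            method = c("chi_square", "exact_multinomial",
                                       "monte_carlo"),
                            alpha = 0.05, nominal_n = NULL, n_sims = 2000,
                            seed = 1L) {
  stopifnot(inherits(table, "coloc_table"))
  method <- match.arg(method)
  if (is.null(predicted)) {
    predicted <- predict_random(marker_marginals(table))
  }
  stopifnot(inherits(predicted, "random_prediction"))
  if (!identical(table$spot, predicted$spot)) {
    rlang::abort("table and prediction are for different spots",
                 class = "tetraspot_validation_error")
  }
  notes <- character(0)
  approximate <- FALSE
  if (!is.null(table$counts)) {
    counts <- unname(table$counts)
  } else {
    if (is.null(nominal_n)) {
      rlang::abort(paste0("fraction-only table has no counts; supply ",
                          "`nominal_n` for an approximate test"),
                   class = "tetraspot_validation_error")
    }
    counts <- round(unname(table$fractions) * nominal_n)
    approximate <- TRUE
    notes <- c(notes, sprintf(
      "counts reconstructed from fractions at nominal n = %d; p-value approximate",
      as.integer(nominal_n)))
  }
  n <- sum(counts)
  prob <- unname(predicted$fractions[table$categories])
  expected <- n * prob
  df <- max(1L, 3L - predicted$estimated_params)
  self_estimated <- predicted$estimated_params > 0L

  if (method == "chi_square" && any(expected < 5)) {
    notes <- c(notes, sprintf(
      "expected count below 5 (min %.2f); fell back to monte_carlo",
      min(expected)))
    method <- "monte_carlo"
  }
  if (method == "exact_multinomial" && !self_estimated && n > 200) {
    notes <- c(notes, "n > 200: exact enumeration infeasible; fell back to monte_carlo")
    method <- "monte_carlo"
  }

  if (method == "chi_square") {
    statistic <- .chisq_stat(counts, expected)
    p_value <- stats::pchisq(statistic, df = df, lower.tail = FALSE)
  } else if (method == "exact_multinomial") {
    if (self_estimated) {
      # categories (c0, A, B, AB) form the 2x2 table of A x B positivity;
      # conditioning on the observed margins gives Fisher's exact test
      tab <- matrix(c(counts[4], counts[2], counts[3], counts[1]), 2L)
      ft <- stats::fisher.test(tab)
      statistic <- unname(ft$estimate)
      p_value <- ft$p.value
      notes <- c(notes,
                 "self-estimated marginals: conditional exact (Fisher) test")
    } else {
      statistic <- .chisq_stat(counts, expected)
      p_value <- .exact_multinomial_p(counts, prob)
    }
  } else {
    statistic <- .chisq_stat(counts, expected)
    p_value <- withr::with_seed(seed, {
      draws <- stats::rmultinom(n_sims, n, prob)
      stat_b <- if (self_estimated) {
        pa <- (draws[2, ] + draws[4, ]) / n
        pb <- (draws[3, ] + draws[4, ]) / n
        eb <- rbind((1 - pa) * (1 - pb), pa * (1 - pb),
                    (1 - pa) * pb, pa * pb) * n
        term <- (draws - eb)^2 / eb
        term[eb == 0 & draws == 0] <- 0
        term[eb == 0 & draws > 0] <- Inf
        colSums(term)
      } else {
        colSums((draws - expected)^2 / pmax(expected, .Machine$double.eps))
      }
      (1 + sum(stat_b >= statistic - 1e-9)) / (n_sims + 1)
    })
  }
  structure(
    list(spot = table$spot, statistic = statistic, df = df,
         p_value = p_value, method = method, alpha = alpha,
         reject = p_value < alpha, approximate = approximate, notes = notes,
         n = n, deviations = deviation_fold(table, predicted),
         sample_label = table$sample_label),
    class = "randomness_test")
}

#' @export
print.randomness_test <- function(x, ...) {
  cat("<randomness_test> spot:", x$spot, "| method:", x$method,
      sprintf("| stat %.3f df %d p %.4g%s", x$statistic, x$df, x$p_value,
              if (x$approximate) " (approx.)" else ""), "\n")
  if (length(x$notes)) cat("  note:", paste(x$notes, collapse = "; "), "\n")
  print(x$deviations[c("category", "measured", "predicted", "fold_1dp",
                       "direction")])
  invisible(x)
}

#' Full randomness report over an experiment or set of tables
#'
#' Runs marginals, closed-form prediction, fold deviations and the
#' goodness-of-fit test for every spot, and applies Benjamini-Hochberg
#' adjustment across all tests in the report.
#'
#' @param x A [chip_experiment()] or a list of [coloc_table()] objects (e.g.
#'   from [read_fraction_table()]).
#' @inheritParams test_randomness
#' @return A tibble of class `randomness_report`, one row per sample x spot
#'   x category: measured and predicted percentages, fold, direction,
#'   statistic, `p_value`, `p_adjusted` (BH across spots), method and
#'   flags. The underlying `randomness_test` objects are in
#'   `attr(, "tests")`.
#' @export
randomness_report <- function(x, method = "chi_square", alpha = 0.05,
                              nominal_n = NULL, n_sims = 2000, seed = 1L) {
  tables <- if (inherits(x, "chip_experiment")) {
    tabulate_experiment(x)
  } else if (inherits(x, "coloc_table")) {
    list(x)
  } else {
    stopifnot(is.list(x), all(vapply(x, inherits, logical(1), "coloc_table")))
    x
  }
  tests <- lapply(tables, test_randomness, method = method, alpha = alpha,
                  nominal_n = nominal_n, n_sims = n_sims, seed = seed)
  p_adj <- stats::p.adjust(vapply(tests, `[[`, numeric(1), "p_value"),
                           method = "BH")
  rows <- dplyr::bind_rows(lapply(seq_along(tests), function(i) {
    tt <- tests[[i]]
    dev <- tt$deviations
    tibble::tibble(
      sample = tt$sample_label, spot = dev$spot, category = dev$category,
      measured_pct = round_half_up(100 * dev$measured, 1),
      predicted_pct = round_half_up(100 * dev$predicted, 1),
      fold = dev$fold_1dp, direction = dev$direction,
      statistic = tt$statistic, df = tt$df, p_value = tt$p_value,
      p_adjusted = p_adj[i], method = tt$method,
      approximate = tt$approximate,
      flags = paste(tt$notes, collapse = "; "))
  }))
  attr(rows, "tests") <- tests
  attr(rows, "adjustment") <- "BH"
  class(rows) <- c("randomness_report", class(rows))
  rows
}
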