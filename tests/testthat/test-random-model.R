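test_that("marker marginals sum the categories containing each marker", {
  tb <- published_table("msc_hpl_cd63")
  m <- marker_marginals(tb)
  expect_equal(m$p[["CD9"]], 0.266, tolerance = 1e-12)
  expect_equal(m$p[["CD81"]], 0.258, tolerance = 1e-12)
  expect_equal(m$p[["CD63"]], 1)
  expect_true(m$estimated)

  # counts are carried in count mode
  tbc <- coloc_table("CD9", counts = c(50, 20, 20, 10))
  mc <- marker_marginals(tbc)
  expect_equal(mc$n_pos[["CD63"]], 30)
  expect_equal(mc$n_pos[["CD81"]], 30)
  expect_equal(mc$n_pos[["CD9"]], 100)
  expect_equal(mc$n_total, 100)

  # capture-only table: both non-capture marginals zero
  m0 <- marker_marginals(coloc_table("CD81", counts = c(7, 0, 0, 0)))
  expect_equal(unname(m0$p[c("CD9", "CD63")]), c(0, 0))
})

test_that("the product-rule prediction is exact and self-consistent", {
  # degenerate marginals
  m0 <- manual_marginals("CD63", c(CD9 = 0, CD81 = 0))
  expect_equal(predict_random(m0)$fractions[["capture_only"]], 1)
  m1 <- manual_marginals("CD63", c(CD9 = 1, CD81 = 1))
  expect_equal(predict_random(m1)$fractions[["triple"]], 1)

  # fractions sum to 1 and marginals -> prediction -> marginals is identity
  set.seed(17)
  for (i in 1:25) {
    spot <- sample(TETRASPANINS, 1)
    p <- stats::runif(2)
    others <- setdiff(TETRASPANINS, spot)
    m <- manual_marginals(spot, stats::setNames(p, others))
    pred <- predict_random(m)
    expect_equal(sum(pred$fractions), 1, tolerance = 1e-12)
    tb <- coloc_table(spot, fractions = pred$fractions)
    m2 <- marker_marginals(tb)
    expect_equal(m2$p, m$p, tolerance = 1e-12)
  }
})

test_that("published near-miss predicted pairs agree within one rounding step", {
  # two printed predictions carry an extra upstream rounding step; they
  # reproduce to within 0.1 of a percentage point, not exactly
  expect_lt(abs(predicted_pct("msc_hpl_cd9", "capture_only") - 69.3), 0.15)
  expect_lt(abs(predicted_pct("msc_hpl_cd9", "triple") - 2.7), 0.15)
  expect_lt(abs(predicted_pct("msc_fcs_cd63", "capture_only") - 28.2), 0.15)
})

test_that("Monte-Carlo reassignment matches the closed form and is seed-stable", {
  m <- marker_marginals(published_table("msc_hpl_cd63"))
  closed <- predict_random(m)
  mc <- simulate_random_reassignment(m, n_draws = 1e5, seed = 42)
  expect_true(all(abs(mc$fractions - closed$fractions) <=
                    3 * pmax(mc$se, 1e-12)))
  expect_equal(sum(mc$fractions), 1, tolerance = 1e-12)

  mc2 <- simulate_random_reassignment(m, n_draws = 1e5, seed = 42)
  expect_identical(mc$fractions, mc2$fractions)

  # degenerate marginals: all mass on capture+A for any seed
  md <- manual_marginals("CD63", c(CD9 = 1, CD81 = 0))
  for (seed in c(1, 2, 3)) {
    dr <- simulate_random_reassignment(md, n_draws = 500, seed = seed)
    expect_equal(dr$fractions[["capture+CD9"]], 1)
  }
})

test_that("deviation folds track the sign and ratio of measured vs predicted", {
  m <- manual_marginals("CD63", c(CD9 = 0.5, CD81 = 0.5))
  pred <- predict_random(m)
  same <- coloc_table("CD63", fractions = pred$fractions)
  dev <- deviation_fold(same, pred)
  expect_equal(dev$fold, rep(1, 4))
  expect_true(all(dev$direction == "none"))

  # predicted 0 with measured > 0: fold undefined, direction over
  m0 <- manual_marginals("CD63", c(CD9 = 0, CD81 = 0))
  meas <- coloc_table("CD63", fractions = c(0.9, 0.05, 0.05, 0))
  dev0 <- deviation_fold(meas, predict_random(m0))
  expect_false(dev0$fold_defined[dev0$category == "capture+CD9"])
  expect_true(is.na(dev0$fold[dev0$category == "capture+CD9"]))
  expect_equal(dev0$direction[dev0$category == "capture+CD9"], "over")

  # fold > 1 iff measured > predicted, on a generic table
  tb <- published_table("hfl1_cd63")
  devg <- deviation_fold(tb, predict_random(marker_marginals(tb)))
  expect_equal(devg$fold > 1, devg$measured > devg$predicted)

  # spot mismatch between table and prediction is refused
  m_cd9 <- manual_marginals("CD9", c(CD63 = 0.5, CD81 = 0.5))
  expect_error(deviation_fold(tb, predict_random(m_cd9)),
               class = "tetraspot_validation_error")
})

test_that("counts exactly proportional to the prediction give statistic 0, p 1", {
  m <- manual_marginals("CD9", c(CD63 = 0.5, CD81 = 0.5))
  tb <- coloc_table("CD9", counts = c(25, 25, 25, 25))
  tt <- test_randomness(tb, predict_random(m), method = "chi_square")
  expect_equal(tt$statistic, 0)
  expect_equal(tt$p_value, 1)
  expect_equal(tt$df, 3)  # external marginals keep 3 df
  expect_false(tt$reject)

  # self-estimated marginals reduce to 1 df
  tt2 <- test_randomness(coloc_table("CD9", counts = c(36, 24, 24, 16)))
  expect_equal(tt2$df, 1)
  expect_equal(tt2$statistic, 0, tolerance = 1e-12)
})

test_that("exact multinomial enumeration matches a brute-force oracle at tiny n", {
  brute <- function(counts, prob) {
    n <- sum(counts)
    p_obs <- stats::dmultinom(counts, prob = prob)
    total <- 0
    for (a in 0:n) for (b in 0:(n - a)) for (cc in 0:(n - a - b)) {
      x <- c(a, b, cc, n - a - b - cc)
      px <- stats::dmultinom(x, prob = prob)
      if (px <= p_obs * (1 + 1e-7)) total <- total + px
    }
    total
  }
  prob <- c(0.4, 0.3, 0.2, 0.1)
  for (counts in list(c(5, 3, 2, 2), c(12, 0, 0, 0), c(2, 2, 4, 4))) {
    expect_equal(tetraspot:::.exact_multinomial_p(counts, prob),
                 brute(counts, prob), tolerance = 1e-9)
  }
  # and through the user-facing test with external marginals
  m <- manual_marginals("CD81", c(CD9 = 0.4, CD63 = 0.25))
  tb <- coloc_table("CD81", counts = c(10, 5, 3, 2))
  tt <- test_randomness(tb, predict_random(m), method = "exact_multinomial")
  pr <- predict_random(m)$fractions
  expect_equal(tt$p_value,
               brute(c(10, 5, 3, 2), unname(pr)), tolerance = 1e-9)
})

test_that("low expected counts trigger the documented fallback", {
  m <- manual_marginals("CD63", c(CD9 = 0.01, CD81 = 0.5))
  tb <- coloc_table("CD63", counts = c(50, 1, 48, 1))
  tt <- test_randomness(tb, predict_random(m), method = "chi_square",
                        seed = 5)
  expect_equal(tt$method, "monte_carlo")
  expect_match(paste(tt$notes, collapse = " "), "fell back")
})

test_that("fraction-only tables test only with a nominal n, clearly flagged", {
  tb <- published_table("hmec1_cd63")
  expect_error(test_randomness(tb), class = "tetraspot_validation_error")
  tt <- test_randomness(tb, nominal_n = 300)
  expect_true(tt$approximate)
  expect_match(paste(tt$notes, collapse = " "), "nominal")
})

test_that("report rows carry BH-adjusted p-values across spots", {
  exp <- simulate_chip(sim_config(n_vesicles = 4000, seed = 51))
  rep <- randomness_report(exp)
  tests <- attr(rep, "tests")
  p <- vapply(tests, `[[`, numeric(1), "p_value")
  adj <- stats::p.adjust(p, method = "BH")
  for (i in seq_along(tests)) {
    expect_equal(unique(rep$p_adjusted[rep$spot == tests[[i]]$spot]),
                 unname(adj[i]))
  }
  expect_equal(nrow(rep), 12)
})
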