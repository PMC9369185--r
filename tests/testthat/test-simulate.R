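test_that("sim_config validates its probability and rate fields", {
  expect_s3_class(sim_config(), "sim_config")
  bad <- independent_phenotype_probs(c(CD9 = 0.4, CD63 = 0.4, CD81 = 0.4))
  expect_error(sim_config(phenotype_probs = bad * 1.01),
               class = "tetraspot_validation_error")
  expect_error(sim_config(fn_rate = 1.2))
  expect_error(sim_config(capture_affinity = c(CD9 = -1, CD63 = 1, CD81 = 1)),
               class = "tetraspot_validation_error")
})

test_that("sampling respects degenerate and generic phenotype distributions", {
  triple <- "CD9+CD63+CD81+"
  probs <- stats::setNames(rep(0, 8), phenotype_levels())
  probs[triple] <- 1
  cfg <- sim_config(n_vesicles = 500, phenotype_probs = probs, seed = 3)
  pop <- sample_population(cfg, seed = 3)
  expect_true(all(pop$phenotype == triple))
  expect_true(all(pop$cd9 & pop$cd63 & pop$cd81))

  # empirical frequencies within the 4-SE binomial band of their probability
  cfg2 <- sim_config(n_vesicles = 100000, seed = 4)
  pop2 <- sample_population(cfg2, seed = 4)
  freq <- table(factor(pop2$phenotype, levels = phenotype_levels())) /
    cfg2$n_vesicles
  p <- cfg2$phenotype_probs
  bound <- 4 * sqrt(p * (1 - p) / cfg2$n_vesicles)
  expect_true(all(abs(as.numeric(freq) - p) <= bound))

  # same seed twice: identical populations
  expect_identical(sample_population(cfg2, seed = 11),
                   sample_population(cfg2, seed = 11))
})

test_that("capture respects antigen eligibility, affinity shares and background", {
  triple <- "CD9+CD63+CD81+"
  probs <- stats::setNames(rep(0, 8), phenotype_levels())
  probs[triple] <- 1
  cfg <- sim_config(n_vesicles = 30000, phenotype_probs = probs,
                    background_rate = 0, seed = 5)
  pop <- sample_population(cfg, seed = 5)
  cap <- simulate_capture(pop, cfg, seed = 5)
  shares <- table(factor(cap$spot, levels = TETRASPANINS)) / cfg$n_vesicles
  expect_true(all(abs(as.numeric(shares) - 1 / 3) <=
                    4 * sqrt((1 / 3) * (2 / 3) / cfg$n_vesicles)))
  # all-triple population with background 0: empty IgG, nothing dropped
  expect_equal(sum(cap$spot == IGG_CONTROL, na.rm = TRUE), 0)
  expect_equal(cap$n_background, 0)
  expect_equal(cap$n_dropped, 0)

  # a CD9-only population never lands on CD63 or CD81 spots
  probs9 <- stats::setNames(rep(0, 8), phenotype_levels())
  probs9["CD9+CD63-CD81-"] <- 1
  cfg9 <- sim_config(n_vesicles = 5000, phenotype_probs = probs9,
                     background_rate = 0, seed = 6)
  pop9 <- sample_population(cfg9, seed = 6)
  cap9 <- simulate_capture(pop9, cfg9, seed = 6)
  expect_equal(sum(cap9$spot %in% c("CD63", "CD81"), na.rm = TRUE), 0)
  # vesicles that encountered a non-matching spot are dropped and counted
  expect_equal(cap9$n_dropped + sum(!is.na(cap9$spot)), cfg9$n_vesicles)
  expect_gt(cap9$n_dropped, 0)
})

test_that("noiseless detection reproduces ground truth channel flags", {
  cfg <- sim_config(n_vesicles = 3000, fn_rate = 0, fp_rate = 0, seed = 7)
  exp <- simulate_chip(cfg)
  truth <- attr(exp, "truth")
  expect_identical(exp$particles$cd9_pos, truth$true_cd9)
  expect_identical(exp$particles$cd63_pos, truth$true_cd63)
  expect_identical(exp$particles$cd81_pos, truth$true_cd81)
})

test_that("shrinkage and the sizing floor censor sizes as the log-normal law predicts", {
  cfg <- sim_config(n_vesicles = 20000, shrinkage_factor = 0.8,
                    sizing_floor_nm = 50, size_log_mean = log(60),
                    size_log_sd = 0.25, background_rate = 0, seed = 8)
  exp <- simulate_chip(cfg)
  truth <- attr(exp, "truth")
  sized <- !is.na(exp$particles$size_nm)
  expect_true(all(exp$particles$size_nm[sized] >= 50))
  # observed = shrunk true size at 0.01 nm report quantization
  expect_equal(exp$particles$size_nm[sized],
               round(truth$true_size_nm[sized] * 0.8, 2))
  # fraction unsized matches the closed-form log-normal tail P(true < 62.5)
  p_unsized <- stats::plnorm(50 / 0.8, log(60), 0.25)
  frac <- mean(!sized)
  n <- nrow(exp$particles)
  expect_lt(abs(frac - p_unsized),
            4 * sqrt(p_unsized * (1 - p_unsized) / n))
})

test_that("channel false negatives thin the triple fraction as (1-fn)^2", {
  triple <- "CD9+CD63+CD81+"
  probs <- stats::setNames(rep(0, 8), phenotype_levels())
  probs[triple] <- 1
  fn <- 0.1
  cfg <- sim_config(n_vesicles = 30000, phenotype_probs = probs,
                    fn_rate = fn, fp_rate = 0, background_rate = 0, seed = 9)
  exp <- simulate_chip(cfg)
  for (spot in TETRASPANINS) {
    tb <- tabulate_spot(exp, spot, include_nonfluorescent = TRUE)
    expected <- (1 - fn)^2
    se <- sqrt(expected * (1 - expected) / tb$total)
    expect_lt(abs(tb$fractions[["triple"]] - expected), 4 * se)
  }
})

test_that("identical configs give byte-identical serialized experiments", {
  cfg <- sim_config(n_vesicles = 1500, seed = 10)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_particle_table(simulate_chip(cfg), f1)
  write_particle_table(simulate_chip(cfg), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
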