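#' Configuration of a synthetic chip experiment
#'
#' Defines the ground truth and measurement model of the forward simulator:
#' a joint tetraspanin phenotype distribution over all 8 marker sets
#' (including the marker-negative set, i.e. contaminant-like particles), a
#' log-normal true-size law, multiplicative drying shrinkage, the
#' interferometric sizing floor below which fluorescent particles stay
#' unsized, independent per-channel false-negative/false-positive rates,
#' relative capture-spot affinities and a nonspecific IgG background rate.
#'
#' Defaults emulate a typical small-EV preparation on a three-tetraspanin
#' chip: median true diameter 60 nm with a 5-95 percentile band of roughly
#' 40-110 nm, 15% shrinkage on drying, 50 nm sizing floor, 2% channel error
#' rates, equal spot affinities, and marker prevalences 65/55/50% for
#' CD9/CD63/CD81 assigned independently across markers (so ~8% of particles
#' are marker-negative contaminants ending up on the IgG control).
#'
#' @param n_vesicles Number of true vesicles to simulate.
#' @param phenotype_probs Named numeric of length 8 over [phenotype_levels()]
#'   summing to 1 (tolerance 1e-12).
#' @param size_log_mean,size_log_sd Log-normal parameters of the true
#'   diameter in ln-nm.
#' @param shrinkage_factor Multiplicative factor in (0, 1] applied to true
#'   size before sizing (vesicles shrink when the chip is dried).
#' @param sizing_floor_nm Observed sizes below this are recorded as unsized.
#' @param fn_rate,fp_rate Per-channel probability that a truly present
#'   (absent) marker reads negative (positive).
#' @param capture_affinity Named non-negative weights for the three
#'   tetraspanin spots; relative encounter probabilities.
#' @param background_rate Expected nonspecific IgG-spot particles per
#'   captured tetraspanin-spot particle (Poisson).
#' @param seed Integer seed making the whole simulation reproducible.
#' @param sample_label,chip_id Labels stamped into the generated experiment.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_vesicles = 10000,
                       phenotype_probs = independent_phenotype_probs(
                         c(CD9 = 0.65, CD63 = 0.55, CD81 = 0.50)),
                       size_log_mean = log(60),
                       size_log_sd = 0.25,
                       shrinkage_factor = 0.85,
                       sizing_floor_nm = 50,
                       fn_rate = 0.02,
                       fp_rate = 0.02,
                       capture_affinity = c(CD9 = 1, CD63 = 1, CD81 = 1),
                       background_rate = 0.02,
                       seed = 1L,
                       sample_label = "simulated",
                       chip_id = "SIM1") {
  levels <- phenotype_levels()
  if (length(phenotype_probs) != 8L) {
    rlang::abort("phenotype_probs must have length 8",
                 class = "tetraspot_validation_error")
  }
  if (is.null(names(phenotype_probs))) {
    names(phenotype_probs) <- levels
  }
  if (!setequal(names(phenotype_probs), levels)) {
    rlang::abort("phenotype_probs names must be phenotype_levels()",
                 class = "tetraspot_validation_error")
  }
  phenotype_probs <- phenotype_probs[levels]
  if (any(phenotype_probs < 0) || abs(sum(phenotype_probs) - 1) > 1e-12) {
    rlang::abort("phenotype_probs must be non-negative and sum to 1 (1e-12)",
                 class = "tetraspot_validation_error")
  }
  stopifnot(n_vesicles >= 1, size_log_sd > 0,
            shrinkage_factor > 0, shrinkage_factor <= 1,
            sizing_floor_nm > 0,
            fn_rate >= 0, fn_rate <= 1, fp_rate >= 0, fp_rate <= 1,
            background_rate >= 0)
  if (!setequal(names(capture_affinity), TETRASPANINS) ||
      any(capture_affinity < 0) || sum(capture_affinity) <= 0) {
    rlang::abort("capture_affinity must be non-negative weights named CD9, CD63, CD81",
                 class = "tetraspot_validation_error")
  }
  structure(
    list(n_vesicles = as.integer(n_vesicles),
         phenotype_probs = phenotype_probs,
         size_log_mean = size_log_mean, size_log_sd = size_log_sd,
         shrinkage_factor = shrinkage_factor,
         sizing_floor_nm = sizing_floor_nm,
         fn_rate = fn_rate, fp_rate = fp_rate,
         capture_affinity = capture_affinity[TETRASPANINS],
         background_rate = background_rate,
         seed = as.integer(seed),
         sample_label = sample_label, chip_id = chip_id),
    class = "sim_config")
}

#' Joint phenotype distribution with independent markers
#'
#' Builds the 8-way phenotype distribution in which each tetraspanin is
#' present independently with its marginal prevalence — the ground truth
#' under which the random-assignment null model is exactly correct.
#'
#' @param prevalence Named numeric over `CD9`, `CD63`, `CD81` in \[0, 1\].
#' @return Named probability vector of length 8 over [phenotype_levels()].
#' @export
#' @examples
#' independent_phenotype_probs(c(CD9 = 0.3, CD63 = 0.3, CD81 = 0.3))
independent_phenotype_probs <- function(prevalence) {
  stopifnot(setequal(names(prevalence), TETRASPANINS),
            all(prevalence >= 0), all(prevalence <= 1))
  p <- prevalence[TETRASPANINS]
  levels <- phenotype_levels()
  probs <- vapply(levels, function(lv) {
    m <- parse_marker_set(lv)
    prod(ifelse(m, p, 1 - p))
  }, numeric(1))
  probs / sum(probs)
}

#' Shift phenotype mass from single-positive phenotypes to the triple
#'
#' Produces an alternative (non-random) ground truth by moving `shift` total
#' probability mass out of the three single-positive phenotypes
#' (proportionally to their mass) into the triple-positive phenotype; used to
#' study the power of the randomness test against coordinated tetraspanin
#' sorting.
#'
#' @param phenotype_probs Named probability vector over [phenotype_levels()].
#' @param shift Total probability mass to move (default 0.15).
#' @return Named probability vector of length 8.
#' @export
shift_singles_to_triple <- function(phenotype_probs, shift = 0.15) {
  levels <- phenotype_levels()
  phenotype_probs <- phenotype_probs[levels]
  singles <- vapply(levels, function(lv) sum(parse_marker_set(lv)) == 1L,
                    logical(1))
  triple <- levels[vapply(levels, function(lv) all(parse_marker_set(lv)),
                          logical(1))]
  avail <- sum(phenotype_probs[singles])
  if (avail < shift) {
    rlang::abort(sprintf(
      "single-positive phenotypes carry only %.3f mass; cannot move %.3f",
      avail, shift), class = "tetraspot_validation_error")
  }
  out <- phenotype_probs
  out[singles] <- out[singles] * (1 - shift / avail)
  out[triple] <- out[triple] + shift
  out / sum(out)
}

#' Sample a ground-truth vesicle population
#'
#' Draws `n_vesicles` i.i.d. phenotypes from `phenotype_probs` and i.i.d.
#' log-normal true diameters. Uses the current RNG stream unless `seed` is
#' given.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return A tibble of class `true_population` with columns `vesicle_id`,
#'   `phenotype`, `cd9`, `cd63`, `cd81`, `true_size_nm`.
#' @export
sample_population <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  draw <- function() {
    levels <- phenotype_levels()
    idx <- sample.int(8L, config$n_vesicles, replace = TRUE,
                      prob = config$phenotype_probs)
    phen <- levels[idx]
    flags <- t(vapply(levels, parse_marker_set, logical(3)))[idx, ,
                                                            drop = FALSE]
    tibble::tibble(
      vesicle_id = seq_len(config$n_vesicles),
      phenotype = phen,
      cd9 = unname(flags[, "CD9"]), cd63 = unname(flags[, "CD63"]),
      cd81 = unname(flags[, "CD81"]),
      true_size_nm = stats::rlnorm(config$n_vesicles,
                                   config$size_log_mean, config$size_log_sd))
  }
  pop <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  class(pop) <- c("true_population", class(pop))
  pop
}

#' Assign vesicles to capture spots
#'
#' Capture model: each vesicle encounters exactly one anti-tetraspanin spot,
#' drawn with probability proportional to `capture_affinity`, and is
#' immobilized there if and only if it truly bears that spot's antigen;
#' otherwise it is washed away (dropped, counted). Marker-negative vesicles
#' adhere nonspecifically to the IgG isotype-control spot, as does an
#' additional Poisson(`background_rate` x number captured) stream of
#' contaminant particles. Because the encountered spot is independent of the
#' vesicle's other markers, the distribution of the two non-capture markers
#' among particles captured on a spot equals their population distribution
#' conditional on the capture marker — conditional independence in the
#' ground truth is preserved on-spot, so the random null is self-consistent
#' with an independent-marker population.
#'
#' @param population A [sample_population()] result.
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @return A list of class `capture_assignment`: `spot` (character per
#'   vesicle, `NA` = washed away), `n_background` (extra IgG contaminant
#'   particles), `n_dropped`.
#' @export
simulate_capture <- function(population, config, seed = NULL) {
  stopifnot(inherits(population, "true_population"),
            inherits(config, "sim_config"))
  if (nrow(population) == 0) {
    rlang::abort("population is empty", class = "tetraspot_validation_error")
  }
  draw <- function() {
    n <- nrow(population)
    w <- config$capture_affinity / sum(config$capture_affinity)
    encountered <- TETRASPANINS[sample.int(3L, n, replace = TRUE, prob = w)]
    bears <- cbind(CD9 = population$cd9, CD63 = population$cd63,
                   CD81 = population$cd81)
    caught <- bears[cbind(seq_len(n), match(encountered, TETRASPANINS))]
    spot <- ifelse(caught, encountered, NA_character_)
    negative <- !population$cd9 & !population$cd63 & !population$cd81
    spot[negative] <- IGG_CONTROL
    n_captured <- sum(spot %in% TETRASPANINS)
    n_background <- stats::rpois(1L, config$background_rate * n_captured)
    list(spot = spot, n_background = n_background,
         n_dropped = sum(is.na(spot)))
  }
  out <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  class(out) <- "capture_assignment"
  out
}

#' Simulate fluorescence detection and interferometric sizing
#'
#' Applies the measurement model to captured vesicles: each channel flag is
#' the true marker state flipped independently with `fn_rate` (present reads
#' negative) or `fp_rate` (absent reads positive); the observed diameter is
#' the true diameter times `shrinkage_factor`, recorded only when it reaches
#' the sizing floor, otherwise the particle is fluorescent-but-unsized.
#' Contaminant background particles on the IgG spot are marker-negative in
#' truth (channels can still fire at `fp_rate`) with sizes from the same
#' size law. Ground truth is retained in the `truth` attribute for oracle
#' tests; it is not serialized by [write_particle_table()].
#'
#' @param assignment A [simulate_capture()] result.
#' @param population The matching [sample_population()] result.
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @return A [chip_experiment()]; `attr(, "truth")` holds per-particle ground
#'   truth (`true_cd9/63/81`, `true_size_nm`, `is_background`).
#' @export
simulate_detection <- function(assignment, population, config, seed = NULL) {
  stopifnot(inherits(assignment, "capture_assignment"),
            inherits(population, "true_population"),
            inherits(config, "sim_config"),
            length(assignment$spot) == nrow(population))
  draw <- function() {
    keep <- !is.na(assignment$spot)
    truth <- tibble::tibble(
      spot = assignment$spot[keep],
      true_cd9 = population$cd9[keep],
      true_cd63 = population$cd63[keep],
      true_cd81 = population$cd81[keep],
      true_size_nm = population$true_size_nm[keep],
      is_background = FALSE)
    nb <- assignment$n_background
    if (nb > 0) {
      truth <- dplyr::bind_rows(truth, tibble::tibble(
        spot = rep(IGG_CONTROL, nb),
        true_cd9 = FALSE, true_cd63 = FALSE, true_cd81 = FALSE,
        true_size_nm = stats::rlnorm(nb, config$size_log_mean,
                                     config$size_log_sd),
        is_background = TRUE))
    }
    n <- nrow(truth)
    flip <- function(truth_flag) {
      u <- stats::runif(n)
      ifelse(truth_flag, u >= config$fn_rate, u < config$fp_rate)
    }
    # observed sizes are quantized to 0.01 nm, instrument-report style
    shrunk <- round(truth$true_size_nm * config$shrinkage_factor, 2)
    size_obs <- ifelse(shrunk >= config$sizing_floor_nm, shrunk, NA_real_)
    particles <- tibble::tibble(
      chip_id = config$chip_id, bio_rep = 1L, tech_rep = 1L,
      particle_id = sprintf("P%06d", seq_len(n)),
      spot = truth$spot,
      cd9_pos = flip(truth$true_cd9),
      cd63_pos = flip(truth$true_cd63),
      cd81_pos = flip(truth$true_cd81),
      size_nm = size_obs)
    exp <- chip_experiment(particles, sample_label = config$sample_label,
                           sizing_floor_nm = config$sizing_floor_nm)
    attr(exp, "truth") <- dplyr::bind_cols(
      tibble::tibble(particle_id = particles$particle_id), truth)
    attr(exp, "n_dropped") <- assignment$n_dropped
    exp
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Run the full chip simulator
#'
#' Convenience wrapper: seeds the RNG once with `config$seed`, then runs
#' [sample_population()], [simulate_capture()] and [simulate_detection()].
#' Identical configs produce byte-identical serialized experiments.
#'
#' @param config A [sim_config()].
#' @return A [chip_experiment()] with ground truth attached (see
#'   [simulate_detection()]).
#' @export
#' @examples
#' exp <- simulate_chip(sim_config(n_vesicles = 500, seed = 7))
#' exp
simulate_chip <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    pop <- sample_population(config)
    cap <- simulate_capture(pop, config)
    simulate_detection(cap, pop, config)
  })
}
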