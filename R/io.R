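#' Construct a chip experiment
#'
#' A `chip_experiment` holds every particle detected on one multiplexed
#' immunocapture chip (or a set of replicate chips for one sample): one row
#' per particle with its capture spot, three fluorescence-channel positivity
#' flags and, when the particle was large enough to be sized
#' interferometrically, its diameter in nm. Particles with sufficient
#' fluorescence are detected irrespective of size, so `size_nm` may be `NA`
#' (fluorescent-but-unsized).
#'
#' @param particles A data frame with columns `chip_id` (character),
#'   `bio_rep`, `tech_rep` (integer replicate indices), `particle_id`
#'   (character, unique within `chip_id`), `spot` (one of CD9/CD63/CD81/IgG),
#'   `cd9_pos`, `cd63_pos`, `cd81_pos` (logical) and `size_nm` (numeric, `NA`
#'   for unsized particles).
#' @param sample_label Character label of the biological sample.
#' @param sizing_floor_nm Smallest interferometrically sizable diameter in nm
#'   (default 50, the platform's stated floor). Recorded sizes below the floor
#'   are a validation error.
#' @param channel_map Named character vector mapping detection channel labels
#'   to tetraspanins; must be a bijection onto `CD9`, `CD63`, `CD81`.
#' @return An object of class `chip_experiment`.
#' @export
chip_experiment <- function(particles,
                            sample_label = "sample",
                            sizing_floor_nm = 50,
                            channel_map = c(CF488 = "CD9", CF555 = "CD81",
                                            CF647 = "CD63")) {
  particles <- tibble::as_tibble(particles)
  required <- c("chip_id", "bio_rep", "tech_rep", "particle_id", "spot",
                "cd9_pos", "cd63_pos", "cd81_pos", "size_nm")
  missing <- setdiff(required, names(particles))
  if (length(missing) > 0) {
    rlang::abort(paste0("particle table is missing column(s): ",
                        paste(missing, collapse = ", ")),
                 class = "tetraspot_format_error")
  }
  particles <- particles[required]
  particles$chip_id <- as.character(particles$chip_id)
  particles$bio_rep <- as.integer(particles$bio_rep)
  particles$tech_rep <- as.integer(particles$tech_rep)
  particles$particle_id <- as.character(particles$particle_id)
  particles$spot <- vapply(particles$spot, match_spot, character(1))
  for (col in c("cd9_pos", "cd63_pos", "cd81_pos")) {
    if (!is.logical(particles[[col]])) {
      rlang::abort(paste0("column '", col, "' must be logical"),
                   class = "tetraspot_format_error")
    }
    if (anyNA(particles[[col]])) {
      rlang::abort(paste0("column '", col, "' contains missing values"),
                   class = "tetraspot_validation_error")
    }
  }
  particles$size_nm <- as.numeric(particles$size_nm)

  dup <- duplicated(particles[c("chip_id", "particle_id")])
  if (any(dup)) {
    rlang::abort(paste0("duplicate particle_id within chip at row(s): ",
                        paste(utils::head(which(dup), 5), collapse = ", ")),
                 class = "tetraspot_validation_error")
  }
  stopifnot(is.numeric(sizing_floor_nm), length(sizing_floor_nm) == 1L,
            sizing_floor_nm > 0)
  below <- which(!is.na(particles$size_nm) &
                   particles$size_nm < sizing_floor_nm)
  if (length(below) > 0) {
    rlang::abort(paste0("size_nm below the sizing floor (", sizing_floor_nm,
                        " nm) at row(s): ",
                        paste(utils::head(below, 5), collapse = ", ")),
                 class = "tetraspot_validation_error")
  }
  if (!setequal(unname(channel_map), TETRASPANINS) ||
      length(channel_map) != 3L) {
    rlang::abort("channel_map must be a bijection onto CD9, CD63, CD81",
                 class = "tetraspot_validation_error")
  }
  structure(
    list(sample_label = as.character(sample_label),
         particles = particles,
         sizing_floor_nm = sizing_floor_nm,
         channel_map = channel_map),
    class = "chip_experiment")
}

#' @export
print.chip_experiment <- function(x, ...) {
  n_spot <- table(factor(x$particles$spot, levels = CAPTURE_SPOTS))
  cat("<chip_experiment> sample:", x$sample_label,
      "|", nrow(x$particles), "particles\n")
  cat("  per spot:", paste(names(n_spot), n_spot, sep = "=", collapse = "  "),
      "\n")
  cat("  sizing floor:", x$sizing_floor_nm, "nm |",
      sum(!is.na(x$particles$size_nm)), "sized\n")
  invisible(x)
}

#' Construct a per-spot colocalization table
#'
#' Counts (or printed fractions) of captured particles over the four
#' observable colocalization categories of one anti-tetraspanin spot:
#' capture-only ("single positive" / "non-colocalizing"), the two double
#' positives with the non-capture tetraspanins, and the triple positive.
#'
#' Count-backed tables derive fractions from counts and are never
#' renormalized. Fraction-only tables (transcribed from printed percentages)
#' carry no counts; their fractions must sum to 1 within 0.002 to absorb
#' 1-decimal print rounding, and by default are stored exactly as given so
#' that predictions propagate printed precision faithfully. Set
#' `renormalize = TRUE` to rescale them to sum exactly 1.
#'
#' @param spot Capture spot, one of `"CD9"`, `"CD63"`, `"CD81"`.
#' @param counts Non-negative integer vector of length 4 in the canonical
#'   category order of [coloc_categories()] (names optional), or `NULL`.
#' @param fractions Numeric vector of length 4 in the same order, or `NULL`.
#'   Exactly one of `counts`, `fractions` must be supplied.
#' @param sample_label Optional sample label carried into reports.
#' @param renormalize For fraction-only tables: rescale to sum exactly 1.
#' @return An object of class `coloc_table` with elements `spot`, `markers`
#'   (the two non-capture tetraspanins), `categories`, `counts` (or `NULL`),
#'   `total` (or `NULL`) and `fractions`.
#' @export
#' @examples
#' coloc_table("CD63", counts = c(10, 4, 3, 3))
coloc_table <- function(spot, counts = NULL, fractions = NULL,
                        sample_label = NA_character_, renormalize = FALSE) {
  spot <- match_spot(spot, allow_igg = FALSE)
  cats <- coloc_categories(spot)
  if (is.null(counts) == is.null(fractions)) {
    rlang::abort("supply exactly one of `counts` or `fractions`",
                 class = "tetraspot_validation_error")
  }
  check4 <- function(x, what) {
    if (length(x) != 4L) {
      rlang::abort(paste0(what, " must have length 4"),
                   class = "tetraspot_validation_error")
    }
    if (!is.null(names(x))) {
      if (!setequal(names(x), cats)) {
        rlang::abort(paste0(what, " names must be: ",
                            paste(cats, collapse = ", ")),
                     class = "tetraspot_validation_error")
      }
      x <- x[cats]
    }
    stats::setNames(as.numeric(x), cats)
  }
  if (!is.null(counts)) {
    counts <- check4(counts, "counts")
    if (any(counts < 0) || any(abs(counts - round(counts)) > 1e-9)) {
      rlang::abort("counts must be non-negative integers",
                   class = "tetraspot_validation_error")
    }
    counts <- round(counts)
    total <- sum(counts)
    fractions <- if (total > 0) counts / total else rep(NA_real_, 4)
    names(fractions) <- cats
  } else {
    fractions <- check4(fractions, "fractions")
    if (any(fractions < 0)) {
      rlang::abort("fractions must be non-negative",
                   class = "tetraspot_validation_error")
    }
    s <- sum(fractions)
    if (abs(s - 1) > 0.002) {
      rlang::abort(sprintf(
        "fractions on the %s spot sum to %.4f; must be 1 within 0.002",
        spot, s), class = "tetraspot_validation_error")
    }
    if (renormalize) fractions <- fractions / s
    counts <- NULL
    total <- NULL
  }
  structure(
    list(spot = spot, markers = other_markers(spot), categories = cats,
         counts = counts, total = total, fractions = fractions,
         sample_label = as.character(sample_label)),
    class = "coloc_table")
}

#' @export
print.coloc_table <- function(x, ...) {
  cat("<coloc_table>", if (!is.na(x$sample_label)) x$sample_label else "",
      "spot:", x$spot,
      if (is.null(x$counts)) "(fraction-only)" else paste0("n=", x$total),
      "\n")
  pct <- round_half_up(100 * x$fractions, 1)
  for (i in seq_along(x$categories)) {
    cat(sprintf("  %-14s %6.1f%%", x$categories[i], pct[i]))
    if (!is.null(x$counts)) cat(sprintf("  (%d)", x$counts[i]))
    cat("\n")
  }
  invisible(x)
}

# fixed header of the particle-table interchange format
.PARTICLE_COLUMNS <- c("chip_id", "bio_rep", "tech_rep", "particle_id",
                       "spot", "cd9_pos", "cd63_pos", "cd81_pos", "size_nm")

#' Read a per-particle table
#'
#' Reads the comma-delimited particle interchange format (UTF-8, '.' decimal
#' separator, fixed header `chip_id, bio_rep, tech_rep, particle_id, spot,
#' cd9_pos, cd63_pos, cd81_pos, size_nm`; empty `size_nm` = unsized) emulating
#' an instrument export, and validates it into a [chip_experiment()].
#' Malformed rows are reported with their line numbers.
#'
#' @param path Path to the CSV file.
#' @param sizing_floor Sizing floor in nm passed to [chip_experiment()].
#' @param sample_label Sample label; defaults to the file name without
#'   extension.
#' @return A [chip_experiment()]; row order of the file is preserved.
#' @export
read_particle_table <- function(path, sizing_floor = 50,
                                sample_label = NULL) {
  if (!file.exists(path)) {
    rlang::abort(paste0("file not found: ", path), class = "tetraspot_io_error")
  }
  raw <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      chip_id = readr::col_character(),
      bio_rep = readr::col_integer(),
      tech_rep = readr::col_integer(),
      particle_id = readr::col_character(),
      spot = readr::col_character(),
      cd9_pos = readr::col_logical(),
      cd63_pos = readr::col_logical(),
      cd81_pos = readr::col_logical(),
      size_nm = readr::col_double()),
    progress = FALSE, show_col_types = FALSE))
  missing <- setdiff(.PARTICLE_COLUMNS, names(raw))
  if (length(missing) > 0) {
    rlang::abort(paste0("particle table ", path, " is missing column(s): ",
                        paste(missing, collapse = ", ")),
                 class = "tetraspot_format_error")
  }
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    lines <- paste(utils::head(probs$row, 5) + 1L, collapse = ", ")
    rlang::abort(paste0("malformed field(s) in ", path, " at line(s): ",
                        lines),
                 class = "tetraspot_format_error")
  }
  if (is.null(sample_label)) {
    sample_label <- sub("\\.[^.]*$", "", basename(path))
  }
  chip_experiment(raw, sample_label = sample_label,
                  sizing_floor_nm = sizing_floor)
}

#' Write a per-particle table
#'
#' Serializes a [chip_experiment()] in the canonical interchange format:
#' deterministic column order, preserved row order, locale-independent
#' number formatting, `NA` sizes written as empty fields. Two writes of the
#' same experiment are byte-identical.
#'
#' @param experiment A [chip_experiment()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_particle_table <- function(experiment, path) {
  stopifnot(inherits(experiment, "chip_experiment"))
  out <- experiment$particles[.PARTICLE_COLUMNS]
  tryCatch(
    readr::write_csv(out, path, na = "", eol = "\n", progress = FALSE),
    error = function(e) {
      rlang::abort(paste0("cannot write particle table to ", path, ": ",
                          conditionMessage(e)),
                   class = "tetraspot_io_error")
    })
  invisible(path)
}

# canonical + accepted synonyms for category labels in fraction tables
.normalize_category <- function(category, spot) {
  cats <- coloc_categories(spot)
  x <- trimws(category)
  lx <- tolower(x)
  if (lx %in% c("capture_only", "capture-only", "single_positive",
                "single positive", "non_colocalizing", "non-colocalizing",
                "none")) {
    return(cats[1])
  }
  if (lx %in% c("triple", "triple_positive", "triple positive", "all")) {
    return(cats[4])
  }
  m <- toupper(sub("^capture[+_]", "", x, ignore.case = TRUE))
  hit <- paste0("capture+", m)
  if (hit %in% cats) return(hit)
  rlang::abort(paste0("unknown colocalization category '", category,
                      "' for the ", spot, " spot"),
               class = "tetraspot_format_error")
}

#' Read a table of transcribed colocalization percentages
#'
#' Reads printed per-spot colocalization percentages (one row per sample x
#' spot x category, columns `sample, spot, category, percent`) into
#' fraction-only [coloc_table()] objects. Such tables carry no particle
#' counts; they let published percentage tables drive the random-model
#' pipeline. Per-spot percentages must sum to 100 within 0.2 (1-decimal
#' print rounding); by default they are stored as printed, not renormalized,
#' so that predictions computed from them propagate the printed precision.
#'
#' @param path CSV path.
#' @param renormalize Rescale each spot's fractions to sum exactly 1
#'   (default `FALSE`).
#' @return A list of [coloc_table()] objects, one per sample x spot, in file
#'   order.
#' @export
read_fraction_table <- function(path, renormalize = FALSE) {
  if (!file.exists(path)) {
    rlang::abort(paste0("file not found: ", path), class = "tetraspot_io_error")
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      sample = readr::col_character(),
      spot = readr::col_character(),
      category = readr::col_character(),
      percent = readr::col_double()),
    progress = FALSE, show_col_types = FALSE)
  missing <- setdiff(c("sample", "spot", "category", "percent"), names(raw))
  if (length(missing) > 0) {
    rlang::abort(paste0("fraction table is missing column(s): ",
                        paste(missing, collapse = ", ")),
                 class = "tetraspot_format_error")
  }
  raw$spot <- vapply(raw$spot, match_spot, character(1), allow_igg = FALSE)
  key <- paste(raw$sample, raw$spot, sep = "\r")
  out <- lapply(unique(key), function(k) {
    rows <- raw[key == k, ]
    spot <- rows$spot[1]
    cats <- vapply(rows$category, .normalize_category, character(1),
                   spot = spot)
    if (anyDuplicated(cats) || length(cats) != 4L) {
      rlang::abort(paste0("spot ", spot, " of sample '", rows$sample[1],
                          "' must have exactly the 4 categories once each"),
                   class = "tetraspot_format_error")
    }
    s <- sum(rows$percent)
    if (abs(s - 100) > 0.2) {
      rlang::abort(sprintf(
        "percentages for sample '%s' spot %s sum to %.2f; must be 100 +/- 0.2",
        rows$sample[1], spot, s), class = "tetraspot_validation_error")
    }
    coloc_table(spot,
                fractions = stats::setNames(rows$percent / 100, cats),
                sample_label = rows$sample[1], renormalize = renormalize)
  })
  out
}

#' Write fraction-only colocalization tables
#'
#' Inverse of [read_fraction_table()]: canonical category order, percentages
#' with full precision, deterministic output.
#'
#' @param tables A list of [coloc_table()] objects (or a single one).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fraction_table <- function(tables, path) {
  if (inherits(tables, "coloc_table")) tables <- list(tables)
  rows <- dplyr::bind_rows(lapply(tables, function(tb) {
    tibble::tibble(sample = tb$sample_label, spot = tb$spot,
                   category = tb$categories,
                   percent = 100 * unname(tb$fractions))
  }))
  readr::write_csv(rows, path, na = "", eol = "\n", progress = FALSE)
  invisible(path)
}
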