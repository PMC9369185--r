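#' Tetraspanin and capture-spot vocabulary
#'
#' The platform captures particles on antibody spots against the three
#' canonical small-EV tetraspanins plus a mouse-IgG isotype control, and
#' detects the same three markers by immunofluorescence. The canonical
#' marker order used everywhere in this package is CD9, CD63, CD81.
#'
#' @format `TETRASPANINS` is a character vector of the three marker names in
#'   canonical order; `IGG_CONTROL` is the spot label of the isotype-control
#'   spot; `CAPTURE_SPOTS` is `c(TETRASPANINS, IGG_CONTROL)`.
#' @name marker-vocabulary
NULL

#' @rdname marker-vocabulary
#' @export
TETRASPANINS <- c("CD9", "CD63", "CD81")

#' @rdname marker-vocabulary
#' @export
IGG_CONTROL <- "IgG"

#' @rdname marker-vocabulary
#' @export
CAPTURE_SPOTS <- c(TETRASPANINS, IGG_CONTROL)

#' Format a marker set in canonical notation
#'
#' A marker set is a named logical vector over `CD9`, `CD63`, `CD81`. Its
#' canonical serialization is e.g. `"CD9+CD63-CD81+"`; the empty set
#' (`"CD9-CD63-CD81-"`) is a valid value (a marker-negative particle).
#'
#' @param x Named logical vector; names must be the three tetraspanins (any
#'   order; missing names default to `FALSE`).
#' @return A length-1 character string.
#' @seealso [parse_marker_set()]
#' @export
#' @examples
#' format_marker_set(c(CD9 = TRUE, CD63 = FALSE, CD81 = TRUE))
format_marker_set <- function(x) {
  stopifnot(is.logical(x))
  full <- stats::setNames(rep(FALSE, 3L), TETRASPANINS)
  bad <- setdiff(names(x), TETRASPANINS)
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown marker name(s): ", paste(bad, collapse = ", ")),
                 class = "tetraspot_validation_error")
  }
  full[names(x)] <- x
  paste0(TETRASPANINS, ifelse(full, "+", "-"), collapse = "")
}

#' Parse canonical marker-set notation
#'
#' Inverse of [format_marker_set()]: `parse_marker_set(format_marker_set(x))`
#' is the identity on valid marker sets.
#'
#' @param s Length-1 character, e.g. `"CD9+CD63-CD81+"`.
#' @return Named logical vector over the three tetraspanins in canonical order.
#' @export
parse_marker_set <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  pat <- "^CD9([+-])CD63([+-])CD81([+-])$"
  if (!grepl(pat, s)) {
    rlang::abort(paste0("not a canonical marker-set string: '", s, "'"),
                 class = "tetraspot_format_error")
  }
  signs <- regmatches(s, regexec(pat, s))[[1]][2:4]
  stats::setNames(signs == "+", TETRASPANINS)
}

#' All eight marker-set phenotype labels
#'
#' Enumerates the 2^3 joint phenotypes in canonical bit order (CD9 the most
#' significant bit), from the marker-negative set to the triple positive.
#'
#' @return Character vector of length 8 of canonical marker-set strings.
#' @export
phenotype_levels <- function() {
  grid <- expand.grid(CD81 = c(FALSE, TRUE), CD63 = c(FALSE, TRUE),
                      CD9 = c(FALSE, TRUE))
  apply(grid, 1L, function(r) {
    format_marker_set(c(CD9 = r[["CD9"]], CD63 = r[["CD63"]], CD81 = r[["CD81"]]))
  })
}

#' Colocalization category labels for a capture spot
#'
#' Every particle captured on an anti-tetraspanin spot is scored positive for
#' the capture marker regardless of its fluorescence in that channel (the
#' platform's export convention), so its observable phenotype reduces to the
#' two non-capture channel flags: four categories. Canonical order is
#' capture-only, then the two double positives with the non-capture markers
#' in canonical marker order, then the triple positive.
#'
#' @param spot One of `"CD9"`, `"CD63"`, `"CD81"`.
#' @return Character vector of 4 category labels, e.g. for the CD63 spot:
#'   `c("capture_only", "capture+CD9", "capture+CD81", "triple")`.
#' @export
coloc_categories <- function(spot) {
  spot <- match_spot(spot, allow_igg = FALSE)
  others <- setdiff(TETRASPANINS, spot)
  c("capture_only", paste0("capture+", others), "triple")
}

#' The two non-capture tetraspanins of a spot, canonical order
#' @noRd
other_markers <- function(spot) {
  setdiff(TETRASPANINS, match_spot(spot, allow_igg = FALSE))
}

#' Normalize a spot label, accepting common synonyms for the IgG control
#' @noRd
match_spot <- function(spot, allow_igg = TRUE) {
  stopifnot(is.character(spot), length(spot) == 1L)
  s <- toupper(trimws(spot))
  if (s %in% c("IGG", "IGG_CONTROL", "MIGG", "MOUSE IGG")) s <- "IGG"
  lut <- c(CD9 = "CD9", CD63 = "CD63", CD81 = "CD81", IGG = IGG_CONTROL)
  if (!s %in% names(lut)) {
    rlang::abort(paste0("unknown capture spot: '", spot, "'"),
                 class = "tetraspot_format_error")
  }
  out <- unname(lut[[s]])
  if (!allow_igg && identical(out, IGG_CONTROL)) {
    rlang::abort("the IgG isotype-control spot has no colocalization categories",
                 class = "tetraspot_validation_error")
  }
  out
}

#' Round half away from zero
#'
#' Reported percentages and fold values are rounded half-away-from-zero,
#' matching the print convention of instrument reports (base `round()` uses
#' IEEE round-half-even). A one-ulp guard absorbs binary representation error
#' in decimal inputs.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1).
#' @return Numeric vector.
#' @export
#' @examples
#' round_half_up(c(0.25, -0.25, 2.345), 1)
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + sqrt(.Machine$double.eps)) / m
}
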