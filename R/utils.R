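#' @import data.table
#' @keywords internal
"_PACKAGE"

#' Round half away from zero
#'
#' Commercial ("half-up") rounding at a fixed number of decimal digits.
#' `base::round()` rounds half to even, which does not match the convention
#' used for the printed percentages this package reproduces.
#'
#' @param x numeric vector
#' @param digits number of decimal places (default 0)
#' @return numeric vector rounded half-up
#' @export
#' @examples
#' round_half_up(c(0.5, 1.5, 2.45), 0)
#' round_half_up(70.538, 0)  # 71
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  # small epsilon guards against values like 2.45 stored as 2.4499999...
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

# Collapse runs of whitespace and trim; used symmetrically on lexicon
# strings and report text.
squish <- function(x) {
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

# Case-fold + strip punctuation + squish: the canonical form under which
# drug strings and lexicon entries are compared.
canonical_drug_string <- function(x) {
  x <- toupper(x)
  x <- gsub("[^A-Z0-9 ]+", " ", x)
  squish(x)
}

# Case-fold + squish only (MedDRA PT terms are controlled vocabulary;
# punctuation is meaningful there).
canonical_pt_term <- function(x) {
  squish(tolower(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_aersdm <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "aersdm_error")))
}
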