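#' Round half away from zero
#'
#' Printed SRS tables round percentages with the "half-up" rule (0.005 -> 0.01),
#' which differs from [base::round()]'s banker's rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(100 * 1875 / 3953, 2) # 47.43
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # nudge by an ulp-scale epsilon so values stored just below .xx5 still round up
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Percentage of a denominator, rounded as printed tables do
#'
#' @param count numerator count(s).
#' @param denominator positive denominator.
#' @param digits decimals (default 2, the convention of published ADR tables).
#' @return numeric percentage(s) on the 0-100 scale.
#' @export
pct_of <- function(count, denominator, digits = 2) {
  stopifnot(denominator > 0)
  round_half_up(100 * count / denominator, digits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize a dictionary lookup key
#'
#' Lookups in drug/term dictionaries are case- and whitespace-insensitive:
#' keys are lower-cased, trimmed, and internal runs of whitespace collapsed.
#'
#' @param x character vector of raw names.
#' @return normalized keys.
#' @export
normalize_key <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

# categorical sampler that tolerates weight vectors not summing exactly to 1
sample_cat <- function(n, values, prob) {
  values[sample.int(length(values), n, replace = TRUE, prob = prob)]
}

stop_srs <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "srsmine_error")))
}
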