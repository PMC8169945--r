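#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; report tables here use the
#' conventional half-up rule (77.95 -> 78.0) so printed percentages are
#' stable across platforms.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(77.95, 1)
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Format a count/denominator pair the way result tables print them
#'
#' Produces strings such as `"53/68, 77.9%"`, with the percentage rounded
#' half-up to one decimal place.
#'
#' @param numerator,denominator non-negative counts; `denominator` must be
#'   positive.
#' @return character vector `"n/d, x.y%"`.
#' @export
#' @examples
#' format_count_percentage(53, 68)
format_count_percentage <- function(numerator, denominator) {
  if (any(denominator == 0)) {
    abort("`denominator` must be > 0.", class = "hspnet_validation_error")
  }
  pct <- round_half_up(100 * numerator / denominator, 1)
  sprintf("%d/%d, %.1f%%", as.integer(numerator), as.integer(denominator), pct)
}

#' Significance threshold shared across enrichment tools
#'
#' Divides a family-wise alpha by the number of tools whose results are
#' merged, truncating (not rounding) to `digits` decimals: truncation can
#' only make the threshold stricter, so the printed value is never
#' anti-conservative. With the defaults this gives 0.05 / 3 = 0.0166.
#'
#' @param alpha family-wise significance level.
#' @param n_tools number of enrichment tools merged.
#' @param digits decimals kept after truncation.
#' @return a single numeric threshold.
#' @export
#' @examples
#' bonferroni_alpha(0.05, 3)
bonferroni_alpha <- function(alpha = 0.05, n_tools = 3, digits = 4) {
  stopifnot(alpha > 0, n_tools >= 1)
  trunc(alpha / n_tools * 10^digits) / 10^digits
}

# Canonical gene identity: exact match after uppercasing + whitespace strip.
normalize_gene <- function(x) {
  toupper(trimws(as.character(x)))
}

# Abort with a validation class so callers can distinguish bad config/input.
validation_error <- function(msg) {
  abort(msg, class = "hspnet_validation_error")
}

config_error <- function(msg) {
  abort(msg, class = "hspnet_config_error")
}

is_count <- function(x, min = 0) {
  length(x) == 1 && is.numeric(x) && !is.na(x) && x >= min && x == trunc(x)
}
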