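# Operationalisation of Cole's presentation guidelines for percents:
# the ideal number of decimal places as a band rule on the percent's value,
# classification of observed vs ideal, and guideline-conformant formatting.

#' Ideal number of decimal places for a percent
#'
#' Band rule: integers for percents in [10, 90] and for percents of 100 or
#' more; one decimal place for percents in [0.1, 10), for percents in
#' (90, 100) (where 100 can be a natural upper bound, e.g. sensitivity of a
#' test: 99.9 not 100), and for a percent of exactly 0; two decimal places
#' under 0.1; three under 0.01; four under 0.001 (but above 0). All bands
#' are half-open so the function is total on [0, Inf); the conventions at
#' exactly 10, 90 and 100 are documented package choices.
#'
#' @param value Numeric vector of non-negative percents (percentage
#'   points).
#' @return Integer vector of ideal decimal places, each in 0..4.
#' @examples
#' ideal_decimal_places(c(22.2, 1.1, 99.9, 0, 0.05, 150))
#' @export
ideal_decimal_places <- function(value) {
  value <- as.numeric(value)
  if (any(is.na(value))) {
    stop("value contains NA")
  }
  if (any(value < 0)) {
    stop("negative percent value (signs are stripped during extraction)")
  }
  out <- integer(length(value))
  out[value == 0] <- 1L
  out[value > 0 & value < 0.001] <- 4L
  out[value >= 0.001 & value < 0.01] <- 3L
  out[value >= 0.01 & value < 0.1] <- 2L
  out[value >= 0.1 & value < 10] <- 1L
  out[value >= 10 & value <= 90] <- 0L
  out[value > 90 & value < 100] <- 1L
  out[value >= 100] <- 0L
  out
}

#' Classify percent mentions against the decimal-place guidelines
#'
#' Adds, for every mention, the ideal number of decimal places for its
#' value, the difference d - d* (observed minus ideal), and the category:
#' \code{too_few} (negative difference), \code{just_right} (zero) or
#' \code{too_many} (positive).
#'
#' @param mentions A mention data frame with at least columns \code{value}
#'   and \code{decimals} (see \code{\link{find_percents}}).
#' @return The input with columns \code{ideal_decimals},
#'   \code{difference} and \code{category} (factor with levels
#'   \code{too_few}, \code{just_right}, \code{too_many}) appended.
#' @examples
#' m <- data.frame(value = c(31.69, 3, 64), decimals = c(2, 0, 0))
#' classify_percents(m)
#' @export
classify_percents <- function(mentions) {
  mentions$ideal_decimals <- ideal_decimal_places(mentions$value)
  mentions$difference <- as.integer(mentions$decimals) -
    mentions$ideal_decimals
  mentions$category <- factor(
    ifelse(mentions$difference < 0L, "too_few",
           ifelse(mentions$difference == 0L, "just_right", "too_many")),
    levels = c("too_few", "just_right", "too_many")
  )
  mentions
}

#' Round half away from zero
#'
#' Manuscript-style rounding: .5 always rounds up in magnitude, unlike
#' base \code{round}'s round-half-even. A small epsilon guards against
#' values like 2.675 sitting just below .5 in binary.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits to keep.
#' @return Numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  scaled <- abs(x) * 10^digits
  sign(x) * floor(scaled + 0.5 + sqrt(.Machine$double.eps)) / 10^digits
}

#' Format a percent with its guideline-ideal decimal places
#'
#' Rounds the value (half away from zero) to
#' \code{\link{ideal_decimal_places}} digits and renders exactly that many
#' decimals, trailing zeros kept. When rounding pushes the value across a
#' band edge (9.97 rounds to 10, which wants an integer), the decimals are
#' recomputed for the rounded value until stable, so the printed token
#' always carries the ideal decimals of the value it shows.
#'
#' @param value Numeric vector of non-negative percents.
#' @return Character vector, e.g. \code{format_percent(100 * 263 / 8313)}
#'   is \code{"3.2"}.
#' @examples
#' format_percent(c(100 * 263 / 8313, 100 * 1947 / 9482, 55.37))
#' @export
format_percent <- function(value) {
  vapply(value, function(v) {
    d <- ideal_decimal_places(v)
    for (i in 1:5) {
      r <- round_half_up(v, d)
      d_new <- ideal_decimal_places(r)
      if (d_new == d) break
      d <- d_new
    }
    formatC(round_half_up(v, d), format = "f", digits = d)
  }, character(1L))
}
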