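# Sensitivity exclusions: digit-preference percents (round values that are
# often thresholds or pre-rounded, not computed results) and the 90-100%
# band (values that may or may not have a natural upper bound at 100, where
# the ideal-decimals judgement cannot be automated).

#' Is a mention a digit-preference value?
#'
#' True for percents printed with no decimal places whose value is a
#' multiple of 10, or exactly 75. The multiple-of-10 check is exact
#' integer arithmetic on the printed value; a value printed "50.0" has one
#' decimal place and is never flagged.
#'
#' @param value,decimals Numeric and integer vectors (recycled) of the
#'   mentions' printed values and decimal places.
#' @return Logical vector.
#' @examples
#' is_digit_preference(c(50, 75, 50), c(0, 0, 1))
#' @export
is_digit_preference <- function(value, decimals) {
  decimals == 0L & (value %% 10 == 0 | value == 75)
}

#' Is a mention in the 90-100% natural-upper-bound band?
#'
#' Closed band: 90 and 100 are both included, since both endpoints can sit
#' against the natural ceiling of 100.
#'
#' @param value Numeric vector of percent values.
#' @return Logical vector.
#' @examples
#' in_upper_bound_band(c(95, 89.9, 100))
#' @export
in_upper_bound_band <- function(value) {
  value >= 90 & value <= 100
}

#' Apply the sensitivity exclusions to classified mentions
#'
#' Returns the subsequence of rows failing every active exclusion
#' predicate; never reorders rows or alters classifications. Enabling more
#' flags can only shrink the result.
#'
#' @param classified A classified mention data frame (see
#'   \code{\link{classify_percents}}).
#' @param exclude_digit_preference Drop digit-preference percents
#'   (multiples of 10 and 75, printed with no decimals).
#' @param exclude_90_100 Drop percents in the closed band [90, 100].
#' @return The filtered data frame.
#' @examples
#' m <- classify_percents(data.frame(value = c(50, 31.69, 95),
#'                                   decimals = c(0, 2, 0)))
#' apply_sensitivity(m, TRUE, TRUE)
#' @export
apply_sensitivity <- function(classified,
                              exclude_digit_preference = FALSE,
                              exclude_90_100 = FALSE) {
  drop <- rep(FALSE, nrow(classified))
  if (exclude_digit_preference) {
    drop <- drop | is_digit_preference(classified$value,
                                       classified$decimals)
  }
  if (exclude_90_100) {
    drop <- drop | in_upper_bound_band(classified$value)
  }
  out <- classified[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}
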