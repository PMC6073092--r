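# Exclusion of percents that label statistical intervals ("95% CI") or
# significance levels ("5% significance") rather than reporting results.
# Rules pair a set of trigger values (matched only when printed with no
# decimal places) with keyword patterns searched in a character window
# around the mention.

#' Build an exclusion rule
#'
#' @param trigger_values Percent values that can act as labels (matched
#'   only when printed with zero decimal places).
#' @param keywords Character vector of patterns; entries flagged in
#'   \code{word_boundary} are matched as whole words (acronyms), others as
#'   case-insensitive fixed phrases.
#' @param window Maximum number of characters between the percent token
#'   and the keyword.
#' @param side Where the keyword may sit relative to the percent:
#'   \code{"before"}, \code{"after"} or \code{"either"}.
#' @param word_boundary Logical vector (recycled) marking keywords matched
#'   with word boundaries.
#' @param kind Whether the rule flags interval labels or significance
#'   labels; only used to name the flag column it sets.
#' @return An object of class \code{exclusion_rule}.
#' @export
exclusion_rule <- function(trigger_values, keywords, window = 30L,
                           side = c("either", "before", "after"),
                           word_boundary = FALSE,
                           kind = c("interval", "significance")) {
  side <- match.arg(side)
  kind <- match.arg(kind)
  stopifnot(length(trigger_values) > 0L, window >= 0L)
  structure(list(
    trigger_values = as.numeric(trigger_values),
    keywords = as.character(keywords),
    window = as.integer(window),
    side = side,
    word_boundary = rep_len(word_boundary, length(keywords)),
    kind = kind
  ), class = "exclusion_rule")
}

#' Default interval and significance exclusion rules
#'
#' The interval rule pairs the common interval levels 80, 90, 95 and 99
#' with the phrases "confidence interval", "credible interval", "Bayesian
#' credible interval", "uncertainty interval" (and the observed typo
#' "uncertainly interval"), "prediction interval", "posterior interval",
#' and the acronyms CI, PI and the transposed IC, within 30 characters on
#' either side. "range" is matched only within 5 characters because it is
#' a common English word. The significance rule pairs 1, 5 and 10 with
#' "significance", "statistical significance" and "alpha level".
#'
#' @return A list of \code{\link{exclusion_rule}} objects.
#' @export
default_exclusion_rules <- function() {
  list(
    interval = exclusion_rule(
      trigger_values = c(80, 90, 95, 99),
      keywords = c("confidence interval", "credible interval",
                   "bayesian credible interval", "uncertainty interval",
                   "uncertainly interval", "prediction interval",
                   "posterior interval", "CI", "PI", "IC"),
      window = 30L, side = "either",
      word_boundary = c(rep(FALSE, 7L), TRUE, TRUE, TRUE)
    ),
    interval_range = exclusion_rule(
      trigger_values = c(80, 90, 95, 99),
      keywords = "range", window = 5L, side = "either"
    ),
    significance = exclusion_rule(
      trigger_values = c(1, 5, 10),
      keywords = c("statistical significance", "significance",
                   "alpha level"),
      window = 30L, side = "either", kind = "significance"
    )
  )
}

# Does any keyword of `rule` occur with at most `rule$window` characters
# between it and the mention's span (on an admissible side)? The window
# bounds the gap, not the keyword itself.
rule_keyword_near <- function(rule, text, span_start, span_end) {
  for (k in seq_along(rule$keywords)) {
    pat <- if (rule$word_boundary[k]) {
      paste0("\\b", rule$keywords[k], "\\b")
    } else {
      gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", rule$keywords[k])
    }
    m <- gregexpr(pat, text, ignore.case = TRUE, perl = TRUE)[[1L]]
    if (m[1L] == -1L) next
    k_start <- as.integer(m) - 1L                     # 0-based
    k_end <- k_start + attr(m, "match.length")        # half-open
    before_ok <- rule$side %in% c("either", "before") &
      k_end <= span_start & span_start - k_end <= rule$window
    after_ok <- rule$side %in% c("either", "after") &
      k_start >= span_end & k_start - span_end <= rule$window
    if (any(before_ok | after_ok)) {
      return(TRUE)
    }
  }
  FALSE
}

mention_triggers <- function(rule, value, decimals) {
  decimals == 0L & value %in% rule$trigger_values
}

#' Is a percent mention a statistical-interval label?
#'
#' True when the mention's value is one of the rule's trigger levels
#' (printed with no decimal places) and an interval keyword or acronym
#' occurs within the rule's window. A mention printed with decimals
#' ("95.0%") is never excluded: the triggers are the printed common
#' values.
#'
#' @param value,decimals,span_start,span_end Fields of one mention
#'   (0-based half-open span into \code{text}).
#' @param text The normalised abstract text the mention came from.
#' @param rules List of \code{\link{exclusion_rule}}s; only the interval
#'   rules of \code{\link{default_exclusion_rules}} by default.
#' @return Logical.
#' @export
is_interval_label <- function(value, decimals, span_start, span_end, text,
                              rules = default_exclusion_rules()[
                                c("interval", "interval_range")]) {
  for (rule in rules) {
    if (mention_triggers(rule, value, decimals) &&
        rule_keyword_near(rule, text, span_start, span_end)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Is a percent mention a significance-level label?
#'
#' True for the common levels 1, 5 and 10 (printed with no decimals) when
#' a significance keyword ("significance", "alpha level") occurs within
#' the window.
#'
#' @inheritParams is_interval_label
#' @param rule A single \code{\link{exclusion_rule}}.
#' @return Logical.
#' @export
is_significance_label <- function(value, decimals, span_start, span_end,
                                  text,
                                  rule = default_exclusion_rules()$significance) {
  mention_triggers(rule, value, decimals) &&
    rule_keyword_near(rule, text, span_start, span_end)
}

#' Partition mentions into kept results and removed labels
#'
#' Applies every exclusion rule to every mention of one abstract. The
#' output is a strict partition: kept and removed rows together are the
#' input rows, order preserved in both.
#'
#' @param mentions Mention data frame for one abstract (see
#'   \code{\link{find_percents}}).
#' @param text The normalised abstract text.
#' @param rules List of \code{\link{exclusion_rule}}s.
#' @return A list with data frames \code{kept} and \code{removed}; both
#'   gain logical columns \code{is_interval_label} and
#'   \code{is_significance_label}.
#' @examples
#' txt <- "from 12% [95% CI 6-21%], to 3% [1-7%]"
#' filter_labels(find_percents(txt), txt)
#' @export
filter_labels <- function(mentions, text,
                          rules = default_exclusion_rules()) {
  kinds <- vapply(rules, `[[`, "", "kind")
  interval_rules <- rules[kinds == "interval"]
  signif_rules <- rules[kinds == "significance"]
  n <- nrow(mentions)
  is_int <- logical(n)
  is_sig <- logical(n)
  for (i in seq_len(n)) {
    is_int[i] <- is_interval_label(mentions$value[i], mentions$decimals[i],
                                   mentions$span_start[i],
                                   mentions$span_end[i], text,
                                   rules = interval_rules)
    is_sig[i] <- any(vapply(signif_rules, function(r) {
      is_significance_label(mentions$value[i], mentions$decimals[i],
                            mentions$span_start[i], mentions$span_end[i],
                            text, rule = r)
    }, logical(1L)))
  }
  mentions$is_interval_label <- is_int
  mentions$is_significance_label <- is_sig
  drop <- is_int | is_sig
  list(kept = mentions[!drop, , drop = FALSE],
       removed = mentions[drop, , drop = FALSE])
}
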