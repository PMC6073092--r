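# Aggregation of classified percents: category tallies, the share of
# abstracts with every percent ideally presented, Dirichlet-multinomial
# credible intervals for the category proportions, and printable tables.

#' Tally classification categories, overall or per journal
#'
#' @param classified A classified mention data frame (see
#'   \code{\link{classify_percents}}).
#' @param group_by \code{"all"} for a single pooled group, or
#'   \code{"journal"} for one row per journal.
#' @return A data frame with columns \code{group}, \code{n_too_few},
#'   \code{n_just_right}, \code{n_too_many}, \code{total}.
#' @export
tally_categories <- function(classified, group_by = c("all", "journal")) {
  group_by <- match.arg(group_by)
  groups <- if (group_by == "all") {
    rep("ALL", nrow(classified))
  } else {
    as.character(classified$journal)
  }
  if (nrow(classified) == 0L) {
    if (group_by == "all") {
      return(data.frame(group = "ALL", n_too_few = 0L, n_just_right = 0L,
                        n_too_many = 0L, total = 0L,
                        stringsAsFactors = FALSE))
    }
    return(data.frame(group = character(), n_too_few = integer(),
                      n_just_right = integer(), n_too_many = integer(),
                      total = integer(), stringsAsFactors = FALSE))
  }
  cat <- factor(as.character(classified$category),
                levels = c("too_few", "just_right", "too_many"))
  tab <- table(group = groups, category = cat)
  out <- data.frame(
    group = rownames(tab),
    n_too_few = as.integer(tab[, "too_few"]),
    n_just_right = as.integer(tab[, "just_right"]),
    n_too_many = as.integer(tab[, "too_many"]),
    stringsAsFactors = FALSE
  )
  out$total <- out$n_too_few + out$n_just_right + out$n_too_many
  rownames(out) <- NULL
  out
}

#' Share of abstracts with every percent ideally presented
#'
#' Numerator: abstracts whose every retained percent is classified
#' just_right. Denominator: abstracts contributing at least one retained
#' percent (abstracts with none are excluded).
#'
#' @param classified A classified mention data frame carrying
#'   \code{record_id}.
#' @return A list with \code{n_all_ideal}, \code{n_abstracts} and
#'   \code{share} (their ratio, \code{NaN} when the denominator is 0).
#' @export
all_ideal_share <- function(classified) {
  if (nrow(classified) == 0L) {
    return(list(n_all_ideal = 0L, n_abstracts = 0L, share = NaN))
  }
  ok <- tapply(classified$category == "just_right", classified$record_id,
               all)
  n_abs <- length(ok)
  n_ideal <- sum(ok)
  list(n_all_ideal = as.integer(n_ideal), n_abstracts = as.integer(n_abs),
       share = n_ideal / n_abs)
}

#' Dirichlet-multinomial credible intervals for category proportions
#'
#' With a Dirichlet(\code{prior}) prior on the three category proportions
#' and observed counts n, the posterior is Dirichlet(prior + n) and each
#' category's marginal is Beta(prior_i + n_i, sum of the others). The
#' default is the deterministic equal-tailed interval from Beta quantiles;
#' \code{method = "montecarlo"} draws from the posterior instead (a
#' validation mode).
#'
#' @param counts Numeric vector of three category counts (too few, just
#'   right, too many), or a one-row tally from
#'   \code{\link{tally_categories}}.
#' @param prior Dirichlet prior parameters, all positive; flat (1,1,1) by
#'   default.
#' @param level Credibility level in (0,1).
#' @param method \code{"quantile"} (exact marginal Beta quantiles) or
#'   \code{"montecarlo"}.
#' @param n_draws Posterior draws for the Monte-Carlo mode.
#' @return A data frame with one row per category: \code{category},
#'   \code{count}, \code{proportion} (observed), \code{post_mean},
#'   \code{lower}, \code{upper}.
#' @examples
#' dirichlet_intervals(c(4981, 23872, 14266))
#' @export
dirichlet_intervals <- function(counts, prior = c(1, 1, 1), level = 0.95,
                                method = c("quantile", "montecarlo"),
                                n_draws = 1e5L) {
  method <- match.arg(method)
  if (is.data.frame(counts)) {
    stopifnot(nrow(counts) == 1L)
    counts <- c(counts$n_too_few, counts$n_just_right, counts$n_too_many)
  }
  stopifnot(length(counts) == 3L, length(prior) == 3L)
  if (any(prior <= 0)) {
    stop("prior components must all be positive")
  }
  if (level <= 0 || level >= 1) {
    stop("level must be in (0, 1)")
  }
  if (sum(counts) == 0 && sum(prior) <= 3 * .Machine$double.eps) {
    stop("no counts and a degenerate prior: posterior undefined")
  }
  alpha <- prior + counts
  a0 <- sum(alpha)
  tail <- (1 - level) / 2
  if (method == "quantile") {
    lower <- stats::qbeta(tail, alpha, a0 - alpha)
    upper <- stats::qbeta(1 - tail, alpha, a0 - alpha)
  } else {
    g <- matrix(stats::rgamma(3L * n_draws, shape = rep(alpha,
                                                        each = n_draws)),
                ncol = 3L)
    p <- g / rowSums(g)
    lower <- apply(p, 2L, stats::quantile, probs = tail, names = FALSE)
    upper <- apply(p, 2L, stats::quantile, probs = 1 - tail,
                   names = FALSE)
  }
  data.frame(
    category = c("too_few", "just_right", "too_many"),
    count = as.numeric(counts),
    proportion = if (sum(counts) > 0) counts / sum(counts) else
      rep(NaN, 3L),
    post_mean = alpha / a0,
    lower = lower,
    upper = upper,
    stringsAsFactors = FALSE
  )
}

#' Render a category summary the way audit tables print it
#'
#' Proportions are multiplied by 100 and formatted with
#' \code{\link{format_percent}} (guideline-ideal decimal places); counts
#' get thousands separators.
#'
#' @param summary A summary data frame from
#'   \code{\link{dirichlet_intervals}}.
#' @return A data frame with columns \code{category}, \code{percent},
#'   \code{count}, \code{ci}.
#' @export
render_summary_table <- function(summary) {
  data.frame(
    category = summary$category,
    percent = format_percent(100 * summary$proportion),
    count = formatC(summary$count, format = "d", big.mark = ","),
    ci = sprintf("%s to %s", format_percent(100 * summary$lower),
                 format_percent(100 * summary$upper)),
    stringsAsFactors = FALSE
  )
}

#' Histogram bin counts for percents between 0 and 100
#'
#' One-percentage-point bins [0,1), [1,2), ..., [99,100]; values above 100
#' are excluded (their count is reported separately by
#' \code{\link{audit_percents}}).
#'
#' @param value Numeric vector of percent values.
#' @return A data frame with \code{bin_start}, \code{bin_end},
#'   \code{count}.
#' @export
histogram_bins <- function(value) {
  value <- value[value <= 100]
  bin <- pmin(floor(value), 99)
  counts <- tabulate(bin + 1L, nbins = 100L)
  data.frame(bin_start = 0:99, bin_end = 1:100, count = counts)
}
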