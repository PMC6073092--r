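#' Audit decimal-place presentation of percents in a corpus of abstracts
#'
#' Runs the full pipeline on a corpus: publication-type filtering, text
#' normalisation, percent extraction, interval/significance label
#' exclusion, guideline classification, optional sensitivity exclusions,
#' and Dirichlet-multinomial summaries overall and per journal.
#'
#' @param corpus A corpus data frame (see \code{\link{read_corpus}}) or a
#'   path to a jsonl/csv corpus file.
#' @param format File format when \code{corpus} is a path.
#' @param filter_types Apply the publication-type filter before
#'   extraction.
#' @param include_types,exclude_types Publication-type lists for the
#'   filter.
#' @param rules Label-exclusion rules
#'   (\code{\link{default_exclusion_rules}}).
#' @param exclude_digit_preference,exclude_90_100 Sensitivity exclusions
#'   (\code{\link{apply_sensitivity}}); both off for the main analysis.
#'   When either is on, the object additionally carries the sensitivity
#'   summary next to the main one.
#' @param prior,level Dirichlet prior and credibility level for the
#'   category-proportion intervals.
#' @return An object of class \code{percent_audit}: a list with the
#'   mention table (\code{mentions}), removed labels (\code{removed}),
#'   classified retained mentions (\code{classified}), overall and
#'   per-journal summaries, the all-ideal abstract share, histogram bins,
#'   the count of percents above 100, and the call parameters.
#' @examples
#' syn <- generate_corpus(generator_config(n_abstracts = 50), seed = 7)
#' fit <- audit_percents(syn$corpus)
#' fit
#' summary(fit)
#' @export
audit_percents <- function(corpus, format = c("jsonl", "csv"),
                           filter_types = FALSE,
                           include_types = include_types_default,
                           exclude_types = exclude_types_default,
                           rules = default_exclusion_rules(),
                           exclude_digit_preference = FALSE,
                           exclude_90_100 = FALSE,
                           prior = c(1, 1, 1), level = 0.95) {
  if (is.character(corpus) && length(corpus) == 1L) {
    corpus <- read_corpus(corpus, format = match.arg(format))
  }
  n_input <- nrow(corpus)
  if (filter_types) {
    corpus <- filter_corpus(corpus, include_types, exclude_types)
  }
  # extraction + per-abstract label exclusion
  kept_list <- vector("list", nrow(corpus))
  removed_list <- vector("list", nrow(corpus))
  full_list <- vector("list", nrow(corpus))
  for (i in seq_len(nrow(corpus))) {
    txt <- normalize_text(corpus$abstract_text[i])
    mm <- find_percents(txt, record_id = corpus$record_id[i])
    mm$journal <- rep(corpus$journal[i], nrow(mm))
    fl <- filter_labels(mm, txt, rules = rules)
    kept_list[[i]] <- fl$kept
    removed_list[[i]] <- fl$removed
    full <- rbind(fl$kept, fl$removed)
    full_list[[i]] <- full[order(full$span_start), , drop = FALSE]
  }
  kept <- do.call(rbind, c(kept_list, list(make.row.names = FALSE)))
  removed <- do.call(rbind, c(removed_list, list(make.row.names = FALSE)))
  mentions <- do.call(rbind, c(full_list, list(make.row.names = FALSE)))
  if (!is.data.frame(kept)) {  # empty corpus
    blank <- find_percents("")
    blank$journal <- character()
    blank <- filter_labels(blank, "")$kept
    kept <- removed <- mentions <- blank
  }
  classified <- classify_percents(kept)
  main <- apply_sensitivity(classified, exclude_digit_preference,
                            exclude_90_100)

  overall_counts <- tally_categories(main, "all")
  overall <- dirichlet_intervals(overall_counts, prior = prior,
                                 level = level)
  by_journal <- tally_categories(main, "journal")
  journal_summaries <- lapply(seq_len(nrow(by_journal)), function(j) {
    s <- dirichlet_intervals(by_journal[j, , drop = FALSE], prior = prior,
                             level = level)
    s$journal <- by_journal$group[j]
    s
  })
  by_journal_summary <- do.call(rbind, journal_summaries)

  structure(list(
    mentions = mentions,
    removed = removed,
    classified = classified,
    analysed = main,
    overall_counts = overall_counts,
    overall = overall,
    by_journal = by_journal_summary,
    all_ideal = all_ideal_share(main),
    histogram = histogram_bins(main$value),
    n_over_100 = sum(main$value > 100),
    n_abstracts_input = n_input,
    n_abstracts_used = nrow(corpus),
    params = list(exclude_digit_preference = exclude_digit_preference,
                  exclude_90_100 = exclude_90_100,
                  prior = prior, level = level,
                  filter_types = filter_types)
  ), class = "percent_audit")
}

#' @export
print.percent_audit <- function(x, ...) {
  cat("Percent decimal-place audit\n")
  cat(sprintf("  abstracts: %d used (of %d read)\n", x$n_abstracts_used,
              x$n_abstracts_input))
  cat(sprintf("  percents : %d extracted, %d excluded as labels, %d analysed\n",
              nrow(x$classified) + nrow(x$removed), nrow(x$removed),
              nrow(x$analysed)))
  if (x$params$exclude_digit_preference || x$params$exclude_90_100) {
    cat("  sensitivity exclusions:",
        paste(c("digit-preference", "90-100% band")[
          c(x$params$exclude_digit_preference, x$params$exclude_90_100)],
          collapse = ", "), "\n")
  }
  tab <- render_summary_table(x$overall)
  cat("  category split (% of analysed percents):\n")
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("    %-10s %s%% (%s)  [%s%%]\n", tab$category[i],
                tab$percent[i], tab$count[i], tab$ci[i]))
  }
  ai <- x$all_ideal
  if (ai$n_abstracts > 0) {
    cat(sprintf("  abstracts with every percent ideal: %s%% (%s of %s)\n",
                format_percent(100 * ai$share),
                formatC(ai$n_all_ideal, big.mark = ","),
                formatC(ai$n_abstracts, big.mark = ",")))
  }
  invisible(x)
}

#' @export
summary.percent_audit <- function(object, ...) {
  out <- list(
    overall = object$overall,
    overall_table = render_summary_table(object$overall),
    by_journal = object$by_journal,
    all_ideal = object$all_ideal,
    n_over_100 = object$n_over_100
  )
  class(out) <- "summary.percent_audit"
  out
}

#' @export
print.summary.percent_audit <- function(x, ...) {
  cat("Overall category proportions (with credible intervals):\n")
  print(x$overall_table, row.names = FALSE)
  cat("\nPer-journal summaries:\n")
  print(x$by_journal[, c("journal", "category", "count", "proportion",
                         "lower", "upper")], row.names = FALSE,
        digits = 3)
  ai <- x$all_ideal
  cat(sprintf("\nAbstracts fully ideal: %d of %d\n", ai$n_all_ideal,
              ai$n_abstracts))
  cat(sprintf("Percents above 100%%: %d\n", x$n_over_100))
  invisible(x)
}

#' Write the audit's output tables to CSV
#'
#' Emits \code{summary_overall.csv} (Table-1 shape),
#' \code{summary_by_journal.csv}, \code{histogram_bins.csv} (1-point bins
#' over 0-100, values above 100 excluded) and \code{mentions.csv} (the
#' full per-mention table with classifications).
#'
#' @param audit A \code{percent_audit} object.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_audit_tables <- function(audit, dir) {
  stopifnot(inherits(audit, "percent_audit"))
  if (!dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
  }
  ov <- render_summary_table(audit$overall)
  ov$raw_count <- audit$overall$count
  utils::write.csv(ov, file.path(dir, "summary_overall.csv"),
                   row.names = FALSE)
  utils::write.csv(audit$by_journal,
                   file.path(dir, "summary_by_journal.csv"),
                   row.names = FALSE)
  utils::write.csv(audit$histogram,
                   file.path(dir, "histogram_bins.csv"),
                   row.names = FALSE)
  utils::write.csv(audit$analysed, file.path(dir, "mentions.csv"),
                   row.names = FALSE)
  invisible(dir)
}
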