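span_key <- function(d) paste(d$record_id, d$span_start, d$span_end)

test_that("pipeline recovers the planted ground truth end to end", {
  syn <- generate_corpus(generator_config(n_abstracts = 300), seed = 19)
  fit <- audit_percents(syn$corpus)
  tr <- syn$truth
  # extraction: exactly the planted spans
  expect_setequal(span_key(fit$mentions), span_key(tr))
  # label exclusion: exactly the flagged labels
  expect_setequal(span_key(fit$removed),
                  span_key(tr[tr$is_interval_label, ]))
  # classification: equals the planted category on every retained mention
  m <- merge(fit$classified, tr,
             by = c("record_id", "span_start", "span_end"))
  expect_identical(nrow(m), nrow(fit$classified))
  expect_identical(as.character(m$category), m$planted_category)
  # sensitivity: removes exactly the rows matching its own predicate
  sens <- apply_sensitivity(fit$classified, TRUE, TRUE)
  keep <- !(is_digit_preference(fit$classified$value,
                                fit$classified$decimals) |
              in_upper_bound_band(fit$classified$value))
  expect_identical(sens$span_start, fit$classified$span_start[keep])
})

test_that("tallies and the all-ideal share match the ground truth", {
  syn <- generate_corpus(generator_config(n_abstracts = 300), seed = 23)
  fit <- audit_percents(syn$corpus)
  tr <- syn$truth[!syn$truth$is_interval_label, ]
  want <- table(factor(tr$planted_category,
                       c("too_few", "just_right", "too_many")))
  tab <- fit$overall_counts
  expect_identical(c(tab$n_too_few, tab$n_just_right, tab$n_too_many),
                   as.integer(want))
  ideal_by_abs <- tapply(tr$planted_category == "just_right",
                         tr$record_id, all)
  expect_identical(fit$all_ideal$n_all_ideal, sum(ideal_by_abs))
  expect_identical(fit$all_ideal$n_abstracts, length(ideal_by_abs))
})

test_that("the audit object prints and summarises without error", {
  syn <- generate_corpus(generator_config(n_abstracts = 40), seed = 2)
  fit <- audit_percents(syn$corpus)
  expect_s3_class(fit, "percent_audit")
  expect_output(print(fit), "category split")
  expect_output(print(summary(fit)), "Per-journal")
  expect_identical(nrow(fit$by_journal) %% 3L, 0L)
})

test_that("audit runs from a corpus file path and writes its tables", {
  syn <- generate_corpus(generator_config(n_abstracts = 25), seed = 6)
  path <- write_jsonl_corpus(syn$corpus)
  fit <- audit_percents(path, format = "jsonl")
  expect_identical(fit$n_abstracts_used, 25L)
  out <- file.path(tempdir(), "audit-tables")
  write_audit_tables(fit, out)
  expect_true(all(file.exists(file.path(out,
    c("summary_overall.csv", "summary_by_journal.csv",
      "histogram_bins.csv", "mentions.csv")))))
  ov <- read.csv(file.path(out, "summary_overall.csv"),
                 colClasses = "character")
  expect_identical(ov$category, c("too_few", "just_right", "too_many"))
})

test_that("an empty corpus audits to zero counts without error", {
  fit <- audit_percents(make_corpus_df(character(), character()))
  expect_identical(fit$overall_counts$total, 0L)
  expect_identical(fit$all_ideal$n_abstracts, 0L)
})

test_that("publication-type filtering inside the audit drops excluded records", {
  corp <- make_corpus_df(c("a", "b"), c("Rate was 12%.", "Rate was 13%."))
  corp$publication_types <- list("Journal Article",
                                 c("Journal Article", "Editorial"))
  fit <- audit_percents(corp, filter_types = TRUE)
  expect_identical(fit$n_abstracts_used, 1L)
  expect_identical(fit$classified$record_id, "a")
})
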