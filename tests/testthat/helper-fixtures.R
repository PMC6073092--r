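# Small in-code fixtures shared across test files.

make_corpus_df <- function(ids, texts, journal = "J", types = "Journal Article") {
  out <- data.frame(record_id = as.character(ids),
                    journal = rep_len(journal, length(ids)),
                    year = rep_len(2017L, length(ids)),
                    stringsAsFactors = FALSE)
  out$publication_types <- rep(list(types), length(ids))
  out$abstract_text <- texts
  out
}

write_jsonl_corpus <- function(corpus, path = tempfile(fileext = ".jsonl")) {
  percentaudit::write_corpus(corpus, path)
  path
}

write_csv_corpus <- function(corpus, path = tempfile(fileext = ".csv")) {
  flat <- data.frame(
    record_id = corpus$record_id, journal = corpus$journal,
    year = corpus$year,
    publication_types = vapply(corpus$publication_types, paste,
                               "", collapse = ";"),
    abstract_text = corpus$abstract_text, stringsAsFactors = FALSE
  )
  utils::write.csv(flat, path, row.names = FALSE)
  path
}
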