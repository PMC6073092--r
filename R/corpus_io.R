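#' Default publication-type inclusion and exclusion lists
#'
#' The inclusion list names the research article types kept in the audit;
#' the exclusion list names the non-research types that disqualify a record
#' even when a research type is also present (e.g. a retraction of a
#' clinical trial carries both "Clinical Trial" and "Retraction" and is
#' excluded). Matching is case-insensitive substring matching, so the
#' exclusion entry "Historical" also catches "Historical Article".
#'
#' @format Character vectors of PubMed-style publication type strings.
#' @export
include_types_default <- c(
  "Journal Article", "Clinical Trial", "Meta-Analysis", "Review",
  "Randomized Controlled Trial", "Multicenter Study"
)

#' @rdname include_types_default
#' @export
exclude_types_default <- c(
  "Biography", "Conference", "Comment", "Corrected", "Editorial",
  "Erratum", "Guideline", "Historical", "News", "Lectures", "Letter",
  "Retraction"
)

#' Read a corpus of abstract records
#'
#' Reads one abstract record per row/line from a JSON-lines file (one JSON
#' object per line with keys \code{record_id}, \code{journal}, \code{year},
#' \code{publication_types}, \code{abstract_text}) or a CSV file with the
#' same headers, where \code{publication_types} is a ";"-joined string.
#' Text is passed through unmodified; records are returned in input order.
#'
#' @param path Path to the corpus file.
#' @param format Either \code{"jsonl"} or \code{"csv"}.
#' @return A data frame with columns \code{record_id}, \code{journal},
#'   \code{year}, \code{publication_types} (a list column of character
#'   vectors) and \code{abstract_text}.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("record_id,journal,year,publication_types,abstract_text",
#'              'a,PLOS ONE,2017,Journal Article,"Response was 12%."'), f)
#' read_corpus(f, format = "csv")
#' @export
read_corpus <- function(path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("corpus file not found: ", path)
  }
  required <- c("record_id", "journal", "year", "publication_types",
                "abstract_text")
  if (format == "jsonl") {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) {
      return(empty_corpus())
    }
    recs <- lapply(seq_along(lines), function(i) {
      obj <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                      error = function(e) {
                        stop("record ", i, ": unparsable JSON line: ",
                             conditionMessage(e), call. = FALSE)
                      })
      miss <- setdiff(required, names(obj))
      if (length(miss) > 0L) {
        stop("record ", i, ": missing required field(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
      }
      list(record_id = as.character(obj$record_id),
           journal = as.character(obj$journal),
           year = as.integer(obj$year),
           publication_types = as.character(unlist(obj$publication_types)),
           abstract_text = as.character(obj$abstract_text))
    })
    out <- data.frame(
      record_id = vapply(recs, `[[`, "", "record_id"),
      journal = vapply(recs, `[[`, "", "journal"),
      year = vapply(recs, `[[`, 0L, "year"),
      stringsAsFactors = FALSE
    )
    out$publication_types <- lapply(recs, `[[`, "publication_types")
    out$abstract_text <- vapply(recs, `[[`, "", "abstract_text")
  } else {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character", encoding = "UTF-8")
    if (nrow(tab) == 0L && ncol(tab) == 0L) {
      return(empty_corpus())
    }
    miss <- setdiff(required, names(tab))
    if (length(miss) > 0L) {
      stop("missing required column(s): ", paste(miss, collapse = ", "))
    }
    out <- data.frame(
      record_id = tab$record_id,
      journal = tab$journal,
      year = as.integer(tab$year),
      stringsAsFactors = FALSE
    )
    out$publication_types <- lapply(strsplit(tab$publication_types, ";",
                                             fixed = TRUE), trimws)
    out$abstract_text <- tab$abstract_text
  }
  bad <- which(is.na(out$abstract_text))
  if (length(bad) > 0L) {
    stop("record ", bad[1L], ": missing abstract_text")
  }
  if (anyDuplicated(out$record_id)) {
    stop("duplicate record_id values in corpus")
  }
  rownames(out) <- NULL
  out
}

empty_corpus <- function() {
  out <- data.frame(record_id = character(), journal = character(),
                    year = integer(), stringsAsFactors = FALSE)
  out$publication_types <- list()
  out$abstract_text <- character()
  out
}

#' Publication-type filter for one record
#'
#' A record passes when it carries at least one included article type and
#' none of the excluded ones. Both checks are case-insensitive substring
#' matches against the record's type strings, so the exclusion entry
#' "Historical" matches the PubMed type "Historical Article".
#'
#' @param publication_types Character vector of the record's article types.
#' @param include_types,exclude_types Character vectors of type patterns;
#'   defaults are the audit's standard lists.
#' @return \code{TRUE} if the record should be kept.
#' @examples
#' passes_type_filter(c("Journal Article"))
#' passes_type_filter(c("Clinical Trial", "Retraction"))
#' @export
passes_type_filter <- function(publication_types,
                               include_types = include_types_default,
                               exclude_types = exclude_types_default) {
  if (length(publication_types) == 0L) {
    return(FALSE)
  }
  has_any <- function(patterns) {
    any(vapply(patterns, function(p) {
      any(grepl(p, publication_types, ignore.case = TRUE, fixed = FALSE))
    }, logical(1L)))
  }
  has_any(include_types) && !has_any(exclude_types)
}

#' Filter a corpus by publication type
#'
#' Applies \code{\link{passes_type_filter}} to every record and keeps the
#' passing ones, preserving order. Filtering is idempotent.
#'
#' @param corpus A corpus data frame from \code{\link{read_corpus}}.
#' @inheritParams passes_type_filter
#' @return The filtered corpus data frame.
#' @export
filter_corpus <- function(corpus,
                          include_types = include_types_default,
                          exclude_types = exclude_types_default) {
  keep <- vapply(corpus$publication_types, passes_type_filter,
                 logical(1L), include_types = include_types,
                 exclude_types = exclude_types)
  out <- corpus[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a corpus to JSON-lines
#'
#' Inverse of \code{\link{read_corpus}} for the jsonl format; used mainly to
#' persist synthetic corpora.
#'
#' @param corpus A corpus data frame.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  lines <- vapply(seq_len(nrow(corpus)), function(i) {
    jsonlite::toJSON(list(
      record_id = corpus$record_id[i],
      journal = corpus$journal[i],
      year = corpus$year[i],
      publication_types = as.list(corpus$publication_types[[i]]),
      abstract_text = corpus$abstract_text[i]
    ), auto_unbox = TRUE)
  }, character(1L))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
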