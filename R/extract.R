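# Text normalisation and percent-mention extraction.
#
# The extractor works on normalised text only: spans recorded in the mention
# table are 0-based half-open offsets into the normalised string, not the
# raw abstract.

#' Normalise abstract text before percent extraction
#'
#' Removes the plus-minus sign, maps non-breaking and narrow spaces to
#' ordinary spaces, maps the Unicode minus and en/em dashes to an ASCII
#' hyphen, maps the full-width percent sign to "%", and maps the mid-dot
#' decimal marker (Lancet house style, "12·3") to ".". All other
#' characters are preserved; relative character order never changes.
#'
#' @param text Character vector of abstract text.
#' @return Character vector of the same length.
#' @examples
#' normalize_text("12·3 ± 4%")
#' normalize_text("5 %")
#' @export
normalize_text <- function(text) {
  text <- enc2utf8(as.character(text))
  # plus-minus sign removed outright
  text <- gsub("\u00b1", "", text, fixed = TRUE)
  # no-break, narrow no-break, thin and figure spaces -> plain space
  text <- gsub("[\u00a0\u202f\u2009\u2007]", " ", text, perl = TRUE)
  # unicode minus, figure/en/em dashes -> ASCII hyphen
  text <- gsub("[\u2212\u2012\u2013\u2014]", "-", text, perl = TRUE)
  # full-width percent sign
  text <- gsub("\uff05", "%", text, fixed = TRUE)
  # mid-dot decimal marker between digits (Lancet style)
  text <- gsub("(?<=[0-9])\u00b7(?=[0-9])", ".", text, perl = TRUE)
  text
}

# Numeric token: plain digits or comma-grouped thousands, optional single
# decimal part; or a bare ".5"-style fraction. The token must be followed by
# at most one space and then "%". A lookbehind stops us matching the tail of
# a longer number ("6-21%" matches "21", not "1").
.percent_regex <- "(?<![0-9.,])((?:[0-9]{1,3}(?:,[0-9]{3})+|[0-9]+)(?:\\.[0-9]+)?|\\.[0-9]+) ?%"
.scientific_regex <- "[0-9](?:\\.[0-9]+)?[eE][-+]?[0-9]+ ?%"

#' Find every percent mention in normalised text
#'
#' A mention is a number immediately followed by an optional single space
#' and "%". Thousands separators ("4,214.53%") are accepted and stripped
#' from the recorded value. Leading signs and comparison characters
#' ("-10%", "<10%") are not part of the token, so the absolute value is
#' recorded. In a range ("5 to 10%", "5-10%") only the number adjacent to
#' "%" is a mention. Percents written in scientific notation are skipped
#' with a warning rather than mis-read as their mantissa.
#'
#' @param text A single normalised abstract string (see
#'   \code{\link{normalize_text}}).
#' @param record_id Identifier copied into each mention row.
#' @return A data frame with one row per mention: \code{record_id},
#'   \code{raw_token} (matched substring including "%"), \code{value},
#'   \code{decimals}, \code{sig_figs}, \code{span_start}, \code{span_end}
#'   (0-based half-open offsets into \code{text}), in left-to-right order.
#' @examples
#' find_percents("Response fell from 31.69% vs 64% after 2010.")
#' find_percents("The range was 5 to 10%.")
#' @export
find_percents <- function(text, record_id = NA_character_) {
  stopifnot(length(text) == 1L)
  m <- gregexpr(.percent_regex, text, perl = TRUE)[[1L]]
  empty <- data.frame(record_id = character(), raw_token = character(),
                      value = numeric(), decimals = integer(),
                      sig_figs = integer(), span_start = integer(),
                      span_end = integer(), stringsAsFactors = FALSE)
  if (m[1L] == -1L) {
    return(empty)
  }
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  # drop matches that are the tail of a scientific-notation percent
  sci <- gregexpr(.scientific_regex, text, perl = TRUE)[[1L]]
  if (sci[1L] != -1L) {
    sci_start <- as.integer(sci)
    sci_end <- sci_start + attr(sci, "match.length") - 1L
    inside <- vapply(starts, function(s) {
      any(s >= sci_start & s <= sci_end)
    }, logical(1L))
    if (any(inside)) {
      warning("skipped ", sum(inside),
              " percent(s) in scientific notation (not extractable)")
      starts <- starts[!inside]
      lens <- lens[!inside]
    }
    if (length(starts) == 0L) {
      return(empty)
    }
  }
  raw <- substring(text, starts, starts + lens - 1L)
  numeric_part <- sub(" ?%$", "", raw)
  plain <- gsub(",", "", numeric_part, fixed = TRUE)
  data.frame(
    record_id = rep(record_id, length(raw)),
    raw_token = raw,
    value = as.numeric(plain),
    decimals = vapply(numeric_part, count_decimals, integer(1L),
                      USE.NAMES = FALSE),
    sig_figs = vapply(numeric_part, count_sig_figs, integer(1L),
                      USE.NAMES = FALSE),
    span_start = starts - 1L,
    span_end = starts - 1L + lens,
    stringsAsFactors = FALSE
  )
}

#' Count printed decimal places of a numeric token
#'
#' The number of digit characters after the decimal point as printed;
#' trailing zeros count ("50.0" has one decimal place), and a token without
#' a point has zero.
#'
#' @param numeric_token Character vector of numeric tokens (no "%").
#' @return Integer vector.
#' @examples
#' count_decimals(c("242.73", "50.0", "64"))
#' @export
count_decimals <- function(numeric_token) {
  vapply(as.character(numeric_token), function(tok) {
    tok <- gsub(",", "", tok, fixed = TRUE)
    if (!grepl(".", tok, fixed = TRUE)) {
      return(0L)
    }
    nchar(sub("^[^.]*\\.", "", tok))
  }, integer(1L), USE.NAMES = FALSE)
}

#' Count printed significant figures of a numeric token
#'
#' Standard printed-digit convention: leading zeros are not significant;
#' trailing zeros after a decimal point are significant; trailing zeros of
#' a bare integer are counted as printed ("50" has two significant
#' figures). A token of all zeros ("0", "0.0") counts as one.
#'
#' @param numeric_token Character vector of numeric tokens (no "%").
#' @return Integer vector.
#' @examples
#' count_sig_figs(c("0.05", "50.0", "4214.53"))
#' @export
count_sig_figs <- function(numeric_token) {
  vapply(as.character(numeric_token), function(tok) {
    digits <- gsub("[^0-9]", "", gsub(",", "", tok, fixed = TRUE))
    stripped <- sub("^0+", "", digits)
    if (nchar(stripped) == 0L) {
      return(1L)
    }
    nchar(stripped)
  }, integer(1L), USE.NAMES = FALSE)
}

#' Extract percent mentions from a whole corpus
#'
#' Normalises each abstract and runs \code{\link{find_percents}} on it,
#' carrying the journal label through for downstream grouping.
#'
#' @param corpus A corpus data frame (see \code{\link{read_corpus}}).
#' @return A mention data frame (one row per percent) with an extra
#'   \code{journal} column.
#' @export
extract_corpus <- function(corpus) {
  pieces <- lapply(seq_len(nrow(corpus)), function(i) {
    mm <- find_percents(normalize_text(corpus$abstract_text[i]),
                        record_id = corpus$record_id[i])
    if (nrow(mm) > 0L) {
      mm$journal <- corpus$journal[i]
    } else {
      mm$journal <- character()
    }
    mm
  })
  out <- do.call(rbind, c(pieces, list(make.row.names = FALSE)))
  if (!is.data.frame(out)) {
    out <- find_percents("")
    out$journal <- character()
  }
  out[, c("record_id", "journal", "raw_token", "value", "decimals",
          "sig_figs", "span_start", "span_end")]
}
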