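test_that("normalisation strips plus-minus, odd spaces, dashes and mid-dots", {
  expect_identical(normalize_text("12·3 ± 4%"), "12.3  4%")
  expect_identical(normalize_text("5 %"), "5 %")
  expect_identical(normalize_text(""), "")
  expect_identical(normalize_text("5–10%"), "5-10%")
  expect_identical(normalize_text("−10％"), "-10%")
  # idempotent: re-normalising changes nothing
  txt <- normalize_text("12·3 ± 4% and 5–10%")
  expect_identical(normalize_text(txt), txt)
})

test_that("only the number adjacent to % is extracted from ranges and signs", {
  m <- find_percents("5 to 10%")
  expect_identical(nrow(m), 1L)
  expect_identical(m$value, 10)
  expect_identical(m$decimals, 0L)

  m <- find_percents(normalize_text("–10%"))
  expect_identical(m$value, 10)
  m <- find_percents("<10%")
  expect_identical(m$value, 10)

  m <- find_percents("31.69% vs 64%")
  expect_identical(m$value, c(31.69, 64))
  expect_identical(m$decimals, c(2L, 0L))

  expect_identical(nrow(find_percents("no percents here")), 0L)
})

test_that("thousands separators, bare fractions and spacing rules apply", {
  m <- find_percents("up to 4,214.53% higher")
  expect_identical(m$value, 4214.53)
  expect_identical(m$raw_token, "4,214.53%")
  expect_identical(find_percents("about .5% of cases")$decimals, 1L)
  # at most one space before the sign
  expect_identical(nrow(find_percents("5  %")), 0L)
  expect_identical(find_percents("5 %")$value, 5)
  # words "percent"/"per cent" are never matched (no % suffix)
  expect_identical(nrow(find_percents("10 percent of cases")), 0L)
})

test_that("scientific notation is skipped with a warning, not misread", {
  expect_warning(m <- find_percents("rate of 1e-4% overall"),
                 "scientific notation")
  expect_identical(nrow(m), 0L)
})

test_that("spans are 0-based half-open offsets that recover the raw token", {
  txt <- "From 12% [95% CI 6-21%], to 3%"
  m <- find_percents(txt)
  for (i in seq_len(nrow(m))) {
    expect_identical(substr(txt, m$span_start[i] + 1L, m$span_end[i]),
                     m$raw_token[i])
  }
  # spans of distinct mentions never overlap
  expect_true(all(m$span_start[-1] >= m$span_end[-nrow(m)]))
})

test_that("decimal places count printed digits after the point", {
  expect_identical(count_decimals(c("242.73", "50.0", "64", ".5")),
                   c(2L, 1L, 0L, 1L))
})

test_that("significant figures follow the printed-digit convention", {
  expect_identical(count_sig_figs(c("0.05", "50.0", "4214.53", "50", "0")),
                   c(1L, 3L, 6L, 2L, 1L))
})

test_that("round-trip: parsing raw_token reproduces value and decimals", {
  set.seed(4)
  vals <- c(exp(runif(40, log(0.001), log(100))), 150, 0, 99.9)
  dps <- sample(0:4, length(vals), replace = TRUE)
  toks <- render_percent(vals, dps)
  txt <- paste0("Values were ", paste0(toks, "%", collapse = " and "), ".")
  m <- find_percents(txt)
  expect_identical(nrow(m), length(vals))
  expect_equal(m$value, as.numeric(toks))
  expect_identical(m$decimals, as.integer(dps))
})
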