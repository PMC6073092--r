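test_that("the generator is deterministic given the seed", {
  a <- generate_corpus(generator_config(n_abstracts = 20), seed = 42)
  b <- generate_corpus(generator_config(n_abstracts = 20), seed = 42)
  expect_identical(a, b)
  c <- generate_corpus(generator_config(n_abstracts = 20), seed = 43)
  expect_false(identical(a$corpus$abstract_text, c$corpus$abstract_text))
})

test_that("invalid generator configs fail before any output", {
  expect_error(generator_config(interval_label_rate = 1.5), "rates")
  expect_error(generator_config(category_probs = c(0.5, 0.5, 0.5)),
               "sum to 1")
  expect_error(generator_config(n_abstracts = 0))
})

test_that("render_percent prints exactly the requested decimals", {
  expect_identical(render_percent(3.1637, 1L), "3.2")
  expect_identical(render_percent(64, 0L), "64")
  expect_identical(render_percent(0.0004, 4L), "0.0004")
  expect_identical(render_percent(2.25, 1L), "2.3")  # half away from zero
  expect_error(render_percent(1, 7L))
})

test_that("planted truth is span-accurate and category-consistent", {
  syn <- generate_corpus(generator_config(n_abstracts = 60), seed = 3)
  tr <- syn$truth
  txt <- setNames(syn$corpus$abstract_text, syn$corpus$record_id)
  for (i in seq_len(nrow(tr))) {
    expect_identical(substr(txt[[tr$record_id[i]]], tr$span_start[i] + 1L,
                            tr$span_end[i]), tr$token[i])
  }
  # category is the sign of planted decimals minus ideal of printed value
  printed <- as.numeric(sub("%$", "", tr$token))
  diff <- tr$planted_decimals - ideal_decimal_places(printed)
  want <- ifelse(diff < 0, "too_few",
                 ifelse(diff == 0, "just_right", "too_many"))
  expect_identical(tr$planted_category, want)
})

test_that("forced all-just-right corpus classifies 100% just_right", {
  cfg <- generator_config(n_abstracts = 40,
                          category_probs = c(0, 1, 0),
                          interval_label_rate = 0,
                          digit_preference_rate = 0)
  syn <- generate_corpus(cfg, seed = 8)
  fit <- audit_percents(syn$corpus)
  expect_identical(nrow(fit$removed), 0L)
  expect_true(all(fit$classified$category == "just_right"))
})

test_that("per-abstract percent counts hit median 3 and IQR 2-6", {
  syn <- generate_corpus(generator_config(n_abstracts = 1500), seed = 14)
  tr <- syn$truth[!syn$truth$is_interval_label, ]
  counts <- as.integer(table(tr$record_id))
  q <- as.integer(stats::quantile(counts, c(0.25, 0.5, 0.75), type = 1))
  expect_identical(q, c(2L, 3L, 6L))
})

test_that("adversarial decoys are never extracted as percents", {
  cfg <- generator_config(n_abstracts = 60, adversarial = TRUE)
  syn <- generate_corpus(cfg, seed = 5)
  fit <- audit_percents(syn$corpus)
  key <- function(d) paste(d$record_id, d$span_start, d$span_end)
  expect_setequal(key(fit$mentions), key(syn$truth))
})

test_that("digit-preference spikes appear at the configured values", {
  syn <- generate_corpus(generator_config(n_abstracts = 800,
                                          digit_preference_rate = 0.5),
                         seed = 21)
  tr <- syn$truth[syn$truth$is_digit_preference, ]
  expect_true(all(tr$true_value %in% c(seq(10, 90, 10), 75, 1, 5, 95)))
  expect_true(all(tr$planted_decimals == 0L))
  # spikes visible in the histogram relative to neighbours
  fit <- audit_percents(syn$corpus)
  h <- fit$histogram
  at50 <- h$count[h$bin_start == 50]
  near <- mean(h$count[h$bin_start %in% c(48, 49, 51, 52)])
  expect_gt(at50, 3 * near)
})
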