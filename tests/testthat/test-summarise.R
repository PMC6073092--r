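test_that("tallies add up overall and by journal", {
  cl <- data.frame(
    record_id = c("a", "a", "b", "c"),
    journal = c("J1", "J1", "J2", "J2"),
    category = factor(c("too_few", "just_right", "too_many", "just_right"),
                      levels = c("too_few", "just_right", "too_many")),
    stringsAsFactors = FALSE
  )
  all_tab <- tally_categories(cl, "all")
  expect_identical(all_tab$total, 4L)
  expect_identical(c(all_tab$n_too_few, all_tab$n_just_right,
                     all_tab$n_too_many), c(1L, 2L, 1L))
  jt <- tally_categories(cl, "journal")
  expect_identical(sum(jt$total), nrow(cl))
  expect_setequal(jt$group, c("J1", "J2"))
  empty <- tally_categories(cl[0, ], "all")
  expect_identical(empty$total, 0L)
})

test_that("all-ideal share counts abstracts whose every percent is ideal", {
  cl <- data.frame(
    record_id = c("a", "a", "b", "b"),
    category = c("just_right", "just_right", "just_right", "too_many"),
    stringsAsFactors = FALSE
  )
  got <- all_ideal_share(cl)
  expect_identical(got$n_all_ideal, 1L)
  expect_identical(got$n_abstracts, 2L)
  cl$category <- "just_right"
  expect_identical(all_ideal_share(cl)$n_all_ideal, 2L)
  expect_identical(all_ideal_share(cl[0, ])$n_abstracts, 0L)
})

test_that("posterior marginals are Beta with the complementary total", {
  s <- dirichlet_intervals(c(2, 3, 5), level = 0.9)
  alpha <- c(1, 1, 1) + c(2, 3, 5)
  expect_equal(s$lower, qbeta(0.05, alpha, sum(alpha) - alpha))
  expect_equal(s$upper, qbeta(0.95, alpha, sum(alpha) - alpha))
  expect_equal(s$post_mean, alpha / sum(alpha))
  expect_equal(sum(s$proportion), 1)
  expect_true(all(s$lower <= s$post_mean & s$post_mean <= s$upper))
})

test_that("symmetric counts give three identical interval widths", {
  s <- dirichlet_intervals(c(40, 40, 40))
  w <- s$upper - s$lower
  expect_equal(w[1], w[2])
  expect_equal(w[2], w[3])
})

test_that("quantile mode matches the Monte-Carlo sampler", {
  set.seed(5)
  q <- dirichlet_intervals(c(2, 3, 5))
  mc <- dirichlet_intervals(c(2, 3, 5), method = "montecarlo",
                            n_draws = 1e6L)
  expect_true(all(abs(q$lower - mc$lower) < 0.002))
  expect_true(all(abs(q$upper - mc$upper) < 0.002))
})

test_that("interval width shrinks as counts grow at fixed proportions", {
  widths <- sapply(c(1, 10, 100, 1000), function(k) {
    s <- dirichlet_intervals(k * c(12, 55, 33))
    max(s$upper - s$lower)
  })
  expect_true(all(diff(widths) < 0))
})

test_that("degenerate inputs are rejected", {
  expect_error(dirichlet_intervals(c(1, 2, 3), prior = c(0, 1, 1)),
               "positive")
  expect_error(dirichlet_intervals(c(1, 2, 3), level = 1.2), "level")
})

test_that("95% intervals attain nominal coverage over multinomial draws", {
  set.seed(2024)
  truth <- c(0.12, 0.55, 0.33)
  n <- 2000L
  reps <- 500L
  draws <- stats::rmultinom(reps, n, truth)
  hit <- matrix(FALSE, reps, 3L)
  for (r in seq_len(reps)) {
    s <- dirichlet_intervals(draws[, r])
    hit[r, ] <- s$lower <= truth & truth <= s$upper
  }
  cov <- colMeans(hit)
  expect_true(all(cov >= 0.92 & cov <= 0.98))
})

test_that("summary rendering uses guideline formatting and separators", {
  s <- dirichlet_intervals(c(4981, 23872, 14266))
  tab <- render_summary_table(s)
  expect_identical(tab$percent, c("12", "55", "33"))
  expect_identical(tab$count, c("4,981", "23,872", "14,266"))
})

test_that("histogram bins cover 0-100 and drop values above 100", {
  h <- histogram_bins(c(0.2, 0.7, 1.5, 99.9, 100, 150))
  expect_identical(nrow(h), 100L)
  expect_identical(sum(h$count), 5L)
  expect_identical(h$count[h$bin_start == 0], 2L)
  expect_identical(h$count[h$bin_start == 99], 2L)  # 99.9 and 100
})
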