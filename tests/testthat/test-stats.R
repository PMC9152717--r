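test_that("descriptive summaries follow the n-1 convention", {
  s <- descriptive_summary(c(5, 5, 5), "const")
  expect_equal(s$mean, 5)
  expect_equal(s$sd, 0)

  one <- descriptive_summary(42, "single")
  expect_true(is.na(one$sd))
  expect_equal(one$n, 1)

  vals <- c(3.2, 5.1, 4.4, 6.0, 2.9, 5.5, 4.1, 3.8, 5.0, 4.6)
  s10 <- descriptive_summary(vals, "ten")
  expect_equal(s10$mean, sum(vals) / 10)
  expect_equal(s10$sd, sqrt(sum((vals - mean(vals))^2) / 9))
  expect_equal(s10$min, 2.9)
  expect_equal(s10$max, 6.0)

  expect_error(descriptive_summary(numeric(), "none"),
               class = "wr_empty_group")
})

test_that("the two-sample test matches the Welch formula oracle", {
  # identical samples: no effect
  x <- c(1, 2, 3, 4, 5)
  r0 <- two_sample_t(x, x)
  expect_equal(r0$t_stat, 0)
  expect_equal(r0$p_raw, 1)

  # frozen fixture, n = 8 vs n = 10
  set.seed(88)
  a <- rnorm(8, 30, 10)
  b <- rnorm(10, 25, 5)
  r <- two_sample_t(a, b, labels = c("a", "b"))
  o <- welch_oracle(a, b)
  expect_equal(r$t_stat, o$t, tolerance = 1e-12)
  expect_equal(r$df, o$df, tolerance = 1e-12)
  expect_equal(r$p_raw, o$p, tolerance = 1e-12)
  expect_equal(c(r$ci_lo, r$ci_hi), o$ci, tolerance = 1e-12)
  expect_equal(r$diff, mean(a) - mean(b))
  # CI contains the point estimate
  expect_true(r$ci_lo <= r$diff && r$diff <= r$ci_hi)

  # random-pair property
  for (i in 1:50) {
    x <- rnorm(sample(5:40, 1), rnorm(1, 0, 5), runif(1, 0.5, 4))
    y <- rnorm(sample(5:40, 1), rnorm(1, 0, 5), runif(1, 0.5, 4))
    expect_equal(two_sample_t(x, y)$p_raw, welch_oracle(x, y)$p,
                 tolerance = 1e-10)
  }

  # location shift is recovered
  set.seed(12)
  base <- rnorm(500)
  sh <- two_sample_t(base + 3, base)
  expect_equal(sh$diff, 3)
  expect_lt(sh$p_raw, 1e-10)

  expect_error(two_sample_t(1, c(1, 2)), class = "wr_insufficient_sample")
})

test_that("the one-sample upper-tail test matches its oracle", {
  r <- one_sample_t_greater(rep(7, 5) + c(-1, 1, -2, 2, 0), mu0 = 7)
  expect_equal(r$t_stat, 0)
  expect_equal(r$p_raw, 0.5)

  set.seed(4)
  x <- rnorm(30, 12, 2)
  r2 <- one_sample_t_greater(x, mu0 = 7)
  o <- one_sample_oracle(x, 7)
  expect_equal(r2$t_stat, o$t, tolerance = 1e-12)
  expect_equal(r2$df, o$df)
  expect_equal(r2$p_raw, o$p, tolerance = 1e-12)
  expect_lt(r2$p_raw, 1e-6)

  expect_error(one_sample_t_greater(7), class = "wr_insufficient_sample")
})

test_that("Holm adjustment equals the longhand step-down", {
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(c(1, 1)), c(1, 1))
  set.seed(66)
  for (i in 1:100) {
    p <- runif(sample(1:10, 1))
    expect_equal(holm_adjust(p), brute_holm(p))
  }
  expect_error(holm_adjust(c(0.5, 1.2)), class = "wr_invalid_pvalue")
  expect_error(holm_adjust(c(-0.1)), class = "wr_invalid_pvalue")
})

test_that("interlanguage comparison adjusts a family of three", {
  set.seed(9)
  base <- rnorm(80, 30, 10)
  scored <- tibble::tibble(
    language = rep(c("en", "de", "ru"), each = 80),
    fre = c(base, base, base)
  )
  r <- compare_languages(scored)
  expect_equal(nrow(r), 3)
  expect_equal(r$p_adj, rep(1, 3))
  expect_false(any(r$significant))
  expect_true(all(r$p_adj >= r$p_raw))

  expect_error(compare_languages(scored[scored$language != "ru", ]),
               class = "wr_missing_corpus")

  # planted offsets are recovered inside the CI
  set.seed(10)
  scored2 <- tibble::tibble(
    language = rep(c("en", "de", "ru"), each = 400),
    fre = c(rnorm(400, 36, 10), rnorm(400, 28, 10), rnorm(400, 46, 12))
  )
  r2 <- compare_languages(scored2)
  en_de <- r2[r2$group1 == "en" & r2$group2 == "de", ]
  expect_true(en_de$ci_lo <= 8 && 8 <= en_de$ci_hi)
  expect_true(en_de$significant)
})

test_that("chapter comparison applies the strict n > 25 rule", {
  set.seed(21)
  ref <- rnorm(400, 30, 10)
  inst <- tibble::tibble(
    id = as.character(1:175),
    chapter = rep(c("A", "B", "F"), c(25, 50, 100)),
    fre = c(rnorm(25, 30, 10), rnorm(50, 30, 10), rnorm(100, 20, 10))
  )
  r <- compare_chapters(inst, reference = ref)
  expect_false(r$included[r$group1 == "A"])   # exactly 25 -> excluded
  expect_true(r$included[r$group1 == "B"])
  expect_true(is.na(r$p_raw[r$group1 == "A"]))
  # planted 10-point deficit in F is flagged with a negative difference
  f <- r[r$group1 == "F", ]
  expect_true(f$significant)
  expect_lt(f$diff, 0)
})

test_that("chapter null comparisons reject at about the nominal rate", {
  set.seed(300)
  hits <- 0L
  n_rep <- 400
  for (i in seq_len(n_rep)) {
    ref <- rnorm(200, 30, 10)
    ch <- rnorm(60, 30, 10)
    inst <- tibble::tibble(id = as.character(1:60), chapter = "X", fre = ch)
    hits <- hits + compare_chapters(inst, reference = ref)$significant[1]
  }
  expect_gt(hits / n_rep, 0.02)
  expect_lt(hits / n_rep, 0.09)
})

test_that("grade-level benchmark is one-tailed against grade 7", {
  inst7 <- tibble::tibble(id = as.character(1:30), language = "en",
                          chapter = "F", fkgl = rep(7, 30) + rep(c(-1, 1), 15))
  r <- compare_to_grade(inst7)
  expect_equal(r$p_raw[1], 0.5, tolerance = 1e-12)
  expect_false(r$significant[1])

  set.seed(14)
  inst14 <- tibble::tibble(id = as.character(1:100), language = "en",
                           chapter = "F", fkgl = rnorm(100, 14, 2))
  r2 <- compare_to_grade(inst14)
  expect_true(r2$significant[1])
  expect_gt(r2$diff[1], 0)

  small <- tibble::tibble(id = as.character(1:20), language = "en",
                          chapter = "Q", fkgl = rnorm(20, 14, 2))
  r3 <- compare_to_grade(small)
  expect_false(r3$included[1])

  expect_error(
    compare_to_grade(tibble::tibble(id = "x", language = "de",
                                    chapter = "A", fkgl = 9)),
    class = "wr_unsupported_metric"
  )
})

test_that("comparison objects expose tidy, glance and autoplot", {
  set.seed(2)
  r <- two_sample_t(rnorm(20), rnorm(20))
  td <- tidy(r)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "wr_comparison"))
  gl <- glance(r)
  expect_equal(gl$n_tests, 1)
  p <- autoplot(r)
  expect_s3_class(p, "ggplot")
})
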