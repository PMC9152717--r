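# direct-substitution values computed by hand from the published
# coefficient sets
stats_from <- function(asl = 10, asw = 1.5, ms = 10, n_chars = 400,
                       n_words = 100, n_sentences = 10, p_poly = 0) {
  tibble::tibble(
    n_sentences = n_sentences, n_words = n_words, n_chars = n_chars,
    n_syllables = round(asw * n_words), n_complex_words = round(ms),
    asl = asl, asw = asw, ms = ms, pct_hard_words = ms,
    l_per100 = 100 * n_chars / n_words,
    s_per100 = 100 * n_sentences / n_words, p_poly = p_poly
  )
}

test_that("FRE coefficient sets reproduce direct substitutions", {
  st <- stats_from(asl = 1, asw = 1)
  expect_equal(fre(st, "en"), 121.22)
  expect_equal(fre(st, "de"), 120.5)
  expect_equal(fre(st, "ru"), 166.9)
})

test_that("FKGL reproduces direct substitutions for English and Russian", {
  st <- stats_from(asl = 1, asw = 1)
  expect_equal(fkgl(st, "en"), -3.40, tolerance = 1e-12)
  expect_equal(fkgl(st, "ru"), -5.85, tolerance = 1e-12)
  expect_equal(fkgl(stats_from(asl = 15, asw = 1.5), "en"), 7.96)
  expect_error(fkgl(st, "de"), class = "wr_unsupported_metric")
})

test_that("FOG, SMOG, ARI, CLI and WSTF4 match hand arithmetic", {
  expect_equal(gunning_fog(stats_from(asl = 10, ms = 10)), 8.0)
  expect_equal(gunning_fog(stats_from(asl = 20, ms = 0)), 8.0)

  expect_equal(smog(stats_from(p_poly = 0)), 3.1291)
  expect_equal(smog(stats_from(n_sentences = 30, p_poly = 30)),
               3.1291 + 1.0430 * sqrt(30))
  # normalization is scale-invariant
  expect_equal(smog(stats_from(n_sentences = 60, p_poly = 60)),
               smog(stats_from(n_sentences = 30, p_poly = 30)))

  expect_equal(ari(stats_from(n_chars = 400, n_words = 100, asl = 10)), 2.41)
  expect_equal(ari(stats_from(n_chars = 500, n_words = 100, asl = 20)),
               12.12, tolerance = 1e-12)

  expect_equal(coleman_liau(stats_from(n_chars = 400, n_words = 100,
                                       n_sentences = 5)), 6.24)
  expect_equal(coleman_liau(stats_from(n_chars = 500, n_words = 100,
                                       n_sentences = 4)), 12.416)

  expect_equal(wstf4(stats_from(asl = 10, ms = 20)), 6.4501)
  expect_equal(wstf4(stats_from(asl = 18, ms = 30)), 11.3189)
  expect_error(wstf4(stats_from(), lang = "en"),
               class = "wr_unsupported_metric")
})

test_that("all formulas agree with an arithmetic oracle on a frozen grid", {
  # 12 frozen statistics records spanning the plausible range
  set.seed(5150)
  grid <- tibble::tibble(
    asl = c(5, 8, 11, 14, 17, 20, 23, 26, 12, 15, 18, 21),
    asw = c(1.2, 1.4, 1.6, 1.8, 2.0, 2.2, 1.3, 1.7, 2.5, 2.9, 1.5, 2.1),
    ms = c(5, 10, 15, 20, 25, 30, 8, 18, 35, 40, 12, 28),
    n_sentences = c(10, 20, 30, 40, 12, 25, 33, 50, 15, 22, 28, 44),
    n_words = c(120, 300, 250, 400, 180, 500, 260, 380, 140, 330, 410, 220),
    n_chars = c(500, 1400, 1200, 2100, 800, 2600, 1100, 1900, 700, 1800,
                2000, 1000),
    p_poly = c(6, 30, 37, 80, 45, 150, 20, 68, 49, 132, 49, 61)
  )
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    st <- stats_from(asl = g$asl, asw = g$asw, ms = g$ms,
                     n_chars = g$n_chars, n_words = g$n_words,
                     n_sentences = g$n_sentences, p_poly = g$p_poly)
    expect_equal(fre(st, "en"), 206.835 - 1.015 * g$asl - 84.6 * g$asw,
                 tolerance = 1e-9)
    expect_equal(fre(st, "de"), 180 - g$asl - 58.5 * g$asw, tolerance = 1e-9)
    expect_equal(fre(st, "ru"), 208.7 - 2.6 * g$asl - 39.2 * g$asw,
                 tolerance = 1e-9)
    expect_equal(fkgl(st, "en"), 0.39 * g$asl + 11.8 * g$asw - 15.59,
                 tolerance = 1e-9)
    expect_equal(fkgl(st, "ru"), 0.36 * g$asl + 5.76 * g$asw - 11.97,
                 tolerance = 1e-9)
    expect_equal(gunning_fog(st), 0.4 * (g$asl + g$ms), tolerance = 1e-9)
    expect_equal(smog(st),
                 3.1291 + 1.0430 * sqrt(g$p_poly * 30 / g$n_sentences),
                 tolerance = 1e-9)
    expect_equal(ari(st),
                 4.71 * g$n_chars / g$n_words + 0.5 * g$asl - 21.43,
                 tolerance = 1e-9)
    expect_equal(coleman_liau(st),
                 0.0588 * 100 * g$n_chars / g$n_words -
                   0.296 * 100 * g$n_sentences / g$n_words - 15.8,
                 tolerance = 1e-9)
    expect_equal(wstf4(st), 0.2656 * g$asl + 0.2744 * g$ms - 1.6939,
                 tolerance = 1e-9)
  }
})

test_that("difficulty banding uses inclusive lower edges", {
  expect_equal(as.character(fre_band(c(29.999, 30, 49.99, 50, 59.9, 60,
                                       69.9, 75, 80, 89.9, 90, 120))),
               c("very_difficult", "difficult", "difficult",
                 "fairly_difficult", "fairly_difficult", "standard",
                 "standard", "fairly_easy", "easy", "easy", "very_easy",
                 "very_easy"))
})

test_that("fre decreases and grade levels increase with sentence length", {
  asw <- 1.7
  asl <- seq(5, 40, by = 5)
  for (lang in c("en", "de", "ru")) {
    v <- fre(stats_from(asl = asl, asw = asw), lang)
    expect_true(all(diff(v) < 0))
  }
  expect_true(all(diff(fkgl(stats_from(asl = asl, asw = asw), "en")) > 0))
  expect_true(all(diff(gunning_fog(stats_from(asl = asl, ms = 15))) > 0))
  expect_true(all(diff(wstf4(stats_from(asl = asl, ms = 15))) > 0))
})

test_that("English FRE and FKGL are strongly anti-correlated", {
  # both metrics are affine in (ASL, ASW); across texts whose variation is
  # carried by word complexity (ASW) they move in near-perfect opposition
  set.seed(90)
  st <- stats_from(asl = rnorm(1000, 18, 1), asw = runif(1000, 1.1, 3.0))
  expect_lt(cor(fre(st, "en"), fkgl(st, "en")), -0.99)
})

test_that("metrics refuse degenerate statistics", {
  degen <- stats_from(n_sentences = 0)
  expect_error(fre(degen, "en"), class = "wr_degenerate_text")
  expect_error(smog(degen), class = "wr_degenerate_text")
})

test_that("score_articles populates exactly the language-specific metric set", {
  set.seed(31)
  arts <- tibble::tibble(
    id = c("e1", "d1", "r1", "x1"),
    language = c("en", "de", "ru", "en"),
    title = c("En", "De", "Ru", "Empty"),
    text = c(make_constructed_text("en", 4, 8, 2),
             make_constructed_text("de", 4, 8, 2),
             make_constructed_text("ru", 4, 8, 2),
             "")
  )
  sc <- score_articles(arts, strip = FALSE)
  en <- sc[sc$id == "e1", ]
  expect_true(all(!is.na(en[c("fre", "fkgl", "fog", "smog", "ari", "cli")])))
  expect_true(is.na(en$wstf4))
  de <- sc[sc$id == "d1", ]
  expect_true(all(!is.na(de[c("fre", "wstf4")])))
  expect_true(all(is.na(de[c("fkgl", "fog", "smog", "ari", "cli")])))
  ru <- sc[sc$id == "r1", ]
  expect_true(all(!is.na(ru[c("fre", "fkgl")])))
  expect_true(all(is.na(ru[c("fog", "smog", "ari", "cli", "wstf4")])))
  # degenerate article excluded, not scored
  x <- sc[sc$id == "x1", ]
  expect_equal(x$excluded_reason, "degenerate_text")
  expect_true(is.na(x$fre))
})
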