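# The comparison layer: descriptive summaries, Welch t tests, Holm
# adjustment, and the three test scenarios (pairwise interlanguage, chapter
# vs group-A mean, chapter vs the recommended grade level).

#' Descriptive summary of a score vector
#'
#' Sample SD uses the n-1 denominator and is reported absent (`NA`) for a
#' single observation, the convention the per-chapter tables follow.
#'
#' @param values Numeric vector (NAs dropped).
#' @param label Group label carried into the output.
#' @return One-row tibble: `label`, `n`, `mean`, `sd`, `min`, `max`.
#' @export
descriptive_summary <- function(values, label = "group") {
  values <- values[!is.na(values)]
  if (length(values) == 0L) {
    abort("no values to summarize", class = "wr_empty_group")
  }
  tibble::tibble(
    label = label,
    n = length(values),
    mean = mean(values),
    sd = if (length(values) > 1L) stats::sd(values) else NA_real_,
    min = min(values),
    max = max(values)
  )
}

comparison_row <- function(label1, label2, ht, x, y = NULL) {
  tibble::tibble(
    group1 = label1,
    group2 = label2,
    n1 = length(x),
    n2 = if (is.null(y)) NA_integer_ else length(y),
    mean1 = mean(x),
    mean2 = if (is.null(y)) unname(ht$null.value) else mean(y),
    sd1 = if (length(x) > 1) stats::sd(x) else NA_real_,
    sd2 = if (is.null(y) || length(y) < 2) NA_real_ else stats::sd(y),
    diff = mean(x) - (if (is.null(y)) unname(ht$null.value) else mean(y)),
    ci_lo = ht$conf.int[1],
    ci_hi = ht$conf.int[2],
    t_stat = unname(ht$statistic),
    df = unname(ht$parameter),
    p_raw = ht$p.value
  )
}

new_comparison <- function(tb, scenario, alpha, metric, adjusted) {
  p <- if (adjusted) tb$p_adj else tb$p_raw
  tb$significant <- p < alpha
  structure(tb, class = c("wr_comparison", class(tb)),
            scenario = scenario, alpha = alpha, metric = metric)
}

#' Unpaired two-sample Welch t test
#'
#' The workhorse for the interlanguage and chapter comparisons: an unpaired
#' t test with unequal variances (Welch-Satterthwaite degrees of freedom)
#' and a 95% CI for the difference of means.
#'
#' @param x,y Numeric vectors, each of length at least 2.
#' @param labels Character pair naming the groups.
#' @param tails `"two"` (default) or `"greater"` (H_a: mean(x) > mean(y)).
#' @param alpha Significance level.
#' @return A one-row `wr_comparison` tibble (see [compare_languages()] for
#'   the columns).
#' @export
two_sample_t <- function(x, y, labels = c("x", "y"), tails = c("two", "greater"),
                         alpha = 0.05) {
  tails <- match.arg(tails)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    abort("each sample needs at least 2 observations",
          class = "wr_insufficient_sample")
  }
  ht <- stats::t.test(x, y, var.equal = FALSE,
                      alternative = if (tails == "two") "two.sided" else "greater")
  tb <- comparison_row(labels[1], labels[2], ht, x, y)
  tb$p_adj <- NA_real_
  new_comparison(tb, scenario = "two_sample", alpha = alpha,
                 metric = NA_character_, adjusted = FALSE)
}

#' One-sample t test against a reference grade level (upper tail)
#'
#' Tests H_a: the group's mean grade exceeds `mu0`, the recommended
#' patient-education reading level (default grade 7).
#'
#' @param x Numeric vector of grade-level scores (length at least 2).
#' @param mu0 Reference constant.
#' @param labels Character pair naming the group and the reference.
#' @param alpha Significance level.
#' @return A one-row `wr_comparison` tibble.
#' @export
one_sample_t_greater <- function(x, mu0 = 7, labels = c("group", "grade7"),
                                 alpha = 0.05) {
  x <- x[!is.na(x)]
  if (length(x) < 2) {
    abort("need at least 2 observations", class = "wr_insufficient_sample")
  }
  ht <- stats::t.test(x, mu = mu0, alternative = "greater")
  tb <- comparison_row(labels[1], labels[2], ht, x)
  tb$p_adj <- NA_real_
  new_comparison(tb, scenario = "one_sample_greater", alpha = alpha,
                 metric = NA_character_, adjusted = FALSE)
}

#' Holm step-down adjustment of p values
#'
#' Step-down Holm: sort ascending, multiply the i-th smallest by (m - i + 1),
#' enforce monotonicity, cap at 1, return in the input order. Controls the
#' family-wise error rate for the pairwise interlanguage family.
#'
#' @param p Numeric vector of p values in \[0, 1\].
#' @return Adjusted p values, same order as the input.
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03))
#' @export
holm_adjust <- function(p) {
  if (length(p) == 0L) return(numeric())
  if (anyNA(p) || any(p < 0 | p > 1)) {
    abort("p values must lie in [0, 1]", class = "wr_invalid_pvalue")
  }
  stats::p.adjust(p, method = "holm")
}

#' Scenario 1: pairwise interlanguage comparison of FRE
#'
#' Compares the FRE scores of all scored articles (groups A and B together)
#' pairwise across the three language editions with unpaired two-tailed
#' Welch t tests, then Holm-adjusts the family of three p values.
#'
#' @param scored Tibble of scored articles (needs `language` and the metric
#'   column; excluded/degenerate rows are dropped via `NA` metrics).
#' @param metric Metric column to compare (default `"fre"`, the one metric
#'   on a compatible scale in all three languages).
#' @param alpha Significance level.
#' @return A three-row `wr_comparison` tibble with columns `group1`,
#'   `group2`, `n1`, `n2`, `mean1`, `mean2`, `sd1`, `sd2`, `diff`, `ci_lo`,
#'   `ci_hi`, `t_stat`, `df`, `p_raw`, `p_adj`, `significant`.
#' @export
compare_languages <- function(scored, metric = "fre", alpha = 0.05) {
  missing <- setdiff(WR_LANGS, unique(scored$language))
  if (length(missing) > 0) {
    abort(paste0("missing language corpora: ", paste(missing, collapse = ", ")),
          class = "wr_missing_corpus")
  }
  vals <- lapply(WR_LANGS, function(lg) {
    v <- scored[[metric]][scored$language == lg]
    v[!is.na(v)]
  })
  names(vals) <- WR_LANGS
  pairs <- list(c("en", "de"), c("en", "ru"), c("de", "ru"))
  rows <- lapply(pairs, function(pr) {
    r <- two_sample_t(vals[[pr[1]]], vals[[pr[2]]], labels = pr, alpha = alpha)
    tibble::as_tibble(r)
  })
  tb <- dplyr::bind_rows(rows)
  tb$p_adj <- holm_adjust(tb$p_raw)
  new_comparison(tb, scenario = "interlanguage_pairwise", alpha = alpha,
                 metric = metric, adjusted = TRUE)
}

#' Scenario 2: each ICD-10 chapter against all group-A articles
#'
#' For every chapter whose instance count exceeds `min_n` (strictly), the
#' chapter's FRE values are tested against the FRE values of all group-A
#' articles of that language with an unpaired two-tailed Welch t test. The
#' reference includes the chapter's own members — the literal reading of
#' "against the mean of all the articles" — so the two samples overlap;
#' reports note this dependence. Chapters at or below `min_n` are returned
#' with `included = FALSE` and no test.
#'
#' @param instances Chapter-instance tibble (from [assign_chapters()], scored;
#'   needs `chapter` and the metric column) for one language.
#' @param reference Numeric vector of the language's full group-A metric
#'   values. If `NULL`, derived from `instances` by deduplicating on `id`.
#' @param metric Metric column (default `"fre"`).
#' @param min_n Inclusion threshold; a chapter needs n > `min_n`.
#' @param alpha Significance level.
#' @return A `wr_comparison` tibble, one row per chapter, with an `included`
#'   column; excluded chapters carry `NA` test fields.
#' @export
compare_chapters <- function(instances, reference = NULL, metric = "fre",
                             min_n = 25, alpha = 0.05) {
  instances <- tibble::as_tibble(instances)
  if (is.null(reference)) {
    ded <- instances[!duplicated(instances$id), , drop = FALSE]
    reference <- ded[[metric]]
  }
  reference <- reference[!is.na(reference)]
  rows <- lapply(sort(unique(instances$chapter)), function(ch) {
    v <- instances[[metric]][instances$chapter == ch]
    v <- v[!is.na(v)]
    if (length(v) <= min_n) {
      return(tibble::tibble(
        group1 = ch, group2 = "group_A", n1 = length(v), n2 = length(reference),
        mean1 = if (length(v)) mean(v) else NA_real_, mean2 = mean(reference),
        sd1 = if (length(v) > 1) stats::sd(v) else NA_real_,
        sd2 = stats::sd(reference),
        diff = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
        t_stat = NA_real_, df = NA_real_, p_raw = NA_real_, p_adj = NA_real_,
        included = FALSE
      ))
    }
    r <- tibble::as_tibble(two_sample_t(v, reference, labels = c(ch, "group_A"),
                                        alpha = alpha))
    r$included <- TRUE
    r$significant <- NULL
    r
  })
  tb <- dplyr::bind_rows(rows)
  tb <- new_comparison(tb, scenario = "chapter_vs_groupA", alpha = alpha,
                       metric = metric, adjusted = FALSE)
  tb$significant[!tb$included] <- NA
  tb
}

#' Scenario 3: English chapters against the recommended grade level
#'
#' One-sample upper-tail t test of each English chapter's FKGL values
#' against the recommended patient-education reading level (grade 7).
#' Chapters at or below `min_n` instances are excluded, as in
#' [compare_chapters()].
#'
#' @param instances English chapter-instance tibble with an `fkgl` column.
#' @param mu0 Recommended grade level (default 7).
#' @param min_n Inclusion threshold (strict).
#' @param alpha Significance level.
#' @return A `wr_comparison` tibble, one row per chapter.
#' @export
compare_to_grade <- function(instances, mu0 = 7, min_n = 25, alpha = 0.05) {
  instances <- tibble::as_tibble(instances)
  if (!all(instances$language == "en")) {
    abort("the grade-level benchmark applies to English FKGL scores only",
          class = "wr_unsupported_metric")
  }
  rows <- lapply(sort(unique(instances$chapter)), function(ch) {
    v <- instances$fkgl[instances$chapter == ch]
    v <- v[!is.na(v)]
    if (length(v) <= min_n) {
      return(tibble::tibble(
        group1 = ch, group2 = "grade7", n1 = length(v), n2 = NA_integer_,
        mean1 = if (length(v)) mean(v) else NA_real_, mean2 = mu0,
        sd1 = if (length(v) > 1) stats::sd(v) else NA_real_, sd2 = NA_real_,
        diff = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
        t_stat = NA_real_, df = NA_real_, p_raw = NA_real_, p_adj = NA_real_,
        included = FALSE
      ))
    }
    r <- tibble::as_tibble(one_sample_t_greater(v, mu0 = mu0,
                                                labels = c(ch, "grade7"),
                                                alpha = alpha))
    r$included <- TRUE
    r$significant <- NULL
    r
  })
  tb <- dplyr::bind_rows(rows)
  tb <- new_comparison(tb, scenario = "chapter_vs_grade7", alpha = alpha,
                       metric = "fkgl", adjusted = FALSE)
  tb$significant[!tb$included] <- NA
  tb
}

#' @exportS3Method generics::tidy
tidy.wr_comparison <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "wr_comparison")
  for (a in c("scenario", "alpha", "metric")) attr(out, a) <- NULL
  tibble::as_tibble(out)
}

#' @exportS3Method generics::glance
glance.wr_comparison <- function(x, ...) {
  tibble::tibble(
    scenario = attr(x, "scenario"),
    metric = attr(x, "metric"),
    alpha = attr(x, "alpha"),
    n_tests = sum(!is.na(x$p_raw)),
    n_significant = sum(x$significant, na.rm = TRUE)
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.wr_comparison <- function(object, ...) {
  tb <- tidy(object)
  tb <- tb[!is.na(tb$diff), , drop = FALSE]
  tb$comparison <- paste(tb$group1, "vs", tb$group2)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$diff, y = .data$comparison)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_lo, xmax = .data$ci_hi), height = 0.2
    ) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant), size = 2) +
    ggplot2::labs(
      x = sprintf("difference of means (%s, 95%% CI)",
                  attr(object, "metric") %||% "score"),
      y = NULL, colour = sprintf("p < %.2f", attr(object, "alpha"))
    ) +
    ggplot2::theme_minimal()
}

#' Distribution of articles over FRE difficulty bands
#'
#' Histogram-style summary of how many scored articles fall in each
#' difficulty band, per language (the data behind a per-language FRE
#' distribution figure).
#'
#' @param scored Scored article tibble (needs `language`, `fre_band`).
#' @return Tibble `language`, `fre_band`, `n`, `pct`.
#' @export
band_distribution <- function(scored) {
  scored |>
    dplyr::filter(!is.na(.data$fre_band)) |>
    dplyr::count(.data$language, .data$fre_band, .drop = FALSE) |>
    dplyr::group_by(.data$language) |>
    dplyr::mutate(pct = round(100 * .data$n / sum(.data$n), 2)) |>
    dplyr::ungroup()
}

#' Plot the FRE distribution per language
#'
#' @param scored Scored article tibble.
#' @param binwidth Histogram bin width in FRE points.
#' @return A ggplot object, one facet per language.
#' @export
plot_fre_distribution <- function(scored, binwidth = 5) {
  tb <- scored[!is.na(scored$fre), , drop = FALSE]
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$fre)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "steelblue",
                            colour = "white") +
    ggplot2::facet_wrap(~language, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Flesch Reading Ease", y = "articles") +
    ggplot2::theme_minimal()
}

#' Box plot of FRE per ICD-10 chapter
#'
#' @param instances Scored chapter-instance tibble for one language.
#' @param metric Metric column to plot.
#' @return A ggplot object with per-chapter boxes and mean markers.
#' @export
plot_chapter_boxes <- function(instances, metric = "fre") {
  tb <- instances[!is.na(instances[[metric]]), , drop = FALSE]
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$chapter, y = .data[[metric]])) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 18, size = 3,
                          colour = "darkred") +
    ggplot2::labs(x = "ICD-10 chapter", y = toupper(metric)) +
    ggplot2::theme_minimal()
}
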