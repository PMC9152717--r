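# The readability formulas. Each takes a text-statistics record (the tibble
# from text_statistics(), or any data frame / named list with the needed
# columns) and is vectorized over rows. Scores are never clamped or rounded
# here; presentation layers round to 2 decimals.

stats_field <- function(stats, field) {
  v <- stats[[field]]
  if (is.null(v)) {
    abort(paste0("text statistics are missing field '", field, "'"),
          class = "wr_bad_stats")
  }
  v
}

check_nondegenerate <- function(stats) {
  ns <- stats_field(stats, "n_sentences")
  nw <- stats_field(stats, "n_words")
  if (any(ns <= 0 | nw <= 0)) abort_degenerate()
  invisible(stats)
}

#' Flesch Reading Ease, with language-specific coefficients
#'
#' English uses the original Flesch coefficients; German the Amstad
#' adaptation; Russian the Solovyev adaptation. Higher values mean easier
#' text. Values are not clamped to \[0, 100\]: a one-syllable-per-word,
#' one-word-per-sentence text scores above 100.
#'
#' \deqn{FRE_{en} = 206.835 - 1.015\,ASL - 84.6\,ASW}
#' \deqn{FRE_{de} = 180 - ASL - 58.5\,ASW}
#' \deqn{FRE_{ru} = 208.7 - 2.6\,ASL - 39.2\,ASW}
#'
#' @param stats A text-statistics record (see [text_statistics()]) with
#'   columns `asl`, `asw`, `n_sentences`, `n_words`.
#' @param lang Language code (`"en"`, `"de"`, `"ru"`).
#' @return Numeric vector of FRE scores.
#' @export
fre <- function(stats, lang) {
  check_lang(lang)
  check_nondegenerate(stats)
  asl <- stats_field(stats, "asl")
  asw <- stats_field(stats, "asw")
  switch(lang,
    en = 206.835 - 1.015 * asl - 84.6 * asw,
    de = 180 - asl - 58.5 * asw,
    ru = 208.7 - 2.6 * asl - 39.2 * asw
  )
}

#' Flesch-Kincaid Grade Level (English and Russian)
#'
#' \deqn{FKGL_{en} = 0.39\,ASL + 11.8\,ASW - 15.59}
#' \deqn{FKGL_{ru} = 0.36\,ASL + 5.76\,ASW - 11.97}
#'
#' The Russian coefficients are the Solovyev adaptation. No German variant
#' exists in this pipeline; `lang = "de"` raises
#' `wr_unsupported_metric`.
#'
#' @inheritParams fre
#' @return Numeric vector of grade levels.
#' @export
fkgl <- function(stats, lang) {
  check_lang(lang, allowed = c("en", "ru"))
  check_nondegenerate(stats)
  asl <- stats_field(stats, "asl")
  asw <- stats_field(stats, "asw")
  switch(lang,
    en = 0.39 * asl + 11.8 * asw - 15.59,
    ru = 0.36 * asl + 5.76 * asw - 11.97
  )
}

#' Gunning FOG index (English)
#'
#' \deqn{FOG = 0.4 (ASL + \%\,hard\ words)} where hard words are words with
#' three or more syllables and the percentage is on the 0-100 scale.
#'
#' @inheritParams fre
#' @return Numeric vector of grade levels.
#' @export
gunning_fog <- function(stats) {
  check_nondegenerate(stats)
  0.4 * (stats_field(stats, "asl") + stats_field(stats, "pct_hard_words"))
}

#' SMOG grade (English)
#'
#' McLaughlin's formula on the polysyllabic word count \eqn{p}
#' (words with three or more syllables), normalized to a 30-sentence sample:
#' \deqn{SMOG = 3.1291 + 1.0430 \sqrt{p \cdot 30 / n_{sentences}}}
#'
#' @inheritParams fre
#' @return Numeric vector of grade levels.
#' @export
smog <- function(stats) {
  check_nondegenerate(stats)
  p <- stats_field(stats, "p_poly")
  ns <- stats_field(stats, "n_sentences")
  3.1291 + 1.0430 * sqrt(p * 30 / ns)
}

#' Automated Readability Index (English)
#'
#' \deqn{ARI = 4.71\,(chars/words) + 0.5\,(words/sentences) - 21.43}
#' Characters are letters and digits.
#'
#' @inheritParams fre
#' @return Numeric vector of grade levels.
#' @export
ari <- function(stats) {
  check_nondegenerate(stats)
  4.71 * stats_field(stats, "n_chars") / stats_field(stats, "n_words") +
    0.5 * stats_field(stats, "asl") - 21.43
}

#' Coleman-Liau Index (English)
#'
#' \deqn{CLI = 0.0588\,L - 0.296\,S - 15.8} with \eqn{L} the mean letters
#' per 100 words and \eqn{S} the mean sentences per 100 words.
#'
#' @inheritParams fre
#' @return Numeric vector of grade levels.
#' @export
coleman_liau <- function(stats) {
  check_nondegenerate(stats)
  0.0588 * stats_field(stats, "l_per100") -
    0.296 * stats_field(stats, "s_per100") - 15.8
}

#' Fourth Wiener Sachtextformel (German)
#'
#' The fourth variant of the Vienna formula for non-fiction German prose:
#' \deqn{WSTF_4 = 0.2656\,ASL + 0.2744\,MS - 1.6939} with MS the percentage
#' (0-100) of words with three or more syllables.
#'
#' @inheritParams fre
#' @param lang Language code; only `"de"` is accepted.
#' @return Numeric vector of grade levels.
#' @export
wstf4 <- function(stats, lang = "de") {
  check_lang(lang, allowed = "de")
  check_nondegenerate(stats)
  0.2656 * stats_field(stats, "asl") +
    0.2744 * stats_field(stats, "ms") - 1.6939
}

# difficulty bands: lower edge inclusive, so 30.00 is "difficult"
.wr_band_breaks <- c(-Inf, 30, 50, 60, 70, 80, 90, Inf)
.wr_band_labels <- c(
  "very_difficult", "difficult", "fairly_difficult",
  "standard", "fairly_easy", "easy", "very_easy"
)

#' Map Flesch Reading Ease scores to difficulty bands
#'
#' Half-open bands with inclusive lower edges: below 30 is very difficult,
#' \[30, 50) difficult, \[50, 60) fairly difficult, \[60, 70) standard,
#' \[70, 80) fairly easy, \[80, 90) easy, 90 and above very easy.
#'
#' @param fre Numeric vector of FRE scores.
#' @return Ordered factor of difficulty labels.
#' @examples
#' fre_band(c(29.999, 30, 75))
#' @export
fre_band <- function(fre) {
  cut(fre, breaks = .wr_band_breaks, labels = .wr_band_labels,
      right = FALSE, ordered_result = TRUE)
}

# which metrics exist for which language
.wr_metric_sets <- list(
  en = c("fre", "fkgl", "fog", "smog", "ari", "cli"),
  de = c("fre", "wstf4"),
  ru = c("fre", "fkgl")
)

score_stats_row <- function(stats, lang) {
  out <- list(
    fre = NA_real_, fkgl = NA_real_, fog = NA_real_, smog = NA_real_,
    ari = NA_real_, cli = NA_real_, wstf4 = NA_real_
  )
  out$fre <- fre(stats, lang)
  if (lang %in% c("en", "ru")) out$fkgl <- fkgl(stats, lang)
  if (lang == "en") {
    out$fog <- gunning_fog(stats)
    out$smog <- smog(stats)
    out$ari <- ari(stats)
    out$cli <- coleman_liau(stats)
  }
  if (lang == "de") out$wstf4 <- wstf4(stats, lang)
  out
}

#' Score a table of articles with the language-appropriate readability metrics
#'
#' The workhorse of the scoring stage. Takes a tibble of articles (columns
#' `id`, `language`, `text`; `title` and any annotation columns are carried
#' through), strips markup if asked, computes text statistics, and populates
#' exactly the metric set defined for each article's language: English gets
#' FRE, FKGL, FOG, SMOG, ARI and CLI; German FRE and WSTF4; Russian FRE and
#' FKGL. Metrics undefined for a language stay `NA`.
#'
#' Articles whose text yields zero sentences or zero words cannot be scored;
#' they are returned with `excluded_reason = "degenerate_text"` and `NA`
#' metrics, mirroring the exclusion-and-count treatment of texts for which
#' the metrics are technically uncomputable.
#'
#' @param articles Tibble with at least `id`, `language` and `text` columns.
#' @param strip If `TRUE` (default), pass text through [strip_wiki_markup()]
#'   first.
#' @return The input tibble with text-statistics columns, metric columns
#'   (`fre`, `fkgl`, `fog`, `smog`, `ari`, `cli`, `wstf4`), `fre_band`, and
#'   an `excluded_reason` column (`NA` for scored rows).
#' @export
score_articles <- function(articles, strip = TRUE) {
  stopifnot(all(c("id", "language", "text") %in% names(articles)))
  articles <- tibble::as_tibble(articles)
  txt <- if (strip) strip_wiki_markup(articles$text) else articles$text

  rows <- purrr::map2(txt, articles$language, function(tx, lg) {
    st <- tryCatch(text_statistics(tx, lg), wr_degenerate_text = function(e) NULL)
    if (is.null(st)) {
      return(tibble::tibble(n_sentences = NA_integer_, n_words = NA_integer_,
                            n_chars = NA_integer_, n_syllables = NA_integer_,
                            n_complex_words = NA_integer_, asl = NA_real_,
                            asw = NA_real_, ms = NA_real_,
                            pct_hard_words = NA_real_, l_per100 = NA_real_,
                            s_per100 = NA_real_, p_poly = NA_integer_,
                            fre = NA_real_, fkgl = NA_real_, fog = NA_real_,
                            smog = NA_real_, ari = NA_real_, cli = NA_real_,
                            wstf4 = NA_real_, degenerate = TRUE))
    }
    sc <- score_stats_row(st, lg)
    dplyr::bind_cols(st, tibble::as_tibble(sc), tibble::tibble(degenerate = FALSE))
  })
  res <- dplyr::bind_cols(
    articles[setdiff(names(articles), names(rows[[1]]))],
    dplyr::bind_rows(rows)
  )
  res$fre_band <- fre_band(res$fre)
  prev <- if ("excluded_reason" %in% names(articles)) {
    articles$excluded_reason
  } else {
    rep(NA_character_, nrow(res))
  }
  res$excluded_reason <- dplyr::if_else(res$degenerate, "degenerate_text", prev)
  dplyr::select(res, -"degenerate")
}
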