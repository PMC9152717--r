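# Turning raw article text into the counts every readability formula consumes:
# sentences, words, characters, syllables, and the derived ratios.

#' Strip wiki markup from article source
#'
#' Best-effort removal of the common wikitext constructs: templates
#' (`{{...}}`, nested), tables (`{|...|}`), reference tags, HTML comments and
#' tags, file/image links, headings markers, bold/italic quotes. Internal
#' links are replaced by their anchor text, external links by their label.
#' Unbalanced markup is stripped as far as possible; this function never
#' throws.
#'
#' @param wikitext Character vector of wikitext (or plain text, which passes
#'   through unchanged).
#' @return Character vector of plain text, same length as the input.
#' @examples
#' strip_wiki_markup("[[cough|Coughing]] is common")
#' strip_wiki_markup("{{Infobox disease}}Text.")
#' @export
strip_wiki_markup <- function(wikitext) {
  if (length(wikitext) == 0L) return(character())
  x <- as.character(wikitext)
  x[is.na(x)] <- ""

  x <- stringr::str_replace_all(x, stringr::regex("<!--.*?-->", dotall = TRUE), "")
  x <- stringr::str_replace_all(x, stringr::regex("<ref[^>/]*/>", ignore_case = TRUE), "")
  x <- stringr::str_replace_all(
    x, stringr::regex("<ref[^>]*>.*?</ref>", dotall = TRUE, ignore_case = TRUE), ""
  )
  # innermost-first so nested templates/tables/links unwind; file links are
  # dropped before plain links each round so captions do not leak
  repeat {
    y <- stringr::str_replace_all(x, stringr::regex("\\{\\{[^{}]*\\}\\}", dotall = TRUE), "")
    y <- stringr::str_replace_all(y, stringr::regex("\\{\\|[^{}]*?\\|\\}", dotall = TRUE), "")
    y <- stringr::str_replace_all(
      y,
      stringr::regex("\\[\\[(?:File|Image|Datei|Файл):[^\\[\\]]*\\]\\]",
                     ignore_case = TRUE),
      ""
    )
    y <- stringr::str_replace_all(
      y, "\\[\\[(?:[^\\[\\]|]*\\|)*([^\\[\\]|]*)\\]\\]", "\\1"
    )
    if (identical(y, x)) break
    x <- y
  }
  x <- stringr::str_replace_all(x, "\\[\\S+\\s+([^\\]]*)\\]", "\\1")
  x <- stringr::str_replace_all(x, "(?m)^\\s*=+\\s*(.*?)\\s*=+\\s*$", "\\1")
  x <- stringr::str_replace_all(x, "'{2,}", "")
  x <- stringr::str_replace_all(x, "<[^>]+>", "")
  # leftovers from unbalanced markup
  x <- stringr::str_replace_all(x, "[{}]|\\[\\[|\\]\\]", "")
  x <- stringr::str_replace_all(x, "(?m)^[*#:;]+\\s*", "")
  stringr::str_squish(x)
}

# Abbreviation stop lists ship as editable plain-text config, one entry per
# line; cached per language after first load.
.wr_abbrev_cache <- new.env(parent = emptyenv())

#' Sentence-boundary abbreviation list for a language
#'
#' Loaded from the plain-text config shipped under `extdata/abbrev/` (one
#' abbreviation per line, `#` comments allowed). Users can pass their own
#' file via `path`.
#'
#' @param lang Language code (`"en"`, `"de"`, `"ru"`).
#' @param path Optional path to a replacement list.
#' @return Character vector of abbreviations (with trailing periods).
#' @export
abbreviation_list <- function(lang, path = NULL) {
  check_lang(lang)
  if (!is.null(path)) {
    x <- readr::read_lines(path)
    x <- x[!startsWith(x, "#") & nzchar(trimws(x))]
    return(trimws(x))
  }
  if (!is.null(.wr_abbrev_cache[[lang]])) return(.wr_abbrev_cache[[lang]])
  f <- system.file("extdata", "abbrev", paste0(lang, ".txt"), package = "wikiread")
  x <- if (nzchar(f)) readr::read_lines(f) else character()
  x <- trimws(x[!startsWith(x, "#") & nzchar(trimws(x))])
  .wr_abbrev_cache[[lang]] <- x
  x
}

# one combined, cached alternation over the abbreviation list
.wr_abbrev_rx_cache <- new.env(parent = emptyenv())

abbrev_regex <- function(lang) {
  hit <- .wr_abbrev_rx_cache[[lang]]
  if (!is.null(hit)) return(if (identical(hit, FALSE)) NULL else hit)
  abb <- abbreviation_list(lang)
  if (length(abb) == 0L) {
    .wr_abbrev_rx_cache[[lang]] <- FALSE
    return(NULL)
  }
  esc <- stringr::str_replace_all(abb, "([\\\\.^$|()\\[\\]{}*+?])", "\\\\\\1")
  rx <- stringr::regex(paste0(
    "(?<=^|[^\\p{L}])(?:", paste(esc, collapse = "|"), ")"
  ), ignore_case = TRUE)
  .wr_abbrev_rx_cache[[lang]] <- rx
  rx
}

#' Split plain text into sentences
#'
#' Sentences end at terminal punctuation (`.`, `!`, `?`, `…`).
#' Language-specific abbreviation lists and decimal numbers are protected
#' from producing false boundaries. The concatenation of the returned
#' sentences equals the input up to boundary whitespace.
#'
#' @param text A single plain-text string.
#' @param lang Language code.
#' @return Character vector of sentences (empty for empty/whitespace input).
#' @examples
#' segment_sentences("A. B? C!", "en")
#' segment_sentences("Dr. Smith came. He left.", "en")
#' @export
segment_sentences <- function(text, lang) {
  check_lang(lang)
  stopifnot(length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) return(character())
  x <- text
  prot <- "\u0001" # protected-period placeholder
  x <- stringr::str_replace_all(x, "(?<=\\d)\\.(?=\\d)", prot)
  rx <- abbrev_regex(lang)
  if (!is.null(rx)) {
    x <- stringr::str_replace_all(
      x, rx,
      function(m) stringr::str_replace_all(m, stringr::fixed("."), prot)
    )
  }
  parts <- stringr::str_split(x, "(?<=[.!?…])\\s+")[[1]]
  parts <- stringr::str_replace_all(parts, stringr::fixed(prot), ".")
  parts <- trimws(parts)
  parts[nzchar(parts)]
}

#' Tokenize a sentence into words
#'
#' Tokens are maximal runs of letters/digits, allowing internal hyphens and
#' apostrophes (so hyphenated compounds stay one word). Pure punctuation is
#' discarded.
#'
#' @param sentence A single string (one sentence).
#' @param lang Language code (accepted for interface symmetry; the rule is
#'   script-agnostic).
#' @return Character vector of word tokens.
#' @examples
#' tokenize_words("The cat-door, open.", "en")
#' @export
tokenize_words <- function(sentence, lang = "en") {
  check_lang(lang)
  stopifnot(length(sentence) == 1L)
  if (is.na(sentence) || !nzchar(sentence)) return(character())
  m <- stringr::str_extract_all(sentence, .wr_token_rx)[[1]]
  m[nzchar(m)]
}

.wr_token_rx <- "[\\p{L}\\p{N}]+(?:[-'’][\\p{L}\\p{N}]+)*"

# vowel classes per language (lowercase); y counts as a vowel in English
.wr_vowels <- c(
  en = "[aeiouy]",
  de = "[aeiouyäöü]",
  ru = "[аеёиоуыэюя]"
)

#' Count syllables in word tokens
#'
#' Russian: the number of vowel letters, the standard rule for Cyrillic
#' (one vowel per syllable). English and German: vowel-group counting with
#' orthographic adjustments (adjacent vowels count once; English silent
#' final `e`, `es`, `ed` are discounted except after `l`). Every token gets
#' at least one syllable; tokens without letters (pure numbers) count as one.
#'
#' @param words Character vector of tokens.
#' @param lang Language code.
#' @return Integer vector of syllable counts, `>= 1` elementwise.
#' @examples
#' count_syllables(c("a", "readability"), "en")
#' count_syllables("кашель", "ru")
#' @export
count_syllables <- function(words, lang) {
  check_lang(lang)
  if (length(words) == 0L) return(integer())
  w <- stringr::str_to_lower(words)
  w <- stringr::str_replace_all(w, "[^\\p{L}]", "")
  vow <- .wr_vowels[[lang]]
  # Russian counts vowel letters (one per syllable); en/de count vowel
  # groups so diphthongs and digraphs weigh once
  n <- if (lang == "ru") {
    stringr::str_count(w, vow)
  } else {
    stringr::str_count(w, paste0(vow, "+"))
  }
  if (lang == "en") {
    # silent final e ("disease"), and the weak -es / -ed endings after a
    # consonant ("makes", "walked"); -le keeps its syllable ("table")
    silent <- stringr::str_detect(w, "[^aeiouyl]e$") |
      stringr::str_detect(w, "[^aeiouy]e[sd]$") &
        !stringr::str_detect(w, "[sxzcg]e[sd]$|[td]ed$")
    n <- n - as.integer(silent & n > 1L)
  }
  pmax(n, 1L)
}

#' Compute the full text-statistics record for one article text
#'
#' Runs segmentation, tokenization and syllable counting and derives every
#' ratio the readability formulas need: average sentence length (ASL),
#' average syllables per word (ASW), the percentage of complex words with
#' three or more syllables (MS, identical to the "hard word" percentage),
#' letters per 100 words (L), sentences per 100 words (S) and the
#' polysyllabic word count (p). Characters are letters and digits only.
#'
#' @param text A single plain-text string (strip markup first if needed).
#' @param lang Language code.
#' @return A one-row tibble with columns `n_sentences`, `n_words`,
#'   `n_chars`, `n_syllables`, `n_complex_words`, `asl`, `asw`, `ms`,
#'   `pct_hard_words`, `l_per100`, `s_per100`, `p_poly`.
#'
#'   Texts with zero sentences or zero words cannot support any metric and
#'   raise a condition of class `wr_degenerate_text`; batch callers catch it
#'   and record the article as excluded (see [score_articles()]).
#' @examples
#' text_statistics("The cat sat. The dog ran.", "en")
#' @export
text_statistics <- function(text, lang) {
  check_lang(lang)
  sents <- segment_sentences(text, lang)
  if (length(sents) == 0L) abort_degenerate()
  toks <- stringr::str_extract_all(sents, .wr_token_rx)
  words <- unlist(toks, use.names = FALSE)
  if (length(words) == 0L) abort_degenerate()

  syl <- count_syllables(words, lang)
  n_sent <- length(sents)
  n_words <- length(words)
  n_chars <- sum(stringr::str_count(words, "[\\p{L}\\p{N}]"))
  n_syl <- sum(syl)
  n_complex <- sum(syl >= 3L)

  tibble::tibble(
    n_sentences = n_sent,
    n_words = n_words,
    n_chars = n_chars,
    n_syllables = n_syl,
    n_complex_words = n_complex,
    asl = n_words / n_sent,
    asw = n_syl / n_words,
    ms = 100 * n_complex / n_words,
    pct_hard_words = 100 * n_complex / n_words,
    l_per100 = 100 * n_chars / n_words,
    s_per100 = 100 * n_sent / n_words,
    p_poly = n_complex
  )
}
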