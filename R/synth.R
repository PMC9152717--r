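# Synthetic snapshot generator. Produces complete, deterministic snapshots
# (articles, category graph, interlanguage links, metadata code map, filter
# lists) with controlled statistical structure: known sentence counts and
# syllables per word, planted decoys for each harvesting filter, partial
# ICD annotation across linked editions, multi-chapter code sets, and
# optional per-chapter FRE offsets injected through the ASW channel.

.wr_synth_alphabet <- list(
  en = list(cons = c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t"),
            vows = c("a", "i", "o", "u")),
  de = list(cons = c("b", "d", "f", "g", "k", "l", "m", "n", "r", "s", "t", "w"),
            vows = c("a", "i", "o", "u")),
  ru = list(cons = c("к", "т", "м", "н", "р", "с", "л", "в", "п", "д"),
            vows = c("а", "о", "у", "и", "я", "е"))
)

#' Generate pseudo-words with an exact, known syllable count
#'
#' Words are built from consonant-vowel syllable templates in the language's
#' script; every syllable holds exactly one isolated vowel, so the
#' construction count is the ground truth and [count_syllables()] recovers
#' it exactly (the letter inventory avoids the orthographic special cases —
#' no final `e` in Latin-script words). Uses the current RNG state; wrap in
#' [withr::with_seed()] for reproducibility.
#'
#' @param lang Language code.
#' @param n_syllables Integer vector; one word per element, each with that
#'   many syllables.
#' @return Character vector of pseudo-words.
#' @export
generate_word <- function(lang, n_syllables) {
  check_lang(lang)
  stopifnot(all(n_syllables >= 1))
  ab <- .wr_synth_alphabet[[lang]]
  k <- as.integer(n_syllables)
  total <- sum(k)
  syl <- paste0(sample(ab$cons, total, replace = TRUE),
                sample(ab$vows, total, replace = TRUE))
  idx <- rep.int(seq_along(k), k)
  words <- vapply(split(syl, idx), paste0, character(1), collapse = "")
  # close roughly half the words with a final consonant (adds letters, not
  # syllables)
  coda <- stats::runif(length(words)) < 0.5
  words[coda] <- paste0(words[coda], sample(ab$cons, sum(coda), replace = TRUE))
  # a generated word must never collide with a sentence-boundary
  # abbreviation ("no" + period would merge two sentences); extend it with a
  # coda consonant, which changes no syllable count
  stems <- abbrev_stems(lang)
  bad <- tolower(words) %in% stems
  while (any(bad)) {
    words[bad] <- paste0(words[bad], sample(ab$cons, sum(bad), replace = TRUE))
    bad <- tolower(words) %in% stems
  }
  unname(words)
}

abbrev_stems <- function(lang) {
  tolower(sub("\\.$", "", abbreviation_list(lang)))
}

# syllables per word: 1 + Binomial(5, p), support 1..6, mean 1 + 5p
syllable_draw <- function(n, asw_target) {
  p <- min(max((asw_target - 1) / 5, 0), 1)
  1L + stats::rbinom(n, 5L, p)
}

#' Generate one synthetic article with known text statistics
#'
#' Builds `n_sentences` sentences whose lengths are Poisson around
#' `asl_target` (minimum 2 words) and whose words draw syllable counts from
#' a truncated discrete distribution on 1-6 with mean `asw_target`
#' (`1 + Binomial(5, (asw - 1)/5)`, a one-parameter moment match). The
#' realized counts are returned as ground truth alongside the text.
#'
#' @param lang Language code.
#' @param n_sentences Number of sentences (>= 1).
#' @param asl_target Target mean words per sentence.
#' @param asw_target Target mean syllables per word.
#' @return A list with `text` (single string) and `truth` (one-row tibble:
#'   `n_sentences`, `n_words`, `n_syllables`, `asl`, `asw`).
#' @export
generate_article <- function(lang, n_sentences, asl_target, asw_target) {
  check_lang(lang)
  stopifnot(n_sentences >= 1, asl_target > 0, asw_target >= 1)
  lens <- pmax(2L, stats::rpois(n_sentences, asl_target))
  # nudge sentence lengths so the realized ASL lands on the target (within
  # rounding), keeping the Poisson shape otherwise
  target_total <- max(2L * n_sentences, as.integer(round(asl_target * n_sentences)))
  while (sum(lens) != target_total) {
    gap <- target_total - sum(lens)
    if (gap > 0) {
      i <- sample.int(n_sentences, min(gap, n_sentences))
      lens[i] <- lens[i] + 1L
    } else {
      adj <- which(lens > 2L)
      i <- adj[sample.int(length(adj), min(-gap, length(adj)))]
      lens[i] <- lens[i] - 1L
    }
  }
  n_words <- sum(lens)
  syl <- syllable_draw(n_words, asw_target)
  words <- generate_word(lang, syl)
  sent_id <- rep.int(seq_len(n_sentences), lens)
  sents <- vapply(split(words, sent_id), function(w) {
    w[1] <- paste0(toupper(substr(w[1], 1, 1)), substr(w[1], 2, nchar(w[1])))
    paste0(paste(w, collapse = " "), ".")
  }, character(1))
  list(
    text = paste(sents, collapse = " "),
    truth = tibble::tibble(
      n_sentences = n_sentences, n_words = n_words, n_syllables = sum(syl),
      asl = n_words / n_sentences, asw = sum(syl) / n_words
    )
  )
}

# invert the language's FRE formula: the ASW that hits `fre` at given `asl`
asw_for_fre <- function(lang, fre, asl) {
  out <- switch(lang,
    en = (206.835 - 1.015 * asl - fre) / 84.6,
    de = (180 - asl - fre) / 58.5,
    ru = (208.7 - 2.6 * asl - fre) / 39.2
  )
  pmin(pmax(out, 1.01), 5.9)
}

#' Specification of a synthetic corpus
#'
#' Defaults echo the study conditions of a disease-article corpus at desk
#' scale: per-language group-A mean FRE and SD (en 28.69/11.00, de
#' 20.33/9.98, ru 38.54/13.51), lognormal sentence counts on the scale of
#' real disease articles, unequal per-language article counts
#' (en:de:ru roughly 2:2:1), partial interlanguage coverage, ~70% of
#' concept clusters carrying an ICD-10 code, and a share of multi-chapter
#' code sets. Chapter FRE offsets are expressed in FRE points and injected
#' by shifting the ASW channel through the language's own FRE coefficients.
#'
#' @param n_clusters Number of disease-concept clusters.
#' @param coverage Named per-language probability that a cluster has an
#'   article in that edition (English is the reference edition with 1).
#' @param sentences_meanlog,sentences_sdlog Lognormal parameters of the
#'   per-article sentence count (per language).
#' @param asl_mean,asl_sd Per-language Normal parameters of target ASL.
#' @param fre_mean,fre_sd Per-language Normal parameters of target FRE;
#'   converted to per-article ASW targets via the FRE coefficients.
#' @param code_fraction Fraction of clusters that carry an ICD-10 code.
#' @param multi_chapter_fraction Among coded clusters, fraction whose code
#'   set spans two different chapters.
#' @param chapter_letters,chapter_weights Chapter alphabet to sample codes
#'   from and its sampling weights.
#' @param chapter_fre_offset Named numeric (by chapter letter) of FRE-point
#'   offsets applied to articles of that chapter, per language listed in
#'   `offset_langs`.
#' @param offset_langs Languages the chapter offsets apply to.
#' @param lang_fre_offset Named per-language FRE-point shifts added to
#'   `fre_mean` (used to plant interlanguage differences).
#' @param decoys Named counts of planted decoy articles per filter type
#'   (English edition): `category_wildcard`, `given_name`, `geographic`,
#'   `stop_word`.
#' @param n_degenerate Number of empty-text articles planted per language.
#' @param seed Integer seed; fully determines the snapshot.
#' @return A list of class `wr_corpus_spec`.
#' @export
corpus_spec <- function(
    n_clusters = 320,
    coverage = c(en = 1.0, de = 0.95, ru = 0.52),
    sentences_meanlog = c(en = 3.75, de = 3.4, ru = 3.3),
    sentences_sdlog = c(en = 0.85, de = 0.85, ru = 0.85),
    asl_mean = c(en = 21.5, de = 15.5, ru = 12.5),
    asl_sd = c(en = 3, de = 2.5, ru = 2),
    fre_mean = c(en = 28.69, de = 20.33, ru = 38.54),
    fre_sd = c(en = 11.00, de = 9.98, ru = 13.51),
    code_fraction = 0.70,
    multi_chapter_fraction = 0.15,
    chapter_letters = c("A", "B", "C", "E", "F", "G", "I", "J", "K", "M",
                        "N", "O", "Q", "S", "T"),
    chapter_weights = NULL,
    chapter_fre_offset = NULL,
    offset_langs = "en",
    lang_fre_offset = c(en = 0, de = 0, ru = 0),
    decoys = c(category_wildcard = 5, given_name = 5, geographic = 5,
               stop_word = 5),
    n_degenerate = 2,
    seed = 20210630) {
  if (!is.null(chapter_fre_offset) &&
      !all(names(chapter_fre_offset) %in% chapter_letters)) {
    abort("chapter_fre_offset names chapters outside chapter_letters",
          class = "wr_config_error")
  }
  if (is.null(chapter_weights)) {
    chapter_weights <- rep(1, length(chapter_letters))
  }
  stopifnot(code_fraction >= 0, code_fraction <= 1,
            multi_chapter_fraction >= 0, multi_chapter_fraction <= 1)
  structure(as.list(environment()), class = "wr_corpus_spec")
}

synth_root_title <- c(en = "Human diseases and disorders",
                      de = "Krankheit",
                      ru = "Заболевания человека")

synth_decoy_defs <- list(
  category_wildcard = list(category = "Diseases and disorders by country",
                           title = "List of diseases in region %d"),
  given_name = list(category = "Disease researchers",
                    title = "Maria Example%d"),
  geographic = list(category = "Health by place",
                    title = "Health in Germany %d"),
  stop_word = list(category = "Health movements",
                   title = "Disease awareness organization %d")
)

#' Filter configuration matched to the synthetic decoys
#'
#' The pattern lists that target exactly the decoy articles
#' [generate_snapshot()] plants; each decoy matches its intended filter and
#' no earlier one.
#'
#' @return A [filter_config()].
#' @export
synth_filter_config <- function() {
  filter_config(
    category_wildcards = "*by country",
    given_names = "Maria",
    geo_terms = "*Germany*",
    stop_words = "*organization*"
  )
}

#' Generate a complete synthetic snapshot
#'
#' Emits the four interchange files ([load_snapshot()]'s format) plus the
#' matching filter lists into `dir`: a per-language category tree (with a
#' planted cycle) rooted at the language's disease concept; disease articles
#' organised in interlanguage clusters with partial coverage; ICD-10 codes
#' placed in the metadata map for a random strict subset of each coded
#' cluster's editions (so cross-language propagation is exercised), with a
#' configurable share of two-chapter code sets; decoy categories/articles
#' for each filter; and a few empty-text articles that exercise the
#' degenerate-text exclusion. Fully determined by `spec$seed`.
#'
#' @param spec A [corpus_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `dir`, the file `paths`, and `truth`
#'   (tibbles `articles` — per-article ground-truth stats, cluster, chapter
#'   set, coded flag — and `clusters`).
#' @export
generate_snapshot <- function(spec, dir) {
  stopifnot(inherits(spec, "wr_corpus_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  withr::with_seed(spec$seed, generate_snapshot_impl(spec, dir))
}

generate_snapshot_impl <- function(spec, dir) {
  langs <- WR_LANGS
  nc <- spec$n_clusters

  # cluster-level structure
  member <- vapply(langs, function(lg) {
    stats::runif(nc) < spec$coverage[[lg]]
  }, logical(nc))
  member[, "en"] <- member[, "en"] | rowSums(member) == 0
  coded <- stats::runif(nc) < spec$code_fraction
  multi <- coded & stats::runif(nc) < spec$multi_chapter_fraction
  ch1 <- sample(spec$chapter_letters, nc, replace = TRUE,
                prob = spec$chapter_weights)
  ch2 <- vapply(ch1, function(c1) {
    sample(setdiff(spec$chapter_letters, c1), 1)
  }, character(1))
  code_of <- function(ch) {
    sprintf("%s%02d.%d", ch, sample(0:99, length(ch), replace = TRUE),
            sample(0:9, length(ch), replace = TRUE))
  }
  codes <- vector("list", nc)
  codes[coded & !multi] <- lapply(ch1[coded & !multi], code_of)
  codes[multi] <- Map(function(a, b) c(code_of(a), code_of(b)),
                      ch1[multi], ch2[multi])

  clusters <- tibble::tibble(
    cluster = seq_len(nc), coded = coded,
    chapters = lapply(seq_len(nc), function(i) {
      if (!coded[i]) character() else unique(substr(codes[[i]], 1, 1))
    }),
    codes = codes
  )

  # per-language article generation
  arts <- list(); truth <- list()
  for (lg in langs) {
    rows <- which(member[, lg])
    n <- length(rows)
    ns <- pmax(3L, as.integer(round(stats::rlnorm(
      n, spec$sentences_meanlog[[lg]], spec$sentences_sdlog[[lg]]
    ))))
    asl <- pmax(5, stats::rnorm(n, spec$asl_mean[[lg]], spec$asl_sd[[lg]]))
    mu <- spec$fre_mean[[lg]] + (spec$lang_fre_offset[[lg]] %||% 0)
    fre_t <- stats::rnorm(n, mu, spec$fre_sd[[lg]])
    if (!is.null(spec$chapter_fre_offset) && lg %in% spec$offset_langs) {
      for (ch in names(spec$chapter_fre_offset)) {
        has_ch <- vapply(clusters$chapters[rows], function(cc) ch %in% cc,
                         logical(1))
        fre_t[has_ch] <- fre_t[has_ch] + spec$chapter_fre_offset[[ch]]
      }
    }
    asw <- asw_for_fre(lg, fre_t, asl)
    gen <- Map(generate_article, lang = lg, n_sentences = ns,
               asl_target = asl, asw_target = asw)
    arts[[lg]] <- tibble::tibble(
      id = sprintf("%s-%04d", lg, rows),
      language = lg,
      title = synth_title(lg, rows),
      text = vapply(gen, `[[`, character(1), "text"),
      icd_codes = rep(list(character()), n),
      cluster = rows
    )
    truth[[lg]] <- dplyr::bind_cols(
      tibble::tibble(id = arts[[lg]]$id, language = lg, cluster = rows,
                     coded = coded[rows], fre_target = fre_t),
      dplyr::bind_rows(lapply(gen, `[[`, "truth"))
    )
  }
  articles <- dplyr::bind_rows(arts)

  # degenerate plants
  degen <- dplyr::bind_rows(lapply(langs, function(lg) {
    k <- spec$n_degenerate
    if (k == 0) return(NULL)
    tibble::tibble(
      id = sprintf("%s-degen-%02d", lg, seq_len(k)), language = lg,
      title = paste0(synth_root_title[[lg]], " stub ", seq_len(k)),
      text = "", icd_codes = rep(list(character()), k), cluster = NA_integer_
    )
  }))

  # decoys (English edition)
  decoy <- dplyr::bind_rows(lapply(names(synth_decoy_defs), function(f) {
    k <- spec$decoys[[f]] %||% 0
    if (k == 0) return(NULL)
    d <- synth_decoy_defs[[f]]
    tibble::tibble(
      id = sprintf("en-%s-%02d", gsub("_", "", f), seq_len(k)),
      language = "en", title = sprintf(d$title, seq_len(k)),
      text = "Decoy text. More decoy text here.",
      icd_codes = rep(list(character()), k), cluster = NA_integer_,
      decoy = f
    )
  }))
  if (nrow(decoy) == 0) {
    decoy <- tibble::tibble(id = character(), language = character(),
                            title = character(), text = character(),
                            icd_codes = list(), cluster = integer(),
                            decoy = character())
  }

  all_articles <- dplyr::bind_rows(articles, degen,
                                   dplyr::select(decoy, -"decoy"))

  # category graph per language: root -> 4 topic categories (+ cycle), with
  # articles spread over them; decoy categories hang off the root
  nodes <- list(); edges <- list()
  for (lg in langs) {
    aa <- all_articles[all_articles$language == lg, ]
    root_id <- paste0(lg, "-cat-root")
    topics <- paste0(lg, "-cat-", 1:4)
    nd <- tibble::tibble(
      node_id = c(root_id, topics),
      type = "category",
      title = c(synth_root_title[[lg]], paste0("Topic ", 1:4, " (", lg, ")")),
      language = lg
    )
    ed <- tibble::tibble(parent_id = root_id, child_id = topics)
    # planted cycle
    ed <- dplyr::bind_rows(ed, tibble::tibble(
      parent_id = c(topics[1], topics[2]), child_id = c(topics[2], topics[1])
    ))
    is_decoy_art <- aa$id %in% decoy$id
    reg <- aa$id[!is_decoy_art]
    ed <- dplyr::bind_rows(ed, tibble::tibble(
      parent_id = sample(topics, length(reg), replace = TRUE),
      child_id = reg
    ))
    if (lg == "en" && nrow(decoy) > 0) {
      dcats <- vapply(synth_decoy_defs, `[[`, character(1), "category")
      dcat_ids <- paste0("en-cat-decoy-", seq_along(dcats))
      nd <- dplyr::bind_rows(nd, tibble::tibble(
        node_id = dcat_ids, type = "category", title = unname(dcats),
        language = "en"
      ))
      ed <- dplyr::bind_rows(ed, tibble::tibble(parent_id = root_id,
                                                child_id = dcat_ids))
      dcat_of <- setNames(dcat_ids, names(synth_decoy_defs))
      ed <- dplyr::bind_rows(ed, tibble::tibble(
        parent_id = dcat_of[decoy$decoy], child_id = decoy$id
      ))
    }
    nd <- dplyr::bind_rows(nd, tibble::tibble(
      node_id = aa$id, type = "article", title = aa$title, language = lg
    ))
    nodes[[lg]] <- nd; edges[[lg]] <- ed
  }

  # interlanguage links: en-de and en-ru pairs (plus de-ru when en absent)
  links <- list()
  for (i in seq_len(nc)) {
    present <- langs[member[i, ]]
    if (length(present) < 2) next
    keys <- lang_key(present, synth_title(present, i))
    links[[length(links) + 1]] <- tibble::tibble(
      key1 = keys[1], key2 = keys[-1]
    )
  }
  langlinks <- dplyr::bind_rows(links)
  if (nrow(langlinks) == 0) {
    langlinks <- tibble::tibble(key1 = character(), key2 = character())
  }

  # metadata code map: codes placed in a strict random subset of the coded
  # cluster's editions (1 of k, or all when only one edition exists)
  icd_rows <- list()
  for (i in which(coded)) {
    present <- langs[member[i, ]]
    n_keep <- max(1L, min(length(present) - 1L, sample(1:2, 1)))
    keep <- sample(present, n_keep)
    icd_rows[[length(icd_rows) + 1]] <- tibble::tibble(
      key = lang_key(keep, synth_title(keep, i)),
      codes = paste(codes[[i]], collapse = ",")
    )
  }
  icd_map <- dplyr::bind_rows(icd_rows)
  if (nrow(icd_map) == 0) {
    icd_map <- tibble::tibble(key = character(), codes = character())
  }

  paths <- write_snapshot_files(dir, all_articles, dplyr::bind_rows(nodes),
                                dplyr::bind_rows(edges), langlinks, icd_map)

  truth_articles <- dplyr::bind_rows(truth)
  truth_articles$chapters <- clusters$chapters[truth_articles$cluster]
  invisible(list(
    dir = dir, paths = paths,
    truth = list(articles = truth_articles, clusters = clusters,
                 decoys = decoy, degenerate = degen)
  ))
}

#' Replicated recovery of planted interlanguage FRE offsets
#'
#' Validation simulation: each replicate generates a small synthetic
#' snapshot whose per-language mean FRE plants the pairwise offsets
#' `en - de = offset_en_de` and `en - ru = offset_en_ru` (the de-ru offset
#' follows), scores it, and runs the pairwise interlanguage comparison. The
#' returned table records, per replicate and pair, the estimated difference
#' of means and whether the 95% CI covered the planted value. With a
#' correctly calibrated Welch interval the coverage rate is close to 95%.
#'
#' @param n_rep Number of replicates.
#' @param offset_en_de,offset_en_ru Planted mean FRE differences, in FRE
#'   points.
#' @param n_clusters Clusters per replicate snapshot (small by design; CI
#'   coverage does not depend on n).
#' @param seed Integer seed for the whole simulation.
#' @return Tibble with `rep`, `pair`, `planted`, `diff`, `ci_lo`, `ci_hi`,
#'   `covered`.
#' @export
simulate_interlanguage_recovery <- function(n_rep = 200, offset_en_de = 8,
                                            offset_en_ru = -10,
                                            n_clusters = 40, seed = 1) {
  base <- 28.69
  planted <- c(en_de = offset_en_de, en_ru = offset_en_ru,
               de_ru = offset_en_ru - offset_en_de)
  withr::with_seed(seed, {
    seeds <- sample.int(.Machine$integer.max, n_rep)
  })
  rows <- lapply(seq_len(n_rep), function(r) {
    spec <- corpus_spec(
      n_clusters = n_clusters,
      coverage = c(en = 0.95, de = 0.95, ru = 0.95),
      sentences_meanlog = c(en = 2.2, de = 2.2, ru = 2.2),
      sentences_sdlog = c(en = 0.3, de = 0.3, ru = 0.3),
      fre_mean = c(en = base, de = base - offset_en_de,
                   ru = base - offset_en_ru),
      decoys = c(category_wildcard = 0, given_name = 0, geographic = 0,
                 stop_word = 0),
      n_degenerate = 0,
      seed = seeds[r]
    )
    dir <- tempfile("wr-rec-")
    on.exit(unlink(dir, recursive = TRUE), add = TRUE)
    generate_snapshot(spec, dir)
    arts <- load_snapshot(dir)$articles
    sc <- score_articles(arts, strip = FALSE)
    cmp <- tidy(compare_languages(sc))
    pair <- paste(cmp$group1, cmp$group2, sep = "_")
    target <- unname(planted[pair])
    tibble::tibble(
      rep = r, pair = pair, planted = target,
      diff = cmp$diff, ci_lo = cmp$ci_lo, ci_hi = cmp$ci_hi,
      covered = cmp$ci_lo <= target & target <= cmp$ci_hi
    )
  })
  dplyr::bind_rows(rows)
}

synth_title <- function(lang, i) {
  stem <- c(en = "Synthetic disease", de = "Synthetische Krankheit",
            ru = "Синтетическая болезнь")
  paste0(stem[lang], " ", i)
}

write_snapshot_files <- function(dir, articles, nodes, edges, langlinks,
                                 icd_map) {
  f_art <- file.path(dir, "articles.jsonl")
  recs <- vapply(seq_len(nrow(articles)), function(i) {
    jsonlite::toJSON(list(
      id = articles$id[i], language = articles$language[i],
      title = articles$title[i], text = articles$text[i],
      icd_codes = as.list(articles$icd_codes[[i]])
    ), auto_unbox = TRUE)
  }, character(1))
  writeLines(recs, f_art, useBytes = TRUE)

  f_nodes <- file.path(dir, "nodes.tsv")
  readr::write_tsv(nodes, f_nodes, progress = FALSE)
  f_edges <- file.path(dir, "edges.tsv")
  readr::write_tsv(edges, f_edges, progress = FALSE)
  f_links <- file.path(dir, "langlinks.tsv")
  readr::write_tsv(langlinks, f_links, progress = FALSE)
  f_icd <- file.path(dir, "icd_map.tsv")
  readr::write_tsv(icd_map, f_icd, progress = FALSE)

  fdir <- file.path(dir, "filters")
  dir.create(fdir, showWarnings = FALSE)
  cfg <- synth_filter_config()
  for (nm in names(cfg)) {
    writeLines(cfg[[nm]], file.path(fdir, paste0(nm, ".txt")))
  }
  list(articles = f_art, nodes = f_nodes, edges = f_edges,
       langlinks = f_links, icd_map = f_icd, filters = fdir)
}
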