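# End-to-end orchestration: collect -> merge/ICD -> score -> compare, with
# CSV/JSONL report files and a stage-count log. A thin command-line wrapper
# around these functions ships at inst/cli/wikiread.R.

.wr_metric_cols <- c("fre", "fkgl", "fog", "smog", "ari", "cli", "wstf4")

#' Long-format descriptive table of metric values
#'
#' @param scored Scored article (or chapter-instance) tibble.
#' @param by Character vector of grouping columns (e.g. `c("language",
#'   "group")` or `c("language", "chapter")`).
#' @return Tibble with the grouping columns, `metric`, `n`, `mean`, `sd`,
#'   `min`, `max`; SD is `NA` for single-observation groups.
#' @export
metric_descriptives <- function(scored, by = c("language", "group")) {
  scored |>
    dplyr::select(dplyr::all_of(by),
                  dplyr::any_of(c(.wr_metric_cols,
                                  "n_sentences", "n_words", "n_complex_words"))) |>
    tidyr::pivot_longer(-dplyr::all_of(by), names_to = "metric",
                        values_to = "value",
                        values_transform = as.numeric) |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "metric")))) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sd = dplyr::if_else(dplyr::n() > 1, stats::sd(.data$value), NA_real_),
      min = min(.data$value),
      max = max(.data$value),
      .groups = "drop"
    )
}

#' Run the whole analysis pipeline on a snapshot
#'
#' Stages: (1) load the snapshot; (2) per language, traverse the category
#' graph from the root concept and apply the four-filter exclusion pipeline;
#' (3) expand each language's set through interlanguage links; (4) resolve,
#' validate and propagate ICD-10 codes and split into groups A/B; (5) score
#' every article with its language's readability metrics (degenerate texts
#' excluded and counted); (6) expand group A into per-chapter instances;
#' (7) run the three comparison scenarios. When `out_dir` is given, writes
#' the report files: `group_summary.csv`, `descriptives_groups.csv`,
#' `descriptives_chapters.csv`, `interlanguage.csv`, `chapters_<lang>.csv`,
#' `grade7_en.csv`, `exclusions.csv`, `band_distribution.csv`,
#' `scored.csv`, and `run_log.json` with counts at every stage.
#'
#' @param snapshot_dir Directory with the snapshot interchange files.
#' @param out_dir Optional report directory.
#' @param config A [filter_config()]; default reads the `filters/` lists
#'   inside the snapshot directory.
#' @param root_titles Named character vector of per-language root category
#'   titles.
#' @param manual_exclusions Optional manual ICD-code exclusion list (tibble
#'   or TSV path), see [resolve_icd_codes()].
#' @param alpha Significance level for all scenarios.
#' @param min_n Strict chapter-inclusion threshold (chapters need n >
#'   `min_n`).
#' @param mu0 Recommended grade level for scenario 3.
#' @return A list of class `wr_run`: `scored`, `instances`, `group_summary`,
#'   `interlanguage`, `chapters` (per language), `grade7`, `exclusions`,
#'   `bands`, `log`.
#' @export
run_pipeline <- function(snapshot_dir, out_dir = NULL, config = NULL,
                         root_titles = synth_root_title,
                         manual_exclusions = NULL,
                         alpha = 0.05, min_n = 25, mu0 = 7) {
  snap <- load_snapshot(snapshot_dir)
  if (is.null(config)) {
    fdir <- file.path(snapshot_dir, "filters")
    config <- if (dir.exists(fdir)) {
      filter_config(
        category_wildcards = file.path(fdir, "category_wildcards.txt"),
        given_names = file.path(fdir, "given_names.txt"),
        geo_terms = file.path(fdir, "geo_terms.txt"),
        stop_words = file.path(fdir, "stop_words.txt")
      )
    } else {
      filter_config()
    }
  }
  log <- list(snapshot = snap$counts)
  members <- category_memberships(snap)

  collected <- list(); exclusions <- list()
  for (lg in intersect(WR_LANGS, unique(snap$articles$language))) {
    ids <- traverse_from_root(snap, root_titles[[lg]], lg)
    arts <- snap$articles[snap$articles$id %in% ids, , drop = FALSE]
    fl <- apply_filters(arts, members, config)
    collected[[lg]] <- fl$kept
    exclusions[[lg]] <- fl$excluded
    log[[paste0("collect_", lg)]] <- list(
      traversed = length(ids), kept = nrow(fl$kept),
      excluded = as.list(fl$counts)
    )
  }
  collected <- dplyr::bind_rows(collected)
  collected$source_step <- "graph_traversal"
  excluded <- dplyr::bind_rows(exclusions)

  merged <- merge_cross_language(collected, snap)
  log$cross_link <- list(added = nrow(merged$articles) - nrow(collected),
                         missing_links = merged$missing_links)

  annotated <- resolve_icd_codes(merged$articles, snap$icd_map,
                                 manual_exclusions = manual_exclusions)
  annotated <- propagate_codes(annotated, snap$langlinks)
  grp <- split_groups(annotated)

  scored <- score_articles(grp$articles)
  degen <- scored[!is.na(scored$excluded_reason) &
                    scored$excluded_reason == "degenerate_text", , drop = FALSE]
  scored_ok <- scored[is.na(scored$excluded_reason), , drop = FALSE]
  log$scoring <- list(input = nrow(scored), scored = nrow(scored_ok),
                      degenerate = nrow(degen))
  # group split over analyzable articles only
  group_summary <- split_groups(scored_ok)$summary

  instances <- assign_chapters(scored_ok[scored_ok$group == "A", , drop = FALSE])

  interlanguage <- if (all(WR_LANGS %in% scored_ok$language)) {
    compare_languages(scored_ok, alpha = alpha)
  } else {
    NULL
  }

  chapters <- list(); grade7 <- NULL
  for (lg in intersect(WR_LANGS, unique(instances$language))) {
    inst <- instances[instances$language == lg, , drop = FALSE]
    ref <- scored_ok$fre[scored_ok$language == lg & scored_ok$group == "A"]
    chapters[[lg]] <- compare_chapters(inst, reference = ref,
                                       min_n = min_n, alpha = alpha)
  }
  inst_en <- instances[instances$language == "en", , drop = FALSE]
  if (nrow(inst_en) > 0) {
    grade7 <- compare_to_grade(inst_en, mu0 = mu0, min_n = min_n, alpha = alpha)
  }

  bands <- band_distribution(scored_ok)

  run <- structure(list(
    scored = scored, instances = instances, group_summary = group_summary,
    interlanguage = interlanguage, chapters = chapters, grade7 = grade7,
    exclusions = dplyr::bind_rows(
      excluded,
      dplyr::select(degen, dplyr::any_of(c("id", "language", "title",
                                           "excluded_reason")))
    ),
    bands = bands, log = log
  ), class = "wr_run")

  if (!is.null(out_dir)) write_reports(run, out_dir)
  run
}

flatten_for_csv <- function(tb) {
  tb$codes <- vapply(tb$codes %||% list(), paste, character(1), collapse = ";")
  dplyr::select(tb, -dplyr::any_of(c("icd_codes", "code_origin", "text")))
}

write_reports <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(tb, name) {
    readr::write_csv(tb, file.path(out_dir, name), progress = FALSE)
  }
  w(run$group_summary, "group_summary.csv")
  scored_ok <- run$scored[is.na(run$scored$excluded_reason), , drop = FALSE]
  w(flatten_for_csv(scored_ok), "scored.csv")
  w(metric_descriptives(scored_ok, c("language", "group")),
    "descriptives_groups.csv")
  if (nrow(run$instances) > 0) {
    w(metric_descriptives(run$instances, c("language", "chapter")),
      "descriptives_chapters.csv")
  }
  if (!is.null(run$interlanguage)) w(tidy(run$interlanguage), "interlanguage.csv")
  for (lg in names(run$chapters)) {
    w(tidy(run$chapters[[lg]]), paste0("chapters_", lg, ".csv"))
  }
  if (!is.null(run$grade7)) w(tidy(run$grade7), "grade7_en.csv")
  if (nrow(run$exclusions) > 0) {
    w(dplyr::select(run$exclusions,
                    dplyr::any_of(c("id", "language", "title",
                                    "excluded_reason"))),
      "exclusions.csv")
  }
  w(run$bands, "band_distribution.csv")
  jsonlite::write_json(run$log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.wr_run <- function(x, ...) {
  cat("<wikiread pipeline run>\n")
  cat("  scored articles:", sum(is.na(x$scored$excluded_reason)), "\n")
  cat("  excluded:", nrow(x$exclusions), "\n")
  print(x$group_summary)
  invisible(x)
}
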