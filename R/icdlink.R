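# Cross-language merging via interlanguage links, ICD-10 code resolution and
# propagation, chapter assignment, and the group A / group B split.

lang_key <- function(language, title) paste0(language, ":", title)

#' Build interlanguage-link clusters
#'
#' Interlanguage links are pairs of `lang:title` keys. Their symmetric,
#' transitive closure partitions article keys into equivalence classes
#' ("clusters"); lookup by any member returns the whole cluster. Computed
#' with union-find so chained links (en-de, de-ru) land in one cluster.
#'
#' @param langlinks Tibble with `key1`, `key2` columns of `lang:title` keys.
#' @return Tibble with `key`, `language`, `title`, `cluster` (integer id).
#' @export
link_clusters <- function(langlinks) {
  keys <- unique(c(langlinks$key1, langlinks$key2))
  parent <- seq_along(keys)
  idx <- setNames(seq_along(keys), keys)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(langlinks))) {
    a <- find(idx[[langlinks$key1[k]]])
    b <- find(idx[[langlinks$key2[k]]])
    if (a != b) parent[b] <- a
  }
  root <- vapply(seq_along(keys), find, integer(1))
  tibble::tibble(
    key = keys,
    language = stringr::str_extract(keys, "^[^:]+"),
    title = stringr::str_remove(keys, "^[^:]+:"),
    cluster = match(root, unique(root))
  )
}

#' Expand per-language article sets through interlanguage links
#'
#' For every collected article, its linked counterparts in the other two
#' language editions are pulled from the snapshot's article store (when they
#' exist there) and added to those languages' sets, tagged
#' `source_step = "cross_link"`. The operation is symmetric across languages
#' and idempotent: re-running it adds nothing. Links pointing at articles
#' absent from the snapshot are counted and skipped.
#'
#' @param collected Tibble of harvested articles (columns `id`, `language`,
#'   `title`, `text`, `icd_codes`; a `source_step` column is added/kept).
#' @param snapshot A `wr_snapshot` whose `articles` store supplies linked
#'   counterparts and whose `langlinks` define the clusters.
#' @return A list with `articles` (augmented tibble) and `missing_links`
#'   (count of linked titles absent from the snapshot).
#' @export
merge_cross_language <- function(collected, snapshot) {
  collected <- tibble::as_tibble(collected)
  if (!"source_step" %in% names(collected)) {
    collected$source_step <- "graph_traversal"
  }
  cl <- link_clusters(snapshot$langlinks)
  key <- lang_key(collected$language, collected$title)
  have <- cl[cl$key %in% key, ]
  wanted <- cl[cl$cluster %in% have$cluster, ]
  new_keys <- setdiff(wanted$key, key)

  store <- snapshot$articles
  store_key <- lang_key(store$language, store$title)
  hit <- store[store_key %in% new_keys, , drop = FALSE]
  missing <- length(new_keys) - nrow(hit)
  if (nrow(hit) > 0) {
    hit$source_step <- "cross_link"
    collected <- dplyr::bind_rows(collected, hit)
  }
  list(articles = collected, missing_links = missing)
}

#' Validate an ICD-10 code string
#'
#' A valid code is one uppercase Latin letter, two digits, and optionally a
#' period followed by one or two further digits or letters (so `T79.0`,
#' `F20`, `O88.0` pass; a mangled `0.00` fails). Dagger/asterisk modifiers
#' are expected to be stripped upstream.
#'
#' @param code Character vector of (normalized) code strings.
#' @return Logical vector.
#' @examples
#' validate_icd_code(c("T79.0", "0.00"))
#' @export
validate_icd_code <- function(code) {
  stringr::str_detect(code, "^[A-Z][0-9]{2}(\\.[0-9A-Z]{1,2})?$")
}

normalize_icd_code <- function(code) {
  toupper(stringr::str_replace_all(code, "\\s+", ""))
}

#' Resolve ICD-10 codes for articles from their own annotations and metadata
#'
#' Each article's code set is the union of its own annotations (origin
#' `"direct"`) and the codes the metadata map holds for its `lang:title` key
#' (origin `"metadata"`). Codes are normalized (uppercased, whitespace
#' stripped); invalid codes are dropped with a warning. A manual exclusion
#' list — `lang:title`, code, reason — removes codes known to be wrong at
#' the source (e.g. a body-part code pasted onto a behavioural-disorder
#' article), mirroring manual curation of falsely retrieved codes.
#'
#' @param articles Tibble with `language`, `title` and a list-column
#'   `icd_codes` of the articles' own annotations (may be absent).
#' @param icd_map Tibble with `key` (`lang:title`) and `codes`
#'   (comma-separated) from the snapshot.
#' @param manual_exclusions Optional tibble with `key`, `code` columns (or a
#'   TSV path with columns key, code, reason).
#' @return The input tibble with list-columns `codes` (character vectors of
#'   valid normalized codes) and `code_origin` (parallel vectors of
#'   `"direct"`/`"metadata"`).
#' @export
resolve_icd_codes <- function(articles, icd_map, manual_exclusions = NULL) {
  articles <- tibble::as_tibble(articles)
  if (is.character(manual_exclusions) && length(manual_exclusions) == 1L) {
    manual_exclusions <- readr::read_tsv(
      manual_exclusions, col_types = readr::cols(.default = "c"),
      progress = FALSE
    )
  }
  map_codes <- setNames(
    lapply(strsplit(icd_map$codes, ","), normalize_icd_code),
    icd_map$key
  )
  own <- if ("icd_codes" %in% names(articles)) {
    articles$icd_codes
  } else {
    rep(list(character()), nrow(articles))
  }
  keys <- lang_key(articles$language, articles$title)

  dropped <- 0L
  res <- purrr::pmap(list(own, keys), function(ow, ky) {
    ow <- normalize_icd_code(as.character(unlist(ow)))
    md <- map_codes[[ky]] %||% character()
    codes <- c(ow, md)
    origin <- c(rep("direct", length(ow)), rep("metadata", length(md)))
    keep <- !duplicated(codes)
    codes <- codes[keep]; origin <- origin[keep]
    ok <- validate_icd_code(codes)
    dropped <<- dropped + sum(!ok)
    codes <- codes[ok]; origin <- origin[ok]
    if (!is.null(manual_exclusions)) {
      bad <- manual_exclusions$code[manual_exclusions$key == ky]
      drop <- codes %in% normalize_icd_code(bad)
      codes <- codes[!drop]; origin <- origin[!drop]
    }
    list(codes = codes, origin = origin)
  })
  if (dropped > 0) {
    warn(paste0("dropped ", dropped, " invalid ICD-10 code(s)"))
  }
  articles$codes <- purrr::map(res, "codes")
  articles$code_origin <- purrr::map(res, "origin")
  articles
}

#' Propagate ICD-10 codes across linked language editions
#'
#' Within each interlanguage cluster the code set becomes the union over all
#' members; codes a member gains this way are tagged origin `"propagated"`.
#' After propagation no cluster holds two members with different code sets
#' (the operation is a closure and idempotent).
#'
#' @param articles Tibble from [resolve_icd_codes()] (needs `language`,
#'   `title`, `codes`, `code_origin`).
#' @param langlinks Link table from the snapshot.
#' @return The tibble with updated `codes` / `code_origin`.
#' @export
propagate_codes <- function(articles, langlinks) {
  cl <- link_clusters(langlinks)
  key <- lang_key(articles$language, articles$title)
  cluster <- cl$cluster[match(key, cl$key)]
  # articles with no links form singleton clusters
  solo <- is.na(cluster)
  cluster[solo] <- max(0L, cl$cluster, na.rm = TRUE) + seq_len(sum(solo))

  union_codes <- tapply(articles$codes, cluster, function(cc) {
    unique(unlist(cc, use.names = FALSE))
  }, simplify = FALSE)
  new <- purrr::map2(articles$codes, articles$code_origin, function(cd, og) {
    list(codes = cd, origin = og)
  })
  for (i in seq_along(new)) {
    u <- union_codes[[as.character(cluster[i])]] %||% character()
    gained <- setdiff(u, new[[i]]$codes)
    new[[i]]$codes <- c(new[[i]]$codes, gained)
    new[[i]]$origin <- c(new[[i]]$origin, rep("propagated", length(gained)))
  }
  articles$codes <- purrr::map(new, "codes")
  articles$code_origin <- purrr::map(new, "origin")
  articles
}

#' Assign group A / group B labels and summarize the split
#'
#' Group A holds the articles with at least one resolved (valid) ICD-10
#' code; group B the rest. The summary reports, per language, each group's n
#' and its percentage of the language total, rounded to two decimals.
#'
#' @param articles Tibble with `language` and `codes` list-column.
#' @return A list with `articles` (tibble plus a `group` column) and
#'   `summary` (tibble `language`, `n_total`, `n_a`, `pct_a`, `n_b`,
#'   `pct_b`).
#' @export
split_groups <- function(articles) {
  articles <- tibble::as_tibble(articles)
  articles$group <- ifelse(lengths(articles$codes) > 0, "A", "B")
  summary <- articles |>
    dplyr::count(.data$language, .data$group) |>
    tidyr::pivot_wider(names_from = "group", values_from = "n",
                       values_fill = 0L) |>
    dplyr::rename_with(tolower)
  for (g in c("a", "b")) if (!g %in% names(summary)) summary[[g]] <- 0L
  summary <- dplyr::transmute(
    summary,
    language = .data$language,
    n_total = .data$a + .data$b,
    n_a = .data$a,
    pct_a = round(100 * .data$a / .data$n_total, 2),
    n_b = .data$b,
    pct_b = round(100 * .data$b / .data$n_total, 2)
  )
  list(articles = articles, summary = summary)
}

#' Expand group-A articles into per-chapter instances
#'
#' The ICD-10 chapter of a code is taken as its leading letter (A-Z), the
#' label the per-chapter tables use. An article whose codes span several
#' chapters is duplicated into each of them exactly once — codes `O88.0`
#' and `T79.0` yield two instances, chapters O and T — while several codes
#' in one chapter deduplicate to a single instance. Group-B articles yield
#' no instances.
#'
#' @param articles Tibble with a `codes` list-column (post-propagation).
#' @return Tibble of chapter instances: all article columns plus `chapter`,
#'   one row per (article, distinct chapter letter).
#' @export
assign_chapters <- function(articles) {
  articles <- tibble::as_tibble(articles)
  chapters <- purrr::map(articles$codes, function(cd) {
    sort(unique(substr(cd[validate_icd_code(cd)], 1, 1)))
  })
  out <- articles[rep(seq_len(nrow(articles)), lengths(chapters)), , drop = FALSE]
  out$chapter <- unlist(chapters, use.names = FALSE)
  tibble::as_tibble(out)
}

#' Null-coalescing helper
#' @param a,b Values; `b` is returned when `a` is `NULL`.
#' @return `a` unless it is `NULL`, else `b`.
#' @keywords internal
#' @export
`%||%` <- function(a, b) if (is.null(a)) b else a
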