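# Harvesting the per-language article set: loading a snapshot, walking the
# category graph from the root disease concept, and applying the four-stage
# exclusion filter pipeline.

read_pattern_list <- function(x) {
  if (is.null(x)) return(character())
  if (length(x) == 1L && is.character(x) && file.exists(x)) {
    x <- readr::read_lines(x)
  }
  x <- trimws(x[!startsWith(trimws(x), "#")])
  x[nzchar(x)]
}

#' Filter configuration for the harvesting stage
#'
#' Four lists drive the four filters, applied in this fixed order: shell-style
#' category-name wildcards (excludes whole list-like subcategories), given
#' names (excludes person pages by their first title token), geographic
#' patterns (country/city/location pages), and title stop-word patterns
#' (organizations, awareness days, and other residual non-disease pages).
#' Each argument may be a character vector or a path to a plain-text file
#' with one pattern per line (`#` comments allowed). Empty lists make the
#' corresponding filter a no-op. The shipped defaults under
#' `extdata/filters/` are small illustrative lists meant to be replaced by
#' study-specific ones.
#'
#' @param category_wildcards,given_names,geo_terms,stop_words Character
#'   vectors of patterns, or file paths.
#' @param use_defaults If `TRUE` and an argument is missing, load the shipped
#'   illustrative list for it.
#' @return A list of class `wr_filter_config`.
#' @export
filter_config <- function(category_wildcards = NULL, given_names = NULL,
                          geo_terms = NULL, stop_words = NULL,
                          use_defaults = FALSE) {
  default_for <- function(name) {
    f <- system.file("extdata", "filters", paste0(name, ".txt"),
                     package = "wikiread")
    if (nzchar(f)) read_pattern_list(f) else character()
  }
  pick <- function(x, name) {
    if (is.null(x) && use_defaults) default_for(name) else read_pattern_list(x)
  }
  cfg <- list(
    category_wildcards = pick(category_wildcards, "category_wildcards"),
    given_names = pick(given_names, "given_names"),
    geo_terms = pick(geo_terms, "geo_terms"),
    stop_words = pick(stop_words, "stop_words")
  )
  structure(cfg, class = "wr_filter_config")
}

# shell-style glob -> anchored regex: * and ? wildcards, [...] classes kept
glob_to_regex <- function(patterns) {
  vapply(patterns, function(p) {
    if (is.na(p) || !nzchar(p)) {
      abort(paste0("invalid glob pattern: '", p, "'"), class = "wr_config_error")
    }
    rx <- stringr::str_replace_all(p, "([.^$+(){}\\\\|])", "\\\\\\1")
    rx <- stringr::str_replace_all(rx, stringr::fixed("*"), ".*")
    rx <- stringr::str_replace_all(rx, stringr::fixed("?"), ".")
    rx <- paste0("^", rx, "$")
    ok <- tryCatch({ grepl(rx, "probe", perl = TRUE); TRUE },
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) abort(paste0("invalid glob pattern: '", p, "'"),
                   class = "wr_config_error")
    rx
  }, character(1), USE.NAMES = FALSE)
}

matches_any_glob <- function(x, patterns) {
  if (length(patterns) == 0L || length(x) == 0L) {
    return(rep(FALSE, length(x)))
  }
  rx <- glob_to_regex(patterns)
  out <- rep(FALSE, length(x))
  for (r in rx) out <- out | grepl(r, x, ignore.case = TRUE, perl = TRUE)
  out
}

#' Load a snapshot: articles, category graph, links, metadata code map
#'
#' A snapshot directory holds the four plain interchange files the pipeline
#' consumes:
#' \describe{
#'   \item{`articles.jsonl`}{one JSON object per line with `id`, `language`,
#'     `title`, `text`, and optionally `icd_codes` (array of strings).}
#'   \item{`nodes.tsv` + `edges.tsv`}{the typed category graph: a node table
#'     (`node_id`, `type` in \{category, article\}, `title`, `language`) and a
#'     directed edge list (`parent_id`, `child_id`).}
#'   \item{`langlinks.tsv`}{interlanguage links, two columns of
#'     `lang:title` keys per line.}
#'   \item{`icd_map.tsv`}{metadata ICD-10 code map, `lang:title` key to a
#'     comma-separated code list (emulating a structured-metadata property
#'     such as Wikidata's P4229).}
#' }
#' Malformed JSONL records are skipped and counted; edges referencing
#' missing nodes are dropped with a warning naming the line.
#'
#' @param dir Snapshot directory containing the standard file names, or
#'   `NULL` if individual paths are given.
#' @param articles,nodes,edges,langlinks,icd_map Optional individual paths
#'   overriding the directory convention.
#' @return A list of class `wr_snapshot` with tibbles `articles`, `nodes`,
#'   `edges`, `langlinks`, `icd_map`, and a `counts` list of load
#'   diagnostics.
#' @export
load_snapshot <- function(dir = NULL, articles = NULL, nodes = NULL,
                          edges = NULL, langlinks = NULL, icd_map = NULL) {
  pth <- function(given, name) {
    if (!is.null(given)) given else file.path(dir, name)
  }
  f_art <- pth(articles, "articles.jsonl")
  f_nodes <- pth(nodes, "nodes.tsv")
  f_edges <- pth(edges, "edges.tsv")
  f_links <- pth(langlinks, "langlinks.tsv")
  f_icd <- pth(icd_map, "icd_map.tsv")

  lines <- readr::read_lines(f_art)
  lines <- lines[nzchar(trimws(lines))]
  parsed <- lapply(lines, function(l) {
    tryCatch(jsonlite::fromJSON(l), error = function(e) NULL)
  })
  bad <- sum(vapply(parsed, is.null, logical(1)))
  parsed <- parsed[!vapply(parsed, is.null, logical(1))]
  art <- dplyr::bind_rows(lapply(parsed, function(p) {
    tibble::tibble(
      id = as.character(p$id),
      language = as.character(p$language),
      title = as.character(p$title),
      text = if (is.null(p$text)) "" else as.character(p$text),
      icd_codes = list(as.character(unlist(p$icd_codes)))
    )
  }))

  nodes_tb <- readr::read_tsv(f_nodes, col_types = "cccc", progress = FALSE)
  edges_tb <- readr::read_tsv(f_edges, col_types = "cc", progress = FALSE)
  known <- nodes_tb$node_id
  dangle <- !(edges_tb$parent_id %in% known & edges_tb$child_id %in% known)
  if (any(dangle)) {
    warn(paste0(
      "dropped ", sum(dangle), " edge(s) referencing missing nodes (lines ",
      paste(head(which(dangle), 5) + 1L, collapse = ", "), if (sum(dangle) > 5) ", ...", ")"
    ))
    edges_tb <- edges_tb[!dangle, ]
  }

  links_tb <- readr::read_tsv(f_links, col_types = "cc", progress = FALSE,
                              col_names = c("key1", "key2"), skip = 1)
  icd_tb <- readr::read_tsv(f_icd, col_types = "cc", progress = FALSE,
                            col_names = c("key", "codes"), skip = 1)

  structure(list(
    articles = art,
    nodes = nodes_tb,
    edges = edges_tb,
    langlinks = links_tb,
    icd_map = icd_tb,
    counts = list(
      articles = nrow(art), malformed_records = bad,
      nodes = nrow(nodes_tb), edges = nrow(edges_tb),
      dropped_edges = sum(dangle)
    )
  ), class = "wr_snapshot")
}

#' Collect all article nodes reachable from a root category
#'
#' Breadth-first traversal over directed category containment edges starting
#' at the root concept (e.g. the human-diseases category). Cycle-safe via a
#' visited set; every article id is returned once. Traversal depth is
#' unbounded by default.
#'
#' @param snapshot A `wr_snapshot` (or any list with `nodes`/`edges`
#'   tibbles).
#' @param root_title Title of the root category.
#' @param language Language edition to traverse.
#' @param max_depth Optional traversal depth cap (default unlimited).
#' @return Character vector of article `node_id`s reachable from the root.
#' @export
traverse_from_root <- function(snapshot, root_title, language,
                               max_depth = Inf) {
  check_lang(language)
  nodes <- dplyr::filter(snapshot$nodes, .data$language == !!language)
  root <- nodes$node_id[nodes$type == "category" & nodes$title == root_title]
  if (length(root) == 0L) {
    abort(paste0("root category '", root_title, "' not found for language '",
                 language, "'"), class = "wr_root_not_found")
  }
  edges <- snapshot$edges[snapshot$edges$parent_id %in% nodes$node_id, ]
  kids <- split(edges$child_id, edges$parent_id)
  type_of <- setNames(nodes$type, nodes$node_id)

  visited <- new.env(parent = emptyenv())
  frontier <- root
  for (r in root) assign(r, TRUE, envir = visited)
  articles <- character()
  depth <- 0
  while (length(frontier) > 0 && depth < max_depth) {
    nxt <- unique(unlist(kids[frontier], use.names = FALSE))
    if (length(nxt) == 0L) break
    nxt <- nxt[!vapply(nxt, exists, logical(1), envir = visited)]
    for (n in nxt) assign(n, TRUE, envir = visited)
    articles <- c(articles, nxt[type_of[nxt] == "article"])
    frontier <- nxt[type_of[nxt] == "category"]
    depth <- depth + 1
  }
  sort(unique(articles))
}

#' Direct category memberships of article nodes
#'
#' @param snapshot A `wr_snapshot`.
#' @return Tibble with `article_id` and `category_title` (one row per direct
#'   parent category).
#' @export
category_memberships <- function(snapshot) {
  nodes <- snapshot$nodes
  cats <- nodes[nodes$type == "category", c("node_id", "title")]
  arts <- nodes$node_id[nodes$type == "article"]
  e <- snapshot$edges[snapshot$edges$child_id %in% arts, ]
  dplyr::transmute(
    dplyr::inner_join(e, cats, by = c(parent_id = "node_id")),
    article_id = .data$child_id, category_title = .data$title
  )
}

#' Apply the four-stage exclusion filter pipeline
#'
#' Filters are applied in a fixed order — category wildcard, given name,
#' geographic, stop word — and an article is excluded by the first filter
#' that matches, tagged with that reason. Per-filter exclusion counts are
#' therefore order-dependent, which reports note. Matching rules: category
#' wildcards are case-insensitive globs over the article's direct category
#' titles; the given-name filter matches when the first whitespace-separated
#' title token equals a configured name; geographic and stop-word patterns
#' are globs over the article title (geographic patterns also match category
#' titles).
#'
#' @param articles Tibble of articles (needs `id` and `title`).
#' @param memberships Tibble from [category_memberships()] (may be empty).
#' @param config A [filter_config()].
#' @return A list with `kept` (tibble), `excluded` (tibble with
#'   `excluded_reason`), and `counts` (named integer vector per filter).
#' @export
apply_filters <- function(articles, memberships, config) {
  stopifnot(inherits(config, "wr_filter_config"))
  articles <- tibble::as_tibble(articles)
  n <- nrow(articles)
  reason <- rep(NA_character_, n)

  cats_of <- split(memberships$category_title, memberships$article_id)
  art_cats <- cats_of[articles$id]

  # 1: wildcard over category titles
  if (length(config$category_wildcards) > 0) {
    hit <- vapply(art_cats, function(cc) {
      length(cc) > 0 && any(matches_any_glob(cc, config$category_wildcards))
    }, logical(1))
    reason[is.na(reason) & hit] <- "category_wildcard"
  } else {
    glob_to_regex(config$category_wildcards) # still validate (no-op)
  }
  # 2: given name on first title token
  if (length(config$given_names) > 0) {
    first_tok <- stringr::str_extract(articles$title, "^\\S+")
    hit <- tolower(first_tok) %in% tolower(config$given_names)
    reason[is.na(reason) & hit] <- "given_name"
  }
  # 3: geographic, over title and category titles
  if (length(config$geo_terms) > 0) {
    hit_t <- matches_any_glob(articles$title, config$geo_terms)
    hit_c <- vapply(art_cats, function(cc) {
      length(cc) > 0 && any(matches_any_glob(cc, config$geo_terms))
    }, logical(1))
    reason[is.na(reason) & (hit_t | hit_c)] <- "geographic"
  }
  # 4: stop words over title
  if (length(config$stop_words) > 0) {
    hit <- matches_any_glob(articles$title, config$stop_words)
    reason[is.na(reason) & hit] <- "stop_word"
  }

  excluded <- articles[!is.na(reason), , drop = FALSE]
  excluded$excluded_reason <- reason[!is.na(reason)]
  counts <- vapply(
    c("category_wildcard", "given_name", "geographic", "stop_word"),
    function(r) sum(reason == r, na.rm = TRUE), integer(1)
  )
  list(kept = articles[is.na(reason), , drop = FALSE],
       excluded = excluded, counts = counts)
}
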