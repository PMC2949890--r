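# Concept-graph search: map a term to a concept, walk a bounded number of
# steps towards more general concepts, and keyword-scan every alias
# string collected on the way (the federated controlled-vocabulary search
# used by filter 4).

new_concept_graph <- function(aliases, edges, map) {
  structure(list(concepts = sort(unique(aliases$cui)),
                 aliases = aliases, edges = edges, map = map),
            class = "concept_graph")
}

#' Load a concept graph from pipe-delimited tables
#'
#' Reads the minimal three-file dialect used to carry a concept hierarchy:
#'
#' * `mapping`: `term_id|term_name|CUI` — maps external term ids (and,
#'   case-insensitively, term names) to concept identifiers;
#' * `relations`: `child_CUI|parent_CUI|source` — hierarchical edges, each
#'   labelled with the source vocabulary that asserted it (the file is
#'   assumed pre-filtered to parent relations);
#' * `strings`: `CUI|string|source` — the alias strings of each concept.
#'
#' Duplicate rows are collapsed. Every concept must have at least one
#' alias string, and every mapping or relation row must reference a known
#' concept; violations are errors naming the row.
#'
#' @param mapping_path,relations_path,strings_path Paths to the three
#'   header-less pipe-delimited files.
#' @return An object of class `concept_graph`.
#' @export
load_concept_graph <- function(mapping_path, relations_path, strings_path) {
  read_psv <- function(path, what) {
    if (!file.exists(path)) stop(what, " file not found: ", path)
    lines <- read_text_lines(path)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "|", fixed = TRUE)
    bad <- which(lengths(parts) != 3L)
    if (length(bad)) {
      stop(sprintf("%s row %d does not have 3 pipe-delimited fields",
                   what, bad[1]))
    }
    data.frame(a = vapply(parts, `[[`, character(1), 1),
               b = vapply(parts, `[[`, character(1), 2),
               c = vapply(parts, `[[`, character(1), 3),
               stringsAsFactors = FALSE)
  }
  strings <- unique(read_psv(strings_path, "strings"))
  names(strings) <- c("cui", "string", "source")
  if (nrow(strings) == 0L) stop("strings file defines no concepts")
  concepts <- unique(strings$cui)

  relations <- unique(read_psv(relations_path, "relations"))
  names(relations) <- c("child", "parent", "source")
  for (i in seq_len(nrow(relations))) {
    unk <- setdiff(c(relations$child[i], relations$parent[i]), concepts)
    if (length(unk)) {
      stop(sprintf(
        "relations row %d references concept(s) with no strings: %s",
        i, paste(unk, collapse = ", ")))
    }
  }

  mapping <- unique(read_psv(mapping_path, "mapping"))
  names(mapping) <- c("term_id", "term_name", "cui")
  for (i in seq_len(nrow(mapping))) {
    if (!(mapping$cui[i] %in% concepts)) {
      stop(sprintf(
        "mapping row %d references concept with no strings: %s",
        i, mapping$cui[i]))
    }
  }
  map <- data.frame(
    key = c(mapping$term_id, tolower(mapping$term_name)),
    cui = c(mapping$cui, mapping$cui),
    stringsAsFactors = FALSE
  )
  map <- unique(map)
  new_concept_graph(strings, relations, map)
}

#' @export
print.concept_graph <- function(x, ...) {
  cat(sprintf(
    "Concept graph: %d concepts, %d alias strings, %d parent edges, %d mapped keys\n",
    length(x$concepts), nrow(x$aliases), nrow(x$edges), nrow(x$map)))
  invisible(x)
}

#' Keyword search around a term's concept neighbourhood
#'
#' Maps `term` to its concept (trying an exact external-id match first,
#' then a case-insensitive name match), collects the concept and every
#' concept reachable within `max_up` parent-edge steps (breadth-first,
#' visited-set guarded so cyclic inputs still terminate), and scans every
#' alias string of every collected concept for each keyword as a
#' case-insensitive substring. The seed's own aliases sit at depth 0.
#'
#' @param term External term id or term name.
#' @param graph A `concept_graph` from [load_concept_graph()].
#' @param keywords Non-empty character vector of keyword fragments;
#'   default [neural_immune_keywords()].
#' @param max_up Maximum number of upward steps (default 3).
#' @param name Optional term name to try if `term` itself does not map.
#' @return An object of class `termfind_result`: `positive` (logical),
#'   `matches` (data frame with columns `string`, `keyword`, `concept`,
#'   `depth`, `path`), and `reason` (`"unmapped"` or `"no-match"`) when
#'   negative. An unmapped term is a negative result, not an error.
#' @export
termfind <- function(term, graph, keywords = neural_immune_keywords(), max_up = 3L,
                     name = NULL) {
  stopifnot(inherits(graph, "concept_graph"))
  keywords <- as.character(keywords)
  if (length(keywords) == 0L) stop("'keywords' must be non-empty")
  max_up <- as.integer(max_up)
  if (is.na(max_up) || max_up < 0L) stop("'max_up' must be >= 0")

  seed <- lookup_concept(graph, term)
  if (is.na(seed) && !is.null(name)) seed <- lookup_concept(graph, name)
  if (is.na(seed)) {
    return(new_termfind_result(matches = NULL, reason = "unmapped"))
  }

  # breadth-first walk up the parent edges, remembering the first path
  # that reached each concept
  depth <- c(stats::setNames(0L, seed))
  paths <- list()
  paths[[seed]] <- seed
  frontier <- seed
  d <- 0L
  while (length(frontier) && d < max_up) {
    d <- d + 1L
    nxt <- character(0)
    for (v in frontier) {
      parents <- unique(graph$edges$parent[graph$edges$child == v])
      for (p in setdiff(parents, names(depth))) {
        depth[p] <- d
        paths[[p]] <- c(paths[[v]], p)
        nxt <- c(nxt, p)
      }
    }
    frontier <- nxt
  }

  visited <- names(depth)
  al <- graph$aliases[graph$aliases$cui %in% visited, , drop = FALSE]
  kw_lc <- tolower(keywords)
  rows <- list()
  for (i in seq_len(nrow(al))) {
    s_lc <- tolower(al$string[i])
    for (k in seq_along(kw_lc)) {
      if (grepl(kw_lc[k], s_lc, fixed = TRUE)) {
        cui <- al$cui[i]
        rows[[length(rows) + 1L]] <- data.frame(
          string = al$string[i], keyword = keywords[k], concept = cui,
          depth = depth[[cui]],
          path = paste(paths[[cui]], collapse = " -> "),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(new_termfind_result(matches = NULL, reason = "no-match"))
  }
  matches <- do.call(rbind, rows)
  matches <- matches[order(matches$depth, matches$concept, matches$keyword,
                           matches$string), , drop = FALSE]
  rownames(matches) <- NULL
  new_termfind_result(matches = matches, reason = NA_character_)
}

lookup_concept <- function(graph, key) {
  key <- as.character(key)
  hit <- match(key, graph$map$key)
  if (is.na(hit)) hit <- match(tolower(key), graph$map$key)
  if (is.na(hit)) NA_character_ else graph$map$cui[hit]
}

new_termfind_result <- function(matches, reason) {
  if (is.null(matches)) {
    matches <- data.frame(string = character(), keyword = character(),
                          concept = character(), depth = integer(),
                          path = character(), stringsAsFactors = FALSE)
  }
  structure(list(positive = nrow(matches) > 0L, matches = matches,
                 reason = reason),
            class = "termfind_result")
}

#' @export
print.termfind_result <- function(x, ...) {
  if (x$positive) {
    cat(sprintf("termfind: POSITIVE (%d match(es))\n", nrow(x$matches)))
    print(x$matches)
  } else {
    cat(sprintf("termfind: negative (%s)\n", x$reason))
  }
  invisible(x)
}

#' Write a concept graph as its three pipe-delimited tables
#'
#' Inverse of [load_concept_graph()]; writes `mapping.psv`,
#' `relations.psv` and `strings.psv` into `dir`.
#'
#' @param graph A `concept_graph`.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_concept_graph <- function(graph, dir) {
  stopifnot(inherits(graph, "concept_graph"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(mapping = file.path(dir, "mapping.psv"),
             relations = file.path(dir, "relations.psv"),
             strings = file.path(dir, "strings.psv"))
  # every stored key is written as both the id and the name column, which
  # reloads to an equivalent lookup table
  keys <- graph$map
  writeLines(sprintf("%s|%s|%s", keys$key, keys$key, keys$cui),
             paths["mapping"])
  writeLines(sprintf("%s|%s|%s", graph$edges$child, graph$edges$parent,
                     graph$edges$source), paths["relations"])
  writeLines(sprintf("%s|%s|%s", graph$aliases$cui, graph$aliases$string,
                     graph$aliases$source), paths["strings"])
  invisible(paths)
}
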