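# OBO 1.2 flat-file reading and writing, including subset tagging.

#' Read an OBO 1.2 flat file
#'
#' Parses `[Term]` stanzas into an [ontology_dag()]. `is_a:` tags and
#' `relationship:` tags carrying `part_of`, `regulates`,
#' `positively_regulates` or `negatively_regulates` become typed edges;
#' other relationship types are skipped with a warning. `synonym:` and
#' `subset:` tags are captured, `is_obsolete: true` marks the term obsolete
#' and discards its edges. Header lines before the first stanza are
#' preserved for round-tripping. `[Typedef]` stanzas are ignored.
#'
#' @param path Path to the OBO file.
#' @return An [ontology_dag()].
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) stop("OBO file not found: ", path)
  lines <- read_text_lines(path)
  stanza_start <- grep("^\\[.*\\]\\s*$", lines)
  header <- if (length(stanza_start)) {
    lines[seq_len(max(stanza_start[1] - 1L, 0L))]
  } else {
    lines
  }
  header <- header[nzchar(trimws(header))]
  default_ns <- NULL
  dns <- grep("^default-namespace:", header, value = TRUE)
  if (length(dns)) default_ns <- trimws(sub("^default-namespace:", "", dns[1]))

  terms <- list()
  edges <- list()
  bounds <- c(stanza_start, length(lines) + 1L)
  if (length(stanza_start)) {
    for (s in seq_along(stanza_start)) {
      first <- stanza_start[s]
      if (!identical(trimws(lines[first]), "[Term]")) next
      body_idx <- seq(first + 1L, bounds[s + 1L] - 1L)
      body_idx <- body_idx[body_idx <= length(lines)]
      parsed <- parse_term_stanza(lines, body_idx, first, default_ns)
      terms[[length(terms) + 1L]] <- parsed$term
      if (!is.null(parsed$edges)) edges[[length(edges) + 1L]] <- parsed$edges
    }
  }
  if (length(terms) == 0L) {
    return(ontology_dag(data.frame(id = character()), header = header))
  }
  tt <- data.frame(
    id = vapply(terms, `[[`, character(1), "id"),
    name = vapply(terms, `[[`, character(1), "name"),
    namespace = vapply(terms, `[[`, character(1), "namespace"),
    obsolete = vapply(terms, `[[`, logical(1), "obsolete"),
    stringsAsFactors = FALSE
  )
  tt$synonyms <- lapply(terms, `[[`, "synonyms")
  tt$subsets <- lapply(terms, `[[`, "subsets")
  ee <- if (length(edges)) do.call(rbind, edges) else NULL
  # obsolete terms participate in no edges
  if (!is.null(ee)) {
    obs <- tt$id[tt$obsolete]
    ee <- ee[!(ee$child %in% obs | ee$parent %in% obs), , drop = FALSE]
  }
  ontology_dag(tt, ee, header = header)
}

parse_term_stanza <- function(lines, body_idx, stanza_line, default_ns) {
  id <- NULL
  name <- NA_character_
  namespace <- default_ns %||% "biological_process"
  obsolete <- FALSE
  synonyms <- character()
  subsets <- character()
  isa <- character()
  rel_type <- character()
  rel_to <- character()

  for (i in body_idx) {
    line <- lines[i]
    if (!nzchar(trimws(line)) || grepl("^!", line)) next
    m <- regexpr("^([A-Za-z_]+):\\s*", line)
    if (m == -1L) {
      stop(sprintf("malformed OBO line %d: %s", i, line))
    }
    key <- sub("^([A-Za-z_]+):\\s*.*$", "\\1", line)
    value <- sub("^[A-Za-z_]+:\\s*", "", line)
    if (key == "id") {
      id <- strip_obo_comment(value)
    } else if (key == "name") {
      name <- trimws(value)
    } else if (key == "namespace") {
      namespace <- strip_obo_comment(value)
    } else if (key == "is_obsolete") {
      obsolete <- identical(strip_obo_comment(value), "true")
    } else if (key == "synonym") {
      syn <- sub('^"(.*?)".*$', "\\1", value)
      synonyms <- c(synonyms, syn)
    } else if (key == "subset") {
      subsets <- c(subsets, strip_obo_comment(value))
    } else if (key == "is_a") {
      isa <- c(isa, strip_obo_comment(value))
    } else if (key == "relationship") {
      v <- strip_obo_comment(value)
      parts <- strsplit(trimws(v), "\\s+")[[1]]
      if (length(parts) < 2L) {
        stop(sprintf("malformed OBO relationship at line %d: %s", i, line))
      }
      if (parts[1] %in% setdiff(relation_kinds(), "is_a")) {
        rel_type <- c(rel_type, parts[1])
        rel_to <- c(rel_to, parts[2])
      } else {
        warning(sprintf("skipping unknown relationship type '%s' (line %d)",
                        parts[1], i))
      }
    }
    # other tags (def, xref, comment, ...) are ignored
  }
  if (is.null(id)) {
    stop(sprintf("OBO [Term] stanza at line %d has no id", stanza_line))
  }
  if (is.na(name)) name <- id
  edges <- NULL
  if (!obsolete && (length(isa) || length(rel_type))) {
    edges <- data.frame(
      child = id,
      parent = c(isa, rel_to),
      relation = c(rep("is_a", length(isa)), rel_type),
      stringsAsFactors = FALSE
    )
  }
  list(term = list(id = id, name = name, namespace = namespace,
                   obsolete = obsolete, synonyms = synonyms,
                   subsets = subsets),
       edges = edges)
}

strip_obo_comment <- function(value) {
  trimws(sub("\\s*!.*$", "", value))
}

#' Write an ontology as an OBO 1.2 flat file
#'
#' Two modes. `standalone` writes exactly the terms and edges of `dag`,
#' producing a self-contained subset ontology. `tag-subset` writes the
#' *full* ontology (`full_dag`) with a `subsetdef` header line and a
#' `subset: <subset_name>` tag on every term of `dag`, the layout used to
#' mark a clipped subset inside the distributed full ontology so that
#' enrichment tools can select it.
#'
#' @param dag The (sub)ontology to write; in tag mode, the subset.
#' @param path Output path.
#' @param mode `"standalone"` or `"tag-subset"`.
#' @param subset_name Subset label, required in tag mode.
#' @param full_dag Full ontology, required in tag mode; every term of `dag`
#'   must exist in it.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path, mode = c("standalone", "tag-subset"),
                      subset_name = NULL, full_dag = NULL) {
  stopifnot(inherits(dag, "ontology_dag"))
  mode <- match.arg(mode)
  if (mode == "standalone") {
    header <- dag$header %||% "format-version: 1.2"
    body <- obo_stanzas(dag)
  } else {
    if (is.null(full_dag) || !inherits(full_dag, "ontology_dag")) {
      stop("tag-subset mode requires 'full_dag'")
    }
    if (is.null(subset_name) || !nzchar(subset_name)) {
      stop("tag-subset mode requires a non-empty 'subset_name'")
    }
    missing_ids <- setdiff(dag$terms$id, full_dag$terms$id)
    if (length(missing_ids)) {
      stop("subset term(s) absent from full ontology: ",
           paste(sort(missing_ids), collapse = ", "))
    }
    header <- c(full_dag$header %||% "format-version: 1.2",
                sprintf('subsetdef: %s "%s subset"', subset_name,
                        subset_name))
    tagged <- full_dag
    hit <- tagged$terms$id %in% dag$terms$id
    tagged$terms$subsets[hit] <- lapply(tagged$terms$subsets[hit],
                                        function(s) unique(c(s, subset_name)))
    body <- obo_stanzas(tagged)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

obo_stanzas <- function(dag) {
  tt <- dag$terms[order(dag$terms$id), , drop = FALSE]
  ee <- dag$edges
  out <- character(0)
  for (i in seq_len(nrow(tt))) {
    id <- tt$id[i]
    stanza <- c("", "[Term]",
                paste0("id: ", id),
                paste0("name: ", tt$name[i]),
                paste0("namespace: ", tt$namespace[i]))
    for (s in tt$subsets[[i]]) stanza <- c(stanza, paste0("subset: ", s))
    for (s in tt$synonyms[[i]]) {
      stanza <- c(stanza, sprintf('synonym: "%s" RELATED []', s))
    }
    my <- ee[ee$child == id, , drop = FALSE]
    my <- my[order(my$relation, my$parent), , drop = FALSE]
    for (j in seq_len(nrow(my))) {
      if (my$relation[j] == "is_a") {
        stanza <- c(stanza, paste0("is_a: ", my$parent[j]))
      } else {
        stanza <- c(stanza,
                    sprintf("relationship: %s %s", my$relation[j],
                            my$parent[j]))
      }
    }
    if (tt$obsolete[i]) stanza <- c(stanza, "is_obsolete: true")
    out <- c(out, stanza)
  }
  out
}
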