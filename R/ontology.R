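# In-memory ontology model: a term table plus typed child->parent edges.

go_namespaces <- function() {
  c("biological_process", "molecular_function", "cellular_component")
}

#' Construct an ontology DAG
#'
#' The central container: a table of terms and a table of typed
#' child-to-parent edges. Edges are directed from the more specific term
#' (child) to the more general one (parent) and each carries one relation
#' kind from [relation_kinds()]. The constructor performs structural checks
#' only (column presence, unique ids, valid relation labels); semantic
#' invariants — acyclicity over `is_a`/`part_of`, no dangling endpoints, no
#' edges on obsolete terms, one root per namespace — are checked by
#' [validate_ontology()], so deliberately broken graphs can still be built
#' and inspected.
#'
#' @param terms A data frame with column `id` and optional columns `name`
#'   (default: the id), `namespace` (default `"biological_process"`),
#'   `obsolete` (logical, default `FALSE`), and list columns `synonyms` and
#'   `subsets` (character vectors per term).
#' @param edges A data frame with columns `child`, `parent`, `relation`, or
#'   `NULL` for an edgeless ontology. Duplicate edges are collapsed.
#' @param header Optional character vector of OBO header lines, preserved
#'   for round-tripping by [write_obo()].
#' @return An object of class `ontology_dag` with elements `terms`, `edges`
#'   and `header`.
#' @examples
#' dag <- ontology_dag(
#'   terms = data.frame(id = c("T:1", "T:2")),
#'   edges = data.frame(child = "T:2", parent = "T:1", relation = "is_a")
#' )
#' dag
#' @export
ontology_dag <- function(terms, edges = NULL, header = NULL) {
  if (!is.data.frame(terms) || !"id" %in% names(terms)) {
    stop("'terms' must be a data frame with an 'id' column")
  }
  n <- nrow(terms)
  id <- as.character(terms$id)
  if (anyDuplicated(id)) {
    stop("duplicate term id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  tt <- data.frame(
    id = id,
    name = if ("name" %in% names(terms)) as.character(terms$name) else id,
    namespace = if ("namespace" %in% names(terms))
      as.character(terms$namespace) else rep("biological_process", n),
    obsolete = if ("obsolete" %in% names(terms))
      as.logical(terms$obsolete) else rep(FALSE, n),
    stringsAsFactors = FALSE
  )
  tt$synonyms <- if ("synonyms" %in% names(terms)) {
    lapply(terms$synonyms, as.character)
  } else {
    rep(list(character()), n)
  }
  tt$subsets <- if ("subsets" %in% names(terms)) {
    lapply(terms$subsets, as.character)
  } else {
    rep(list(character()), n)
  }

  if (is.null(edges)) {
    ee <- data.frame(child = character(), parent = character(),
                     relation = character(), stringsAsFactors = FALSE)
  } else {
    if (!is.data.frame(edges) ||
        !all(c("child", "parent", "relation") %in% names(edges))) {
      stop("'edges' must have columns child, parent, relation")
    }
    ee <- data.frame(child = as.character(edges$child),
                     parent = as.character(edges$parent),
                     relation = as.character(edges$relation),
                     stringsAsFactors = FALSE)
    bad <- setdiff(unique(ee$relation), relation_kinds())
    if (length(bad)) {
      stop("unknown relation kind(s) in edges: ", paste(bad, collapse = ", "))
    }
    ee <- unique(ee)
    ee <- ee[order(ee$child, ee$parent, ee$relation), , drop = FALSE]
    rownames(ee) <- NULL
  }
  structure(list(terms = tt, edges = ee, header = header),
            class = "ontology_dag")
}

#' @export
print.ontology_dag <- function(x, ...) {
  ns <- table(x$terms$namespace)
  cat(sprintf("Ontology DAG: %d terms (%d obsolete), %d edges\n",
              nrow(x$terms), sum(x$terms$obsolete), nrow(x$edges)))
  for (i in seq_along(ns)) {
    cat(sprintf("  %s: %d terms\n", names(ns)[i], ns[i]))
  }
  if (nrow(x$edges)) {
    rel <- table(x$edges$relation)
    cat("  edges:", paste(sprintf("%s=%d", names(rel), rel), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Term identifiers of an ontology
#'
#' @param dag An `ontology_dag`.
#' @param include_obsolete Include obsolete terms? Default `TRUE`.
#' @return Character vector of term ids, in table order.
#' @export
term_ids <- function(dag, include_obsolete = TRUE) {
  stopifnot(inherits(dag, "ontology_dag"))
  if (include_obsolete) dag$terms$id else dag$terms$id[!dag$terms$obsolete]
}

#' Look up term names
#'
#' @param dag An `ontology_dag`.
#' @param ids Term ids to look up.
#' @return Character vector of names (`NA` for unknown ids), named by id.
#' @export
term_names <- function(dag, ids) {
  stopifnot(inherits(dag, "ontology_dag"))
  out <- dag$terms$name[match(ids, dag$terms$id)]
  names(out) <- ids
  out
}

# Subset an ontology to a set of term ids, keeping edges whose endpoints
# both survive.
subset_ontology <- function(dag, keep) {
  keep <- unique(as.character(keep))
  tt <- dag$terms[dag$terms$id %in% keep, , drop = FALSE]
  tt <- tt[order(tt$id), , drop = FALSE]
  rownames(tt) <- NULL
  ee <- dag$edges[dag$edges$child %in% keep & dag$edges$parent %in% keep, ,
                  drop = FALSE]
  rownames(ee) <- NULL
  structure(list(terms = tt, edges = ee, header = dag$header),
            class = "ontology_dag")
}

#' Validate ontology invariants
#'
#' Checks the semantic invariants of an [ontology_dag()]: the graph
#' restricted to `is_a` and `part_of` edges must be acyclic, every edge
#' endpoint must be a known term, obsolete terms must carry no edges, and
#' every namespace with at least one live term must have at least one
#' `is_a` root. An empty issue table means all invariants hold.
#'
#' @param dag An `ontology_dag`.
#' @return An object of class `ontology_validation`: a data frame with
#'   columns `type` and `detail`, one row per violation, carrying the
#'   per-namespace root counts in attribute `root_counts`.
#' @examples
#' dag <- ontology_dag(data.frame(id = c("A", "B")),
#'                     data.frame(child = "B", parent = "A",
#'                                relation = "is_a"))
#' validate_ontology(dag)
#' @export
validate_ontology <- function(dag) {
  stopifnot(inherits(dag, "ontology_dag"))
  issues <- list()
  add <- function(type, detail) {
    issues[[length(issues) + 1L]] <<- data.frame(
      type = type, detail = detail, stringsAsFactors = FALSE)
  }
  ids <- dag$terms$id
  ee <- dag$edges

  dang <- ee[!(ee$child %in% ids) | !(ee$parent %in% ids), , drop = FALSE]
  if (nrow(dang)) {
    for (i in seq_len(nrow(dang))) {
      missing_end <- setdiff(c(dang$child[i], dang$parent[i]), ids)
      add("dangling_edge",
          sprintf("edge %s -[%s]-> %s references unknown term(s): %s",
                  dang$child[i], dang$relation[i], dang$parent[i],
                  paste(missing_end, collapse = ", ")))
    }
  }

  obs <- ids[dag$terms$obsolete]
  on_obs <- ee[ee$child %in% obs | ee$parent %in% obs, , drop = FALSE]
  if (nrow(on_obs)) {
    for (i in seq_len(nrow(on_obs))) {
      add("obsolete_edge",
          sprintf("edge %s -[%s]-> %s touches an obsolete term",
                  on_obs$child[i], on_obs$relation[i], on_obs$parent[i]))
    }
  }

  # Cycle check over is_a + part_of, restricted to edges with known
  # endpoints (dangling edges are reported separately). Kahn peeling:
  # whatever cannot be topologically ordered sits on or above a cycle.
  hier <- ee[ee$relation %in% c("is_a", "part_of") &
               ee$child %in% ids & ee$parent %in% ids, , drop = FALSE]
  if (nrow(hier)) {
    residual <- kahn_residual(hier)
    if (length(residual)) {
      add("cycle",
          sprintf("is_a/part_of cycle involving: %s",
                  paste(sort(residual), collapse = ", ")))
    }
  }

  # Per-namespace is_a roots among live terms.
  live <- dag$terms[!dag$terms$obsolete, , drop = FALSE]
  isa_children <- unique(ee$child[ee$relation == "is_a"])
  root_counts <- integer(0)
  for (ns in sort(unique(live$namespace))) {
    ns_ids <- live$id[live$namespace == ns]
    nroots <- sum(!(ns_ids %in% isa_children))
    root_counts[ns] <- nroots
    if (nroots == 0L) {
      add("no_root", sprintf("namespace '%s' has no is_a root", ns))
    }
  }

  out <- if (length(issues)) {
    do.call(rbind, issues)
  } else {
    data.frame(type = character(), detail = character(),
               stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  structure(out, root_counts = root_counts,
            class = c("ontology_validation", "data.frame"))
}

# Nodes of the child->parent edge list that survive Kahn peeling, i.e.
# participate in or depend on a directed cycle.
kahn_residual <- function(edges) {
  nodes <- unique(c(edges$child, edges$parent))
  ch <- edges$child
  pa <- edges$parent
  indeg <- table(factor(pa, levels = nodes))  # edges arriving at parents
  indeg <- as.integer(indeg)
  names(indeg) <- nodes
  # peel nodes with no incoming edge (no remaining children)
  alive <- rep(TRUE, length(ch))
  queue <- nodes[indeg == 0L]
  removed <- character(0)
  while (length(queue)) {
    v <- queue[[1]]
    queue <- queue[-1]
    removed <- c(removed, v)
    out_idx <- which(alive & ch == v)
    for (i in out_idx) {
      alive[i] <- FALSE
      p <- pa[i]
      indeg[p] <- indeg[p] - 1L
      if (indeg[p] == 0L) queue <- c(queue, p)
    }
  }
  setdiff(nodes, removed)
}

#' @export
print.ontology_validation <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("Ontology valid: no violations.\n")
  } else {
    cat(sprintf("Ontology INVALID: %d violation(s)\n", nrow(x)))
    for (i in seq_len(nrow(x))) {
      cat(sprintf("  [%s] %s\n", x$type[i], x$detail[i]))
    }
  }
  rc <- attr(x, "root_counts")
  if (length(rc)) {
    cat("Root counts:",
        paste(sprintf("%s=%d", names(rc), rc), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Does a validation report show a valid ontology?
#'
#' @param report An `ontology_validation` object from [validate_ontology()].
#' @return `TRUE` if no violations were found.
#' @export
is_valid_ontology <- function(report) {
  stopifnot(inherits(report, "ontology_validation"))
  nrow(report) == 0L
}
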