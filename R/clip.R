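# Clipping: the ancestor-closure and subset-extraction algorithms.

#' Policy-aware ancestor closure
#'
#' Computes the smallest term set that contains `seeds` and is closed
#' upwards under the traversal policy: every parent reached through a
#' transitive relation (by default `is_a`) is added repeatedly, up to the
#' roots, for *every* member of the result; parents reached through a
#' one-step relation (by default `part_of`) are added once, and only when
#' the child is a seed. Ignored relations (the regulates kinds by default)
#' are never followed. This is the closure that keeps a clipped subset a
#' consistent DAG: ancestors of relevant terms survive even when they are
#' not themselves relevant.
#'
#' @param dag An [ontology_dag()].
#' @param seeds Character vector of term ids to close over.
#' @param policy A [traversal_policy()].
#' @return Sorted character vector of term ids, a superset of `seeds`
#'   (empty for empty `seeds`).
#' @examples
#' dag <- ontology_dag(
#'   data.frame(id = c("R", "A", "C")),
#'   data.frame(child = c("A", "C"), parent = c("R", "A"),
#'              relation = "is_a"))
#' ancestor_closure(dag, "C")  # C, its parent A, and the root R
#' @export
ancestor_closure <- function(dag, seeds, policy = traversal_policy()) {
  stopifnot(inherits(dag, "ontology_dag"))
  policy <- as_traversal_policy(policy)
  seeds <- unique(as.character(seeds))
  if (length(seeds) == 0L) return(character(0))

  unknown <- setdiff(seeds, dag$terms$id)
  if (length(unknown)) {
    stop("unknown seed term id(s): ", paste(sort(unknown), collapse = ", "))
  }
  obs <- intersect(seeds, dag$terms$id[dag$terms$obsolete])
  if (length(obs)) {
    stop("obsolete seed term id(s): ", paste(sort(obs), collapse = ", "))
  }

  ee <- dag$edges
  one <- ee[ee$relation %in% policy$one_step, , drop = FALSE]
  trans <- ee[ee$relation %in% policy$transitive, , drop = FALSE]

  base <- union(seeds, one$parent[one$child %in% seeds])
  # breadth-first closure over the transitive relations
  parent_of <- split(trans$parent, trans$child)
  result <- base
  frontier <- base
  while (length(frontier)) {
    nxt <- unique(unlist(parent_of[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, result)
    result <- c(result, nxt)
    frontier <- nxt
  }
  # closure never resurrects obsolete terms (well-formed inputs have no
  # edges on them anyway)
  result <- setdiff(result, dag$terms$id[dag$terms$obsolete])
  sort(result)
}

new_clip_result <- function(flagged, parental, removed, provenance) {
  if (length(provenance)) {
    provenance <- provenance[order(names(provenance))]
  } else {
    provenance <- stats::setNames(character(0), character(0))
  }
  structure(list(flagged = sort(unique(flagged)),
                 parental = sort(unique(parental)),
                 removed = sort(unique(removed)),
                 provenance = provenance),
            class = "clip_result")
}

#' @export
print.clip_result <- function(x, ...) {
  cat(sprintf(
    "Clip result: %d flagged + %d parental = %d retained; %d removed\n",
    length(x$flagged), length(x$parental),
    length(x$flagged) + length(x$parental), length(x$removed)))
  invisible(x)
}

#' Clip an ontology to a flagged term set
#'
#' Retains the policy-ancestor closure of the flagged terms and drops
#' everything else. Retained terms split into the *flagged* terms
#' themselves (deemed relevant) and *parental* terms kept only so that
#' every retained term still has its ancestors — the property that
#' distinguishes clipping from slimming. The clipped DAG keeps every
#' original edge whose two endpoints both survive.
#'
#' @param dag An [ontology_dag()].
#' @param flagged Character vector of relevant term ids (must exist in
#'   `dag`). Obsolete ids are dropped with a warning.
#' @param policy A [traversal_policy()].
#' @param provenance Optional named character vector mapping flagged ids to
#'   the label of whatever flagged them (e.g. a filter name); unnamed
#'   flagged terms get label `"flagged"`.
#' @return A list with elements `dag` (the clipped `ontology_dag`) and
#'   `result` (a `clip_result` with components `flagged`, `parental`,
#'   `removed`, and a per-term `provenance` map where parental terms are
#'   labelled `"parental"`).
#' @examples
#' dag <- ontology_dag(
#'   data.frame(id = c("R", "A", "B")),
#'   data.frame(child = c("A", "B"), parent = c("R", "R"),
#'              relation = "is_a"))
#' clipped <- clip_ontology(dag, flagged = "A")
#' clipped$result
#' @export
clip_ontology <- function(dag, flagged, policy = traversal_policy(),
                          provenance = NULL) {
  stopifnot(inherits(dag, "ontology_dag"))
  policy <- as_traversal_policy(policy)
  flagged <- unique(as.character(flagged))
  unknown <- setdiff(flagged, dag$terms$id)
  if (length(unknown)) {
    stop("flagged term id(s) absent from ontology: ",
         paste(sort(unknown), collapse = ", "))
  }
  obs <- intersect(flagged, dag$terms$id[dag$terms$obsolete])
  if (length(obs)) {
    warning("dropping obsolete flagged term(s): ",
            paste(sort(obs), collapse = ", "))
    flagged <- setdiff(flagged, obs)
  }

  retained <- ancestor_closure(dag, flagged, policy)
  live <- dag$terms$id[!dag$terms$obsolete]
  parental <- setdiff(retained, flagged)
  removed <- setdiff(live, retained)

  prov <- rep("flagged", length(flagged))
  names(prov) <- flagged
  if (!is.null(provenance)) {
    given <- intersect(names(provenance), flagged)
    prov[given] <- provenance[given]
  }
  ppar <- rep("parental", length(parental))
  names(ppar) <- parental
  prov <- c(prov, ppar)

  list(dag = subset_ontology(dag, retained),
       result = new_clip_result(flagged, parental, removed, prov))
}

#' Organism-based clipping from annotation files
#'
#' Flags every term directly used to annotate a gene or gene product in any
#' of the supplied annotation sets and clips the ontology to those terms
#' plus their policy ancestors. This is the first clipping stage: it prunes
#' the ontology down to the vocabulary actually used for the organisms of
#' interest before any relevance filtering.
#'
#' @param dag An [ontology_dag()].
#' @param annotation_sets A single [annotation_set()] or a non-empty list of
#'   them (one per taxon, typically). Annotation term ids absent from the
#'   ontology are skipped with a warning, since annotation files routinely
#'   lag ontology releases.
#' @param policy A [traversal_policy()].
#' @return As [clip_ontology()]; flagged terms carry provenance
#'   `"organism"`.
#' @export
organism_clip <- function(dag, annotation_sets, policy = traversal_policy()) {
  stopifnot(inherits(dag, "ontology_dag"))
  if (inherits(annotation_sets, "annotation_set")) {
    annotation_sets <- list(annotation_sets)
  }
  if (!is.list(annotation_sets) || length(annotation_sets) == 0L) {
    stop("'annotation_sets' must be a non-empty list of annotation sets")
  }
  ok <- vapply(annotation_sets, inherits, logical(1), "annotation_set")
  if (!all(ok)) stop("all elements of 'annotation_sets' must be annotation sets")

  used <- sort(unique(unlist(lapply(annotation_sets, annotated_terms),
                             use.names = FALSE)))
  known <- intersect(used, dag$terms$id)
  skipped <- setdiff(used, known)
  if (length(skipped)) {
    warning(sprintf(
      "skipping %d annotated term id(s) absent from the ontology: %s",
      length(skipped),
      paste(utils::head(sort(skipped), 10), collapse = ", ")))
  }
  live <- setdiff(known, dag$terms$id[dag$terms$obsolete])
  prov <- rep("organism", length(live))
  names(prov) <- live
  clip_ontology(dag, flagged = live, policy = policy, provenance = prov)
}
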