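# Relation handling during upward traversal.

#' Valid relation kinds
#'
#' The five relation kinds an ontology edge may carry: `is_a`, `part_of`,
#' and the three regulates variants.
#'
#' @return Character vector of the five relation labels.
#' @export
relation_kinds <- function() {
  c("is_a", "part_of", "regulates", "positively_regulates",
    "negatively_regulates")
}

#' Traversal policy for walking towards the ontology roots
#'
#' A traversal policy assigns each relation kind to one of three roles used
#' by [ancestor_closure()] and the clipping operations:
#'
#' * `transitive`: followed repeatedly, all the way to the roots
#'   (default: `is_a`);
#' * `one_step`: followed for a single step, and only from the starting
#'   (flagged) terms, to pull in directly related terms (default:
#'   `part_of`);
#' * `ignored`: never followed (default: the three regulates kinds).
#'
#' Relation kinds not named in any set are also never followed. The three
#' sets must be pairwise disjoint and drawn from [relation_kinds()].
#'
#' @param transitive Character vector of relation kinds closed over
#'   transitively.
#' @param one_step Character vector of relation kinds followed one step from
#'   seed terms only.
#' @param ignored Character vector of relation kinds never followed.
#' @return An object of class `traversal_policy`.
#' @examples
#' traversal_policy()
#' # treat part_of like is_a:
#' traversal_policy(transitive = c("is_a", "part_of"), one_step = character())
#' @export
traversal_policy <- function(transitive = "is_a",
                             one_step = "part_of",
                             ignored = c("regulates",
                                         "positively_regulates",
                                         "negatively_regulates")) {
  transitive <- unique(as.character(transitive))
  one_step <- unique(as.character(one_step))
  ignored <- unique(as.character(ignored))
  all_named <- c(transitive, one_step, ignored)
  bad <- setdiff(all_named, relation_kinds())
  if (length(bad)) {
    stop("unknown relation kind(s): ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(all_named)) {
    stop("traversal policy sets must be pairwise disjoint; duplicated: ",
         paste(unique(all_named[duplicated(all_named)]), collapse = ", "))
  }
  structure(list(transitive = transitive, one_step = one_step,
                 ignored = ignored),
            class = "traversal_policy")
}

#' @export
print.traversal_policy <- function(x, ...) {
  fmt <- function(v) if (length(v)) paste(v, collapse = ", ") else "(none)"
  cat("Traversal policy\n")
  cat("  transitive:", fmt(x$transitive), "\n")
  cat("  one-step:  ", fmt(x$one_step), "\n")
  cat("  ignored:   ", fmt(x$ignored), "\n")
  invisible(x)
}

as_traversal_policy <- function(x) {
  if (inherits(x, "traversal_policy")) return(x)
  if (is.null(x)) return(traversal_policy())
  stop("expected a traversal_policy object")
}
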