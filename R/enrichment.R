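# Term-for-term over-representation analysis and full-vs-clipped subset
# comparison. The statistical mechanism that motivates clipping lives
# here: the raw hypergeometric p-value of a term depends only on its own
# counts, so removing irrelevant terms changes nothing but the
# multiple-testing burden — and therefore improves adjusted p-values.

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: for sorted p-values p(1) <= ... <= p(m),
#' adj(i) = min over j >= i of min(1, m p(j) / j), returned in the input
#' order. Thin validating wrapper over `stats::p.adjust(method = "BH")`.
#'
#' @param pvalues Numeric vector of probabilities in `[0, 1]`.
#' @return Adjusted values, same length and order as the input.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Term-for-term over-representation analysis
#'
#' For each term, tests whether the study set contains more genes
#' annotated to the term than expected from drawing `n` genes at random
#' from the population: the one-sided hypergeometric upper tail
#' `P(X >= k)` with `X ~ Hypergeom(N, K, n)`, where `N` is the population
#' size, `K` the population genes annotated to the term, `n` the study
#' size and `k` the study genes annotated to the term. Adjusted p-values
#' use Benjamini-Hochberg over exactly the terms included, so analysing a
#' clipped subset changes adjusted values while raw p-values stay
#' identical term by term.
#'
#' @param study Character vector of study gene symbols (must be a subset
#'   of the population).
#' @param population Character vector of population gene symbols.
#' @param annotations An [annotation_set()] (or a named gene-set list as
#'   produced by [read_gmt()]).
#' @param terms Term ids to test, or `NULL` for every annotated term.
#'   Terms annotating no population gene are untestable and are dropped
#'   before correction (a message reports how many).
#' @param propagate Propagate annotations to all `is_a`/`part_of`
#'   ancestors (true-path rule) before counting? Default `FALSE`, matching
#'   association files whose gene-term mapping is kept verbatim.
#' @param dag An [ontology_dag()], required when `propagate = TRUE`.
#' @param label Subset label stored in the table metadata.
#' @return An object of class `enrichment_table`: a data frame with
#'   columns `term_id`, `N`, `n`, `K`, `k`, `raw_p`, `adjusted_p`, sorted
#'   by raw p-value then term id, with the query stored in attributes.
#' @export
term_for_term <- function(study, population, annotations, terms = NULL,
                          propagate = FALSE, dag = NULL, label = "all") {
  study <- unique(as.character(study))
  population <- unique(as.character(population))
  if (length(study) == 0L || length(population) == 0L) {
    stop("study and population must be non-empty")
  }
  extra <- setdiff(study, population)
  if (length(extra)) {
    stop("study genes absent from population: ",
         paste(sort(extra), collapse = ", "))
  }

  g2t <- if (inherits(annotations, "annotation_set")) {
    genes_per_term(annotations)
  } else if (is.list(annotations)) {
    annotations
  } else {
    stop("'annotations' must be an annotation_set or a gene-set list")
  }
  if (isTRUE(propagate)) {
    if (is.null(dag)) stop("'dag' is required when propagate = TRUE")
    g2t <- propagate_annotations(g2t, dag)
  }

  if (is.null(terms)) terms <- names(g2t)
  terms <- sort(unique(as.character(terms)))

  N <- length(population)
  n <- length(study)
  K <- integer(length(terms))
  k <- integer(length(terms))
  for (i in seq_along(terms)) {
    genes <- intersect(g2t[[terms[i]]] %||% character(), population)
    K[i] <- length(genes)
    k[i] <- length(intersect(genes, study))
  }
  testable <- K > 0L
  n_dropped <- sum(!testable)
  if (n_dropped > 0L) {
    message(sprintf(
      "dropping %d untestable term(s) with no annotated population gene",
      n_dropped))
  }
  terms <- terms[testable]; K <- K[testable]; k <- k[testable]

  raw_p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  adj_p <- bh_adjust(raw_p)
  tab <- data.frame(term_id = terms, N = N, n = n, K = K, k = k,
                    raw_p = raw_p, adjusted_p = adj_p,
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$raw_p, tab$term_id), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab,
            label = label,
            study = sort(study), population = sort(population),
            n_dropped = n_dropped,
            class = c("enrichment_table", "data.frame"))
}

# True-path rule: credit each gene set to all policy ancestors of its
# term. Both is_a and part_of are treated as transitive here.
propagate_annotations <- function(g2t, dag) {
  policy <- traversal_policy(transitive = c("is_a", "part_of"),
                             one_step = character())
  known <- intersect(names(g2t), term_ids(dag, include_obsolete = FALSE))
  out <- list()
  for (t in known) {
    anc <- ancestor_closure(dag, t, policy)
    for (a in anc) out[[a]] <- union(out[[a]] %||% character(), g2t[[t]])
  }
  # keep annotated terms unknown to the dag untouched
  for (t in setdiff(names(g2t), known)) out[[t]] <- g2t[[t]]
  lapply(out[order(names(out))], sort)
}

#' @export
print.enrichment_table <- function(x, ...) {
  cat(sprintf(
    "Enrichment table '%s': %d terms (N=%d population, n=%d study)\n",
    attr(x, "label"), nrow(x), length(attr(x, "population")),
    length(attr(x, "study"))))
  print.data.frame(utils::head(x, 10))
  if (nrow(x) > 10) cat(sprintf("... and %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

#' Write an enrichment table
#'
#' Tab-delimited export with a term-name column when an ontology is given.
#'
#' @param table An `enrichment_table`.
#' @param path Output path.
#' @param dag Optional [ontology_dag()] for term names.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(table, path, dag = NULL) {
  out <- as.data.frame(table)
  if (!is.null(dag)) {
    out$name <- dag$terms$name[match(out$term_id, dag$terms$id)]
    out <- out[, c("term_id", "name", setdiff(names(out),
                                              c("term_id", "name")))]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Compare enrichment results across ontology subsets
#'
#' For every pair of labelled enrichment tables computed from the same
#' study/population query, reports which terms pass the cutoff only in
#' one subset, which pass in both, and — among the shared passers — how
#' often each subset attains the strictly lower adjusted p-value. When a
#' subset's [clip_ontology()] result is supplied, terms unique to that
#' subset are additionally split into relevance-flagged vs parental, since
#' a hit on a term kept only for graph consistency reads differently from
#' a hit on a term deemed relevant.
#'
#' @param tables Named list of >= 2 `enrichment_table` objects over the
#'   same query.
#' @param cutoff Significance threshold; a term passes iff its p-value is
#'   `<= cutoff`.
#' @param on Apply the cutoff to `"adjusted"` (default) or `"raw"`
#'   p-values, mirroring the mixed FDR-based and raw-p cutoffs used in
#'   practice.
#' @param clip_results Optional named list of `clip_result` objects,
#'   matched to `tables` by name.
#' @return An object of class `subset_comparison`: a data frame with one
#'   row per ordered pair, plus attribute `passing` (the per-table passing
#'   term sets).
#' @export
compare_subsets <- function(tables, cutoff, on = c("adjusted", "raw"),
                            clip_results = NULL) {
  on <- match.arg(on)
  if (!is.list(tables) || length(tables) < 2L) {
    stop("'tables' must be a named list of at least two enrichment tables")
  }
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    stop("every enrichment table must be named")
  }
  ok <- vapply(tables, inherits, logical(1), "enrichment_table")
  if (!all(ok)) stop("all elements of 'tables' must be enrichment tables")
  ref_pop <- attr(tables[[1]], "population")
  ref_study <- attr(tables[[1]], "study")
  for (nm in names(tables)[-1]) {
    if (!identical(attr(tables[[nm]], "population"), ref_pop) ||
        !identical(attr(tables[[nm]], "study"), ref_study)) {
      stop(sprintf(
        "table '%s' was computed from a different query than '%s'",
        nm, names(tables)[1]))
    }
  }
  pcol <- if (on == "adjusted") "adjusted_p" else "raw_p"
  passing <- lapply(tables, function(t) t$term_id[t[[pcol]] <= cutoff])
  names(passing) <- names(tables)

  rows <- list()
  pairs <- utils::combn(names(tables), 2, simplify = FALSE)
  for (pr in pairs) {
    a <- pr[1]; b <- pr[2]
    only_a <- setdiff(passing[[a]], passing[[b]])
    only_b <- setdiff(passing[[b]], passing[[a]])
    shared <- intersect(passing[[a]], passing[[b]])
    adj_a <- tables[[a]]$adjusted_p[match(shared, tables[[a]]$term_id)]
    adj_b <- tables[[b]]$adjusted_p[match(shared, tables[[b]]$term_id)]
    lower_a <- sum(adj_a < adj_b)
    lower_b <- sum(adj_b < adj_a)
    count_prov <- function(ids, label) {
      cr <- clip_results[[label]]
      if (is.null(cr)) return(c(flagged = NA_integer_,
                                parental = NA_integer_))
      c(flagged = length(intersect(ids, cr$flagged)),
        parental = length(intersect(ids, cr$parental)))
    }
    pa <- count_prov(only_a, a)
    pb <- count_prov(only_b, b)
    rows[[length(rows) + 1L]] <- data.frame(
      subset_a = a, subset_b = b,
      unique_a = length(only_a), unique_b = length(only_b),
      shared = length(shared),
      lower_adj_a = lower_a, lower_adj_b = lower_b,
      unique_a_flagged = pa[["flagged"]],
      unique_a_parental = pa[["parental"]],
      unique_b_flagged = pb[["flagged"]],
      unique_b_parental = pb[["parental"]],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, passing = passing, cutoff = cutoff, on = on,
            class = c("subset_comparison", "data.frame"))
}

#' @export
print.subset_comparison <- function(x, ...) {
  cat(sprintf("Subset comparison (cutoff %.4g on %s p-values)\n",
              attr(x, "cutoff"), attr(x, "on")))
  print.data.frame(x)
  invisible(x)
}
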