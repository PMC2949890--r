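# The five-step relevance-filter cascade deciding per-term domain
# relevance. Filters 1-4 live here; step 5 (ontological integrity, i.e.
# the ancestor closure) is applied by clip_ontology() on the cascade's
# flagged set, not by the cascade itself.

#' Default neural/immune keyword vocabulary
#'
#' The six keyword fragments used for both the term-name filter and the
#' concept-graph search: matched as case-insensitive substrings, so
#' `"inflam"` hits both "inflammation" and "inflammatory".
#'
#' @return Character vector of six keyword fragments.
#' @export
neural_immune_keywords <- function() {
  c("immune", "neuro", "inflam", "brain", "lymph", "nerve")
}

#' Default core marker-gene lists
#'
#' Marker genes routinely used as biomarkers of neural and immunological
#' processes; a term annotated by at least one of them is considered
#' domain-relevant by the core-gene filter.
#'
#' @param set `"both"` (default), `"neural"` or `"immune"`.
#' @return Character vector of gene symbols.
#' @export
neural_immune_core_genes <- function(set = c("both", "neural", "immune")) {
  set <- match.arg(set)
  neural <- c("PCNA", "PVALB", "Tuj1", "Calb1", "Calb2", "DCX", "DPYSL2",
              "HH3", "Eno2", "GFAP", "MKI67", "MSI1", "Nes", "NeuN",
              "Map2", "NT3", "P75", "NGFR")
  immune <- c("STAT1", "STAT3", "SOCS1", "SOCS2", "IGF1", "IFNgR", "IL1b",
              "IL6", "BDNF", "CNTF", "IFNg", "TNF", "IL4")
  switch(set, neural = neural, immune = immune,
         both = c(neural, immune))
}

# Uniform decision-table constructor.
filter_decisions <- function(term_id, verdict, filter, evidence) {
  data.frame(term_id = term_id, verdict = verdict, filter = filter,
             evidence = evidence, stringsAsFactors = FALSE)
}

eval_term_ids <- function(dag, terms = NULL) {
  live <- dag$terms$id[!dag$terms$obsolete]
  if (is.null(terms)) live else intersect(as.character(terms), live)
}

#' Filter 1: relevance by term name
#'
#' Flags a term when any keyword occurs as a case-insensitive substring of
#' its name (and, by default, its synonyms). Expert judgment is carried by
#' two optional decision lists: ids on the include list are always flagged
#' (evidence `"include-list"`) and ids on the exclude list are never
#' flagged by this filter, overriding keyword hits.
#'
#' @param dag An [ontology_dag()].
#' @param keywords Keyword fragments; default [neural_immune_keywords()].
#' @param fields Which term fields to scan: subset of
#'   `c("name", "synonyms")`.
#' @param include,exclude Optional term-id decision lists.
#' @param terms Term ids to evaluate (default: all live terms).
#' @return A decision data frame with columns `term_id`, `verdict`
#'   (`"flagged"`/`"passed"`), `filter`, `evidence`.
#' @export
keyword_name_filter <- function(dag, keywords = neural_immune_keywords(),
                                fields = c("name", "synonyms"),
                                include = character(),
                                exclude = character(),
                                terms = NULL) {
  stopifnot(inherits(dag, "ontology_dag"))
  fields <- match.arg(fields, several.ok = TRUE)
  keywords <- as.character(keywords)
  if (length(keywords) == 0L && length(include) == 0L) {
    stop("supply keywords or an include decision list")
  }
  ids <- eval_term_ids(dag, terms)
  idx <- match(ids, dag$terms$id)
  kw <- tolower(keywords)

  verdict <- character(length(ids))
  evidence <- character(length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    if (id %in% include) {
      verdict[i] <- "flagged"; evidence[i] <- "include-list"
      next
    }
    verdict[i] <- "passed"; evidence[i] <- ""
    if (id %in% exclude) next
    texts <- character(0)
    if ("name" %in% fields) texts <- dag$terms$name[idx[i]]
    if ("synonyms" %in% fields) {
      texts <- c(texts, dag$terms$synonyms[[idx[i]]])
    }
    lt <- tolower(texts)
    for (k in seq_along(kw)) {
      hit <- which(grepl(kw[k], lt, fixed = TRUE))
      if (length(hit)) {
        verdict[i] <- "flagged"
        evidence[i] <- sprintf("keyword '%s' in \"%s\"", keywords[k],
                               texts[hit[1]])
        break
      }
    }
  }
  filter_decisions(ids, verdict, "name", evidence)
}

#' Filter 2: association with a core gene list
#'
#' Flags a term when at least one core marker gene annotates it. Gene
#' symbols are matched case-insensitively, since annotation files mix
#' human upper-case and rodent mixed-case symbols.
#'
#' @param dag An [ontology_dag()].
#' @param annotations An [annotation_set()].
#' @param core_genes Marker symbols; default [neural_immune_core_genes()].
#' @param terms Term ids to evaluate (default: all live terms).
#' @return A decision data frame; evidence lists the matching gene(s).
#' @export
core_gene_filter <- function(dag, annotations,
                             core_genes = neural_immune_core_genes(),
                             terms = NULL) {
  stopifnot(inherits(dag, "ontology_dag"),
            inherits(annotations, "annotation_set"))
  if (length(core_genes) == 0L) stop("'core_genes' must be non-empty")
  ids <- eval_term_ids(dag, terms)
  g2t <- genes_per_term(annotations)
  core_lc <- tolower(core_genes)

  verdict <- rep("passed", length(ids))
  evidence <- rep("", length(ids))
  for (i in seq_along(ids)) {
    genes <- g2t[[ids[i]]]
    if (is.null(genes)) next
    hit <- genes[tolower(genes) %in% core_lc]
    if (length(hit)) {
      verdict[i] <- "flagged"
      evidence[i] <- paste("core gene", paste(sort(hit), collapse = ","))
    }
  }
  filter_decisions(ids, verdict, "core-gene", evidence)
}

#' Filter 3: literature relevance (pluggable)
#'
#' The literature step is judgment-based: each term name is searched in
#' the literature and flagged when a domain-related paper appears near the
#' top of the results. That judgment is not reproducible mechanically, so
#' this filter consumes either a precomputed decision file (ids to flag)
#' or a caller-supplied oracle function.
#'
#' @param dag An [ontology_dag()].
#' @param oracle Function taking a term id and returning either a logical
#'   or a list with elements `verdict` (`TRUE`/`FALSE`) and `evidence`.
#' @param decision_file Path to a flat term-id list of terms to flag.
#'   Exactly one of `oracle`/`decision_file` must be supplied.
#' @param terms Term ids to evaluate (default: all live terms).
#' @return A decision data frame. Errors raised by the oracle abort the
#'   cascade with the offending term id in the message.
#' @export
literature_filter <- function(dag, oracle = NULL, decision_file = NULL,
                              terms = NULL) {
  stopifnot(inherits(dag, "ontology_dag"))
  if (is.null(oracle) && is.null(decision_file)) {
    stop("literature filter needs an oracle function or a decision file ",
         "(supply 'decision_file' with precomputed term ids)")
  }
  ids <- eval_term_ids(dag, terms)
  if (!is.null(decision_file)) {
    listed <- read_term_list(decision_file)
    verdict <- ifelse(ids %in% listed, "flagged", "passed")
    evidence <- ifelse(ids %in% listed,
                       paste0("decision list ", basename(decision_file)), "")
    return(filter_decisions(ids, verdict, "literature", evidence))
  }
  verdict <- character(length(ids))
  evidence <- character(length(ids))
  for (i in seq_along(ids)) {
    ans <- tryCatch(oracle(ids[i]), error = function(e) {
      stop(sprintf("literature oracle failed on term %s: %s", ids[i],
                   conditionMessage(e)), call. = FALSE)
    })
    if (is.logical(ans)) ans <- list(verdict = ans, evidence = "oracle")
    verdict[i] <- if (isTRUE(ans$verdict)) "flagged" else "passed"
    evidence[i] <- if (isTRUE(ans$verdict)) {
      if (nzchar(ans$evidence %||% "")) ans$evidence else "oracle"
    } else ""
  }
  filter_decisions(ids, verdict, "literature", evidence)
}

#' Filter 4: concept-graph relevance
#'
#' Flags a term when [termfind()] is positive: the term maps to a concept
#' whose alias strings, or those of any concept up to `max_up` parent
#' steps above it, contain a keyword.
#'
#' @param dag An [ontology_dag()].
#' @param graph A `concept_graph` from [load_concept_graph()].
#' @param keywords Keyword fragments; default [neural_immune_keywords()].
#' @param max_up Maximum number of upward steps (default 3).
#' @param terms Term ids to evaluate (default: all live terms).
#' @return A decision data frame; evidence shows the matched string and
#'   the concept path that reached it.
#' @export
concept_graph_filter <- function(dag, graph, keywords = neural_immune_keywords(),
                                 max_up = 3L, terms = NULL) {
  stopifnot(inherits(dag, "ontology_dag"), inherits(graph, "concept_graph"))
  ids <- eval_term_ids(dag, terms)
  verdict <- rep("passed", length(ids))
  evidence <- rep("", length(ids))
  names_lc <- dag$terms$name[match(ids, dag$terms$id)]
  for (i in seq_along(ids)) {
    res <- termfind(ids[i], graph, keywords = keywords, max_up = max_up,
                    name = names_lc[i])
    if (res$positive) {
      m <- res$matches[1, ]
      verdict[i] <- "flagged"
      evidence[i] <- sprintf("\"%s\" (keyword '%s') via %s", m$string,
                             m$keyword, m$path)
    }
  }
  filter_decisions(ids, verdict, "concept-graph", evidence)
}

#' Assemble a filter cascade
#'
#' A cascade is an ordered list of filters plus a set of exempt
#' namespaces. Each filter is a function `f(dag, term_ids)` returning a
#' decision data frame for exactly those term ids (partially apply the
#' filter functions above via their `terms` argument). Terms in an exempt
#' namespace are flagged wholesale without filtering — the treatment given
#' to the cellular-component branch, where relevance judgments proved
#' impractical and organism-based clipping alone is used.
#'
#' @param filters Named list of filter functions, applied in order.
#' @param exempt_namespaces Character vector of namespaces whose terms are
#'   all flagged with provenance `"namespace-exempt"`.
#' @return An object of class `filter_cascade`.
#' @examples
#' cascade <- filter_cascade(list(
#'   name = function(dag, ids) keyword_name_filter(dag, terms = ids)))
#' @export
filter_cascade <- function(filters, exempt_namespaces = character()) {
  if (!is.list(filters) || length(filters) == 0L) {
    stop("'filters' must be a non-empty list of functions")
  }
  if (is.null(names(filters)) || any(!nzchar(names(filters)))) {
    stop("every filter must be named")
  }
  ok <- vapply(filters, is.function, logical(1))
  if (!all(ok)) stop("every filter must be a function(dag, term_ids)")
  structure(list(filters = filters,
                 exempt_namespaces = as.character(exempt_namespaces)),
            class = "filter_cascade")
}

#' Run a filter cascade
#'
#' Evaluates each live term against the filters in order; a term is
#' evaluated by filter *k* only if filters 1..k-1 did not flag it, so each
#' term's provenance names the first filter that flagged it. Terms in an
#' exempt namespace are flagged up front with provenance
#' `"namespace-exempt"`. The closure step that retains parental terms is
#' *not* part of the cascade: apply [clip_ontology()] to the flagged set.
#'
#' @param dag An [ontology_dag()].
#' @param cascade A [filter_cascade()].
#' @return A list with `flagged` (sorted term ids), `provenance` (named
#'   character vector, flagged terms only), and `decisions` (the full
#'   audit table: every evaluation by every filter, in cascade order).
#' @export
run_cascade <- function(dag, cascade) {
  stopifnot(inherits(dag, "ontology_dag"),
            inherits(cascade, "filter_cascade"))
  live <- dag$terms$id[!dag$terms$obsolete]
  ns <- dag$terms$namespace[match(live, dag$terms$id)]
  exempt <- live[ns %in% cascade$exempt_namespaces]

  decisions <- list()
  provenance <- character(0)
  if (length(exempt)) {
    provenance[exempt] <- "namespace-exempt"
    decisions[[length(decisions) + 1L]] <- filter_decisions(
      exempt, "flagged", "namespace-exempt",
      paste0("namespace ", ns[match(exempt, live)]))
  }
  remaining <- setdiff(live, exempt)
  for (fname in names(cascade$filters)) {
    if (length(remaining) == 0L) break
    dec <- cascade$filters[[fname]](dag, remaining)
    if (!is.data.frame(dec) ||
        !all(c("term_id", "verdict") %in% names(dec))) {
      stop(sprintf("filter '%s' returned an invalid decision table", fname))
    }
    dec$filter <- fname
    decisions[[length(decisions) + 1L]] <- dec
    newly <- dec$term_id[dec$verdict == "flagged"]
    provenance[newly] <- fname
    remaining <- setdiff(remaining, newly)
  }
  audit <- if (length(decisions)) {
    out <- do.call(rbind, decisions)
    rownames(out) <- NULL
    out
  } else {
    filter_decisions(character(), character(), character(), character())
  }
  flagged <- sort(names(provenance))
  list(flagged = flagged, provenance = provenance[flagged],
       decisions = audit)
}

#' Write a cascade audit table
#'
#' Tab-delimited export of the per-term decisions (term id, verdict,
#' filter, evidence), the shape used to publish which filter admitted each
#' term of a subset.
#'
#' @param decisions A decision data frame (e.g. `run_cascade()$decisions`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_decisions <- function(decisions, path) {
  utils::write.table(decisions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
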