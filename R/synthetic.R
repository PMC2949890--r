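# Synthetic fixtures: random acyclic ontologies, annotation tables,
# planted keyword-bearing domain branches, planted-enrichment gene sets,
# and the worked concept-graph example. Everything is deterministic under
# the spec's single seed; each generator draws from its own substream so
# that, e.g., regenerating annotations does not perturb the ontology.

#' Specification for the synthetic generators
#'
#' Bundles every knob the generators use. Background term names (and
#' synonyms) are built from digits only, an alphabet disjoint from the
#' keyword vocabulary, so that after [plant_domain()] the keyword filter
#' has an exact expected answer.
#'
#' @param n_terms Total number of terms across namespaces (default 150).
#' @param n_namespaces Number of namespaces, 1-3 (default 1).
#' @param mean_parents Mean number of parents per non-root term; the first
#'   parent is always `is_a` so every live term reaches its namespace
#'   root (default 1.5).
#' @param part_of_frac,regulates_frac Probability that an *extra* parent
#'   edge is `part_of` / one of the regulates kinds; the remainder are
#'   `is_a` (defaults 0.15 and 0.10; must sum to <= 1).
#' @param p_obsolete Fraction of terms marked obsolete, carrying no edges
#'   (default 0.02).
#' @param n_genes Number of synthetic genes (default 100).
#' @param mean_terms_per_gene Mean annotations per gene, minimum 1
#'   (default 3).
#' @param p_not Probability that a record carries a `NOT` qualifier
#'   (default 0.02).
#' @param domain_branch_size Number of terms in the planted domain branch
#'   (default 12).
#' @param keywords Keyword vocabulary planted into branch names; default
#'   [neural_immune_keywords()].
#' @param theta Enrichment effect: sampling-weight multiplier for genes of
#'   the planted term when drawing the study set (default 8).
#' @param study_size Study-set size (default 25).
#' @param seed Integer seed fixing all outputs (default 1).
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_terms = 150L, n_namespaces = 1L,
                       mean_parents = 1.5, part_of_frac = 0.15,
                       regulates_frac = 0.10, p_obsolete = 0.02,
                       n_genes = 100L, mean_terms_per_gene = 3,
                       p_not = 0.02, domain_branch_size = 12L,
                       keywords = neural_immune_keywords(), theta = 8,
                       study_size = 25L, seed = 1L) {
  if (part_of_frac < 0 || regulates_frac < 0 ||
      part_of_frac + regulates_frac > 1) {
    stop("relation fractions must be in [0,1] and sum to <= 1")
  }
  if (p_obsolete < 0 || p_obsolete >= 1) stop("p_obsolete must be in [0,1)")
  if (n_namespaces < 1L || n_namespaces > 3L) {
    stop("n_namespaces must be 1, 2 or 3")
  }
  if (theta <= 0) stop("theta must be positive")
  structure(list(n_terms = as.integer(n_terms),
                 n_namespaces = as.integer(n_namespaces),
                 mean_parents = mean_parents,
                 part_of_frac = part_of_frac,
                 regulates_frac = regulates_frac,
                 p_obsolete = p_obsolete,
                 n_genes = as.integer(n_genes),
                 mean_terms_per_gene = mean_terms_per_gene,
                 p_not = p_not,
                 domain_branch_size = as.integer(domain_branch_size),
                 keywords = as.character(keywords),
                 theta = theta,
                 study_size = as.integer(study_size),
                 seed = as.integer(seed)),
            class = "synth_spec")
}

# Independent substream seed per generator, kept inside 32-bit range.
substream_seed <- function(seed, k) {
  (as.numeric(seed) * 1009 + k * 99991) %% 2147483647
}

#' Generate a random acyclic ontology
#'
#' Terms are laid down in topological rank order and every edge points
#' from a later term to an earlier one, so acyclicity holds by
#' construction. Each namespace gets a single root; every live non-root
#' term gets one `is_a` parent (guaranteeing a path to the root) plus a
#' random number of extra parents whose relation kind is sampled from the
#' spec fractions. A trailing fraction of terms per namespace is marked
#' obsolete and carries no edges. Term names and synonyms use digits
#' only.
#'
#' @param spec A [synth_spec()].
#' @return An [ontology_dag()] that passes [validate_ontology()].
#' @export
gen_ontology <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(substream_seed(spec$seed, 1L))
  namespaces <- go_namespaces()[seq_len(spec$n_namespaces)]
  per_ns <- diff(round(seq(0, spec$n_terms, length.out =
                             spec$n_namespaces + 1L)))
  if (any(per_ns < 1L)) stop("n_terms too small for n_namespaces")

  terms <- list()
  edges <- list()
  gid <- 0L
  for (w in seq_along(namespaces)) {
    m <- per_ns[w]
    n_obs <- min(floor(spec$p_obsolete * m), m - 1L)
    n_live <- m - n_obs
    ids <- sprintf("ST:%07d", gid + seq_len(m))
    live_ids <- ids[seq_len(n_live)]
    for (j in seq_len(m)) {
      obsolete <- j > n_live
      syn <- if (!obsolete && stats::runif(1) < 0.2) {
        sprintf("%06d", 500000L + gid + j)
      } else character()
      terms[[length(terms) + 1L]] <- list(
        id = ids[j], name = sprintf("%06d", gid + j),
        namespace = namespaces[w], obsolete = obsolete, synonyms = syn)
      if (obsolete || j == 1L) next
      # guaranteed is_a parent among earlier live terms
      primary <- live_ids[sample.int(j - 1L, 1L)]
      child_edges <- data.frame(child = ids[j], parent = primary,
                                relation = "is_a",
                                stringsAsFactors = FALSE)
      n_extra <- stats::rpois(1L, max(spec$mean_parents - 1, 0))
      n_extra <- min(n_extra, j - 2L)
      if (n_extra > 0L) {
        cand <- setdiff(live_ids[seq_len(j - 1L)], primary)
        extra <- sample(cand, n_extra)
        rel <- vapply(seq_len(n_extra), function(i) {
          u <- stats::runif(1)
          if (u < spec$part_of_frac) "part_of"
          else if (u < spec$part_of_frac + spec$regulates_frac) {
            sample(c("regulates", "positively_regulates",
                     "negatively_regulates"), 1L)
          } else "is_a"
        }, character(1))
        child_edges <- rbind(child_edges,
                             data.frame(child = ids[j], parent = extra,
                                        relation = rel,
                                        stringsAsFactors = FALSE))
      }
      edges[[length(edges) + 1L]] <- child_edges
    }
    gid <- gid + m
  }
  tt <- data.frame(
    id = vapply(terms, `[[`, character(1), "id"),
    name = vapply(terms, `[[`, character(1), "name"),
    namespace = vapply(terms, `[[`, character(1), "namespace"),
    obsolete = vapply(terms, `[[`, logical(1), "obsolete"),
    stringsAsFactors = FALSE)
  tt$synonyms <- lapply(terms, `[[`, "synonyms")
  ee <- if (length(edges)) do.call(rbind, edges) else NULL
  ontology_dag(tt, ee)
}

#' Generate random gene annotations
#'
#' Every synthetic gene is annotated to at least one live term; term ids
#' all exist in the ontology. A small fraction of records carries a `NOT`
#' qualifier and evidence codes are sampled from a standard palette, so
#' the derived-view filters have something to act on.
#'
#' @param dag An [ontology_dag()] (non-empty).
#' @param spec A [synth_spec()].
#' @return An [annotation_set()].
#' @export
gen_annotations <- function(dag, spec) {
  stopifnot(inherits(dag, "ontology_dag"), inherits(spec, "synth_spec"))
  set.seed(substream_seed(spec$seed, 2L))
  live <- term_ids(dag, include_obsolete = FALSE)
  if (length(live) == 0L) stop("ontology has no live terms to annotate")
  if (spec$n_genes == 0L) {
    return(annotation_set(data.frame(gene = character(),
                                     term = character())))
  }
  recs <- list()
  for (g in seq_len(spec$n_genes)) {
    gene <- sprintf("g%05d", g)
    n_ann <- 1L + stats::rpois(1L, max(spec$mean_terms_per_gene - 1, 0))
    ts <- sample(live, min(n_ann, length(live)))
    recs[[g]] <- data.frame(
      gene = gene,
      object_id = sprintf("OBJ:%05d", g),
      term = ts,
      evidence = sample(c("IEA", "IDA", "IMP", "ISS", "TAS"),
                        length(ts), replace = TRUE),
      qualifier = ifelse(stats::runif(length(ts)) < spec$p_not, "NOT", ""),
      taxon = "taxon:9606",
      stringsAsFactors = FALSE)
  }
  annotation_set(do.call(rbind, recs))
}

#' Plant a keyword-bearing domain branch
#'
#' Selects a rooted sub-branch (a term plus its `is_a` descendants,
#' breadth-first, truncated to the requested size) and rewrites the names
#' of its terms to embed keywords from the vocabulary. Background names
#' remain digit-only, so a keyword scan recovers exactly the planted
#' branch.
#'
#' @param dag An [ontology_dag()].
#' @param spec A [synth_spec()]; `domain_branch_size` 0 plants nothing,
#'   a value >= the number of live terms plants everything.
#' @return A list with `dag` (names rewritten) and `truth` (list with
#'   `planted`, the sorted branch term ids).
#' @export
plant_domain <- function(dag, spec) {
  stopifnot(inherits(dag, "ontology_dag"), inherits(spec, "synth_spec"))
  set.seed(substream_seed(spec$seed, 3L))
  live <- term_ids(dag, include_obsolete = FALSE)
  size <- spec$domain_branch_size
  if (size <= 0L || length(live) == 0L) {
    return(list(dag = dag, truth = list(planted = character())))
  }
  if (size >= length(live)) {
    branch <- live
  } else {
    isa <- dag$edges[dag$edges$relation == "is_a", , drop = FALSE]
    children_of <- split(isa$child, isa$parent)
    descend <- function(seed_term) {
      out <- seed_term
      frontier <- seed_term
      while (length(frontier) && length(out) < size) {
        nxt <- setdiff(unique(unlist(children_of[frontier],
                                     use.names = FALSE)), out)
        out <- c(out, nxt)
        frontier <- nxt
      }
      out[seq_len(min(size, length(out)))]
    }
    best <- character(0)
    for (cand in sample(live, min(25L, length(live)))) {
      b <- descend(cand)
      if (length(b) > length(best)) best <- b
      if (length(best) >= size) break
    }
    branch <- best
  }
  idx <- match(branch, dag$terms$id)
  kw <- sample(spec$keywords, length(branch), replace = TRUE)
  dag$terms$name[idx] <- sprintf("%s %06d", kw, seq_along(branch))
  list(dag = dag, truth = list(planted = sort(branch)))
}

#' Generate a study/population query with a planted enriched term
#'
#' Chooses a planted term with at least two annotated genes, then samples
#' the study set from the whole gene population with sampling weight
#' `theta` for genes annotated to the planted term and 1 for the rest.
#' `theta = 1` is the null; large `theta` concentrates the study set on
#' the planted term's genes.
#'
#' @param dag An [ontology_dag()].
#' @param annotations An [annotation_set()] over `dag`.
#' @param spec A [synth_spec()].
#' @param planted_term Term id to plant, or `NULL` to pick one at random
#'   among terms with >= 2 annotated genes.
#' @return A list with `query` (list with `population` and `study` gene
#'   vectors) and `truth` (list with `planted_term`).
#' @export
gen_study <- function(dag, annotations, spec, planted_term = NULL) {
  stopifnot(inherits(dag, "ontology_dag"),
            inherits(annotations, "annotation_set"),
            inherits(spec, "synth_spec"))
  set.seed(substream_seed(spec$seed, 4L))
  g2t <- genes_per_term(annotations)
  population <- sort(unique(active_records(annotations)$gene))
  if (length(population) < 2L) stop("need at least two annotated genes")
  if (is.null(planted_term)) {
    eligible <- names(g2t)[lengths(g2t) >= 2L]
    eligible <- intersect(eligible, term_ids(dag))
    if (length(eligible) == 0L) {
      stop("no term has >= 2 annotated genes; increase annotation density")
    }
    planted_term <- sample(eligible, 1L)
  } else if (length(g2t[[planted_term]] %||% character()) < 2L) {
    stop("planted term must have >= 2 annotated genes")
  }
  planted_genes <- g2t[[planted_term]]
  w <- ifelse(population %in% planted_genes, spec$theta, 1)
  size <- min(spec$study_size, length(population) - 1L)
  study <- sort(sample(population, size, prob = w))
  list(query = list(population = population, study = study),
       truth = list(planted_term = planted_term))
}

#' Worked concept-graph fixture
#'
#' A small concept graph reproducing the shape of the classic worked
#' example: the seed concept "muscle hypertrophy" (mapped from
#' GO:0014896) has no domain keyword in its own aliases, but two parent
#' steps up sits a concept whose aliases contain "neuro", with edges
#' asserted by two different source vocabularies. `termfind` on it is
#' positive at the default depth of 3 and negative at depth 0. The files
#' are written with the standard loader dialect and read back through
#' [load_concept_graph()], so the fixture also exercises the loader.
#'
#' @param dir Directory for the three pipe-delimited files (default: a
#'   fresh temporary directory).
#' @return A list with `graph` (the loaded `concept_graph`), `files`
#'   (named paths), and `expected` (list describing the expected positive
#'   match: keyword, concept and depth).
#' @export
fig4_fixture <- function(dir = tempfile("conceptgraph")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(mapping = file.path(dir, "mapping.psv"),
             relations = file.path(dir, "relations.psv"),
             strings = file.path(dir, "strings.psv"))
  writeLines(c(
    "GO:0014896|muscle hypertrophy|C0000001"
  ), files["mapping"])
  writeLines(c(
    "C0000001|C0000002|MSH",
    "C0000002|C0000003|MSH",
    "C0000001|C0000004|SNOMEDCT",
    "C0000004|C0000005|MSH"
  ), files["relations"])
  writeLines(c(
    "C0000001|Muscle Hypertrophy|MSH",
    "C0000001|Hypertrophy of muscle|SNOMEDCT",
    "C0000002|Hypertrophy|MSH",
    "C0000003|Pathologic Processes|MSH",
    "C0000004|Muscle function|SNOMEDCT",
    "C0000005|Neuromuscular physiological phenomena|MSH",
    "C0000005|Neuromuscular function|SNOMEDCT"
  ), files["strings"])
  graph <- load_concept_graph(files["mapping"], files["relations"],
                              files["strings"])
  list(graph = graph, files = files,
       expected = list(positive = TRUE, keyword = "neuro",
                       concept = "C0000005", depth = 2L))
}

#' Write a complete synthetic fixture bundle
#'
#' Generates an ontology with a planted domain branch, annotations, a
#' planted-enrichment query and the concept-graph fixture, and writes
#' them all in their interchange formats: OBO, GAF, GMT, plain-text gene
#' lists, pipe-delimited concept tables, and ground-truth term lists.
#'
#' @param dir Output directory (created if missing).
#' @param spec A [synth_spec()].
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture_bundle <- function(dir, spec = synth_spec()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  planted <- plant_domain(gen_ontology(spec), spec)
  dag <- planted$dag
  anns <- gen_annotations(dag, spec)
  study <- gen_study(dag, anns, spec)

  paths <- c(obo = file.path(dir, "ontology.obo"),
             gaf = file.path(dir, "annotations.gaf"),
             gmt = file.path(dir, "genesets.gmt"),
             population = file.path(dir, "population.txt"),
             study = file.path(dir, "study.txt"),
             planted_terms = file.path(dir, "truth_planted_branch.txt"),
             enriched_term = file.path(dir, "truth_enriched_term.txt"))
  write_obo(dag, paths["obo"])
  write_gaf(anns, paths["gaf"])
  write_gmt(anns, paths["gmt"], dag = dag)
  writeLines(study$query$population, paths["population"])
  writeLines(study$query$study, paths["study"])
  write_term_list(planted$truth$planted, paths["planted_terms"])
  writeLines(study$truth$planted_term, paths["enriched_term"])
  cg <- fig4_fixture(file.path(dir, "conceptgraph"))
  paths <- c(paths, cg$files)
  invisible(paths)
}
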