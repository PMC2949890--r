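# Independent oracles, deliberately implemented with different machinery
# than the package (boolean matrix closure, recursive path enumeration,
# exact binomial-coefficient sums).

# Policy-aware closure via boolean adjacency-matrix reachability:
# base = seeds plus their one-step parents, then everything reachable
# from the base through transitive-relation paths of any length.
oracle_closure <- function(dag, seeds, policy = traversal_policy()) {
  ids <- dag$terms$id[!dag$terms$obsolete]
  n <- length(ids)
  seeds <- intersect(seeds, ids)
  if (length(seeds) == 0L) return(character(0))
  ee <- dag$edges[dag$edges$child %in% ids & dag$edges$parent %in% ids, ]
  one <- ee[ee$relation %in% policy$one_step, , drop = FALSE]
  base <- union(seeds, one$parent[one$child %in% seeds])

  M <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  tr <- ee[ee$relation %in% policy$transitive, , drop = FALSE]
  if (nrow(tr)) M[cbind(tr$child, tr$parent)] <- TRUE
  # reflexive-transitive closure by repeated squaring
  R <- M | diag(n) > 0
  repeat {
    R2 <- (R %*% R) > 0
    if (identical(R2, R)) break
    R <- R2
  }
  reach <- colnames(R)[colSums(R[base, , drop = FALSE]) > 0]
  sort(unique(reach))
}

# All concepts reachable from `seed` by upward paths of length <= max_up,
# by exhaustive recursive enumeration of simple paths.
oracle_reachable_up <- function(edges, seed, max_up) {
  found <- seed
  recurse <- function(node, depth, seen) {
    if (depth == max_up) return()
    for (p in unique(edges$parent[edges$child == node])) {
      if (p %in% seen) next
      found <<- union(found, p)
      recurse(p, depth + 1L, c(seen, p))
    }
  }
  recurse(seed, 0L, seed)
  sort(found)
}

oracle_termfind_positive <- function(term, graph, keywords, max_up) {
  hit <- match(term, graph$map$key)
  if (is.na(hit)) hit <- match(tolower(term), graph$map$key)
  if (is.na(hit)) return(FALSE)
  seed <- graph$map$cui[hit]
  visited <- oracle_reachable_up(graph$edges, seed, max_up)
  strings <- graph$aliases$string[graph$aliases$cui %in% visited]
  any(vapply(tolower(keywords), function(k) {
    any(grepl(k, tolower(strings), fixed = TRUE))
  }, logical(1)))
}

# Exact hypergeometric upper tail P(X >= k) from binomial coefficients.
oracle_hyper_upper <- function(N, K, n, k) {
  top <- min(K, n)
  if (k > top) return(0)
  js <- max(k, 0L):top
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Random DAG with mixed relation kinds over n nodes; edges always point
# from a higher index to a lower one (child -> parent), so the is_a and
# part_of restriction is acyclic by construction.
random_test_dag <- function(n = 30L, p_edge = 0.12) {
  ids <- sprintf("N%03d", seq_len(n))
  ch <- character(0); pa <- character(0); rel <- character(0)
  for (j in 2:n) {
    # guaranteed parent keeps the graph connected
    tgt <- sample.int(j - 1L, 1L)
    ch <- c(ch, ids[j]); pa <- c(pa, ids[tgt]); rel <- c(rel, "is_a")
    extra <- which(stats::runif(j - 1L) < p_edge)
    extra <- setdiff(extra, tgt)
    if (length(extra)) {
      ch <- c(ch, rep(ids[j], length(extra)))
      pa <- c(pa, ids[extra])
      rel <- c(rel, sample(relation_kinds(), length(extra),
                           replace = TRUE,
                           prob = c(0.5, 0.2, 0.1, 0.1, 0.1)))
    }
  }
  ontology_dag(data.frame(id = ids),
               data.frame(child = ch, parent = pa, relation = rel))
}

# Random concept graph: upward edges from higher to lower index, aliases
# partly keyword-bearing.
random_concept_graph <- function(n = 20L, p_edge = 0.15,
                                 keywords = c("neuro", "lymph")) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  cuis <- sprintf("RC%04d", seq_len(n))
  edges <- character(0)
  for (j in 2:n) {
    ups <- which(stats::runif(j - 1L) < p_edge)
    for (u in ups) edges <- c(edges, sprintf("%s|%s|SRC", cuis[j], cuis[u]))
  }
  strings <- vapply(seq_len(n), function(i) {
    if (stats::runif(1) < 0.2) {
      sprintf("%s|alias %s stuff|SRC", cuis[i], sample(keywords, 1))
    } else {
      sprintf("%s|alias %04d|SRC", cuis[i], i)
    }
  }, character(1))
  writeLines(sprintf("%s|term %s|%s", cuis, cuis, cuis),
             file.path(dir, "mapping.psv"))
  writeLines(edges, file.path(dir, "relations.psv"))
  writeLines(strings, file.path(dir, "strings.psv"))
  load_concept_graph(file.path(dir, "mapping.psv"),
                     file.path(dir, "relations.psv"),
                     file.path(dir, "strings.psv"))
}
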