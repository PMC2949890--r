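# Shared fixtures built in code.

# Seven-term single-namespace ontology exercising all three relation
# roles: a transitive is_a backbone, one part_of edge, one regulates
# edge.
#   A is_a R; B is_a R; C is_a A; D is_a C; D part_of B; E is_a B;
#   X is_a R; D regulates X
t6_dag <- function() {
  ontology_dag(
    terms = data.frame(id = c("R", "A", "B", "C", "D", "E", "X"),
                       name = c("root", "alpha", "beta", "gamma",
                                "delta", "epsilon", "chi")),
    edges = data.frame(
      child = c("A", "B", "C", "D", "D", "E", "X", "D"),
      parent = c("R", "R", "A", "C", "B", "B", "R", "X"),
      relation = c("is_a", "is_a", "is_a", "is_a", "part_of", "is_a",
                   "is_a", "regulates"))
  )
}

t6_annotations <- function(records = data.frame(gene = "g1", term = "D",
                                                evidence = "IDA")) {
  annotation_set(records)
}

# A five-concept chain fixture: the only keyword-bearing concept sits
# exactly `levels` parent steps above the seed.
chain_concept_graph <- function(levels = 4L, keyword_alias = "nerve fibre") {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  cuis <- sprintf("CH%04d", seq_len(levels + 1L))
  writeLines(sprintf("%s|%s|%s", cuis[1], "seed concept", cuis[1]),
             file.path(dir, "mapping.psv"))
  writeLines(sprintf("%s|%s|SRC", cuis[-length(cuis)], cuis[-1]),
             file.path(dir, "relations.psv"))
  strings <- c(sprintf("%s|plain alias %d|SRC", cuis[-length(cuis)],
                       seq_len(levels)),
               sprintf("%s|%s|SRC", cuis[length(cuis)], keyword_alias))
  writeLines(strings, file.path(dir, "strings.psv"))
  load_concept_graph(file.path(dir, "mapping.psv"),
                     file.path(dir, "relations.psv"),
                     file.path(dir, "strings.psv"))
}

# Structural equality of two ontologies on the round-trip-preserved
# fields: term inventory, names, namespaces, obsolete flags, synonyms,
# subsets, and the edge multiset.
expect_same_ontology <- function(a, b) {
  ta <- a$terms[order(a$terms$id), ]
  tb <- b$terms[order(b$terms$id), ]
  expect_identical(ta$id, tb$id)
  expect_identical(ta$name, tb$name)
  expect_identical(ta$namespace, tb$namespace)
  expect_identical(ta$obsolete, tb$obsolete)
  expect_identical(lapply(ta$synonyms, sort), lapply(tb$synonyms, sort))
  expect_identical(lapply(ta$subsets, sort), lapply(tb$subsets, sort))
  key <- function(d) sort(sprintf("%s|%s|%s", d$edges$child,
                                  d$edges$parent, d$edges$relation))
  expect_identical(key(a), key(b))
}
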