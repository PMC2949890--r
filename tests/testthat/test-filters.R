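# The relevance-filter cascade.

named_dag <- function(names) {
  ontology_dag(data.frame(id = sprintf("T:%03d", seq_along(names)),
                          name = names))
}

test_that("keyword filter matches case-insensitive substrings in names and synonyms", {
  dag <- ontology_dag(data.frame(
    id = c("T:001", "T:002", "T:003"),
    name = c("neuron migration", "sperm motility",
             "Neuro-Muscular Junction")))
  dec <- keyword_name_filter(dag)
  verdicts <- setNames(dec$verdict, dec$term_id)
  expect_equal(unname(verdicts["T:001"]), "flagged")  # matches 'neuro'
  expect_equal(unname(verdicts["T:002"]), "passed")   # canonical irrelevant
  expect_equal(unname(verdicts["T:003"]), "flagged")  # case-insensitive
  expect_match(dec$evidence[dec$term_id == "T:001"], "neuro")

  # synonym matching is on by default and can be disabled
  syn <- ontology_dag(data.frame(id = "T:001", name = "0001",
                                 synonyms = I(list("brain thing"))))
  expect_equal(keyword_name_filter(syn)$verdict, "flagged")
  expect_equal(keyword_name_filter(syn, fields = "name")$verdict, "passed")
})

test_that("include and exclude decision lists override keyword matching", {
  dag <- named_dag(c("sperm motility", "neuron migration"))
  dec <- keyword_name_filter(dag, include = "T:001", exclude = "T:002")
  expect_equal(dec$verdict, c("flagged", "passed"))
  expect_equal(dec$evidence[1], "include-list")
  # every flagged decision carries non-empty evidence
  expect_true(all(nzchar(dec$evidence[dec$verdict == "flagged"])))
})

test_that("core-gene filter flags terms annotated by at least one marker", {
  dag <- t6_dag()
  anns <- annotation_set(data.frame(
    gene = c("GFAP", "Aqp4", "gfap"),
    term = c("D", "E", "C")))
  dec <- core_gene_filter(dag, anns)
  verdicts <- setNames(dec$verdict, dec$term_id)
  expect_equal(unname(verdicts["D"]), "flagged")
  expect_equal(unname(verdicts["C"]), "flagged")  # symbol match ignores case
  expect_equal(unname(verdicts["E"]), "passed")
  expect_match(dec$evidence[dec$term_id == "D"], "GFAP")

  # empty annotation set: everything passes
  none <- annotation_set(data.frame(gene = character(), term = character()))
  expect_true(all(core_gene_filter(dag, none)$verdict == "passed"))
})

test_that("literature filter consumes decision files or an oracle, and demands one", {
  dag <- t6_dag()
  expect_error(literature_filter(dag), "decision file")

  listed <- withr::local_tempfile(fileext = ".txt")
  writeLines("D", listed)
  dec <- literature_filter(dag, decision_file = listed)
  expect_equal(dec$verdict[dec$term_id == "D"], "flagged")
  expect_equal(sum(dec$verdict == "flagged"), 1L)

  writeLines(character(), listed)
  dec <- literature_filter(dag, decision_file = listed)
  expect_true(all(dec$verdict == "passed"))

  oracle <- function(id) list(verdict = id == "E", evidence = "paper hit")
  dec <- literature_filter(dag, oracle = oracle)
  expect_equal(dec$term_id[dec$verdict == "flagged"], "E")

  boom <- function(id) if (id == "C") stop("search failed") else FALSE
  expect_error(literature_filter(dag, oracle = boom), "term C")
})

test_that("concept-graph filter delegates to termfind with path evidence", {
  fx <- fig4_fixture()
  dag <- ontology_dag(data.frame(
    id = c("GO:0014896", "GO:0099999"),
    name = c("muscle hypertrophy", "unmapped thing")))
  dec <- concept_graph_filter(dag, fx$graph)
  verdicts <- setNames(dec$verdict, dec$term_id)
  expect_equal(unname(verdicts[["GO:0014896"]]), "flagged")
  expect_equal(unname(verdicts[["GO:0099999"]]), "passed")
  expect_match(dec$evidence[dec$term_id == "GO:0014896"], "neuro")
})

test_that("cascade provenance names the first flagging filter only", {
  dag <- named_dag(c("neuron migration", "0002", "0003"))
  anns <- annotation_set(data.frame(gene = "GFAP",
                                    term = c("T:001", "T:002")))
  cascade <- filter_cascade(list(
    name = function(dag, ids) keyword_name_filter(dag, terms = ids),
    core = function(dag, ids) core_gene_filter(dag, anns, terms = ids)))
  res <- run_cascade(dag, cascade)
  # T:001 matched by both filters, but filter 2 never evaluates it
  expect_equal(unname(res$provenance[["T:001"]]), "name")
  expect_equal(unname(res$provenance[["T:002"]]), "core")
  expect_setequal(res$flagged, c("T:001", "T:002"))
  expect_false("T:001" %in%
                 res$decisions$term_id[res$decisions$filter == "core"])
})

test_that("exempt namespaces are flagged wholesale without filtering", {
  dag <- ontology_dag(data.frame(
    id = c("C:1", "C:2", "P:1"),
    name = c("0001", "0002", "neuron migration"),
    namespace = c("cellular_component", "cellular_component",
                  "biological_process")))
  cascade <- filter_cascade(
    list(name = function(dag, ids) keyword_name_filter(dag, terms = ids)),
    exempt_namespaces = "cellular_component")
  res <- run_cascade(dag, cascade)
  expect_setequal(res$flagged, c("C:1", "C:2", "P:1"))
  expect_equal(unname(res$provenance[["C:1"]]), "namespace-exempt")
  expect_equal(unname(res$provenance[["P:1"]]), "name")
})

test_that("the flagged set is order-invariant even though provenance is not", {
  dag <- named_dag(c("neuron migration", "brain 02", "0003", "0004"))
  anns <- annotation_set(data.frame(gene = "IL6", term = c("T:003")))
  f_name <- function(dag, ids) keyword_name_filter(dag, terms = ids)
  f_core <- function(dag, ids) core_gene_filter(dag, anns, terms = ids)
  res_ab <- run_cascade(dag, filter_cascade(list(a = f_name, b = f_core)))
  res_ba <- run_cascade(dag, filter_cascade(list(b = f_core, a = f_name)))
  expect_identical(res_ab$flagged, res_ba$flagged)
})

test_that("empty ontology yields an empty flagged set", {
  dag <- ontology_dag(data.frame(id = character()))
  cascade <- filter_cascade(list(
    name = function(dag, ids) keyword_name_filter(dag, terms = ids)))
  res <- run_cascade(dag, cascade)
  expect_length(res$flagged, 0L)
})

test_that("keyword filter recovers exactly a planted domain branch", {
  for (s in 1:10) {
    spec <- synth_spec(n_terms = 60L, domain_branch_size = 10L, seed = s)
    planted <- plant_domain(gen_ontology(spec), spec)
    dec <- keyword_name_filter(planted$dag, keywords = spec$keywords)
    found <- sort(dec$term_id[dec$verdict == "flagged"])
    expect_identical(found, planted$truth$planted)
  }
})
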