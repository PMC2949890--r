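# ontoclip

Domain-specific subsets of the Gene Ontology (or any OBO-format
ontology) by **clipping**: terms irrelevant to a domain are removed from
*every* hierarchical level, while every ancestor of a relevant term is
retained, so the subset stays a consistent DAG and deep, specific terms
survive. Clipping contrasts with *slimming*, which keeps only high-level
terms and sacrifices exactly the resolution that makes enrichment results
interpretable.

The package is for transcriptomics practitioners who run GO term
enrichment on systems with a clear domain (neural, immune, cardiac, ...)
and want the statistical benefit of a smaller, relevant term universe:
the raw hypergeometric p-value of a term depends only on its own counts,
so restricting the tested set changes nothing but the Benjamini–Hochberg
multiple-testing burden — adjusted p-values of relevant terms improve
without touching the evidence.

## What it provides

* **Graph model and clipping** — `ontology_dag()`, `validate_ontology()`,
  `ancestor_closure()`, `clip_ontology()`, `organism_clip()`. The
  closure follows a configurable `traversal_policy()`: `is_a` parents
  transitively to the root, `part_of` parents one step from flagged
  terms, regulates edges never. Retained terms are partitioned into
  *flagged* (relevant) and *parental* (kept for graph consistency), with
  per-term provenance.
* **Relevance-filter cascade** — `keyword_name_filter()` (case-insensitive
  substring vocabulary, default `immune, neuro, inflam, brain, lymph,
  nerve`, plus expert include/exclude lists), `core_gene_filter()`
  (curated marker genes), `literature_filter()` (pluggable decision
  files/oracles), `concept_graph_filter()`, composed with
  `filter_cascade()` / `run_cascade()`; provenance names the first filter
  that flagged each term, and whole namespaces can be exempted.
* **Concept-graph search** — `termfind()`: map a term to a concept,
  walk up to 3 parent levels, and keyword-scan every alias string
  collected across source vocabularies.
* **Enrichment comparison** — `term_for_term()` (one-sided
  hypergeometric upper tail `P(X >= k)`, `X ~ Hypergeom(N, K, n)`),
  `bh_adjust()`, and `compare_subsets()` for full-vs-clipped reports.
* **I/O** — OBO 1.2 read/write (standalone subsets or `subset:`-tagged
  full ontologies), GAF 2.x, GMT export for external gene-set tools,
  flat term/gene lists.
* **Synthetic data** — seeded generators for random valid ontologies,
  annotations, planted keyword branches and planted-enrichment queries,
  so the whole pipeline is testable offline.
* **CLI** — `exec/ontoclip` with subcommands `validate`,
  `organism-clip`, `filter`, `clip`, `termfind`, `export-gmt`, `enrich`,
  `compare`, `simulate`.

## Worked example

Six terms, two relevance filters, then a clip — followed by enrichment
over the full term set and over the clipped subset:

```r
library(ontoclip)

dag <- ontology_dag(
  terms = data.frame(
    id   = c("T:1", "T:2", "T:3", "T:4", "T:5", "T:6"),
    name = c("root process", "neuron migration", "sperm motility",
             "axon guidance", "cilium assembly", "response to stimulus")),
  edges = data.frame(
    child    = c("T:2", "T:3", "T:4", "T:5", "T:6", "T:4"),
    parent   = c("T:1", "T:1", "T:2", "T:3", "T:1", "T:6"),
    relation = c("is_a", "is_a", "is_a", "is_a", "is_a", "part_of")))

anns <- annotation_set(data.frame(
  gene = c("GFAP", "Dnah5", "Ttll3"),
  term = c("T:4",  "T:5",   "T:5")))

cascade <- filter_cascade(list(
  name = function(dag, ids) keyword_name_filter(dag, terms = ids),
  core = function(dag, ids) core_gene_filter(dag, anns, terms = ids)))
res <- run_cascade(dag, cascade)
clipped <- clip_ontology(dag, res$flagged, provenance = res$provenance)
clipped$result
#> Clip result: 2 flagged + 2 parental = 4 retained; 2 removed
clipped$result$provenance
#>        T:1        T:2        T:4        T:6
#> "parental"     "name"     "core" "parental"
```

"neuron migration" was flagged by the keyword filter, "axon guidance" by
its GFAP annotation; "root process" survives as its `is_a` ancestor and
"response to stimulus" as the one-step `part_of` parent of a flagged
term. "sperm motility" and "cilium assembly" are removed — no relevance,
no relevant descendant.

The statistical payoff, on a 20-gene population with a 5-gene study set
where 4 study genes hit `T:2`:

```r
pop <- sprintf("g%02d", 1:20); study <- pop[1:5]
anns2 <- annotation_set(data.frame(
  gene = c(pop[1:4], pop[6], pop[10:12]),
  term = c(rep("T:2", 5), rep("T:5", 3))))
term_for_term(study, pop, anns2)
#>   term_id  N n K k       raw_p  adjusted_p
#> 1     T:2 20 5 5 4 0.004901961 0.009803922
#> 2     T:5 20 5 3 0 1.000000000 1.000000000
term_for_term(study, pop, anns2, terms = clipped$dag$terms$id)
#>   term_id  N n K k       raw_p  adjusted_p
#> 1     T:2 20 5 5 4 0.004901961 0.004901961
```

The raw p-value of `T:2` (76/15504 ≈ 0.0049) is identical in both runs;
only the adjusted value changes, because the clipped universe no longer
pays a correction penalty for the irrelevant `T:5`.

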