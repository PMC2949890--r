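---
title: "Clipping ontologies: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clipping ontologies: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontoclip)
```

## The problem

Enrichment analysis against a full controlled vocabulary such as the Gene
Ontology tests thousands of terms, most of which are irrelevant to any one
experimental system. Every irrelevant term tested raises the
multiple-testing burden and dilutes the adjusted significance of the terms
that matter: a study of brain aging gains nothing from testing "sperm
motility", but pays for it at correction time. The traditional remedy —
*slimming*, keeping only high-level terms — buys statistical power at the
cost of resolution: a slim cannot contain a term six or seven steps below
the root, which is often exactly the term that makes a result
interpretable.

*Clipping* is the alternative implemented here: remove terms judged
irrelevant to a domain from **every** hierarchical level, but keep any
term that is an ancestor of a relevant term, so that the subset remains a
consistent DAG and deep, specific terms survive. The retained set
therefore splits into *flagged* terms (relevant in their own right) and
*parental* terms (kept only for graph consistency), and the package keeps
that provenance attached to every retained term.

## The graph model and the traversal policy

An ontology is a table of terms (id, name, namespace, obsolete flag,
synonyms, subset labels) plus typed child-to-parent edges carrying one of
five relation kinds: `is_a`, `part_of`, `regulates`,
`positively_regulates`, `negatively_regulates`. The graph restricted to
`is_a` and `part_of` must be acyclic, and each namespace must have an
`is_a` root; `validate_ontology()` checks exactly these invariants plus
dangling endpoints and edges on obsolete terms.

Which relations preserve "relevance" upwards is not obvious, and the three
kinds are treated differently by `ancestor_closure()`, controlled by a
`traversal_policy()`:

* **`is_a` is transitive**: every direct and indirect `is_a` parent of a
  retained term is retained, up to the root. A subclass of a relevant
  process is meaningless without its superclasses.
* **`part_of` is one-step, from flagged terms only**: the direct
  `part_of` parents of a relevant term are pulled in, but the walk does
  not continue transitively through them (beyond their own `is_a`
  ancestors, which condition one then adds). Parthood is a weaker carrier
  of relevance than subsumption, and unbounded `part_of` chains would drag
  in large unrelated regions.
* **The regulates kinds are never followed.** That a relevant process
  regulates something does not make the regulated process relevant.

One genuinely open choice: whether the one-step `part_of` rule should
apply from *every* retained term or only from the originally flagged
terms. We chose flagged-only, the minimal reading — applying it from
parental terms as well would let `part_of` hops chain through the `is_a`
closure and grow without obvious bound. The policy object makes the
alternative a one-line change (`one_step` relations can be promoted to
`transitive`). We also apply the same policy to both clipping stages
(organism-based and relevance-based), since there is no principled reason
for the graph-consistency rule to differ between them.

Obsolete terms never participate: they carry no edges in well-formed
releases, are excluded from closure and clipping, and flagging one is a
warning, not a silent inclusion.

## The two-stage pipeline

**Stage 1 — organism-based clipping** (`organism_clip()`): every term
directly used to annotate a gene in the supplied GAF annotation sets is
flagged, and the ontology is clipped to those terms plus their policy
ancestors. This stage is mechanical and exists mainly to shrink the term
inventory before any judgment-based filtering. Annotation files routinely
reference term ids missing from the ontology release in hand, so unknown
ids are skipped with a warning rather than failing the run.

**Stage 2 — relevance clipping**: a cascade of per-term filters
(`filter_cascade()`, `run_cascade()`) flags relevant terms; a term is
evaluated by filter *k* only if filters 1..k−1 passed on it, so each
flagged term's provenance names the first filter that claimed it. The
flagged set — the *union* of the per-filter flag sets, which is
order-invariant even though provenance is not — then goes through
`clip_ontology()`, which applies the ancestor closure (the "ontological
integrity" step) and produces the final subset plus its
flagged/parental/removed partition.

The four substantive filters:

1. **Term-name keywords** (`keyword_name_filter()`): case-insensitive
   substring match of a keyword vocabulary against names and (by default)
   synonyms. The default vocabulary is the six fragments `immune`,
   `neuro`, `inflam`, `brain`, `lymph`, `nerve`. Substring fragments
   rather than words deliberately catch morphological variants
   ("inflammation", "inflammatory") without stemming machinery. In the
   original workflow this step was an expert reading thousands of names;
   the keyword scan is the automatic approximation, and expert judgment
   re-enters through include/exclude decision lists that override it.
   Whether the original applied the scan to synonyms as well as names is
   unknowable from the outside; both are supported and synonyms default
   to on, since names alone miss common aliases.
2. **Core marker genes** (`core_gene_filter()`): a term annotated by at
   least one gene from a curated marker list is flagged. Defaults are the
   standard neural markers (PCNA through NGFR) and immune markers (STAT1
   through IL4); symbol matching is case-insensitive because human and
   rodent symbol conventions differ in case. The known risk is errors of
   commission through multifunctional genes; this is accepted, since a
   small fraction of falsely included terms costs little power.
3. **Literature relevance** (`literature_filter()`): inherently a
   judgment call on search results, hence not mechanically reproducible.
   The filter consumes a precomputed decision file or a caller-supplied
   oracle function; it refuses to run with neither, and an oracle error
   aborts the cascade naming the term.
4. **Concept-graph search** (`concept_graph_filter()` / `termfind()`):
   described below.

Namespaces can be exempted wholesale (`exempt_namespaces`): every
organism-retained term of an exempt namespace is flagged with provenance
`namespace-exempt` and never filtered. This mirrors the treatment of the
cellular-component branch, where relevance judgments proved impractical
and organism-based clipping alone is applied.

## The concept-graph search

`termfind()` implements a federated keyword search over a concept graph:
concepts with alias strings from multiple source vocabularies, linked by
parent edges. The input term is mapped to a concept (external id first,
then case-insensitive name), the walk collects every concept within
`max_up` parent steps (default 3), and every alias string of every
collected concept is scanned for each keyword as a case-insensitive
substring. The value of the search is that it can connect a term to a
domain through knowledge not encoded in the ontology itself — a term like
"muscle hypertrophy" carries no neural keyword, but a concept two parent
steps above it does.

Numerical/semantic choices: "levels up" counts edges, not source
vocabularies; traversal is breadth-first with a visited set, so the depth
recorded for a concept is the *shortest* upward distance and cyclic
inputs terminate; an unmapped term is a negative result with reason
`unmapped`, not an error, because bulk filtering must tolerate sparse
mappings; matching applies no tokenization, consistent with fragment
keywords. The three pipe-delimited input files are assumed pre-filtered
to hierarchical relations — the loader deliberately does not interpret
relation-type codes, keeping the dialect minimal and the semantics
explicit in the file preparation.

## Enrichment and why clipping helps

`term_for_term()` tests each term by the one-sided hypergeometric upper
tail: with population size $N$, study size $n$, $K$ population genes
annotated to the term and $k$ of them in the study,

$$p = P(X \ge k), \qquad X \sim \mathrm{Hypergeom}(N, K, n),$$

computed by `stats::phyper`. Benjamini–Hochberg adjustment
(`bh_adjust()`, a validating wrapper over `stats::p.adjust`) runs over
exactly the terms included in the table. Terms with $K = 0$ are
untestable and are dropped *before* correction, with a message, because
they would otherwise inflate $m$ and distort every adjusted value.

The mechanism that motivates the whole package is visible in the
arithmetic: the raw $p$ of a term depends only on $(N, K, n, k)$, so it is
identical whether the term is tested among all terms or within a clipped
subset. Only the BH multiplier changes. Clipping therefore never changes
evidence, only correction — and shrinking the tested set from the full
ontology to a domain subset systematically relaxes the adjusted values of
the surviving terms. The converse also happens occasionally: removing
terms shifts the p-value distribution, and a term can receive a *worse*
adjusted value under the subset; `compare_subsets()` reports both
directions rather than assuming improvement.

By default annotations are **not** propagated to ancestors
(`propagate = FALSE`), matching association files whose gene–term mapping
is kept verbatim from the annotation database; `propagate = TRUE` applies
the true-path rule (transitively over `is_a` and `part_of`) for
conventional ontology-aware analyses. Output rows sort by raw $p$, ties
broken by term id, so results are deterministic.

`compare_subsets()` takes labelled enrichment tables over the same query
(it refuses mixed queries) and reports, per pair: terms passing the
cutoff in only one subset, shared passers, and — among shared passers —
how many attain the strictly lower adjusted value on each side. The
cutoff can apply to adjusted or raw p-values, since published comparisons
mix both conventions, and it is a required user input: no universal
threshold is defensible across datasets. When a subset's clip result is
supplied, its unique hits are split into flagged vs parental, because a
hit on a term kept only for graph consistency is interpreted differently
from a hit on a term deemed relevant.

## Synthetic data: what it emulates and what it does not

The generators exist so every stage is testable without downloads, with
exact expected answers where possible.

* `gen_ontology()` builds terms in topological rank order with edges only
  from later to earlier terms, so acyclicity holds by construction; each
  namespace gets one root and every live term one guaranteed `is_a`
  parent, so validity holds by construction too. Defaults (150 terms,
  mean 1.5 parents, 15% `part_of` and 10% regulates among extra edges,
  2% obsolete) give small multi-parent DAGs with all relation kinds
  exercised.
* `plant_domain()` rewrites the names of a rooted sub-branch to embed
  keywords, while background names and synonyms use digits only — an
  alphabet disjoint from any keyword — so the keyword filter's correct
  answer is exactly the planted branch, and recovery tests can demand
  precision = recall = 1 rather than a vague threshold.
* `gen_study()` samples a study set with weight θ (default 8) on the
  genes of a planted term and 1 elsewhere; θ = 1 is the null, under which
  the planted term's discrete raw p-values are stochastically no smaller
  than uniform (checked by simulation in the tests).
* `fig4_fixture()` is the worked concept-graph example: a seed concept
  "muscle hypertrophy" with no keyword of its own and a keyword-bearing
  ancestor two parent steps up, asserted across two source vocabularies.

What the synthetic data does **not** emulate: the depth and branching
statistics of real ontology releases, realistic annotation sparsity and
evidence-code mixtures, correlated gene sets, or expression data (the
generators produce gene lists, not matrices). Passing tests therefore
demonstrate algorithmic correctness — closure semantics, cascade
semantics, format round-trips, count bookkeeping, the BH mechanism — not
biological performance on real data, which inherently depends on expert
judgment inputs the package treats as data.

Determinism: a single integer seed in `synth_spec()` drives every
generator through separate derived substreams, so regenerating one
artifact never perturbs another, and every test and script run is
reproducible bit for bit.

## Problem sizes and numerical notes

The property suites run at sizes chosen to exercise structure while
keeping the whole suite fast on one core: 200 random DAGs up to 100 nodes
for closure-vs-oracle equivalence, 100 random ontology/flag pairs for the
clip invariants, 50 ontologies for serialization round-trips and planted
recovery, 100 random concept graphs up to 50 nodes for search-vs-oracle
equivalence, and 200 replicates of 40-term p-value vectors for the
subset-sensitivity simulation. The independent oracles deliberately use
different machinery from the implementation (boolean matrix closure,
recursive path enumeration, binomial-coefficient sums).

Degenerate inputs are all defined rather than left to chance: empty seed
sets close to the empty set; clipping with an empty flagged set yields an
empty ontology with everything removed; an empty *list* of annotation
sets is an error (a misconfiguration) while annotation sets that are
merely empty are data; an empty decision file passes everything; a GMT
row is never emitted for a term with zero genes. Set-valued outputs are
always returned sorted, so downstream files are byte-stable.

## Limitations

Filters 1 and 3 approximate judgment-based steps; the package can rerun a
published judgment (via decision lists) or a keyword approximation of it,
but cannot reproduce the judgment itself. OBO 1.2 flat files are the only
ontology dialect (no OWL, no OBO 1.4 logical definitions), GPAD/GPI are
not read, and the concept-graph dialect is a minimal stand-in rather than
the full Rich Release Format of a real metathesaurus. Enrichment is
term-for-term only — no parent–child or topology-weighted variants, and
no permutation-based gene-set testing; for the latter, export the clipped
subset with `write_gmt()` and run the external tool of choice.
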