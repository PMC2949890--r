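Package: ontoclip
Title: Domain-Specific Subsets of the Gene Ontology by Clipping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds domain-specific subsets of the Gene Ontology (or any
    OBO-format ontology) by "clipping": terms judged irrelevant to a domain
    are removed from every hierarchical level, while ancestors of relevant
    terms are retained so the subset stays a consistent DAG. Provides
    relation-aware ancestor closure (transitive is_a, single-step part_of,
    regulates edges never traversed), organism-based clipping driven by GAF
    annotation files, a five-step relevance-filter cascade (term-name
    keywords, core marker genes, pluggable literature decisions, and a
    bounded upward search over a concept graph of controlled-vocabulary
    aliases), OBO/GAF/GMT/term-list readers and writers with subset
    tagging, term-for-term over-representation analysis with
    Benjamini-Hochberg correction, comparison reports between full and
    clipped subsets, synthetic-data generators for end-to-end testing, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
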