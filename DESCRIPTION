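Package: phenopair
Title: Paired-Source Comparison of Human Phenotype Ontology Term Sets
Version: 0.1.0
Authors@R:
    person("phenopair", "developers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Compares parent-reported and clinician-reported Human Phenotype
    Ontology (HPO) term sets on a per-participant basis. Provides an OBO
    flat-file parser with ancestor/descendant queries and information
    content, Lin semantic similarity with best-match-average set
    combination, per-participant quantity and ancestor-distance detail
    scores, McNemar paired tests with Benjamini-Hochberg adjustment, Welch
    one-way ANOVA with Holm-adjusted pairwise follow-ups, descendant-closure
    phenotype queries, gene-to-phenotype reference comparison, and a
    seeded synthetic cohort generator over a bundled mini-ontology.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
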