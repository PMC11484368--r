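Package: ontorag
Title: Retrieval-Augmented Completion and Evaluation of Ontology Terms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for completing partially specified biomedical ontology
    terms with retrieval-augmented generation (RAG). Loads ontologies from
    OBO Graph JSON, translates numeric identifiers to camel-case symbols,
    embeds and indexes term objects and GitHub issue records in a vector
    store, assembles few-shot prompts from maximal-marginal-relevance
    re-ranked neighbours, and parses and post-filters the reply of a
    pluggable text-generation backend. Includes an evaluation framework
    with information-content partial credit for predicted relationships, a
    structural subsumption-entailment baseline, greedy token-matching
    definition similarity, one-way ANOVA intraclass correlation for rating
    sheets, and confidence-gap analysis, plus seeded synthetic-ontology and
    issue-tracker generators and a deterministic mock generation backend so
    the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'symbols.R'
    'ontology.R'
    'term-object.R'
    'split.R'
    'embedding.R'
    'index.R'
    'generation.R'
    'completion.R'
    'ic.R'
    'score-relationships.R'
    'entailment.R'
    'definition-similarity.R'
    'icc.R'
    'fixtures.R'
    'ratings.R'
    'run-evaluation.R'
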