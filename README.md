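# ontorag

Retrieval-augmented completion of biomedical ontology terms, with an
offline evaluation framework.

## The problem

Ontology development is slow, expert work: every new class in an OBO-style
ontology (Cell Ontology, GO, Uberon, HP, ...) needs a label, a textual
definition, typed relationships to existing terms, and often a
genus–differentia logical definition. `ontorag` assists a curator by
completing a *partial* term — say, just a label — from the ontology's own
content:

1. every existing term is translated into a JSON **term object** whose
   identifiers are camel-case symbols derived from labels
   (`CL:1001502` → `MitralCell`), because numeric CURIEs are easy for
   language models to hallucinate;
2. term objects (and, optionally, GitHub issue records) are embedded and
   held in a vector index;
3. the nearest neighbours of the partial term are re-ranked by **maximal
   marginal relevance** (MMR), `argmax_d λ·cos(d,q) − (1−λ)·max_s cos(d,s)`,
   and rendered as few-shot input/output pairs in a prompt that fits the
   generation backend's token budget;
4. the backend's reply is parsed (tolerating prose preambles and code
   fences) and post-filtered: any relationship whose predicate or target
   does not resolve in the symbol table is dropped.

The generation and embedding backends are contracts, not services: the
package ships a seeded hashing embedder and deterministic mock/echo
generation backends, so the entire pipeline — including its evaluation —
runs offline and bit-reproducibly. Adapters for hosted models can
implement the same two generics (`embedText`, `generateReply`).

## The evaluation framework

For a dated ontology, `splitByDate()` holds out the newest terms (a
leakage control), `runEvaluation()` masks the field under study and
scores completions against the ontology's own content:

* **Relationships** are scored CAFA-style with information-content
  partial credit. For term *t*, `IC(t) = −log₂ P(t)` with `P(t)` the
  fraction of terms subsuming-closure-below *t* (reflexive). An exact
  predicted edge earns credit 1; an edge more general than a gold edge —
  target reachable over is-a plus the same predicate — earns
  `IC(predicted)/IC(expected)`; anything else is a false positive.
* **A reasoner-recovery baseline**: each asserted `SubClassOf` edge is
  removed and re-predicted iff still entailed by the remaining transitive
  closure or by the term's logical-definition genus. Its precision is 1.0
  by construction; its recall measures the ontology's redundancy.
* **Definitions** are scored by greedy token-matching
  precision/recall/F1 over a pluggable token-embedding backend, and by
  rating sheets: inter-rater reliability via the one-way ANOVA intraclass
  correlation `ICC = (MSB − MSE)/(MSB + (k−1)·MSE)`, plus the Pearson
  correlation between evaluator confidence and the human-vs-model score
  gap.

Seeded generators (`generateOntology`, `generateIssues`,
`generateRatings`) produce synthetic test ontologies with compositional
labels, redundant entailed edges, logical definitions, creation dates,
and issue texts, so every scoring path is exercised against known ground
truth.

## Worked example

```r
library(ontorag)
graph <- loadOntology(system.file("extdata", "mitral-mini.json", package = "ontorag"))
table <- buildSymbolTable(graph)

obj <- termToObject(graph, "CL:1001502", table)
obj
#> TermObject MitralCell
#>   label: mitral cell
#>   definition: The large glutaminergic nerve cells whose dendrites synapse  ...
#>   relationships: 2

partial <- maskTerm(obj, "relationships")   # hide the field to predict
index <- buildTermIndex(
  lapply(setdiff(ontologyTerms(graph)$curie, "CL:1001502"),
         termToObject, graph = graph, table = table),
  hashingEmbedding(128, 1))

reply <- '{"relationships": [
  {"predicate": "SubClassOf", "target": "Interneuron"},
  {"predicate": "PartOf",     "target": "OlfactoryGlomerulus"}]}'
res <- completeTerm(partial, index, table,
                    mockBackend(list(`mitral cell` = reply)))
termRelationships(completedTerm(res))
#>    predicate      target
#> 1 SubClassOf Interneuron
droppedRelationships(res)
#>   predicate              target
#> 1    PartOf OlfactoryGlomerulus
```

The mock "model" proposed two relationships; `OlfactoryGlomerulus` does
not exist in this mini ontology, so post-filtering dropped it — kept
output only ever references real terms.

Evaluation on a synthetic ontology, with the gold-echo backend as the
scoring ceiling and the reasoner-recovery baseline beside it:

```r
runEvaluation(evaluationConfig(
  fixture = fixtureSpec(nTerms = 120, redundancyRate = 0.3, seed = 7),
  task = "relationships", backend = "echo", nTest = 20, seed = 1))$summary
#> ScoreSummary: P=1.0000 R=1.0000 F1=1.0000 (n_pred=39, n_gold=39)

reasonerBaseline(generateOntology(
  fixtureSpec(nTerms = 120, redundancyRate = 0.3, seed = 7)))
#> ScoreSummary: P=1.0000 R=0.5034 F1=0.6696 (n_pred=75, n_gold=149)
```

The echo backend recovers every masked relationship (an upper bound any
real backend is measured against); the entailment baseline re-derives
half of the asserted subsumptions — exactly the redundant ones — at
precision 1.

A thin command-line wrapper is installed as `exec/ontorag`
(subcommands `fixtures`, `split`, `index`, `complete`, `evaluate`).

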