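---
title: "Retrieval-augmented ontology term completion: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retrieval-augmented ontology term completion: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontorag)
```

## The completion model

`ontorag` treats ontology term construction as a constrained
text-completion problem. One ontology class is represented as a JSON
*term object*: a symbolized `id`, the `label`, an optional textual
`definition`, a list of `(predicate, target)` `relationships`, and an
optional genus–differentia `logical_definitions` list whose single
`SubClassOf` entry is the genus. A *partial term* is the same object
with some fields absent and a declared `fieldsToComplete`.

Two assumptions shape the design:

* **Symbols, not CURIEs.** Generation backends see and emit camel-case
  symbols derived from labels (`MitralCell`), never numeric identifiers,
  because numeric identifiers invite hallucination. The `SymbolTable`
  keeps the label–CURIE bijection; collisions between distinct terms
  whose labels camel-case identically are resolved by numeric suffixes
  in load order (`BetaCell`, `BetaCell2`, ...), which is deterministic
  and reversible. `SubClassOf` is reserved for the is-a predicate and is
  never assigned to a term; a symbol that would start with a digit is
  prefixed with `X` so every symbol is a valid identifier.
* **Closed-world relationship targets.** A completion may only reference
  terms that already exist. Post-processing removes any relationship
  whose predicate or target fails to resolve, recording it in
  `droppedRelationships` — a deliberate conservative stance; creating
  referenced-but-missing terms is out of scope.

### Retrieval

Term objects are serialized to key-value text (fixed field order: label,
definition, relationships) and embedded. Retrieval is exact cosine
k-nearest-neighbour search; at the corpus sizes this package targets,
exact search is behaviourally identical to the approximate
(HNSW-style) search a large deployment would use, and the contract is
on the ordering, not the algorithm. Results are re-ranked by maximal
marginal relevance: the first pick maximizes query similarity, each
later pick maximizes $\lambda\,\cos(d, q) - (1-\lambda)\max_{s}\cos(d, s)$
over already-selected $s$, ties broken by original rank.

Tunable parameters, with defaults and rationale:

| parameter | default | meaning |
|---|---|---|
| `k` | 10 | in-context examples requested |
| `lambda` | 0.5 | MMR relevance–diversity trade-off; 1 = pure relevance. No canonical value exists; 0.5 weights both terms equally and is configurable. |
| `poolSize` | `4 * k` | candidate pool before MMR. MMR can only diversify within the pool; four times the final count keeps the pool cheap while giving the re-ranker room. |
| `dimension` | 256 | hashing-embedding width; collisions fall off with width, 256 keeps index matrices small |
| `nIssues` | 3 | issue snippets appended to the prompt |
| `snippetCap` | 2000 chars | per-snippet truncation before budgeting |
| `maxRetries` | 2 | verbatim re-prompts after a parse failure |
| `tokenInflation` | 1.3 | whitespace-token count × 1.3 approximates subword token counts; exact tokenizers are backend concerns, and the budget contract must be backend-agnostic |

### Prompt assembly and budget

Each retrieved example is rendered as an input/output JSON pair: the
input carries exactly the fields present in the partial term, the output
exactly the fields to complete, so the example format mirrors the
requested transformation. Examples are dropped from the tail (least
relevant first) until the rendered prompt fits the backend's token
budget — but never below the user-requested floor `minExamples`. The
floor is honoured even when it forces an overflow, with a warning and
the payload's `overflow` flag set: the two stopping rules ("fits the
budget" and "at least the requested count") genuinely conflict, and we
resolve the conflict in favour of the explicit user request while making
the violation observable. With a floor of 0 the budget is a hard
invariant, and a budget too small for even a zero-example prompt is an
error.

### Reply parsing

Replies are scanned for the first balanced `{...}` region (string
literals and escapes respected), which tolerates prose preambles,
markdown fences, and trailing chatter; the region must parse as JSON.
Recognized keys (`definition`, `relationships`, `logical_definitions`)
are matched case-insensitively because generation backends are
inconsistent about capitalization; unrecognized keys warn and are
ignored. Parsed fields fill only `fieldsToComplete` — input fields always
win on conflict. After symbol filtering, a logical definition left
without exactly one genus is discarded entirely rather than kept
malformed.

## Scoring predicted relationships

The asserted relationships of the evaluated term are the gold standard —
a choice that penalizes alternative-but-valid modelling, which is the
accepted price for an automatic benchmark. Information content uses the
reflexive subsumption closure: $P(t)$ is the fraction of terms having
$t$ among their reflexive is-a ancestors and $IC(t) = -\log_2 P(t)$
(bits; the base is configurable and cancels in credit ratios). The
reflexive convention keeps leaf IC finite. IC is antitone along
subsumption, which the test suite asserts on random DAGs.

A predicted edge that exactly matches gold earns credit 1. Otherwise,
if its target is reachable from the subject over is-a plus
same-predicate edges, it is *more general*; it is paired with the
most informative (highest-IC) unconsumed same-predicate gold edge whose
target lies below the predicted target, and earns
$IC_{p}/IC_{e}$ — the broader prediction captures that fraction of the
expected bits, and $1 - IC_p/IC_e$ remains as the false-negative
fraction on the paired gold edge. Each gold edge pairs at most once.
Pairing requires predicate equality: a prediction that is "more general"
only through another predicate's gold edge is counted as a false
positive, since credit across predicates has no IC interpretation.
Precision is summed credit over predictions, recall summed credit over
gold, micro-averaged across the test set; an empty prediction set has
undefined precision and is reported as zero with a flag.

### The reasoner-recovery baseline

For each asserted `SubClassOf` edge, remove it and ask whether it is
re-derivable. Two structural rules suffice for this baseline: the
transitive closure of the remaining asserted subsumptions, and the
genus of the subject's logical definition (an axiom `X ≡ G ⊓ ...`
entails `X ⊑ G`). Every prediction is by construction an asserted
edge, so precision is identically 1 — the quantity
`scripts/acceptance.R` recomputes — and recall measures how much of the
hierarchy is redundant. This is a deliberately minimal structural
entailment engine, not a description-logic reasoner: existential
restrictions, property chains and equivalence reasoning beyond the
genus rule are out of scope, so its recall is a lower bound on what a
full reasoner would recover.

## Scoring definitions and ratings

Definition similarity is greedy token matching over a pluggable
token-embedding backend: recall is the mean over reference tokens of
the best cosine against candidate tokens, precision the symmetric
quantity, F1 their harmonic mean. The default backend is one-hot
(tokens match only when equal), which makes scores exactly computable
and the P/R swap symmetry testable; a contextual-embedding adapter can
implement the same `tokenSimilarity` generic when nuance matters more
than reproducibility.

Rating sheets hold 1–5 ordinal scores (`accuracy`, optional
`consistency`, `score`) with optional 1–5 confidence. Inter-rater
reliability is the one-way ANOVA intraclass correlation with evaluator
as the random grouping factor,
$ICC = (MSB - MSE)/(MSB + (k-1)\,MSE)$; for unbalanced designs $k$ is
the mean group size, the standard moment correction. Ratings can be
pre-filtered by minimum confidence. Degenerate inputs raise typed
errors rather than returning numbers: fewer than two evaluators with
two ratings each (`insufficientData`), or zero variance both between
and within (`degenerateVariance`); when only `MSE` is zero the ICC is
exactly 1. The confidence-gap analysis computes, per confidence level,
the mean human score minus the mean model score, and the Pearson
correlation of gap against level; fewer than three populated levels is
an error, and zero-variance gaps return a flagged `NA` rather than a
spurious coefficient.

## What the synthetic generator emulates — and what it does not

`generateOntology()` builds a rooted DAG with: compositional labels
from a fixed word bank (a child's label contains its parent's, so
lexical overlap tracks taxonomic proximity and the hashing embedder
retrieves meaningfully); templated definitions mentioning the parent
label; cross-predicate edges to earlier terms; redundant entailed
subclass edges (term → grandparent) at a configurable rate; logical
definitions with genus = parent; and creation dates drawn uniformly
over a range but assigned in creation order, so newer terms never
predate their parents and a date split never orphans a test term's
targets. The root has a single child spine term so every term below
depth 1 has a grandparent available to anchor a redundant edge (the
spine term itself cannot carry one). Default rates (branching 3, depth
4, cross-edge 0.6, redundancy 0.2, logical definitions 0.3, dates over
2021–2023) give graphs whose edge density and redundancy are in the
range of curated OBO-style taxonomies.

The generator deliberately does *not* emulate: real biological
vocabulary or its synonym structure; polysemy and non-compositional
labels; multiple inheritance styles that differ across ontologies;
nested (non genus–differentia) logical definitions; or semantic
similarity beyond lexical overlap. Passing tests therefore demonstrate
the pipeline's mechanics — retrieval ordering, budget trimming,
filtering, scoring arithmetic, determinism — not that any particular
language model writes good ontology terms. The deterministic mock and
gold-echo backends bound what evaluation can show: the echo ceiling
(perfect scores when the backend echoes the ontology) validates the
scoring path end to end, and no configuration can exceed it.

In evaluation runs the gold standard for a test term is restricted to
relationship targets that survive in the core ontology: an edge
pointing at a term that is itself held out cannot be expressed against
the core vocabulary, so counting it against recall would penalize every
backend for an unreachable answer. With the date-monotone generator
this restriction is vacuous (targets are always older than test terms);
on real ontologies it matters.

## Numerical and procedural choices

* Ties in retrieval are broken by indexing order; in MMR by original
  rank; in the date split by CURIE lexical order — all total orders, so
  every pipeline stage is deterministic.
* The hashing embedder uses a seeded polynomial rolling hash modulo a
  prime below $2^{26}$, keeping all arithmetic exact in doubles and
  identical across platforms; it never touches R's RNG state.
* Generators take explicit seeds, set the RNG locally, and restore the
  caller's state; fixture problem sizes in the tests (30–200 terms,
  10–50 test terms, 200 random DAGs for the scoring oracle) were chosen
  as the smallest scales at which every code path — redundancy,
  logical definitions, budget trimming, partial credit — is exercised.
* Terms without creation dates are never eligible for the test set
  (conservative leakage control); obsolete or unlabeled classes are
  skipped at load with a warning, since they cannot be symbolized.
* The JSON emitted by reports uses a fixed serializer configuration, so
  identical runs produce byte-identical files — asserted in the tests.

## Limitations

* The structural entailment engine understates what OWL reasoning
  recovers (see above); its precision claim, however, is exact.
* The general-match pairing rule (highest-IC same-predicate gold edge,
  single use) is one defensible reading of IC partial credit; other
  pairings (e.g. best-credit assignment via matching) would change
  third decimals on dense gold sets.
* Whitespace-based token budgeting is approximate; backends with tight
  budgets should supply their own counts.
* The issue-ingestion path expects the standard issues-API JSON export;
  live crawling, authentication and rate limiting are out of scope.
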