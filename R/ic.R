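## Subsumption machinery shared by IC scoring and the entailment baseline.

## igraph over the SubClassOf edges only, child -> parent, including
## isolated terms as vertices.
.subclassGraph <- function(graph, edges = NULL) {
  ed <- edges %||% graph@edges
  isa <- ed[ed$predicate == "SubClassOf", c("subject", "object"), drop = FALSE]
  igraph::graph_from_data_frame(isa, directed = TRUE,
                                vertices = data.frame(name = graph@terms$curie))
}

## Reflexive-transitive SubClassOf ancestors of one term.
.subsumers <- function(g, curie) {
  names(igraph::subcomponent(g, curie, mode = "out"))
}

## Named vector: for each term, how many terms it subsumes (reflexively).
.subsumeeCounts <- function(graph) {
  g <- .subclassGraph(graph)
  counts <- stats::setNames(integer(nrow(graph@terms)), graph@terms$curie)
  for (curie in graph@terms$curie) {
    anc <- .subsumers(g, curie)
    counts[anc] <- counts[anc] + 1L
  }
  counts
}

#' Information content of ontology terms
#'
#' The information content of a term `t` is `-log(P(t))`, where `P(t)`
#' is the probability that `t` subsumes a term drawn uniformly from the
#' ontology -- the fraction of terms having `t` among their
#' reflexive-transitive SubClassOf ancestors. A root that subsumes every
#' term carries 0 bits; deeper, more specific terms carry more.
#' Subsumption is reflexive (every term subsumes itself), which keeps
#' leaf IC finite.
#'
#' @param graph an [OntologyGraph()].
#' @param term CURIE (or vector of CURIEs).
#' @param logBase 2 for bits (default) or `exp(1)` for nats.
#' @return numeric vector of IC values, named by CURIE.
#' @export
informationContent <- function(graph, term, logBase = 2) {
  unknown <- setdiff(term, graph@terms$curie)
  if (length(unknown))
    .ontoragError(paste("unknown term(s):", paste(unknown, collapse = ", ")),
                  "unknownTerm")
  counts <- .subsumeeCounts(graph)
  p <- counts[term] / nrow(graph@terms)
  -log(p) / log(logBase)
}

#' Is a predicted relationship more general than an asserted one?
#'
#' A relationship `(s, p, o)` counts as more general when the target `o`
#' is traversable from the subject `s` over any combination of is-a
#' (SubClassOf) edges and `p` edges.
#'
#' @param graph an [OntologyGraph()].
#' @param subject,predictedTarget term CURIEs.
#' @param predicate the relationship type (`"SubClassOf"` or a CURIE).
#' @return `TRUE` or `FALSE`.
#' @export
isMoreGeneral <- function(graph, subject, predicate, predictedTarget) {
  for (t in c(subject, predictedTarget)) {
    if (!(t %in% graph@terms$curie))
      .ontoragError(paste("unknown term:", t), "unknownTerm")
  }
  .reachableOver(graph, subject, predictedTarget,
                 c("SubClassOf", predicate))
}

## Reachability from `from` to `to` over edges whose predicate is in preds.
.reachableOver <- function(graph, from, to, preds) {
  ed <- graph@edges
  ed <- ed[ed$predicate %in% preds, c("subject", "object"), drop = FALSE]
  g <- igraph::graph_from_data_frame(ed, directed = TRUE,
                                     vertices = data.frame(name = graph@terms$curie))
  to %in% names(igraph::subcomponent(g, from, mode = "out"))
}
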