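#' Structural re-entailment of an asserted subsumption
#'
#' Removes the asserted edge `subject SubClassOf object` and asks whether
#' the subsumption is still derivable, using two structural rules
#' sufficient for the recapitulation baseline: (a) the transitive
#' closure of the remaining asserted SubClassOf edges, and (b) the genus
#' `g` of the subject's genus--differentia logical definition, with
#' `g = object` or `g SubClassOf* object` in that closure.
#'
#' @param graph an [OntologyGraph()].
#' @param subject,object CURIEs of an asserted SubClassOf edge.
#' @return `TRUE` if the edge is recapitulated after removal.
#' @export
entailSubsumption <- function(graph, subject, object) {
  ed <- graph@edges
  hit <- ed$predicate == "SubClassOf" & ed$subject == subject &
    ed$object == object
  if (!any(hit))
    .ontoragError(paste("edge not asserted:", subject, "SubClassOf", object),
                  "edgeNotAsserted")
  remaining <- ed[!hit, , drop = FALSE]
  g <- .subclassGraph(graph, edges = remaining)
  anc <- .subsumers(g, subject)
  if (object %in% setdiff(anc, subject)) return(TRUE)
  axiom <- graph@logicalDefinitions[[subject]]
  if (!is.null(axiom)) {
    genus <- axiom$genus
    if (identical(genus, object)) return(TRUE)
    if (object %in% .subsumers(g, genus)) return(TRUE)
  }
  FALSE
}

#' Reasoner-recovery baseline for subsumption prediction
#'
#' For every asserted SubClassOf edge of every test term, the edge is
#' removed and predicted if and only if it is re-entailed (see
#' [entailSubsumption()]). Scored against the asserted edges, every
#' prediction is itself an asserted edge, so precision is 1 by
#' construction; recall measures how much of the asserted hierarchy the
#' ontology's redundancy and logical definitions can recover.
#'
#' @param graph an [OntologyGraph()].
#' @param testTerms CURIEs whose subsumptions are evaluated; defaults to
#'   every term with at least one asserted SubClassOf edge.
#' @return a `ScoreSummary` (plus per-edge detail in attribute
#'   `judgements`).
#' @export
reasonerBaseline <- function(graph, testTerms = NULL) {
  isa <- graph@edges[graph@edges$predicate == "SubClassOf", , drop = FALSE]
  if (is.null(testTerms)) testTerms <- unique(isa$subject)
  unknown <- setdiff(testTerms, graph@terms$curie)
  if (length(unknown))
    .ontoragError(paste("unknown term(s):", paste(unknown, collapse = ", ")),
                  "unknownTerm")
  isa <- isa[isa$subject %in% testTerms, , drop = FALSE]
  entailed <- vapply(seq_len(nrow(isa)), function(i) {
    entailSubsumption(graph, isa$subject[[i]], isa$object[[i]])
  }, logical(1))
  predicted <- isa[entailed, , drop = FALSE]
  judgements <- data.frame(
    subject = predicted$subject, predicate = predicted$predicate,
    target = predicted$object, category = rep("exact", nrow(predicted)),
    credit = rep(1, nrow(predicted)), stringsAsFactors = FALSE)
  summary <- aggregatePRF(judgements, nGold = nrow(isa))
  attr(summary, "judgements") <- judgements
  summary
}
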