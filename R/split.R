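#' Split an ontology into a core graph and a dated test set
#'
#' Terms created after `cutoff` are eligible; the `n` most recent of them
#' (ties broken by CURIE lexical order) become the held-out test set, and
#' the core graph is the ontology minus the test terms, their incident
#' edges, and any logical definition that mentions them. Terms without a
#' creation date are never eligible -- a conservative guard against test
#' leakage. If fewer than `n` terms are eligible, all of them are taken
#' and a warning is issued.
#'
#' @param graph an [OntologyGraph()].
#' @param cutoff a `Date` (or ISO date string); eligibility is
#'   `creationDate > cutoff`.
#' @param n requested test-set size.
#' @param seed accepted for interface symmetry with the generators; the
#'   split itself is deterministic.
#' @return `list(core = OntologyGraph, test = character vector of CURIEs)`.
#' @export
splitByDate <- function(graph, cutoff, n = 50L, seed = NULL) {
  if (n < 1L) .ontoragError("n must be >= 1", "invalidSpec")
  cutoff <- as.Date(cutoff)
  tm <- graph@terms
  dates <- suppressWarnings(as.Date(tm$creationDate))
  eligible <- which(!is.na(dates) & dates > cutoff)
  if (!length(eligible))
    .ontoragError("no terms dated after the cutoff", "noEligibleTerms")
  ord <- eligible[order(dates[eligible], tm$curie[eligible],
                        decreasing = c(TRUE, FALSE), method = "radix")]
  if (length(ord) < n) {
    warning("only ", length(ord), " terms dated after cutoff; test set ",
            "smaller than requested n = ", n, call. = FALSE)
    test <- tm$curie[ord]
  } else {
    test <- tm$curie[ord[seq_len(n)]]
  }
  core <- .dropTerms(graph, test)
  list(core = core, test = test)
}

## Remove terms plus incident edges and any logical definition touching them.
.dropTerms <- function(graph, curies) {
  tm <- graph@terms[!(graph@terms$curie %in% curies), , drop = FALSE]
  ed <- graph@edges
  ed <- ed[!(ed$subject %in% curies) & !(ed$object %in% curies), , drop = FALSE]
  ld <- graph@logicalDefinitions
  ld <- ld[!(names(ld) %in% curies)]
  touches <- vapply(ld, function(ax)
    ax$genus %in% curies || any(ax$differentia$target %in% curies), logical(1))
  if (length(ld)) ld <- ld[!touches]
  OntologyGraph(tm, ed, ld, graph@predicateLabels)
}
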