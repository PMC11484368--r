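#' Score predicted relationships with information-content partial credit
#'
#' The asserted relationships of the subject term are the gold standard.
#' A predicted `(predicate, target)` pair that string-matches a gold pair
#' is an exact true positive (credit 1). A prediction that is more
#' general than a gold relationship of the same predicate -- its target
#' reachable from the gold target over is-a plus same-predicate edges --
#' earns partial credit `ICp / ICe`: the information content of the
#' broader predicted target over that of the narrower expected target
#' (the complementary `1 - ICp/ICe` is the false-negative fraction left
#' on the gold edge). Among eligible gold edges the most informative
#' (highest-IC) target is paired, and each gold edge is pairable at most
#' once. Everything else is a false positive (credit 0).
#'
#' @param graph the reference [OntologyGraph()] (closure and IC are
#'   computed on it).
#' @param subject the CURIE of the term whose relationships are scored.
#' @param predicted data.frame with `predicate`, `target` columns, in
#'   CURIE space (is-a as `"SubClassOf"`); assumed already post-filtered
#'   to known terms.
#' @param gold gold relationships in the same shape; defaults to the
#'   subject's asserted outgoing edges.
#' @param taskFilter `"all"` or `"subclass_only"` (keep only is-a rows
#'   of both sets before scoring).
#' @param logBase base for information content (default 2, bits).
#' @return data.frame with one row per prediction: `predicate`, `target`,
#'   `category` (exact / general / false_positive), `matchedGoldTarget`,
#'   `credit`; the gold size used is attached as attribute `nGold`.
#' @export
scoreRelationships <- function(graph, subject, predicted, gold = NULL,
                               taskFilter = c("all", "subclass_only"),
                               logBase = 2) {
  taskFilter <- match.arg(taskFilter)
  if (is.null(gold)) {
    out <- graph@edges[graph@edges$subject == subject, , drop = FALSE]
    gold <- .relFrame(out$predicate, out$object)
  }
  predicted <- .relFrame(predicted$predicate, predicted$target)
  if (taskFilter == "subclass_only") {
    predicted <- predicted[predicted$predicate == "SubClassOf", , drop = FALSE]
    gold <- gold[gold$predicate == "SubClassOf", , drop = FALSE]
  }
  n <- nrow(predicted)
  category <- character(n)
  matched <- rep(NA_character_, n)
  credit <- numeric(n)
  goldUsed <- rep(FALSE, nrow(gold))

  # first pass: exact matches consume their gold edges
  for (i in seq_len(n)) {
    j <- which(!goldUsed & gold$predicate == predicted$predicate[[i]] &
                 gold$target == predicted$target[[i]])
    if (length(j)) {
      j <- j[[1L]]
      goldUsed[[j]] <- TRUE
      category[[i]] <- "exact"
      matched[[i]] <- gold$target[[j]]
      credit[[i]] <- 1
    }
  }
  # second pass: more-general predictions earn IC partial credit
  ic <- if (any(category == "")) {
    counts <- .subsumeeCounts(graph)
    -log(counts / nrow(graph@terms)) / log(logBase)
  }
  for (i in seq_len(n)) {
    if (category[[i]] != "") next
    p <- predicted$predicate[[i]]
    tPred <- predicted$target[[i]]
    cand <- which(!goldUsed & gold$predicate == p)
    cand <- cand[vapply(cand, function(j) {
      .reachableOver(graph, gold$target[[j]], tPred, c("SubClassOf", p))
    }, logical(1))]
    if (length(cand) && isMoreGeneral(graph, subject, p, tPred)) {
      j <- cand[[which.max(ic[gold$target[cand]])]]
      goldUsed[[j]] <- TRUE
      icE <- ic[[gold$target[[j]]]]
      icP <- ic[[tPred]]
      category[[i]] <- "general"
      matched[[i]] <- gold$target[[j]]
      credit[[i]] <- if (icE > 0) icP / icE else 0
    } else {
      category[[i]] <- "false_positive"
    }
  }
  res <- data.frame(predicate = predicted$predicate,
                    target = predicted$target,
                    category = category, matchedGoldTarget = matched,
                    credit = credit, stringsAsFactors = FALSE)
  attr(res, "nGold") <- nrow(gold)
  res
}

#' Aggregate judgement credits into precision / recall / F1
#'
#' Precision is the summed credit over the number of predictions, recall
#' the summed credit over the number of gold relationships, F1 their
#' harmonic mean. An empty prediction set has undefined precision and is
#' reported as all-zero with the `flagged` bit set.
#'
#' @param judgements data.frame from [scoreRelationships()] (needs a
#'   `credit` column), or any data.frame of credits.
#' @param nGold number of gold relationships; defaults to the `nGold`
#'   attribute of `judgements`.
#' @return a `ScoreSummary`.
#' @export
aggregatePRF <- function(judgements, nGold = attr(judgements, "nGold")) {
  if (is.null(nGold)) .ontoragError("nGold is required", "invalidSpec")
  nPred <- nrow(judgements)
  total <- sum(judgements$credit)
  if (nPred == 0L) {
    return(new("ScoreSummary", precision = 0, recall = 0, f1 = 0,
               nPredicted = 0L, nGold = as.integer(nGold), flagged = TRUE))
  }
  precision <- total / nPred
  recall <- if (nGold > 0L) total / nGold else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall)
        else 0
  new("ScoreSummary", precision = precision, recall = recall, f1 = f1,
      nPredicted = as.integer(nPred), nGold = as.integer(nGold),
      flagged = nGold == 0L)
}

#' Exact-match scoring of genus--differentia logical definitions
#'
#' Both logical definitions are treated as sets of `(predicate, target)`
#' pairs, the genus encoded as the `SubClassOf` pair, and compared by
#' exact-match set precision / recall / F1.
#'
#' @param predicted,gold data.frames with `predicate`, `target` columns
#'   containing exactly one `SubClassOf` (genus) row each; an empty
#'   predicted set yields a flagged all-zero summary.
#' @return a `ScoreSummary`.
#' @export
scoreLogicalDefinitions <- function(predicted, gold) {
  checkGenus <- function(df, what) {
    if (nrow(df) && sum(df$predicate == "SubClassOf") != 1L)
      .ontoragError(paste(what, "logical definition must have exactly one genus"),
                    "malformedLogicalDefinition")
  }
  checkGenus(gold, "gold")
  if (!nrow(gold))
    .ontoragError("gold logical definition must have exactly one genus",
                  "malformedLogicalDefinition")
  if (!nrow(predicted)) {
    return(new("ScoreSummary", precision = 0, recall = 0, f1 = 0,
               nPredicted = 0L, nGold = nrow(gold), flagged = TRUE))
  }
  checkGenus(predicted, "predicted")
  pairKey <- function(df) paste(df$predicate, df$target, sep = "\r")
  pk <- unique(pairKey(predicted))
  gk <- unique(pairKey(gold))
  tp <- length(intersect(pk, gk))
  precision <- tp / length(pk)
  recall <- tp / length(gk)
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall)
        else 0
  new("ScoreSummary", precision = precision, recall = recall, f1 = f1,
      nPredicted = length(pk), nGold = length(gk), flagged = FALSE)
}
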