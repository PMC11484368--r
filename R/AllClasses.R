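#' Class definitions
#'
#' Central S4 containers: the symbol table mapping CURIEs to camel-case
#' symbols, the ontology graph, term objects and partial (masked) terms,
#' issue records, vector indexes, generation/embedding backends, prompt
#' payloads, completion results, and evaluation summaries.
#'
#' @name ontorag-classes
#' @keywords internal
NULL

setClass("SymbolTable",
  representation(forward = "environment", reverse = "environment"))

setClass("OntologyGraph",
  representation(
    terms = "data.frame",              # curie, label, definition, creationDate
    edges = "data.frame",              # subject, predicate, object
    logicalDefinitions = "list",       # curie -> list(genus, differentia)
    predicateLabels = "character"),    # predicate curie -> label
  prototype(
    terms = data.frame(curie = character(0), label = character(0),
                       definition = character(0), creationDate = character(0),
                       stringsAsFactors = FALSE),
    edges = data.frame(subject = character(0), predicate = character(0),
                       object = character(0), stringsAsFactors = FALSE),
    logicalDefinitions = list(),
    predicateLabels = character(0)))

.validOntologyGraph <- function(object) {
  msgs <- character(0)
  tm <- object@terms
  ed <- object@edges
  need <- c("curie", "label", "definition", "creationDate")
  if (!all(need %in% names(tm)))
    return(paste("terms must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(tm$curie))
    msgs <- c(msgs, "duplicate term CURIEs")
  if (!all(c("subject", "predicate", "object") %in% names(ed)))
    return("edges must have columns subject, predicate, object")
  if (nrow(ed)) {
    if (!all(ed$subject %in% tm$curie) || !all(ed$object %in% tm$curie))
      msgs <- c(msgs, "edge endpoints must exist in terms")
    isa <- ed[ed$predicate == "SubClassOf", , drop = FALSE]
    if (nrow(isa)) {
      g <- igraph::graph_from_data_frame(
        isa[, c("subject", "object")], directed = TRUE,
        vertices = data.frame(name = tm$curie))
      if (!igraph::is_dag(g))
        msgs <- c(msgs, "SubClassOf edge set must be acyclic")
    }
  }
  bad <- setdiff(names(object@logicalDefinitions), tm$curie)
  if (length(bad))
    msgs <- c(msgs, "logical definitions for unknown terms")
  if (length(msgs)) msgs else TRUE
}
setValidity("OntologyGraph", .validOntologyGraph)

setClass("TermObject",
  representation(
    id = "character",
    originalId = "character",
    label = "character",
    definition = "character",
    relationships = "data.frame",        # predicate, target (symbols)
    logicalDefinitions = "data.frame"),  # predicate, target; one SubClassOf row
  prototype(
    id = character(0), originalId = character(0), label = character(0),
    definition = character(0),
    relationships = data.frame(predicate = character(0), target = character(0),
                               stringsAsFactors = FALSE),
    logicalDefinitions = data.frame(predicate = character(0),
                                    target = character(0),
                                    stringsAsFactors = FALSE)))

.validTermObject <- function(object) {
  msgs <- character(0)
  for (slotName in c("id", "originalId", "label", "definition")) {
    if (length(slot(object, slotName)) > 1L)
      msgs <- c(msgs, paste(slotName, "must have length 0 or 1"))
  }
  for (slotName in c("relationships", "logicalDefinitions")) {
    df <- slot(object, slotName)
    if (!all(c("predicate", "target") %in% names(df)))
      msgs <- c(msgs, paste(slotName, "needs predicate and target columns"))
  }
  ld <- object@logicalDefinitions
  if (nrow(ld) && sum(ld$predicate == "SubClassOf") != 1L)
    msgs <- c(msgs, "logicalDefinitions must contain exactly one genus (SubClassOf) entry")
  if (length(msgs)) msgs else TRUE
}
setValidity("TermObject", .validTermObject)

setClass("PartialTerm",
  contains = "TermObject",
  representation(fieldsToComplete = "character"))

.validPartialTerm <- function(object) {
  msgs <- character(0)
  known <- c("relationships", "definition", "logical_definitions")
  if (!all(object@fieldsToComplete %in% known))
    msgs <- c(msgs, "fieldsToComplete must be among relationships, definition, logical_definitions")
  present <- character(0)
  if (length(object@label)) present <- c(present, "label")
  if (length(object@definition)) present <- c(present, "definition")
  if (nrow(object@relationships)) present <- c(present, "relationships")
  if (nrow(object@logicalDefinitions)) present <- c(present, "logical_definitions")
  if (!length(present))
    msgs <- c(msgs, "a partial term must have at least one field present")
  if (length(intersect(object@fieldsToComplete, present)))
    msgs <- c(msgs, "fieldsToComplete must be disjoint from present fields")
  if (length(msgs)) msgs else TRUE
}
setValidity("PartialTerm", .validPartialTerm)

setClass("IssueRecord",
  representation(issueId = "integer", title = "character", body = "character",
                 comments = "character"),
  prototype(issueId = NA_integer_, title = "", body = "",
            comments = character(0)))

setClass("EmbeddingBackend",
  representation("VIRTUAL", name = "character", dimension = "integer"))

setClass("HashingEmbedding",
  contains = "EmbeddingBackend",
  representation(seed = "integer"))

setClass("OneHotEmbedding", contains = "EmbeddingBackend")

setClass("VectorIndex",
  representation(
    collection = "character",
    docIds = "character",
    texts = "character",
    vectors = "matrix",
    payloads = "list",
    backend = "EmbeddingBackend"))

.validVectorIndex <- function(object) {
  msgs <- character(0)
  n <- length(object@docIds)
  if (anyDuplicated(object@docIds))
    msgs <- c(msgs, "doc ids must be unique within a collection")
  if (length(object@texts) != n || nrow(object@vectors) != n ||
      length(object@payloads) != n)
    msgs <- c(msgs, "docIds, texts, vectors and payloads must align")
  if (length(msgs)) msgs else TRUE
}
setValidity("VectorIndex", .validVectorIndex)

setClass("TermIndex", contains = "VectorIndex")
setClass("IssueIndex", contains = "VectorIndex")

setClass("GenerationBackend",
  representation("VIRTUAL", name = "character", tokenBudget = "integer"))

setClass("MockGenerationBackend",
  contains = "GenerationBackend",
  representation(replyBook = "list", defaultReply = "character"))

setClass("EchoGenerationBackend",
  contains = "GenerationBackend",
  representation(labelToReply = "list", defaultReply = "character"))

setClass("StaticGenerationBackend",
  contains = "GenerationBackend",
  representation(reply = "character"))

setClass("PromptPayload",
  representation(
    instruction = "character",
    examples = "list",         # list of list(input = json, output = json)
    issueSnippets = "character",
    queryJson = "character",
    rendered = "character",
    tokenEstimate = "numeric",
    overflow = "logical"),
  prototype(overflow = FALSE))

setClass("CompletionResult",
  representation(
    completed = "TermObject",
    droppedRelationships = "data.frame",
    rawReply = "character",
    failed = "logical",
    fieldsToComplete = "character"),
  prototype(failed = FALSE))

setClass("ScoreSummary",
  representation(
    precision = "numeric", recall = "numeric", f1 = "numeric",
    nPredicted = "integer", nGold = "integer", flagged = "logical"),
  prototype(flagged = FALSE))

.validScoreSummary <- function(object) {
  p <- object@precision; r <- object@recall; f <- object@f1
  ok <- all(c(p, r, f) >= -1e-12) && all(c(p, r, f) <= 1 + 1e-12)
  if (!ok) "precision, recall and f1 must lie in [0, 1]" else TRUE
}
setValidity("ScoreSummary", .validScoreSummary)

setClass("ICCResult",
  representation(
    metric = "character", icc = "numeric", msb = "numeric", mse = "numeric",
    k = "numeric", nGroups = "integer", nRatings = "integer"))

## ---- show methods ---------------------------------------------------------

setMethod("show", "SymbolTable", function(object) {
  cat("SymbolTable with", length(ls(object@forward)), "entries\n")
})

setMethod("show", "OntologyGraph", function(object) {
  cat("OntologyGraph:", nrow(object@terms), "terms,", nrow(object@edges),
      "edges,", length(object@logicalDefinitions), "logical definitions\n")
})

setMethod("show", "TermObject", function(object) {
  cat(class(object), if (length(object@id)) object@id else "<no id>", "\n")
  if (length(object@label)) cat("  label:", object@label, "\n")
  if (length(object@definition))
    cat("  definition:", substr(object@definition, 1, 60),
        if (nchar(object@definition) > 60) "...\n" else "\n")
  cat("  relationships:", nrow(object@relationships), "\n")
  if (is(object, "PartialTerm"))
    cat("  to complete:", paste(object@fieldsToComplete, collapse = ", "), "\n")
})

setMethod("show", "VectorIndex", function(object) {
  cat(class(object), "(", object@collection, "):", length(object@docIds),
      "documents, dim", ncol(object@vectors), "\n")
})

setMethod("show", "CompletionResult", function(object) {
  cat("CompletionResult", if (object@failed) "(FAILED)" else "", "\n")
  cat("  completed fields:", paste(object@fieldsToComplete, collapse = ", "), "\n")
  cat("  relationships kept:", nrow(object@completed@relationships),
      "dropped:", nrow(object@droppedRelationships), "\n")
})

setMethod("show", "ScoreSummary", function(object) {
  cat(sprintf("ScoreSummary: P=%.4f R=%.4f F1=%.4f (n_pred=%d, n_gold=%d%s)\n",
              object@precision, object@recall, object@f1,
              object@nPredicted, object@nGold,
              if (object@flagged) ", flagged" else ""))
})

setMethod("show", "ICCResult", function(object) {
  cat(sprintf("ICC(%s) = %.4f  [MSB=%.4f, MSE=%.4f, k=%.2f, groups=%d]\n",
              object@metric, object@icc, object@msb, object@mse,
              object@k, object@nGroups))
})

## ---- simple accessors -----------------------------------------------------

#' Accessors for core containers
#'
#' @param x,table the object to access
#' @param curie,symbol,docId lookup keys
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("ontologyTerms", "OntologyGraph", function(x) x@terms)

#' @rdname accessors
#' @export
setMethod("ontologyEdges", "OntologyGraph", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("logicalDefinitions", "OntologyGraph", function(x) x@logicalDefinitions)

#' @rdname accessors
#' @export
setMethod("logicalDefinitions", "TermObject", function(x) x@logicalDefinitions)

#' @rdname accessors
#' @export
setMethod("nTerms", "OntologyGraph", function(x) nrow(x@terms))

#' @rdname accessors
#' @export
setMethod("docIds", "VectorIndex", function(x) x@docIds)

#' @rdname accessors
#' @export
setMethod("nDocs", "VectorIndex", function(x) length(x@docIds))

#' @rdname accessors
#' @export
setMethod("payloadOf", "VectorIndex", function(x, docId) {
  i <- match(docId, x@docIds)
  if (is.na(i)) .ontoragError(paste("unknown document:", docId), "unknownDocument")
  x@payloads[[i]]
})

#' @rdname accessors
#' @export
setMethod("completedTerm", "CompletionResult", function(x) x@completed)

#' @rdname accessors
#' @export
setMethod("droppedRelationships", "CompletionResult", function(x) x@droppedRelationships)

#' @rdname accessors
#' @export
setMethod("rawReply", "CompletionResult", function(x) x@rawReply)

#' @rdname accessors
#' @export
setMethod("isFailed", "CompletionResult", function(x) x@failed)

#' @rdname accessors
#' @export
setMethod("renderPrompt", "PromptPayload", function(x) x@rendered)

#' Term-object field accessors
#'
#' @param x a [TermObject][ontorag-classes]
#' @return the field value; zero-length character when absent.
#' @export
termLabel <- function(x) x@label

#' @rdname termLabel
#' @export
termDefinition <- function(x) x@definition

#' @rdname termLabel
#' @export
termRelationships <- function(x) x@relationships

#' @rdname termLabel
#' @export
termId <- function(x) x@id

#' @rdname termLabel
#' @export
fieldsToComplete <- function(x) x@fieldsToComplete

#' Convert a ScoreSummary to a one-row data frame
#'
#' @param x a ScoreSummary
#' @param row.names,optional,... ignored; present for the generic.
#' @export
as.data.frame.ScoreSummary <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(precision = x@precision, recall = x@recall, f1 = x@f1,
             nPredicted = x@nPredicted, nGold = x@nGold, flagged = x@flagged)
}

#' @exportClass SymbolTable OntologyGraph TermObject PartialTerm IssueRecord
#' @exportClass EmbeddingBackend HashingEmbedding OneHotEmbedding
#' @exportClass VectorIndex TermIndex IssueIndex GenerationBackend
#' @exportClass MockGenerationBackend EchoGenerationBackend
#' @exportClass StaticGenerationBackend PromptPayload CompletionResult
#' @exportClass ScoreSummary ICCResult
#' @name ontorag-class-exports
#' @keywords internal
NULL
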