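#' @import methods
NULL

#' @export
setGeneric("embedText", function(backend, text) standardGeneric("embedText"))

#' @export
setGeneric("embedTokens", function(backend, tokens) standardGeneric("embedTokens"))

#' @export
setGeneric("tokenSimilarity", function(backend, tokensA, tokensB)
  standardGeneric("tokenSimilarity"))

#' @export
setGeneric("generateReply", function(backend, prompt) standardGeneric("generateReply"))

#' @export
setGeneric("serializeForEmbedding", function(x) standardGeneric("serializeForEmbedding"))

#' @export
setGeneric("ontologyTerms", function(x) standardGeneric("ontologyTerms"))

#' @export
setGeneric("ontologyEdges", function(x) standardGeneric("ontologyEdges"))

#' @export
setGeneric("logicalDefinitions", function(x) standardGeneric("logicalDefinitions"))

#' @export
setGeneric("nTerms", function(x) standardGeneric("nTerms"))

#' @export
setGeneric("symbolOf", function(table, curie) standardGeneric("symbolOf"))

#' @export
setGeneric("resolveSymbol", function(table, symbol) standardGeneric("resolveSymbol"))

#' @export
setGeneric("hasSymbol", function(table, symbol) standardGeneric("hasSymbol"))

#' @export
setGeneric("docIds", function(x) standardGeneric("docIds"))

#' @export
setGeneric("nDocs", function(x) standardGeneric("nDocs"))

#' @export
setGeneric("payloadOf", function(x, docId) standardGeneric("payloadOf"))

#' @export
setGeneric("completedTerm", function(x) standardGeneric("completedTerm"))

#' @export
setGeneric("droppedRelationships", function(x) standardGeneric("droppedRelationships"))

#' @export
setGeneric("rawReply", function(x) standardGeneric("rawReply"))

#' @export
setGeneric("isFailed", function(x) standardGeneric("isFailed"))

#' @export
setGeneric("renderPrompt", function(x) standardGeneric("renderPrompt"))
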