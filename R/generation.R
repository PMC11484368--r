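#' Deterministic mock generation backend
#'
#' A generation backend maps a prompt string to a reply string. The mock
#' backend replies from a canned reply book keyed by the query term's
#' label (the label of the final input object in the prompt), falling
#' back to a default reply; the mapping is a pure function of the
#' prompt, so pipelines built on it are bit-reproducible.
#'
#' @param replyBook named list mapping query labels to reply strings.
#' @param defaultReply reply used when no key matches.
#' @param tokenBudget prompt size limit, in estimated tokens.
#' @return a `MockGenerationBackend`.
#' @export
mockBackend <- function(replyBook = list(), defaultReply = "{}",
                        tokenBudget = 4096L) {
  new("MockGenerationBackend", name = "mock",
      tokenBudget = as.integer(tokenBudget),
      replyBook = as.list(replyBook), defaultReply = defaultReply)
}

## The query input object is the last JSON "label" occurrence in the prompt.
.extractQueryLabel <- function(prompt) {
  m <- gregexpr('"label"\\s*:\\s*"((?:[^"\\\\]|\\\\.)*)"', prompt, perl = TRUE)[[1L]]
  if (m[[1L]] == -1L) return(NA_character_)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  last <- substr(prompt, starts[length(starts)],
                 starts[length(starts)] + lens[length(lens)] - 1L)
  sub('^"label"\\s*:\\s*"', "", sub('"$', "", last))
}

#' @rdname mockBackend
#' @param backend a generation backend.
#' @param prompt the rendered prompt string.
#' @export
setMethod("generateReply", "MockGenerationBackend", function(backend, prompt) {
  label <- .extractQueryLabel(prompt)
  if (!is.na(label) && !is.null(backend@replyBook[[label]]))
    return(backend@replyBook[[label]])
  backend@defaultReply
})

#' Fixed-reply generation backend
#'
#' Returns the same reply for every prompt; handy for exercising parse
#' failures and retry behaviour.
#'
#' @param reply the reply string.
#' @param tokenBudget prompt size limit, in estimated tokens.
#' @return a `StaticGenerationBackend`.
#' @export
staticBackend <- function(reply, tokenBudget = 4096L) {
  new("StaticGenerationBackend", name = "static",
      tokenBudget = as.integer(tokenBudget), reply = reply)
}

#' @rdname staticBackend
#' @param backend a generation backend.
#' @param prompt the rendered prompt string.
#' @export
setMethod("generateReply", "StaticGenerationBackend", function(backend, prompt) {
  backend@reply
})

#' Gold-echo generation backend
#'
#' Replies with the gold-standard completion of the query term, read off
#' a reference graph. This is the evaluation ceiling: no configuration
#' can score higher than a backend that echoes the ontology itself.
#'
#' @param graph the reference [OntologyGraph()].
#' @param table a [SymbolTable()] covering `graph`.
#' @param tokenBudget prompt size limit, in estimated tokens.
#' @return an `EchoGenerationBackend`.
#' @export
echoBackend <- function(graph, table = buildSymbolTable(graph),
                        tokenBudget = 100000L) {
  tm <- graph@terms
  replies <- list()
  for (i in seq_len(nrow(tm))) {
    obj <- termToObject(graph, tm$curie[[i]], table)
    replies[[tm$label[[i]]]] <- .toStableJSON(
      .termToList(obj, fields = c("definition", "relationships",
                                  "logical_definitions")))
  }
  new("EchoGenerationBackend", name = "gold-echo",
      tokenBudget = as.integer(tokenBudget),
      labelToReply = replies, defaultReply = "{}")
}

#' @rdname echoBackend
#' @param backend a generation backend.
#' @param prompt the rendered prompt string.
#' @export
setMethod("generateReply", "EchoGenerationBackend", function(backend, prompt) {
  label <- .extractQueryLabel(prompt)
  if (!is.na(label) && !is.null(backend@labelToReply[[label]]))
    return(backend@labelToReply[[label]])
  backend@defaultReply
})
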