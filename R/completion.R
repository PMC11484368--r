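.DEFAULT_INSTRUCTION <- paste(
  "You are an ontology editor's assistant. Complete the partial ontology",
  "term given as the final input, filling in the missing fields, and",
  "reply with a single JSON object in the same format as the example",
  "outputs. Use only relationship targets that exist in the ontology.")

#' Completion configuration
#'
#' Bundles the tunable parameters of the completion pipeline.
#'
#' @param k number of in-context examples to retrieve (default 10).
#' @param lambda MMR relevance--diversity trade-off (default 0.5).
#' @param poolSize candidate pool retrieved before MMR re-ranking
#'   (default `4 * k`).
#' @param nIssues number of issue snippets to retrieve when an issue
#'   index is supplied.
#' @param snippetCap per-snippet character cap applied before budgeting.
#' @param minExamples floor on the number of examples kept during
#'   budget trimming (the user-requested count; see [buildPrompt()]).
#' @param maxRetries times to re-prompt verbatim after a parse failure.
#' @param tokenInflation multiplier turning whitespace token counts into
#'   a budget-comparable token estimate.
#' @param instruction prompt instruction text.
#' @return a named list of settings.
#' @export
completionConfig <- function(k = 10L, lambda = 0.5, poolSize = 4L * k,
                             nIssues = 3L, snippetCap = 2000L,
                             minExamples = 0L, maxRetries = 2L,
                             tokenInflation = 1.3,
                             instruction = .DEFAULT_INSTRUCTION) {
  list(k = as.integer(k), lambda = lambda, poolSize = as.integer(poolSize),
       nIssues = as.integer(nIssues), snippetCap = as.integer(snippetCap),
       minExamples = as.integer(minExamples), maxRetries = as.integer(maxRetries),
       tokenInflation = tokenInflation, instruction = instruction)
}

#' Select in-context examples for a partial term
#'
#' Embeds the partial term's text fields, retrieves a candidate pool by
#' cosine k-nearest-neighbour search, applies MMR re-ranking, and returns
#' the payload term objects. During evaluation the gold term itself must
#' never be retrievable: either build the index from the core ontology or
#' pass its doc id via `exclude`.
#'
#' @param termIndex a `TermIndex`.
#' @param partial a `PartialTerm` (see [maskTerm()]).
#' @param k number of examples (0 gives an empty list).
#' @param lambda MMR trade-off parameter.
#' @param poolSize candidate pool size before re-ranking.
#' @param exclude doc ids to drop from the results.
#' @return list of [TermObject()]s, most relevant first.
#' @export
selectExamples <- function(termIndex, partial, k = 10L, lambda = 0.5,
                           poolSize = 4L * k, exclude = character(0)) {
  if (k <= 0L) return(list())
  pool <- knnQuery(termIndex, serializeForEmbedding(partial),
                   k = max(poolSize, k) + length(exclude))
  if (length(exclude)) {
    keep <- !(pool$docId %in% exclude)
    atts <- attributes(pool)
    pool <- pool[keep, , drop = FALSE]
    pool$rank <- seq_len(nrow(pool))
    attr(pool, "vectors") <- atts$vectors[keep, , drop = FALSE]
    attr(pool, "queryVector") <- atts$queryVector
    class(pool) <- c("RetrievalResults", "data.frame")
  }
  if (!nrow(pool)) return(list())
  reranked <- mmrRerank(pool, lambda = lambda, k = k)
  lapply(reranked$docId, function(id) payloadOf(termIndex, id))
}

.estimateTokens <- function(text, inflation = 1.3) {
  n <- length(strsplit(trimws(text), "\\s+")[[1L]])
  ceiling(n * inflation)
}

.renderPairs <- function(examples, presentFields, completeFields) {
  lapply(examples, function(ex) {
    list(input = .toStableJSON(.termToList(ex, fields = presentFields)),
         output = .toStableJSON(.termToList(ex, fields = completeFields)))
  })
}

.renderPrompt <- function(instruction, pairs, issueSnippets, queryJson) {
  parts <- c(instruction, "")
  for (p in pairs) {
    parts <- c(parts, "input:", p$input, "output:", p$output, "")
  }
  if (length(issueSnippets)) {
    parts <- c(parts, "Relevant issues:", issueSnippets, "")
  }
  parts <- c(parts, "input:", queryJson, "output:")
  paste(parts, collapse = "\n")
}

.partialPresentFields <- function(partial) {
  present <- character(0)
  if (length(partial@label)) present <- c(present, "label")
  if (length(partial@definition)) present <- c(present, "definition")
  if (nrow(partial@relationships)) present <- c(present, "relationships")
  if (nrow(partial@logicalDefinitions))
    present <- c(present, "logical_definitions")
  present
}

#' Assemble the few-shot completion prompt
#'
#' Each retrieved example becomes an input--output pair: the input JSON
#' carries only the fields present in the partial term, the output JSON
#' the fields to be completed. Examples are dropped from the tail until
#' the rendered prompt fits the backend's token budget -- but never below
#' `minExamples` (the user-requested count); if that floor forces an
#' overflow a warning is issued and the payload is marked.
#'
#' @param partial a `PartialTerm`.
#' @param examples list of [TermObject()]s ordered by retrieval rank.
#' @param issues character vector of issue snippets (may be empty).
#' @param backend a generation backend supplying the token budget.
#' @param minExamples floor on retained examples.
#' @param instruction instruction text.
#' @param tokenInflation whitespace-token inflation factor.
#' @return a `PromptPayload`; the rendered prompt is available via
#'   [renderPrompt()].
#' @export
buildPrompt <- function(partial, examples, issues = character(0),
                        backend, minExamples = 0L,
                        instruction = .DEFAULT_INSTRUCTION,
                        tokenInflation = 1.3) {
  presentFields <- .partialPresentFields(partial)
  completeFields <- partial@fieldsToComplete
  pairs <- .renderPairs(examples, presentFields, completeFields)
  queryJson <- .toStableJSON(.termToList(partial, fields = presentFields))
  floor <- min(length(pairs), max(0L, minExamples))

  nKeep <- length(pairs)
  repeat {
    rendered <- .renderPrompt(instruction, pairs[seq_len(nKeep)], issues,
                              queryJson)
    est <- .estimateTokens(rendered, tokenInflation)
    if (est <= backend@tokenBudget || nKeep <= floor) break
    nKeep <- nKeep - 1L
  }
  overflow <- est > backend@tokenBudget
  if (overflow && floor > 0L) {
    warning("example floor of ", floor, " forces the prompt over the ",
            "token budget (", est, " > ", backend@tokenBudget, ")",
            call. = FALSE)
  } else if (overflow) {
    .ontoragError("prompt exceeds the token budget even with no examples",
                  "budgetUnsatisfiable")
  }
  new("PromptPayload", instruction = instruction,
      examples = pairs[seq_len(nKeep)], issueSnippets = issues,
      queryJson = queryJson, rendered = rendered, tokenEstimate = est,
      overflow = overflow)
}

#' Parse a generation reply into recognized term fields
#'
#' Locates the first balanced JSON object in the reply (tolerating
#' preamble or postamble prose and markdown code fences), parses it, and
#' returns the recognized fields: `definition`, `relationships`,
#' `logical_definitions`. Key matching is case-insensitive; unrecognized
#' keys are ignored with a warning.
#'
#' @param rawReply the backend's reply string.
#' @return named list with any of `definition` (string),
#'   `relationships`, `logical_definitions` (data.frames).
#' @export
parseCompletion <- function(rawReply) {
  candidates <- .extractBalancedObjects(rawReply)
  parsed <- NULL
  for (cand in candidates) {
    parsed <- tryCatch(jsonlite::fromJSON(cand, simplifyVector = FALSE),
                       error = function(e) NULL)
    if (!is.null(parsed)) break
  }
  if (is.null(parsed))
    .ontoragError("no parseable JSON object in reply", "parseFailure")
  keys <- names(parsed) %||% character(0)
  canonical <- c(definition = "definition",
                 relationships = "relationships",
                 logical_definitions = "logical_definitions",
                 logicaldefinitions = "logical_definitions")
  norm <- canonical[gsub("[^a-z_]", "", tolower(keys))]
  unknown <- keys[is.na(norm)]
  if (length(unknown))
    warning("ignoring unrecognized keys: ", paste(unknown, collapse = ", "),
            call. = FALSE)
  out <- list()
  for (i in seq_along(keys)) {
    if (is.na(norm[[i]])) next
    field <- norm[[i]]
    value <- parsed[[i]]
    if (field == "definition") {
      if (is.character(value) || is.null(value))
        out$definition <- as.character(value %||% character(0))
    } else {
      rels <- .relsFromList(value)
      out[[field]] <- rels %||% .relFrame()
    }
  }
  out
}

#' Post-filter parsed fields and merge with the input term
#'
#' Relationships whose predicate or target symbol does not resolve in
#' the symbol table are removed (conservative handling of references to
#' non-existent terms) and recorded. Parsed fields fill only the fields
#' the partial term asked to complete; fields already present in the
#' input always win.
#'
#' @param parsed output of [parseCompletion()].
#' @param partial the input `PartialTerm`.
#' @param table the [SymbolTable()] of known symbols.
#' @return a `CompletionResult`.
#' @export
postprocess <- function(parsed, partial, table) {
  toComplete <- partial@fieldsToComplete
  dropped <- .relFrame()
  filterRels <- function(rels) {
    if (!nrow(rels)) return(rels)
    ok <- vapply(seq_len(nrow(rels)), function(i) {
      p <- rels$predicate[[i]]; t <- rels$target[[i]]
      (p == "SubClassOf" || hasSymbol(table, p)) && hasSymbol(table, t)
    }, logical(1))
    dropped <<- rbind(dropped, rels[!ok, , drop = FALSE])
    rels[ok, , drop = FALSE]
  }
  definition <- partial@definition
  relationships <- partial@relationships
  logicalDefs <- partial@logicalDefinitions
  if ("definition" %in% toComplete && !is.null(parsed$definition) &&
      length(parsed$definition))
    definition <- parsed$definition
  if ("relationships" %in% toComplete && !is.null(parsed$relationships))
    relationships <- filterRels(parsed$relationships)
  if ("logical_definitions" %in% toComplete &&
      !is.null(parsed$logical_definitions)) {
    ld <- filterRels(parsed$logical_definitions)
    # a filtered logical definition must still be genus--differentia
    if (nrow(ld) && sum(ld$predicate == "SubClassOf") != 1L) {
      warning("discarding malformed logical definition (genus count != 1)",
              call. = FALSE)
      dropped <- rbind(dropped, ld)
      ld <- .relFrame()
    }
    logicalDefs <- ld
  }
  id <- if (length(partial@label)) symbolize(partial@label) else character(0)
  completed <- new("TermObject", id = id, originalId = character(0),
                   label = partial@label, definition = definition,
                   relationships = relationships,
                   logicalDefinitions = logicalDefs)
  rownames(dropped) <- NULL
  new("CompletionResult", completed = completed,
      droppedRelationships = dropped, rawReply = character(0),
      failed = FALSE, fieldsToComplete = toComplete)
}

#' Complete a partial ontology term
#'
#' The full retrieval-augmented pipeline: select in-context examples from
#' the term index, optionally retrieve issue snippets, build the prompt,
#' invoke the generation backend, parse the reply, and post-filter the
#' result. On a parse failure the same prompt is retried verbatim up to
#' `config$maxRetries` times; if all attempts fail, a `CompletionResult`
#' flagged as failed (with empty completed fields) is returned so batch
#' runs can continue.
#'
#' @param partial a `PartialTerm`.
#' @param termIndex a `TermIndex` built from the core ontology.
#' @param table the core [SymbolTable()].
#' @param backend a generation backend.
#' @param issueIndex optional `IssueIndex`.
#' @param config a [completionConfig()].
#' @param exclude doc ids the retriever must never return (e.g. the gold
#'   term during evaluation).
#' @return a `CompletionResult`.
#' @export
completeTerm <- function(partial, termIndex, table, backend,
                         issueIndex = NULL, config = completionConfig(),
                         exclude = character(0)) {
  examples <- selectExamples(termIndex, partial, k = config$k,
                             lambda = config$lambda,
                             poolSize = config$poolSize, exclude = exclude)
  snippets <- character(0)
  if (!is.null(issueIndex) && config$nIssues > 0L) {
    hits <- knnQuery(issueIndex, serializeForEmbedding(partial),
                     k = config$nIssues)
    snippets <- vapply(hits$docId, function(id) {
      substr(.issueText(payloadOf(issueIndex, id)), 1L, config$snippetCap)
    }, character(1))
    names(snippets) <- NULL
  }
  payload <- buildPrompt(partial, examples, snippets, backend,
                         minExamples = config$minExamples,
                         instruction = config$instruction,
                         tokenInflation = config$tokenInflation)
  prompt <- payload@rendered
  reply <- NULL
  parsed <- NULL
  for (attempt in seq_len(1L + config$maxRetries)) {
    reply <- generateReply(backend, prompt)
    parsed <- tryCatch(parseCompletion(reply), ontoragError = function(e) NULL)
    if (!is.null(parsed)) break
  }
  if (is.null(parsed)) {
    id <- if (length(partial@label)) symbolize(partial@label) else character(0)
    empty <- new("TermObject", id = id, originalId = character(0),
                 label = partial@label, definition = partial@definition,
                 relationships = partial@relationships,
                 logicalDefinitions = partial@logicalDefinitions)
    return(new("CompletionResult", completed = empty,
               droppedRelationships = .relFrame(), rawReply = reply,
               failed = TRUE, fieldsToComplete = partial@fieldsToComplete))
  }
  result <- postprocess(parsed, partial, table)
  result@rawReply <- reply
  result
}
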