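#' Issue record constructor
#'
#' One GitHub-style issue: number, title, body and comment texts. Issues
#' are indexed without any specialized pre-processing: the serialized
#' title, body and comments, newline-joined, are the embedding input.
#'
#' @param issueId issue number, unique per tracker.
#' @param title,body issue title and body.
#' @param comments character vector of comment bodies.
#' @return an `IssueRecord`.
#' @export
IssueRecord <- function(issueId, title, body = "", comments = character(0)) {
  new("IssueRecord", issueId = as.integer(issueId), title = as.character(title),
      body = as.character(body), comments = as.character(comments))
}

#' Read issues from a GitHub issues API JSON export
#'
#' Accepts the JSON array shape emitted by the standard issues API
#' (fields `number`, `title`, `body`, `comments[].body`).
#'
#' @param path path to the JSON file.
#' @return list of [IssueRecord()]s.
#' @export
readIssues <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw, function(x) {
    comments <- vapply(x$comments %||% list(),
                       function(cm) as.character(cm$body %||% ""), character(1))
    IssueRecord(x$number %||% x$issue_id, x$title %||% "", x$body %||% "",
                comments)
  })
}

.issueText <- function(issue) {
  paste(c(issue@title, issue@body, issue@comments), collapse = "\n")
}

.newIndex <- function(class, collection, docIds, texts, payloads, backend) {
  if (!length(docIds)) .ontoragError("empty corpus", "emptyCorpus")
  if (anyDuplicated(docIds))
    .ontoragError("duplicate document ids", "duplicateDocId")
  vectors <- t(vapply(texts, function(tx) embedText(backend, tx),
                      numeric(backend@dimension)))
  rownames(vectors) <- docIds
  new(class, collection = collection, docIds = docIds, texts = texts,
      vectors = vectors, payloads = payloads, backend = backend)
}

#' Build a vector index over term objects
#'
#' One indexed document per term, with text from
#' [serializeForEmbedding()] and the term object as payload. Supports
#' exact k-nearest-neighbour queries by cosine similarity via
#' [knnQuery()].
#'
#' @param objects non-empty list of [TermObject()]s with labels.
#' @param backend an embedding backend, e.g. [hashingEmbedding()].
#' @return a `TermIndex`.
#' @export
buildTermIndex <- function(objects, backend = hashingEmbedding()) {
  if (!length(objects)) .ontoragError("empty corpus", "emptyCorpus")
  docIds <- vapply(objects, function(x) {
    if (length(x@originalId)) x@originalId
    else if (length(x@id)) x@id
    else .ontoragError("term object without id", "emptyLabel")
  }, character(1))
  texts <- vapply(objects, serializeForEmbedding, character(1))
  .newIndex("TermIndex", "terms", docIds, texts, objects, backend)
}

#' Build a vector index over issues
#'
#' Issues live in their own collection, separate from the term index.
#'
#' @param issues non-empty list of [IssueRecord()]s.
#' @param backend an embedding backend.
#' @return an `IssueIndex`.
#' @export
indexIssues <- function(issues, backend = hashingEmbedding()) {
  if (!length(issues)) .ontoragError("empty corpus", "emptyCorpus")
  docIds <- paste0("issue-", vapply(issues, function(x) x@issueId, integer(1)))
  texts <- vapply(issues, .issueText, character(1))
  .newIndex("IssueIndex", "issues", docIds, texts, issues, backend)
}

#' Query an index for the top-k most similar documents
#'
#' Exact cosine-similarity search: all document vectors are scored
#' against the embedded query and the top `k` returned in descending
#' similarity (ties broken by indexing order). The contract is on the
#' ordering; at the corpus sizes handled here exact search stands in for
#' approximate HNSW-style search with no behavioural difference.
#'
#' @param index a `TermIndex` or `IssueIndex`.
#' @param queryText query string (typically a serialized partial term).
#' @param k number of results (default 10).
#' @return a `RetrievalResults` data.frame with columns `rank`, `docId`,
#'   `similarity`, carrying the candidate vectors and the query vector as
#'   attributes for downstream re-ranking.
#' @export
knnQuery <- function(index, queryText, k = 10L) {
  if (!length(index@docIds)) .ontoragError("empty index", "emptyIndex")
  if (k < 1L) .ontoragError("k must be >= 1", "invalidSpec")
  qv <- embedText(index@backend, queryText)
  sims <- as.numeric(index@vectors %*% qv)
  ord <- order(-sims, seq_along(sims), method = "radix")
  ord <- ord[seq_len(min(k, length(ord)))]
  res <- data.frame(rank = seq_along(ord), docId = index@docIds[ord],
                    similarity = sims[ord], stringsAsFactors = FALSE)
  attr(res, "vectors") <- index@vectors[ord, , drop = FALSE]
  attr(res, "queryVector") <- qv
  class(res) <- c("RetrievalResults", "data.frame")
  res
}

## Greedy MMR selection over pre-computed similarities. simToQuery is the
## relevance of each candidate; pairwise is the candidate-candidate cosine
## matrix. Ties broken by candidate position (original rank).
.mmrOrder <- function(simToQuery, pairwise, lambda, k) {
  n <- length(simToQuery)
  k <- min(k, n)
  selected <- integer(0)
  remaining <- seq_len(n)
  for (step in seq_len(k)) {
    if (!length(selected)) {
      scores <- simToQuery[remaining]
    } else {
      redundancy <- apply(pairwise[remaining, selected, drop = FALSE], 1L, max)
      scores <- lambda * simToQuery[remaining] - (1 - lambda) * redundancy
    }
    best <- remaining[which.max(scores)]   # which.max: first max = lowest rank
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
  }
  selected
}

#' Re-rank retrieval results by Maximal Marginal Relevance
#'
#' Greedy selection: the first pick maximizes query similarity; each
#' subsequent pick maximizes
#' `lambda * cos(d, query) - (1 - lambda) * max_s cos(d, s)` over
#' already-selected documents `s`. With `lambda = 1` the input ordering
#' is preserved; smaller values trade relevance for diversity. Ties are
#' broken by the original rank.
#'
#' @param candidates a `RetrievalResults` object from [knnQuery()].
#' @param lambda relevance--diversity trade-off in `[0, 1]` (default 0.5).
#' @param k number of results to keep.
#' @param queryVector optional replacement query vector (defaults to the
#'   one the candidates were retrieved with).
#' @return a `RetrievalResults` data.frame of `k` rows, re-ranked.
#' @export
mmrRerank <- function(candidates, lambda = 0.5, k = nrow(candidates),
                      queryVector = NULL) {
  if (!nrow(candidates)) .ontoragError("no candidates", "emptyIndex")
  vectors <- attr(candidates, "vectors")
  qv <- queryVector %||% attr(candidates, "queryVector")
  if (is.null(vectors) || is.null(qv))
    .ontoragError("candidates must carry vectors and a query vector",
                  "dimensionMismatch")
  if (length(qv) != ncol(vectors))
    .ontoragError("query vector dimension does not match candidates",
                  "dimensionMismatch")
  simToQuery <- as.numeric(vectors %*% .l2normalize(qv))
  pairwise <- vectors %*% t(vectors)
  sel <- .mmrOrder(simToQuery, pairwise, lambda, k)
  res <- data.frame(rank = seq_along(sel), docId = candidates$docId[sel],
                    similarity = candidates$similarity[sel],
                    stringsAsFactors = FALSE)
  attr(res, "vectors") <- vectors[sel, , drop = FALSE]
  attr(res, "queryVector") <- qv
  class(res) <- c("RetrievalResults", "data.frame")
  res
}

#' Persist and reload a vector index
#'
#' Collections are stored as a single JSON document (ids, texts, vectors,
#' backend parameters), one file per collection.
#'
#' @param index a `TermIndex` or `IssueIndex`.
#' @param path file path to write to / read from.
#' @return `saveIndex` returns `path` invisibly; `loadIndex` the index.
#' @export
saveIndex <- function(index, path) {
  payloads <- lapply(index@payloads, function(p) {
    if (is(p, "TermObject")) list(kind = "term", data = .termToList(p))
    else list(kind = "issue",
              data = list(issue_id = p@issueId, title = p@title,
                          body = p@body, comments = as.list(p@comments)))
  })
  backend <- index@backend
  doc <- list(
    collection = index@collection,
    class = class(index)[[1L]],
    backend = list(name = backend@name, dimension = backend@dimension,
                   seed = if (is(backend, "HashingEmbedding")) backend@seed
                          else NULL),
    docIds = as.list(index@docIds),
    texts = as.list(index@texts),
    payloads = payloads)
  writeLines(.toStableJSON(doc), path)
  invisible(path)
}

#' @rdname saveIndex
#' @export
loadIndex <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$backend$name, "hashing"))
    .ontoragError("only hashing-backend collections can be reloaded",
                  "malformedFile")
  backend <- hashingEmbedding(doc$backend$dimension, doc$backend$seed %||% 0L)
  payloads <- lapply(doc$payloads, function(p) {
    if (identical(p$kind, "term")) .termFromList(p$data)
    else IssueRecord(p$data$issue_id, p$data$title, p$data$body,
                     unlist(p$data$comments, use.names = FALSE) %||% character(0))
  })
  .newIndex(doc$class, doc$collection,
            vapply(doc$docIds, as.character, character(1)),
            vapply(doc$texts, as.character, character(1)),
            payloads, backend)
}
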