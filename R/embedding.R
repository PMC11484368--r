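#' Deterministic hashing embedding backend
#'
#' Offline, reproducible stand-in for a sentence-embedding service: each
#' lower-cased alphanumeric token is hashed (seeded polynomial rolling
#' hash) to a signed coordinate of a fixed-dimension vector, token
#' vectors are summed and the result L2-normalized. Embedding is a pure
#' function of the text -- the same text always yields the identical
#' vector -- and token overlap between two texts translates into cosine
#' similarity, which is the property retrieval needs.
#'
#' @param dimension embedding dimension.
#' @param seed hash seed; distinct seeds give unrelated embeddings.
#' @return a `HashingEmbedding` backend.
#' @export
hashingEmbedding <- function(dimension = 256L, seed = 0L) {
  if (dimension < 1L) .ontoragError("dimension must be positive", "invalidSpec")
  new("HashingEmbedding", name = "hashing", dimension = as.integer(dimension),
      seed = as.integer(seed))
}

.hashTokenVector <- function(token, dimension, seed) {
  v <- numeric(dimension)
  idx <- .stableHash(token, seed) %% dimension + 1
  sgn <- if (.stableHash(token, seed + 1L) %% 2 == 0) 1 else -1
  v[idx] <- sgn
  v
}

#' @rdname hashingEmbedding
#' @param backend an embedding backend.
#' @param text a single string.
#' @export
setMethod("embedText", "HashingEmbedding", function(backend, text) {
  tokens <- .tokenize(text)
  v <- numeric(backend@dimension)
  for (tok in tokens) {
    v <- v + .hashTokenVector(tok, backend@dimension, backend@seed)
  }
  .l2normalize(v)
})

#' @rdname hashingEmbedding
#' @param tokens character vector of tokens.
#' @export
setMethod("embedTokens", "HashingEmbedding", function(backend, tokens) {
  t(vapply(tokens, .hashTokenVector, numeric(backend@dimension),
           dimension = backend@dimension, seed = backend@seed))
})

#' One-hot token embedding backend
#'
#' Token-level backend for definition similarity in which two tokens have
#' cosine similarity 1 exactly when they are equal and 0 otherwise
#' (orthogonal vocabulary). Useful as a transparent, exactly computable
#' reference backend.
#'
#' @return a `OneHotEmbedding` backend.
#' @export
oneHotEmbedding <- function() {
  new("OneHotEmbedding", name = "one-hot", dimension = 1L)
}

#' @rdname oneHotEmbedding
#' @param backend an embedding backend.
#' @param tokensA,tokensB token vectors to compare.
#' @export
setMethod("tokenSimilarity", "OneHotEmbedding", function(backend, tokensA, tokensB) {
  outer(tokensA, tokensB, FUN = function(a, b) as.numeric(a == b))
})

#' @rdname oneHotEmbedding
#' @export
setMethod("tokenSimilarity", "EmbeddingBackend", function(backend, tokensA, tokensB) {
  va <- embedTokens(backend, tokensA)
  vb <- embedTokens(backend, tokensB)
  va <- t(apply(va, 1L, .l2normalize))
  vb <- t(apply(vb, 1L, .l2normalize))
  va %*% t(vb)
})
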