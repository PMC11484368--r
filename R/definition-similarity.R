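#' Greedy token-matching similarity between two definitions
#'
#' BERTScore-style greedy matching over token embeddings: recall is the
#' mean, over reference tokens, of the maximum cosine similarity to any
#' candidate token; precision is the symmetric quantity over candidate
#' tokens; F1 is their harmonic mean. The token embedding backend is
#' pluggable -- the [oneHotEmbedding()] backend gives an exactly
#' computable score in which tokens match only when equal, and
#' contextual-model adapters can implement the same `tokenSimilarity`
#' contract.
#'
#' @param candidate,reference definition strings; both must contain at
#'   least one alphanumeric token.
#' @param backend a token-embedding backend (default [oneHotEmbedding()]).
#' @return named list with `precision`, `recall`, `f1`.
#' @export
definitionSimilarity <- function(candidate, reference,
                                 backend = oneHotEmbedding()) {
  candTokens <- .tokenize(candidate)
  refTokens <- .tokenize(reference)
  if (!length(candTokens) || !length(refTokens))
    .ontoragError("both texts must contain at least one token", "emptyText")
  sims <- tokenSimilarity(backend, candTokens, refTokens)
  precision <- mean(apply(sims, 1L, max))
  recall <- mean(apply(sims, 2L, max))
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall)
        else 0
  list(precision = precision, recall = recall, f1 = f1)
}
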