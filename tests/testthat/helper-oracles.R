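## Independent brute-force oracles and tiny fixtures used across tests.
## These deliberately avoid the package's own machinery (igraph closures,
## hashing helpers): ancestors are found by iterated edge expansion,
## counts by enumeration, MMR by a literal transcription of the greedy
## formula.

## 4-term tree: R <- A <- {B, D}
chainGraph4 <- function() {
  OntologyGraph(
    terms = data.frame(curie = c("T:R", "T:A", "T:B", "T:D"),
                       label = c("root", "alpha", "beta", "delta")),
    edges = data.frame(subject = c("T:A", "T:B", "T:D"),
                       predicate = "SubClassOf",
                       object = c("T:R", "T:A", "T:A")))
}

## 5-term chain R <- A <- B <- C, plus D <- A
chainGraph5 <- function() {
  OntologyGraph(
    terms = data.frame(curie = c("T:R", "T:A", "T:B", "T:C", "T:D"),
                       label = c("root", "alpha", "beta", "gamma", "delta")),
    edges = data.frame(subject = c("T:A", "T:B", "T:C", "T:D"),
                       predicate = "SubClassOf",
                       object = c("T:R", "T:A", "T:B", "T:A")))
}

## Reflexive ancestors of `curie` over edges whose predicate is in preds,
## by fixed-point edge expansion.
oracleAncestors <- function(edges, curie, preds = "SubClassOf") {
  anc <- curie
  repeat {
    step <- edges$object[edges$predicate %in% preds & edges$subject %in% anc]
    grown <- union(anc, step)
    if (length(grown) == length(anc)) return(anc)
    anc <- grown
  }
}

## IC by closure-counting enumeration.
oracleIC <- function(graph, curie, base = 2) {
  tm <- ontologyTerms(graph)
  ed <- ontologyEdges(graph)
  nSubsumed <- sum(vapply(tm$curie, function(x)
    curie %in% oracleAncestors(ed, x), logical(1)))
  -log(nSubsumed / nrow(tm)) / log(base)
}

oracleReachable <- function(edges, from, to, preds) {
  to %in% oracleAncestors(edges, from, preds)
}

## Literal greedy MMR: rows of `vectors` need not be normalized.
oracleMMR <- function(vectors, queryVector, lambda, k) {
  cosine <- function(a, b) sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
  n <- nrow(vectors)
  simQ <- vapply(seq_len(n), function(i) cosine(vectors[i, ], queryVector),
                 numeric(1))
  chosen <- integer(0)
  while (length(chosen) < min(k, n)) {
    best <- NA_integer_
    bestScore <- -Inf
    for (i in setdiff(seq_len(n), chosen)) {
      score <- if (!length(chosen)) simQ[[i]]
      else {
        red <- max(vapply(chosen, function(j)
          cosine(vectors[i, ], vectors[j, ]), numeric(1)))
        lambda * simQ[[i]] - (1 - lambda) * red
      }
      if (score > bestScore + 1e-12) {   # strict improvement => first max wins
        bestScore <- score
        best <- i
      }
    }
    chosen <- c(chosen, best)
  }
  chosen
}

## Independent relationship scorer: same credit rules, brute-force
## machinery (path enumeration + closure counting).
oracleScoreRelationships <- function(graph, subject, predicted, gold) {
  ed <- ontologyEdges(graph)
  credits <- numeric(nrow(predicted))
  categories <- character(nrow(predicted))
  used <- rep(FALSE, nrow(gold))
  for (i in seq_len(nrow(predicted))) {
    hit <- which(!used & gold$predicate == predicted$predicate[[i]] &
                   gold$target == predicted$target[[i]])
    if (length(hit)) {
      used[[hit[[1]]]] <- TRUE
      credits[[i]] <- 1
      categories[[i]] <- "exact"
    }
  }
  for (i in seq_len(nrow(predicted))) {
    if (categories[[i]] != "") next
    p <- predicted$predicate[[i]]
    tPred <- predicted$target[[i]]
    cand <- which(!used & gold$predicate == p)
    cand <- cand[vapply(cand, function(j)
      oracleReachable(ed, gold$target[[j]], tPred, c("SubClassOf", p)),
      logical(1))]
    if (length(cand) && oracleReachable(ed, subject, tPred, c("SubClassOf", p))) {
      ics <- vapply(cand, function(j) oracleIC(graph, gold$target[[j]]),
                    numeric(1))
      j <- cand[[which.max(ics)]]
      used[[j]] <- TRUE
      icE <- oracleIC(graph, gold$target[[j]])
      icP <- oracleIC(graph, tPred)
      credits[[i]] <- if (icE > 0) icP / icE else 0
      categories[[i]] <- "general"
    } else {
      categories[[i]] <- "false_positive"
    }
  }
  list(credit = credits, category = categories)
}

## Random rooted DAG over n terms; every non-root picks 1-2 earlier parents.
randomDagGraph <- function(n, seed) {
  set.seed(seed)
  curies <- sprintf("T:%03d", seq_len(n))
  subj <- character(0); obj <- character(0)
  for (i in 2:n) {
    nParents <- if (i == 2) 1L else sample(1:2, 1L)
    parents <- sample(seq_len(i - 1L), min(nParents, i - 1L))
    subj <- c(subj, rep(curies[[i]], length(parents)))
    obj <- c(obj, curies[parents])
  }
  OntologyGraph(
    terms = data.frame(curie = curies, label = paste("term", seq_len(n))),
    edges = unique(data.frame(subject = subj, predicate = "SubClassOf",
                              object = obj)))
}

## Build a RetrievalResults object directly from raw vectors, the way
## knnQuery would, so MMR can be tested on arbitrary geometry.
makeResults <- function(vectors, queryVector, ids = NULL) {
  norm <- function(v) v / sqrt(sum(v^2))
  vectors <- t(apply(vectors, 1L, norm))
  qv <- norm(queryVector)
  sims <- as.numeric(vectors %*% qv)
  ord <- order(-sims, seq_along(sims), method = "radix")
  ids <- ids %||% paste0("d", seq_len(nrow(vectors)))
  res <- data.frame(rank = seq_along(ord), docId = ids[ord],
                    similarity = sims[ord], stringsAsFactors = FALSE)
  attr(res, "vectors") <- vectors[ord, , drop = FALSE]
  attr(res, "queryVector") <- qv
  class(res) <- c("RetrievalResults", "data.frame")
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

mitralPath <- function() {
  system.file("extdata", "mitral-mini.json", package = "ontorag")
}
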