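miniCorpus <- function(n = 10, seed = 2) {
  graph <- generateOntology(fixtureSpec(nTerms = n, seed = seed))
  table <- buildSymbolTable(graph)
  lapply(ontologyTerms(graph)$curie, termToObject, graph = graph,
         table = table)
}

test_that("a term index holds one document per term and finds itself", {
  objects <- miniCorpus(5)
  index <- buildTermIndex(objects, hashingEmbedding(64, 1))
  expect_s4_class(index, "TermIndex")
  expect_identical(nDocs(index), 5L)
  res <- knnQuery(index, serializeForEmbedding(objects[[3]]), k = 1)
  expect_identical(res$docId, objects[[3]]@originalId)
  expect_equal(res$similarity, 1, tolerance = 1e-12)
})

test_that("duplicate document ids and empty corpora are rejected", {
  objects <- miniCorpus(4)
  expect_error(buildTermIndex(list()), class = "emptyCorpus")
  expect_error(buildTermIndex(c(objects, objects[1])),
               class = "duplicateDocId")
})

test_that("embedding is a pure function of the text", {
  be <- hashingEmbedding(32, 7)
  v1 <- embedText(be, "granular duct cell")
  v2 <- embedText(be, "granular duct cell")
  expect_identical(v1, v2)
  expect_length(v1, 32L)
  expect_equal(sqrt(sum(v1^2)), 1, tolerance = 1e-12)
  # a different seed gives a genuinely different embedding space
  expect_false(isTRUE(all.equal(v1, embedText(hashingEmbedding(32, 8),
                                              "granular duct cell"))))
})

test_that("knn ranking equals the exhaustive cosine oracle", {
  objects <- miniCorpus(10)
  be <- hashingEmbedding(64, 3)
  index <- buildTermIndex(objects, be)
  query <- serializeForEmbedding(objects[[7]])
  res <- knnQuery(index, query, k = 10)

  qv <- embedText(be, query)
  cosine <- function(a, b) sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
  sims <- vapply(objects, function(o)
    cosine(embedText(be, serializeForEmbedding(o)), qv), numeric(1))
  ids <- vapply(objects, function(o) o@originalId, character(1))
  oracleOrder <- ids[order(-sims, seq_along(sims), method = "radix")]
  expect_identical(res$docId, oracleOrder)
  # k larger than the corpus returns everything; k = 1 the single best
  expect_identical(nrow(knnQuery(index, query, k = 99)), 10L)
  expect_identical(knnQuery(index, query, k = 1)$docId, oracleOrder[[1]])
})

test_that("issues index separately from terms and are retrievable", {
  objects <- miniCorpus(6)
  be <- hashingEmbedding(64, 1)
  termIndex <- buildTermIndex(objects, be)
  issues <- list(
    IssueRecord(1, "New term request: liver-resident natural killer cell",
                "Please add liver-resident natural killer cell, a tissue-resident lymphocyte."),
    IssueRecord(2, "Typo in definition of acinar cell", body = ""),
    IssueRecord(3, "Add synonyms for goblet cell",
                "The goblet cell entry lacks common synonyms."))
  issueIndex <- indexIssues(issues, be)
  expect_s4_class(issueIndex, "IssueIndex")
  expect_identical(nDocs(issueIndex), 3L)
  expect_identical(nDocs(termIndex), 6L)   # term collection untouched
  expect_identical(issueIndex@collection, "issues")

  res <- knnQuery(issueIndex, "liver-resident natural killer cell", k = 3)
  expect_identical(res$docId[[1]], "issue-1")
  # an issue with an empty body is still indexed via its title
  expect_identical(payloadOf(issueIndex, "issue-2")@title,
                   "Typo in definition of acinar cell")
})

test_that("lambda = 1 makes MMR the identity on the ranking", {
  for (seed in 1:20) {
    set.seed(seed)
    vecs <- matrix(rnorm(12 * 5), nrow = 12)
    res <- makeResults(vecs, rnorm(5))
    rr <- mmrRerank(res, lambda = 1, k = nrow(res))
    expect_identical(rr$docId, res$docId)
  }
})

test_that("MMR picks the diverse candidate in the hand-worked geometry", {
  # query on the x-axis; d1 nearly parallel to it, d2/d3 symmetric about it.
  # After d1 is taken, d2 (same side as d1) is penalized harder than d3.
  vecs <- rbind(d1 = c(0.98, 0.199), d2 = c(0.9, 0.436), d3 = c(0.9, -0.436))
  res <- makeResults(vecs, c(1, 0), ids = c("d1", "d2", "d3"))
  rr <- mmrRerank(res, lambda = 0.5, k = 2)
  expect_identical(rr$docId, c("d1", "d3"))
  # with no diversity pressure d2 would have come second
  expect_identical(mmrRerank(res, lambda = 1, k = 2)$docId, c("d1", "d2"))
})

test_that("greedy MMR matches the brute-force oracle on random vectors", {
  for (seed in 1:30) {
    set.seed(seed)
    n <- sample(3:10, 1)
    d <- sample(2:6, 1)
    vecs <- matrix(rnorm(n * d), nrow = n)
    qv <- rnorm(d)
    lambda <- runif(1)
    res <- makeResults(vecs, qv)
    k <- sample(seq_len(n), 1)
    rr <- mmrRerank(res, lambda = lambda, k = k)
    oracle <- oracleMMR(attr(res, "vectors"), attr(res, "queryVector"),
                        lambda, k)
    expect_identical(rr$docId, res$docId[oracle])
  }
})

test_that("indexes persist to disk and reload intact", {
  objects <- miniCorpus(6)
  index <- buildTermIndex(objects, hashingEmbedding(64, 9))
  path <- withr::local_tempfile(fileext = ".json")
  saveIndex(index, path)
  back <- loadIndex(path)
  expect_identical(docIds(back), docIds(index))
  expect_equal(back@vectors, index@vectors, tolerance = 1e-12)
  q <- serializeForEmbedding(objects[[2]])
  expect_identical(knnQuery(back, q, 6)$docId, knnQuery(index, q, 6)$docId)
})
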