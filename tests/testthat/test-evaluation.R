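test_that("information content matches closure counting on the 4-term tree", {
  g <- chainGraph4()
  expect_equal(unname(informationContent(g, "T:R")), 0)
  expect_equal(unname(informationContent(g, "T:B")), 2)          # -log2(1/4)
  expect_equal(unname(informationContent(g, "T:A")), -log2(3 / 4),
               tolerance = 1e-12)
  expect_equal(unname(informationContent(g, "T:A", logBase = exp(1))),
               -log(3 / 4), tolerance = 1e-12)
  expect_error(informationContent(g, "T:Z"), class = "unknownTerm")
})

test_that("IC is antitone along subsumption and agrees with the oracle", {
  for (seed in 1:10) {
    g <- randomDagGraph(sample(5:25, 1), seed = seed)
    tm <- ontologyTerms(g)
    ic <- informationContent(g, tm$curie)
    ed <- ontologyEdges(g)
    for (i in seq_len(nrow(ed))) {
      expect_lte(ic[[ed$object[[i]]]], ic[[ed$subject[[i]]]] + 1e-12)
    }
    for (curie in sample(tm$curie, 3)) {
      expect_equal(unname(ic[[curie]]), oracleIC(g, curie), tolerance = 1e-12)
    }
  }
})

test_that("generality traversal combines is-a with the query predicate", {
  g <- OntologyGraph(
    terms = data.frame(curie = c("T:A", "T:B", "T:C", "T:S"),
                       label = c("a", "b", "c", "s")),
    edges = data.frame(
      subject = c("T:B", "T:C", "T:S"),
      predicate = c("SubClassOf", "SubClassOf", "SubClassOf"),
      object = c("T:A", "T:B", "T:A")))
  expect_true(isMoreGeneral(g, "T:C", "SubClassOf", "T:A"))
  expect_false(isMoreGeneral(g, "T:C", "SubClassOf", "T:S"))  # sibling branch

  mixed <- OntologyGraph(
    terms = data.frame(curie = c("T:A", "T:B", "T:C"),
                       label = c("a", "b", "c")),
    edges = data.frame(subject = c("T:C", "T:B"),
                       predicate = c("R:partof", "SubClassOf"),
                       object = c("T:B", "T:A")))
  expect_true(isMoreGeneral(mixed, "T:C", "R:partof", "T:A"))
  expect_false(isMoreGeneral(mixed, "T:C", "R:haspart", "T:A"))
})

test_that("relationship credit follows the ICp/ICe partial-credit rule", {
  g5 <- chainGraph5()
  exact <- scoreRelationships(g5, "T:C",
                              data.frame(predicate = "SubClassOf",
                                         target = "T:B"))
  expect_identical(exact$category, "exact")
  expect_equal(exact$credit, 1)

  broader <- scoreRelationships(g5, "T:C",
                                data.frame(predicate = "SubClassOf",
                                           target = "T:A"))
  expect_identical(broader$category, "general")
  expect_identical(broader$matchedGoldTarget, "T:B")
  expect_equal(broader$credit, log2(5 / 4) / log2(5 / 2), tolerance = 1e-12)
  expect_equal(broader$credit, 0.2435, tolerance = 1e-3)

  atRoot <- scoreRelationships(g5, "T:C",
                               data.frame(predicate = "SubClassOf",
                                          target = "T:R"))
  expect_equal(atRoot$credit, 0)

  unrelated <- scoreRelationships(g5, "T:C",
                                  data.frame(predicate = "SubClassOf",
                                             target = "T:D"))
  expect_identical(unrelated$category, "false_positive")
  expect_equal(unrelated$credit, 0)
})

test_that("scoring agrees with the brute-force oracle on random DAGs", {
  set.seed(42)
  for (rep in 1:30) {
    g <- randomDagGraph(sample(6:30, 1), seed = rep + 100)
    tm <- ontologyTerms(g)$curie
    subject <- sample(tm[-1], 1)
    gold <- ontologyEdges(g)
    gold <- gold[gold$subject == subject, c("predicate", "object")]
    names(gold) <- c("predicate", "target")
    predicted <- data.frame(
      predicate = "SubClassOf",
      target = sample(tm, sample(1:4, 1), replace = FALSE))
    got <- scoreRelationships(g, subject, predicted, gold)
    want <- oracleScoreRelationships(g, subject, predicted, gold)
    expect_equal(got$credit, want$credit, tolerance = 1e-10)
    expect_identical(got$category, want$category)
    expect_true(all(got$credit >= 0 & got$credit <= 1))
  }
})

test_that("credits aggregate into CAFA-style precision/recall/F1", {
  j <- data.frame(credit = c(1, 0.5))
  s <- aggregatePRF(j, nGold = 4)
  expect_equal(s@precision, 0.75)
  expect_equal(s@recall, 0.375)
  expect_equal(s@f1, 0.5)

  allExact <- aggregatePRF(data.frame(credit = c(1, 1, 1)), nGold = 3)
  expect_equal(c(allExact@precision, allExact@recall, allExact@f1), c(1, 1, 1))

  none <- aggregatePRF(data.frame(credit = numeric(0)), nGold = 3)
  expect_equal(c(none@precision, none@recall, none@f1), c(0, 0, 0))
  expect_true(none@flagged)
})

test_that("subsumption re-entailment uses remaining closure and genus", {
  g <- OntologyGraph(
    terms = data.frame(curie = c("T:R", "T:A", "T:D"),
                       label = c("root", "alpha", "delta")),
    edges = data.frame(subject = c("T:A", "T:D", "T:D"),
                       predicate = "SubClassOf",
                       object = c("T:R", "T:A", "T:R")))
  expect_true(entailSubsumption(g, "T:D", "T:R"))    # via D<A<R
  expect_false(entailSubsumption(g, "T:D", "T:A"))   # no alternate path
  expect_error(entailSubsumption(g, "T:A", "T:D"), class = "edgeNotAsserted")

  withGenus <- OntologyGraph(
    terms = data.frame(curie = c("T:G", "T:X"), label = c("genus", "x")),
    edges = data.frame(subject = "T:X", predicate = "SubClassOf",
                       object = "T:G"),
    logicalDefinitions = list("T:X" = list(
      genus = "T:G", differentia = data.frame(predicate = character(0),
                                              target = character(0)))))
  expect_true(entailSubsumption(withGenus, "T:X", "T:G"))
})

test_that("the recovery baseline has precision 1 and rate-driven recall", {
  noRed <- generateOntology(fixtureSpec(nTerms = 40, redundancyRate = 0,
                                        logicalDefRate = 0, seed = 2))
  s0 <- reasonerBaseline(noRed)
  expect_equal(s0@recall, 0)

  half <- generateOntology(fixtureSpec(nTerms = 40, redundancyRate = 0.5,
                                       logicalDefRate = 0, seed = 2))
  s1 <- reasonerBaseline(half)
  expect_equal(s1@precision, 1)
  expect_gt(s1@recall, 0)
  # every prediction is one of the asserted edges
  j <- attr(s1, "judgements")
  ed <- ontologyEdges(half)
  keys <- paste(ed$subject, ed$object)
  expect_true(all(paste(j$subject, j$target) %in% keys))
})

test_that("definition similarity implements greedy token matching", {
  self <- definitionSimilarity("excretion of cystathionine",
                               "excretion of cystathionine")
  expect_equal(c(self$precision, self$recall, self$f1), c(1, 1, 1))

  s <- definitionSimilarity("excretion of cystathionine",
                            "excretion of excessive cystathionine")
  expect_equal(s$precision, 1)
  expect_equal(s$recall, 0.75)
  expect_equal(s$f1, 2 * 1 * 0.75 / 1.75, tolerance = 1e-12)

  disjoint <- definitionSimilarity("alpha beta", "gamma delta")
  expect_equal(c(disjoint$precision, disjoint$recall, disjoint$f1), c(0, 0, 0))

  expect_error(definitionSimilarity("", "x"), class = "emptyText")
})

test_that("swapping candidate and reference swaps precision and recall", {
  set.seed(3)
  words <- c("cell", "gland", "layer", "duct", "alpha", "beta", "of", "the")
  for (rep in 1:10) {
    a <- paste(sample(words, sample(3:6, 1), replace = TRUE), collapse = " ")
    b <- paste(sample(words, sample(3:6, 1), replace = TRUE), collapse = " ")
    ab <- definitionSimilarity(a, b)
    ba <- definitionSimilarity(b, a)
    expect_equal(ab$precision, ba$recall, tolerance = 1e-12)
    expect_equal(ab$recall, ba$precision, tolerance = 1e-12)
    expect_equal(ab$f1, ba$f1, tolerance = 1e-12)
  }
})

ratingRows <- function(evaluator, values, metric = "score", confidence = 3) {
  data.frame(term_id = sprintf("T%02d", seq_along(values)), source = "model",
             metric = metric, value = values, confidence = confidence,
             evaluator_id = evaluator, stringsAsFactors = FALSE)
}

test_that("ICC reproduces the hand-worked one-way ANOVA", {
  ratings <- rbind(ratingRows("e1", c(1, 2, 3)), ratingRows("e2", c(4, 5, 6)))
  r <- icc(ratings, "score")
  expect_equal(r@msb, 13.5)
  expect_equal(r@mse, 1)
  expect_equal(r@k, 3)
  expect_equal(r@icc, 12.5 / 15.5, tolerance = 1e-12)
  expect_equal(r@icc, 0.806, tolerance = 1e-3)
})

test_that("ICC mean squares agree with stats::aov on random designs", {
  set.seed(8)
  for (rep in 1:10) {
    nEval <- sample(2:5, 1)
    perEval <- sample(3:8, 1)
    ratings <- do.call(rbind, lapply(seq_len(nEval), function(i)
      ratingRows(paste0("e", i), sample(1:5, perEval, replace = TRUE))))
    if (length(unique(ratings$value)) == 1L) next
    r <- icc(ratings, "score")
    fit <- summary(stats::aov(value ~ evaluator_id,
                              data = transform(ratings,
                                               evaluator_id = factor(evaluator_id))))
    ms <- fit[[1]][["Mean Sq"]]
    expect_equal(r@msb, ms[[1]], tolerance = 1e-12)
    expect_equal(r@mse, ms[[2]], tolerance = 1e-12)
    expect_lte(r@icc, 1)
  }
})

test_that("degenerate and underpowered rating sets raise typed errors", {
  constantWithin <- rbind(ratingRows("e1", c(2, 2, 2)),
                          ratingRows("e2", c(5, 5, 5)))
  expect_equal(icc(constantWithin, "score")@icc, 1)
  expect_error(icc(ratingRows("e1", c(1, 2, 3)), "score"),
               class = "insufficientData")
  allSame <- rbind(ratingRows("e1", c(3, 3, 3)), ratingRows("e2", c(3, 3, 3)))
  expect_error(icc(allSame, "score"), class = "degenerateVariance")
})

test_that("confidence filtering reduces the data entering the ICC", {
  lowConf <- rbind(ratingRows("e1", c(1, 5, 2, 4), confidence = c(1, 1, 5, 5)),
                   ratingRows("e2", c(5, 1, 4, 2), confidence = c(1, 1, 5, 5)))
  rAll <- icc(lowConf, "score", minConfidence = 1)
  rHigh <- icc(lowConf, "score", minConfidence = 4)
  expect_identical(rAll@nRatings, 8L)
  expect_identical(rHigh@nRatings, 4L)
})

gapRatings <- function(gaps, levels = seq_along(gaps)) {
  do.call(rbind, lapply(seq_along(levels), function(i) {
    data.frame(term_id = paste0("T", i), source = c("human", "model"),
               metric = "score", value = c(3 + gaps[[i]], 3),
               confidence = levels[[i]], evaluator_id = "e1",
               stringsAsFactors = FALSE)
  }))
}

test_that("confidence-gap correlation matches the direct Pearson formula", {
  linear <- confidenceGapCorrelation(gapRatings(c(0.5, 1.0, 1.5, 2.0)),
                                     "human", "model")
  expect_equal(linear$pearsonR, 1, tolerance = 1e-12)

  bent <- confidenceGapCorrelation(gapRatings(c(1, 3, 2)), "human", "model")
  expect_equal(bent$gaps, c(1, 3, 2))
  expect_equal(bent$pearsonR, 0.5, tolerance = 1e-12)

  flat <- confidenceGapCorrelation(gapRatings(c(0, 0, 0)), "human", "model")
  expect_true(flat$flagged)
  expect_true(is.na(flat$pearsonR))

  expect_error(confidenceGapCorrelation(gapRatings(c(1, 2)), "human", "model"),
               class = "insufficientLevels")
})

test_that("logical definitions score as exact-match pair sets", {
  predicted <- data.frame(predicate = c("SubClassOf", "R:haspart"),
                          target = c("T:G", "T:X"))
  gold <- data.frame(predicate = c("SubClassOf", "R:haspart", "R:inheresin"),
                     target = c("T:G", "T:X", "T:Y"))
  s <- scoreLogicalDefinitions(predicted, gold)
  expect_equal(s@precision, 1)
  expect_equal(s@recall, 2 / 3, tolerance = 1e-12)
  expect_equal(s@f1, 0.8, tolerance = 1e-12)

  same <- scoreLogicalDefinitions(gold, gold)
  expect_equal(c(same@precision, same@recall, same@f1), c(1, 1, 1))

  none <- scoreLogicalDefinitions(
    data.frame(predicate = character(0), target = character(0)), gold)
  expect_equal(c(none@precision, none@recall, none@f1), c(0, 0, 0))
  expect_true(none@flagged)

  twoGenera <- data.frame(predicate = c("SubClassOf", "SubClassOf"),
                          target = c("T:G", "T:H"))
  expect_error(scoreLogicalDefinitions(twoGenera, gold),
               class = "malformedLogicalDefinition")
})
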