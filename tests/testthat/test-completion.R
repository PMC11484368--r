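## A tiny metabolite-excretion corpus in which lexical overlap between
## definitions drives retrieval, mirroring how a phenotype query pulls in
## kindred phenotype terms.
uriaCorpus <- function() {
  mk <- function(label, def, parent) {
    TermObject(label = label, definition = def,
               relationships = data.frame(predicate = "SubClassOf",
                                          target = parent),
               id = symbolize(label), originalId = paste0("X:", symbolize(label)))
  }
  list(
    mk("cystathioninuria",
       "Excretion of excessive amounts of cystathionine in the urine.",
       "Aminoaciduria"),
    mk("homocystinuria",
       "Excretion of excessive amounts of homocystine in the urine.",
       "Aminoaciduria"),
    mk("cardiomegaly", "An enlargement of the heart.", "HeartAnomaly"),
    mk("hepatomegaly", "An enlargement of the liver.", "AbdominalAnomaly"),
    mk("short stature", "A reduced body height.", "GrowthAnomaly"))
}

test_that("retrieval surfaces kindred terms for a new phenotype label", {
  index <- buildTermIndex(uriaCorpus(), hashingEmbedding(128, 1))
  partial <- PartialTerm(
    label = "hydroxyprolinuria",
    definition = "Excretion of excessive amounts of hydroxyproline in the urine.",
    fieldsToComplete = "relationships")
  examples <- selectExamples(index, partial, k = 2)
  labels <- vapply(examples, termLabel, character(1))
  expect_true("cystathioninuria" %in% labels)
  expect_identical(selectExamples(index, partial, k = 0), list())
})

test_that("example selection equals MMR applied to the cosine ranking", {
  graph <- generateOntology(fixtureSpec(nTerms = 20, seed = 4))
  table <- buildSymbolTable(graph)
  objects <- lapply(ontologyTerms(graph)$curie, termToObject, graph = graph,
                    table = table)
  index <- buildTermIndex(objects, hashingEmbedding(64, 4))
  partial <- maskTerm(objects[[15]], "relationships")
  k <- 5; lambda <- 0.4
  got <- selectExamples(index, partial, k = k, lambda = lambda, poolSize = 20)
  pool <- knnQuery(index, serializeForEmbedding(partial), k = 20)
  want <- mmrRerank(pool, lambda = lambda, k = k)$docId
  expect_identical(vapply(got, function(o) o@originalId, character(1)), want)
})

test_that("excluded documents never reach the example list", {
  objects <- uriaCorpus()
  index <- buildTermIndex(objects, hashingEmbedding(128, 1))
  partial <- maskTerm(objects[[1]], "relationships")
  got <- selectExamples(index, partial, k = 5,
                        exclude = objects[[1]]@originalId)
  ids <- vapply(got, function(o) o@originalId, character(1))
  expect_false(objects[[1]]@originalId %in% ids)
})

test_that("prompts trim tail examples to the token budget", {
  objects <- uriaCorpus()
  partial <- maskTerm(objects[[1]], "relationships")
  examples <- objects[-1]
  big <- buildPrompt(partial, examples, backend = mockBackend(tokenBudget = 4096))
  expect_length(big@examples, 4L)
  expect_lte(big@tokenEstimate, 4096)

  # a budget that cannot hold all examples keeps the highest-ranked prefix
  budget <- as.integer(big@tokenEstimate - 10)
  small <- buildPrompt(partial, examples,
                       backend = mockBackend(tokenBudget = budget))
  nKept <- length(small@examples)
  expect_lt(nKept, 4L)
  expect_identical(small@examples, big@examples[seq_len(nKept)])
  expect_lte(small@tokenEstimate, budget)
  expect_false(small@overflow)
})

test_that("the example floor wins over the budget, with a warning", {
  objects <- uriaCorpus()
  partial <- maskTerm(objects[[1]], "relationships")
  expect_warning(
    p <- buildPrompt(partial, objects[-1],
                     backend = mockBackend(tokenBudget = 60), minExamples = 3),
    "floor")
  expect_length(p@examples, 3L)
  expect_true(p@overflow)
  expect_error(
    buildPrompt(partial, objects[-1], backend = mockBackend(tokenBudget = 5)),
    class = "budgetUnsatisfiable")
})

test_that("issue snippets are appended verbatim and only when supplied", {
  objects <- uriaCorpus()
  partial <- maskTerm(objects[[1]], "relationships")
  plain <- buildPrompt(partial, objects[2:3], backend = mockBackend())
  withIssues <- buildPrompt(partial, objects[2:3],
                            issues = "Please add hydroxyprolinuria soon.",
                            backend = mockBackend())
  expect_false(grepl("Relevant issues", renderPrompt(plain), fixed = TRUE))
  expect_match(renderPrompt(withIssues), "Please add hydroxyprolinuria soon.",
               fixed = TRUE)
  expect_identical(renderPrompt(plain),
                   renderPrompt(buildPrompt(partial, objects[2:3],
                                            issues = character(0),
                                            backend = mockBackend())))
})

test_that("replies parse through preamble, code fences, and bad keys", {
  bare <- '{"definition": "x", "relationships": []}'
  parsed <- parseCompletion(bare)
  expect_identical(parsed$definition, "x")
  expect_identical(nrow(parsed$relationships), 0L)

  fenced <- paste0("Sure! Here is the term:\n```json\n",
                   '{"definition": "x", "Relationships": [',
                   '{"predicate": "SubClassOf", "target": "Interneuron"}]}',
                   "\n```\nLet me know if you need more.")
  parsedFenced <- parseCompletion(fenced)
  expect_identical(parsedFenced$definition, "x")
  expect_identical(parsedFenced$relationships$target, "Interneuron")

  expect_error(parseCompletion("I cannot help with that."),
               class = "parseFailure")
  expect_warning(parseCompletion('{"definition": "x", "confidence": 3}'),
                 "unrecognized")
})

test_that("post-filtering drops relationships to unknown symbols", {
  table <- SymbolTable()
  symbolize("interneuron", table, "CL:0000099")
  symbolize("has soma location", table, "RO:0002100")
  partial <- PartialTerm(label = "mitral cell", definition = "A cell.",
                         fieldsToComplete = "relationships")
  parsed <- list(relationships = data.frame(
    predicate = c("SubClassOf", "HasSomaLocation"),
    target = c("Interneuron", "NotARealTerm")))
  res <- postprocess(parsed, partial, table)
  kept <- termRelationships(completedTerm(res))
  expect_identical(kept$target, "Interneuron")
  expect_identical(nrow(droppedRelationships(res)), 1L)
  expect_identical(droppedRelationships(res)$target, "NotARealTerm")
})

test_that("parsed fields outside fieldsToComplete are discarded and input wins", {
  table <- SymbolTable()
  symbolize("gland", table, "SYN:1")
  partial <- PartialTerm(label = "alpha gland", definition = "Kept as given.",
                         fieldsToComplete = "relationships")
  parsed <- list(definition = "Model tries to overwrite.",
                 relationships = data.frame(predicate = "SubClassOf",
                                            target = "Gland"))
  res <- postprocess(parsed, partial, table)
  expect_identical(termDefinition(completedTerm(res)), "Kept as given.")
  expect_identical(termRelationships(completedTerm(res))$target, "Gland")
  # empty parsed relationships are fine
  res2 <- postprocess(list(relationships = data.frame(
    predicate = character(0), target = character(0))), partial, table)
  expect_identical(nrow(termRelationships(completedTerm(res2))), 0L)
  expect_false(isFailed(res2))
})

test_that("end-to-end completion is deterministic and merges the reply", {
  objects <- uriaCorpus()
  table <- SymbolTable()
  for (o in objects) symbolize(termLabel(o), table, o@originalId)
  symbolize("aminoaciduria", table, "X:Aminoaciduria")
  index <- buildTermIndex(objects, hashingEmbedding(128, 1))
  reply <- paste0('{"definition": "Excretion of excessive amounts of ',
                  'hydroxyproline in the urine.", "relationships": [',
                  '{"predicate": "SubClassOf", "target": "Aminoaciduria"},',
                  '{"predicate": "SubClassOf", "target": "NotATerm"}]}')
  backend <- mockBackend(replyBook = list(hydroxyprolinuria = reply))
  partial <- PartialTerm(label = "hydroxyprolinuria",
                         fieldsToComplete = "relationships")
  r1 <- completeTerm(partial, index, table, backend)
  r2 <- completeTerm(partial, index, table, backend)
  expect_identical(rawReply(r1), reply)
  expect_identical(termRelationships(completedTerm(r1))$target, "Aminoaciduria")
  expect_identical(droppedRelationships(r1)$target, "NotATerm")
  expect_identical(termRelationships(completedTerm(r1)),
                   termRelationships(completedTerm(r2)))
  expect_identical(rawReply(r1), rawReply(r2))
})

test_that("persistent parse failures flag the result and keep going", {
  objects <- uriaCorpus()
  table <- SymbolTable()
  index <- buildTermIndex(objects, hashingEmbedding(128, 1))
  partial <- PartialTerm(label = "hydroxyprolinuria",
                         fieldsToComplete = "relationships")
  res <- completeTerm(partial, index, table,
                      staticBackend("I cannot help with that."))
  expect_true(isFailed(res))
  expect_identical(rawReply(res), "I cannot help with that.")
  expect_identical(nrow(termRelationships(completedTerm(res))), 0L)
})

test_that("no hallucinated relationship survives post-filtering", {
  graph <- generateOntology(fixtureSpec(nTerms = 30, seed = 6))
  table <- buildSymbolTable(graph)
  knownSymbols <- ls(table@reverse)
  set.seed(99)
  for (rep in 1:100) {
    nRels <- sample(1:6, 1)
    targets <- ifelse(runif(nRels) < 0.5,
                      sample(knownSymbols, nRels, replace = TRUE),
                      paste0("Fabricated", sample(1e6, nRels)))
    parsed <- list(relationships = data.frame(
      predicate = "SubClassOf", target = targets))
    partial <- PartialTerm(label = "probe term",
                           fieldsToComplete = "relationships")
    res <- postprocess(parsed, partial, table)
    kept <- termRelationships(completedTerm(res))
    expect_true(all(vapply(kept$target, function(s) hasSymbol(table, s),
                           logical(1))))
    expect_identical(nrow(kept) + nrow(droppedRelationships(res)),
                     nRels)
  }
})
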