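#' Evaluation-run configuration
#'
#' @param ontology path to an OBO Graph JSON file, or `NULL` to generate
#'   a synthetic fixture from `fixture`.
#' @param fixture a [fixtureSpec()] (or argument list for one) used when
#'   `ontology` is `NULL`.
#' @param task prediction task to evaluate.
#' @param method `"rag"` for the completion pipeline, `"reasoner"` for
#'   the subsumption-recovery baseline.
#' @param backend `"echo"` (gold-echo ceiling), a [mockBackend()] /
#'   other generation backend object, or a reply-book list for a mock.
#' @param cutoff date splitting core from candidate test terms.
#' @param nTest requested test-set size.
#' @param k,lambda retrieval parameters (see [completionConfig()]).
#' @param embeddingDim hashing-embedding dimension.
#' @param taskFilter `"all"` or `"subclass_only"` relationship scoring.
#' @param seed seed for the embedding hash and any generator randomness.
#' @param outDir optional directory for report files (per-term JSONL,
#'   summary JSON, summary TSV).
#' @return a named list.
#' @export
evaluationConfig <- function(ontology = NULL, fixture = fixtureSpec(),
                             task = c("relationships", "definition",
                                      "logical_definitions"),
                             method = c("rag", "reasoner"),
                             backend = "echo",
                             cutoff = "2022-11-01", nTest = 50L,
                             k = 10L, lambda = 0.5, embeddingDim = 256L,
                             taskFilter = c("all", "subclass_only"),
                             seed = 1L, outDir = NULL) {
  list(ontology = ontology, fixture = fixture, task = match.arg(task),
       method = match.arg(method), backend = backend,
       cutoff = cutoff, nTest = as.integer(nTest), k = as.integer(k),
       lambda = lambda, embeddingDim = as.integer(embeddingDim),
       taskFilter = match.arg(taskFilter), seed = as.integer(seed),
       outDir = outDir)
}

.relsToCuries <- function(rels, table) {
  if (!nrow(rels)) return(.relFrame())
  .relFrame(
    vapply(rels$predicate, function(p)
      if (p == "SubClassOf") "SubClassOf" else resolveSymbol(table, p),
      character(1)),
    vapply(rels$target, function(t) resolveSymbol(table, t), character(1)))
}

.resolveRunBackend <- function(backend, graph, table) {
  if (is(backend, "GenerationBackend")) return(backend)
  if (identical(backend, "echo")) return(echoBackend(graph, table))
  if (is.list(backend)) return(mockBackend(backend))
  .ontoragError("unrecognized backend specification", "invalidSpec")
}

#' Run a masked-term evaluation experiment
#'
#' Orchestrates the full experiment: split the ontology by date, index
#' the core, mask each test term for the chosen task, complete it with
#' the configured backend, score against the ontology's own content, and
#' micro-average. With a deterministic backend the run (including any
#' report files) is bit-reproducible for a given config and seed.
#' Gold relationships (and logical definitions) are restricted to
#' targets that survive in the core: a relationship pointing at a term
#' that is itself held out cannot be expressed against the core
#' vocabulary, so it is not part of the reachable gold standard.
#'
#' @param config an [evaluationConfig()] (or a YAML file path holding
#'   one).
#' @return list with `summary` (a `ScoreSummary`), `perTerm`
#'   (data.frame), `test` (test-set CURIEs) and `nFailed`.
#' @export
runEvaluation <- function(config) {
  if (is.character(config)) config <- do.call(evaluationConfig,
                                              yaml::read_yaml(config))
  graph <- if (!is.null(config$ontology)) loadOntology(config$ontology)
           else generateOntology(config$fixture)
  split <- splitByDate(graph, config$cutoff, config$nTest)
  test <- split$test
  core <- split$core

  if (config$method == "reasoner") {
    summary <- reasonerBaseline(graph, test)
    perTerm <- attr(summary, "judgements")
    .writeReports(config$outDir, perTerm, summary, config)
    return(list(summary = summary, perTerm = perTerm, test = test,
                nFailed = 0L))
  }

  fullTable <- buildSymbolTable(graph)
  coreTable <- buildSymbolTable(core)
  coreCuries <- core@terms$curie
  embedder <- hashingEmbedding(config$embeddingDim, config$seed)
  coreObjects <- lapply(coreCuries, termToObject, graph = core,
                        table = coreTable)
  index <- buildTermIndex(coreObjects, embedder)
  backend <- .resolveRunBackend(config$backend, graph, fullTable)
  cc <- completionConfig(k = config$k, lambda = config$lambda)

  task <- config$task
  hasGold <- vapply(test, function(curie) {
    obj <- termToObject(graph, curie, fullTable)
    switch(task,
           relationships = nrow(obj@relationships) > 0L,
           definition = length(obj@definition) > 0L,
           logical_definitions = nrow(obj@logicalDefinitions) > 0L)
  }, logical(1))
  test <- test[hasGold]

  rows <- list()
  nFailed <- 0L
  for (curie in test) {
    gold <- termToObject(graph, curie, fullTable)
    partial <- maskTerm(gold, task)
    res <- tryCatch(
      completeTerm(partial, index, coreTable, backend, config = cc),
      ontoragError = function(e) e)
    if (inherits(res, "error") || isFailed(res)) {
      nFailed <- nFailed + 1L
      rows[[curie]] <- .perTermRow(curie, task, NULL, gold, graph, core,
                                   coreTable, config)
      next
    }
    rows[[curie]] <- .perTermRow(curie, task, res, gold, graph, core,
                                 coreTable, config)
  }
  perTerm <- do.call(rbind, unname(rows))
  summary <- .microAverage(perTerm, task)
  .writeReports(config$outDir, perTerm, summary, config)
  list(summary = summary, perTerm = perTerm, test = test, nFailed = nFailed)
}

## Score one completed test term; res = NULL means a failed completion
## (scored as an empty prediction set).
.perTermRow <- function(curie, task, res, gold, graph, core, coreTable,
                        config) {
  coreCuries <- core@terms$curie
  if (task == "relationships") {
    goldEdges <- graph@edges[graph@edges$subject == curie, , drop = FALSE]
    goldEdges <- goldEdges[goldEdges$object %in% coreCuries, , drop = FALSE]
    goldRels <- .relFrame(goldEdges$predicate, goldEdges$object)
    predRels <- if (is.null(res)) .relFrame()
                else .relsToCuries(completedTerm(res)@relationships, coreTable)
    judgements <- scoreRelationships(graph, curie, predRels, goldRels,
                                     taskFilter = config$taskFilter)
    s <- aggregatePRF(judgements)
    credit <- sum(judgements$credit)
    data.frame(curie = curie, precision = s@precision, recall = s@recall,
               f1 = s@f1, credit = credit, nPredicted = s@nPredicted,
               nGold = s@nGold, failed = is.null(res),
               stringsAsFactors = FALSE)
  } else if (task == "definition") {
    predDef <- if (is.null(res)) character(0)
               else completedTerm(res)@definition
    if (!length(predDef) || !length(.tokenize(predDef))) {
      data.frame(curie = curie, precision = 0, recall = 0, f1 = 0,
                 credit = 0, nPredicted = 0L, nGold = 1L, failed = TRUE,
                 stringsAsFactors = FALSE)
    } else {
      s <- definitionSimilarity(predDef, gold@definition)
      data.frame(curie = curie, precision = s$precision, recall = s$recall,
                 f1 = s$f1, credit = s$f1, nPredicted = 1L, nGold = 1L,
                 failed = FALSE, stringsAsFactors = FALSE)
    }
  } else {
    goldLd <- .ldRestrictedToCore(gold@logicalDefinitions, graph, core, curie)
    predLd <- if (is.null(res)) .relFrame()
              else .relsToCuries(completedTerm(res)@logicalDefinitions,
                                 coreTable)
    s <- scoreLogicalDefinitions(predLd, goldLd)
    data.frame(curie = curie, precision = s@precision, recall = s@recall,
               f1 = s@f1, credit = s@precision * s@nPredicted,
               nPredicted = s@nPredicted, nGold = s@nGold,
               failed = is.null(res), stringsAsFactors = FALSE)
  }
}

## Gold logical definition in CURIE space, restricted to core targets.
.ldRestrictedToCore <- function(ldSymbols, graph, core, curie) {
  axiom <- graph@logicalDefinitions[[curie]]
  if (is.null(axiom)) return(.relFrame())
  preds <- c("SubClassOf", axiom$differentia$predicate)
  targets <- c(axiom$genus, axiom$differentia$target)
  keep <- targets %in% core@terms$curie
  keep[1L] <- keep[1L]   # genus kept only if in core, like any target
  .relFrame(preds[keep], targets[keep])
}

.microAverage <- function(perTerm, task) {
  if (is.null(perTerm) || !nrow(perTerm)) {
    return(new("ScoreSummary", precision = 0, recall = 0, f1 = 0,
               nPredicted = 0L, nGold = 0L, flagged = TRUE))
  }
  if (task == "definition") {
    p <- mean(perTerm$precision); r <- mean(perTerm$recall)
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    return(new("ScoreSummary", precision = p, recall = r, f1 = f,
               nPredicted = as.integer(sum(perTerm$nPredicted)),
               nGold = as.integer(sum(perTerm$nGold)), flagged = FALSE))
  }
  nPred <- sum(perTerm$nPredicted)
  nGold <- sum(perTerm$nGold)
  credit <- sum(perTerm$credit)
  p <- if (nPred > 0) credit / nPred else 0
  r <- if (nGold > 0) credit / nGold else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  new("ScoreSummary", precision = p, recall = r, f1 = f,
      nPredicted = as.integer(nPred), nGold = as.integer(nGold),
      flagged = nPred == 0L)
}

.writeReports <- function(outDir, perTerm, summary, config) {
  if (is.null(outDir)) return(invisible(NULL))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  lines <- vapply(seq_len(nrow(perTerm)), function(i)
    .toStableJSON(as.list(perTerm[i, , drop = FALSE])), character(1))
  writeLines(lines, file.path(outDir, "per-term.jsonl"))
  writeLines(.toStableJSON(c(as.list(as.data.frame(summary)),
                             list(task = config$task,
                                  method = config$method))),
             file.path(outDir, "summary.json"))
  utils::write.table(as.data.frame(summary),
                     file.path(outDir, "summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(NULL)
}
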