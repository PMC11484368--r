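#' Synthetic-ontology fixture specification
#'
#' Parameters for the seeded generator: a rooted DAG of labeled terms
#' with templated definitions, heterogeneous relationship types,
#' genus--differentia logical definitions, redundant (entailed) subclass
#' edges, and per-term creation dates. The same spec and seed always
#' produce the identical graph.
#'
#' @param nTerms number of terms (>= 2).
#' @param maxDepth maximum taxonomy depth below the root.
#' @param branching children attempted per parent.
#' @param nPredicates number of non-is-a relationship types.
#' @param crossEdgeRate probability that a term gets a cross-predicate
#'   relationship to an earlier term.
#' @param redundancyRate fraction of depth >= 2 terms given an extra
#'   asserted-but-entailed SubClassOf edge to their grandparent.
#' @param logicalDefRate fraction of depth >= 2 terms given a
#'   genus--differentia logical definition (genus = parent).
#' @param dateRange character vector of two ISO dates; creation dates
#'   are drawn uniformly between them and assigned in creation order, so
#'   later-created terms always carry later dates.
#' @param seed RNG seed.
#' @return a `FixtureSpec` (named list).
#' @export
fixtureSpec <- function(nTerms = 50L, maxDepth = 4L, branching = 3L,
                        nPredicates = 3L, crossEdgeRate = 0.6,
                        redundancyRate = 0.2, logicalDefRate = 0.3,
                        dateRange = c("2021-01-01", "2023-08-01"),
                        seed = 1L) {
  if (nTerms < 2L) .ontoragError("nTerms must be >= 2", "invalidSpec")
  if (redundancyRate < 0 || redundancyRate > 1 ||
      logicalDefRate < 0 || logicalDefRate > 1)
    .ontoragError("rates must lie in [0, 1]", "invalidSpec")
  structure(list(nTerms = as.integer(nTerms), maxDepth = as.integer(maxDepth),
                 branching = as.integer(branching),
                 nPredicates = as.integer(nPredicates),
                 crossEdgeRate = crossEdgeRate,
                 redundancyRate = redundancyRate,
                 logicalDefRate = logicalDefRate,
                 dateRange = as.character(dateRange),
                 seed = as.integer(seed)),
            class = "FixtureSpec")
}

.MODIFIERS <- c("alpha", "beta", "gamma", "delta", "distal", "proximal",
                "dorsal", "ventral", "apical", "basal", "cortical",
                "medullary", "granular", "ciliated", "primary", "secondary",
                "lateral", "medial", "anterior", "posterior", "superficial",
                "deep", "compound", "simple", "accessory", "vestigial")

.NOUNS <- c("gland", "cell", "duct", "membrane", "tissue", "layer",
            "vesicle", "lobe", "fiber", "node", "capsule", "septum")

.PREDICATE_LABELS <- c("part of", "has part", "has quality", "adjacent to",
                       "develops from", "located in", "surrounded by")

#' Generate a seeded synthetic ontology
#'
#' Builds a rooted DAG whose labels are compositional over a small word
#' bank (a child's label contains its parent's label, so lexical overlap
#' tracks taxonomic proximity -- the property retrieval exercises),
#' whose definitions are templated and mention the parent label, and
#' which carries cross-predicate edges, redundant entailed subclass
#' edges at the requested rate, logical definitions, and creation dates.
#' The root has a single child spine term so every term below depth 1
#' has a grandparent to anchor a redundant edge.
#'
#' @param spec a [fixtureSpec()].
#' @return an [OntologyGraph()].
#' @export
generateOntology <- function(spec) {
  if (!inherits(spec, "FixtureSpec")) spec <- do.call(fixtureSpec, spec)
  .withSeed(spec$seed, .generateOntologyImpl(spec))
}

.generateOntologyImpl <- function(spec) {
  n <- spec$nTerms
  curies <- sprintf("SYN:%07d", seq_len(n))
  labels <- character(n)
  definitions <- rep(NA_character_, n)
  parent <- rep(NA_integer_, n)
  depth <- integer(n)

  labels[[1L]] <- "entity"
  definitions[[1L]] <- "The root of the synthetic taxonomy."
  depth[[1L]] <- 0L
  if (n >= 2L) {
    labels[[2L]] <- "material structure"
    definitions[[2L]] <- "An entity that has physical substance."
    parent[[2L]] <- 1L
    depth[[2L]] <- 1L
  }
  used <- new.env(parent = emptyenv())
  assign(labels[[1L]], TRUE, envir = used)
  if (n >= 2L) assign(labels[[2L]], TRUE, envir = used)

  nextIdx <- 3L
  frontier <- 2L      # indices whose children may still be generated
  stalled <- FALSE
  while (nextIdx <= n) {
    sweepStart <- nextIdx
    # deterministic sweep: give each frontier parent up to `branching`
    # children, deepening as the frontier advances
    newFrontier <- integer(0)
    for (p in frontier) {
      if (nextIdx > n) break
      if (depth[[p]] + 1L > spec$maxDepth) next
      kids <- 0L
      for (m in sample(.MODIFIERS)) {
        if (kids >= spec$branching || nextIdx > n) break
        lbl <- if (depth[[p]] == 1L)
          paste(sample(.NOUNS, 1L), "structure")
        else paste(m, labels[[p]])
        if (!is.null(get0(lbl, envir = used, inherits = FALSE))) next
        assign(lbl, TRUE, envir = used)
        labels[[nextIdx]] <- lbl
        definitions[[nextIdx]] <-
          paste0("Any ", labels[[p]], " that is classified as ", lbl, ".")
        parent[[nextIdx]] <- p
        depth[[nextIdx]] <- depth[[p]] + 1L
        newFrontier <- c(newFrontier, nextIdx)
        nextIdx <- nextIdx + 1L
        kids <- kids + 1L
      }
    }
    if (!length(newFrontier)) {
      # frontier reached maxDepth; restart breadth-first over all parents
      if (stalled && nextIdx == sweepStart) break   # label space exhausted
      stalled <- nextIdx == sweepStart
      frontier <- which(depth < spec$maxDepth & seq_len(n) < nextIdx)
      if (!length(frontier)) break
    } else {
      stalled <- FALSE
      frontier <- newFrontier
    }
  }
  n <- nextIdx - 1L   # in case the label space ran out (tiny word banks)
  curies <- curies[seq_len(n)]

  predCuries <- sprintf("SYNREL:%03d", seq_len(spec$nPredicates))
  predicateLabels <- stats::setNames(
    .PREDICATE_LABELS[seq_len(spec$nPredicates)], predCuries)

  subj <- character(0); pred <- character(0); obj <- character(0)
  for (i in seq_len(n)) {
    if (!is.na(parent[[i]])) {
      subj <- c(subj, curies[[i]]); pred <- c(pred, "SubClassOf")
      obj <- c(obj, curies[[parent[[i]]]])
    }
  }
  # cross-predicate edges to earlier-created terms
  if (spec$nPredicates > 0L) {
    for (i in seq_len(n)) {
      if (depth[[i]] < 2L || i < 4L) next
      if (stats::runif(1L) > spec$crossEdgeRate) next
      p <- sample(predCuries, 1L)
      tgt <- sample(seq_len(i - 1L)[-1L], 1L)   # never the root
      subj <- c(subj, curies[[i]]); pred <- c(pred, p)
      obj <- c(obj, curies[[tgt]])
    }
  }
  # redundant entailed subclass edges: term -> grandparent
  for (i in seq_len(n)) {
    if (depth[[i]] < 2L) next
    if (stats::runif(1L) > spec$redundancyRate) next
    gp <- parent[[parent[[i]]]]
    if (is.na(gp)) next
    subj <- c(subj, curies[[i]]); pred <- c(pred, "SubClassOf")
    obj <- c(obj, curies[[gp]])
  }
  edges <- unique(data.frame(subject = subj, predicate = pred, object = obj,
                             stringsAsFactors = FALSE))

  logicalDefs <- list()
  if (spec$nPredicates > 0L) {
    for (i in seq_len(n)) {
      if (depth[[i]] < 2L || i < 4L) next
      if (stats::runif(1L) > spec$logicalDefRate) next
      diffTarget <- sample(seq_len(i - 1L)[-1L], 1L)
      logicalDefs[[curies[[i]]]] <- list(
        genus = curies[[parent[[i]]]],
        differentia = .relFrame(sample(predCuries, 1L), curies[[diffTarget]]))
    }
  }

  range <- as.Date(spec$dateRange)
  offsets <- sort(stats::runif(n, 0, as.numeric(range[[2L]] - range[[1L]])))
  dates <- format(range[[1L]] + floor(offsets), "%Y-%m-%d")

  terms <- data.frame(curie = curies, label = labels[seq_len(n)],
                      definition = definitions[seq_len(n)],
                      creationDate = dates, stringsAsFactors = FALSE)
  OntologyGraph(terms, edges, logicalDefs, predicateLabels)
}

#' Generate synthetic new-term-request issues
#'
#' Each issue names one term's label verbatim, paraphrases its
#' definition, and lists its parent labels in prose -- the shape of a
#' typical new-term request on an ontology issue tracker.
#'
#' @param graph an [OntologyGraph()].
#' @param n number of issues (each about a distinct term).
#' @param seed RNG seed.
#' @return list of [IssueRecord()]s.
#' @export
generateIssues <- function(graph, n, seed = 1L) {
  if (n < 1L) .ontoragError("n must be >= 1", "invalidSpec")
  tm <- graph@terms
  eligible <- which(!is.na(tm$definition) & tm$label != "entity")
  if (n > length(eligible))
    .ontoragError("not enough terms with definitions for that many issues",
                  "invalidSpec")
  .withSeed(seed, {
    chosen <- sample(eligible, n)
    lapply(seq_along(chosen), function(k) {
      i <- chosen[[k]]
      curie <- tm$curie[[i]]
      parents <- graph@edges$object[graph@edges$subject == curie &
                                      graph@edges$predicate == "SubClassOf"]
      parentLabels <- tm$label[match(parents, tm$curie)]
      body <- paste0(
        "Please add the term '", tm$label[[i]], "' to the ontology. ",
        "A candidate definition: ", tm$definition[[i]], " ",
        if (length(parentLabels))
          paste0("It should be classified under ",
                 paste(parentLabels, collapse = " and "), ".")
        else "")
      IssueRecord(k, paste0("New term request: ", tm$label[[i]]), body,
                  c("Thanks, this fits the current design pattern.",
                    "Scheduled for the next release."))
    })
  })
}
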