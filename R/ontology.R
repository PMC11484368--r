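#' Construct an ontology graph
#'
#' @param terms data.frame with columns `curie`, `label`, `definition`
#'   (NA allowed) and `creationDate` (ISO date string or NA).
#' @param edges data.frame with columns `subject`, `predicate`, `object`;
#'   the is-a predicate is the literal string `"SubClassOf"`, other
#'   predicates are CURIEs.
#' @param logicalDefinitions named list (by defined-class CURIE) of
#'   `list(genus = <curie>, differentia = data.frame(predicate, target))`
#'   genus--differentia axioms.
#' @param predicateLabels named character vector mapping relationship-type
#'   CURIEs to their labels.
#' @return an `OntologyGraph`.
#' @export
OntologyGraph <- function(terms, edges = NULL, logicalDefinitions = list(),
                          predicateLabels = character(0)) {
  if (is.null(edges))
    edges <- data.frame(subject = character(0), predicate = character(0),
                        object = character(0), stringsAsFactors = FALSE)
  for (col in c("definition", "creationDate"))
    if (!col %in% names(terms)) terms[[col]] <- NA_character_
  terms <- terms[, c("curie", "label", "definition", "creationDate")]
  terms[] <- lapply(terms, as.character)
  edges[] <- lapply(edges, as.character)
  rownames(terms) <- NULL
  rownames(edges) <- NULL
  new("OntologyGraph", terms = terms, edges = edges,
      logicalDefinitions = logicalDefinitions,
      predicateLabels = predicateLabels)
}

## Contract an IRI to a CURIE; pass CURIEs through.
.contractId <- function(id) {
  if (grepl("^https?://", id)) {
    frag <- sub(".*[/#]", "", id)
    return(sub("_", ":", frag))
  }
  id
}

.IS_A_PREDICATES <- c("is_a", "subClassOf", "rdfs:subClassOf")

.nodeCreationDate <- function(meta) {
  bpv <- meta[["basicPropertyValues"]]
  if (is.null(bpv)) return(NA_character_)
  for (pv in bpv) {
    pred <- .contractId(pv[["pred"]] %||% "")
    if (grepl("creation_date|creationDate|date", pred, ignore.case = TRUE)) {
      val <- pv[["val"]]
      if (!is.null(val)) return(substr(as.character(val), 1L, 10L))
    }
  }
  NA_character_
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load an ontology from OBO Graph JSON
#'
#' Reads the `nodes` / `edges` / `logicalDefinitionAxioms` arrays of an
#' OBO Graph JSON document. Obsolete or unlabeled classes are skipped with
#' a warning (they cannot be symbolized); edges with an endpoint that was
#' not loaded are dropped with a warning rather than failing the load.
#' `oio:creationDate`-style annotations are parsed into per-term creation
#' dates when present. Logical-definition axioms are kept only in simple
#' genus--differentia form (exactly one genus).
#'
#' @param path path to an OBO Graph JSON file.
#' @param format currently only `"obograph-json"`.
#' @return an [OntologyGraph()].
#' @export
loadOntology <- function(path, format = c("obograph-json")) {
  format <- match.arg(format)
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    .ontoragError(paste("cannot parse", path, ":",
                                        conditionMessage(e)), "malformedFile"))
  graphs <- doc[["graphs"]]
  if (is.null(graphs))
    .ontoragError("no 'graphs' array in document", "malformedFile")

  curies <- character(0); labels <- character(0)
  definitions <- character(0); dates <- character(0)
  predicateLabels <- character(0)
  nSkipped <- 0L

  for (g in graphs) {
    for (node in g[["nodes"]] %||% list()) {
      id <- .contractId(node[["id"]] %||% "")
      type <- node[["type"]] %||% "CLASS"
      meta <- node[["meta"]] %||% list()
      lbl <- node[["lbl"]]
      if (type == "PROPERTY") {
        if (!is.null(lbl)) predicateLabels[[id]] <- lbl
        next
      }
      if (type != "CLASS") next
      if (isTRUE(meta[["deprecated"]]) || is.null(lbl) || !nzchar(lbl)) {
        nSkipped <- nSkipped + 1L
        next
      }
      curies <- c(curies, id)
      labels <- c(labels, lbl)
      definitions <- c(definitions,
                       as.character(meta[["definition"]][["val"]] %||% NA))
      dates <- c(dates, .nodeCreationDate(meta))
    }
  }
  if (nSkipped > 0L)
    warning(nSkipped, " obsolete or unlabeled node(s) skipped", call. = FALSE)
  if (!length(curies))
    .ontoragError("no usable classes in document", "malformedFile")

  keep <- !duplicated(curies)
  terms <- data.frame(curie = curies[keep], label = labels[keep],
                      definition = definitions[keep],
                      creationDate = dates[keep], stringsAsFactors = FALSE)
  known <- terms$curie

  subj <- character(0); pred <- character(0); obj <- character(0)
  nDangling <- 0L
  for (g in graphs) {
    for (edge in g[["edges"]] %||% list()) {
      s <- .contractId(edge[["sub"]] %||% "")
      p <- edge[["pred"]] %||% ""
      o <- .contractId(edge[["obj"]] %||% "")
      p <- if (p %in% .IS_A_PREDICATES) "SubClassOf" else .contractId(p)
      if (!(s %in% known) || !(o %in% known)) {
        nDangling <- nDangling + 1L
        next
      }
      subj <- c(subj, s); pred <- c(pred, p); obj <- c(obj, o)
    }
  }
  if (nDangling > 0L)
    warning(nDangling, " edge(s) referencing unknown terms dropped",
            call. = FALSE)
  edges <- unique(data.frame(subject = subj, predicate = pred, object = obj,
                             stringsAsFactors = FALSE))

  logicalDefs <- list()
  for (g in graphs) {
    axioms <- g[["logicalDefinitionAxioms"]] %||%
      g[["meta"]][["logicalDefinitionAxioms"]] %||% list()
    for (ax in axioms) {
      defined <- .contractId(ax[["definedClassId"]] %||% "")
      genusIds <- vapply(ax[["genusIds"]] %||% list(), .contractId, character(1))
      if (length(genusIds) != 1L) next   # nested/multi-genus forms unsupported
      restr <- ax[["restrictions"]] %||% list()
      rp <- character(0); rf <- character(0)
      ok <- defined %in% known && genusIds %in% known
      for (r in restr) {
        p <- .contractId(r[["propertyId"]] %||% "")
        f <- .contractId(r[["fillerId"]] %||% "")
        if (!(f %in% known)) { ok <- FALSE; break }
        rp <- c(rp, p); rf <- c(rf, f)
      }
      if (!ok) next
      logicalDefs[[defined]] <- list(genus = genusIds,
                                     differentia = .relFrame(rp, rf))
    }
  }

  OntologyGraph(terms, edges, logicalDefs, predicateLabels)
}

#' Write an ontology graph as OBO Graph JSON
#'
#' Emits nodes (with definition and creation-date annotations), PROPERTY
#' nodes for relationship types, edges (is-a as `is_a`), and simple
#' genus--differentia `logicalDefinitionAxioms`, so a written graph can
#' be re-read with [loadOntology()].
#'
#' @param graph an [OntologyGraph()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeOntologyJSON <- function(graph, path) {
  tm <- graph@terms
  nodes <- lapply(seq_len(nrow(tm)), function(i) {
    meta <- list()
    if (!is.na(tm$definition[[i]]))
      meta$definition <- list(val = tm$definition[[i]])
    if (!is.na(tm$creationDate[[i]]))
      meta$basicPropertyValues <- list(list(
        pred = "http://www.geneontology.org/formats/oboInOwl#creation_date",
        val = tm$creationDate[[i]]))
    node <- list(id = tm$curie[[i]], lbl = tm$label[[i]], type = "CLASS")
    if (length(meta)) node$meta <- meta
    node
  })
  pl <- graph@predicateLabels
  for (curie in names(pl)) {
    nodes[[length(nodes) + 1L]] <- list(id = curie, lbl = pl[[curie]],
                                        type = "PROPERTY")
  }
  ed <- graph@edges
  edges <- lapply(seq_len(nrow(ed)), function(i) {
    list(sub = ed$subject[[i]],
         pred = if (ed$predicate[[i]] == "SubClassOf") "is_a"
                else ed$predicate[[i]],
         obj = ed$object[[i]])
  })
  ld <- graph@logicalDefinitions
  axioms <- lapply(names(ld), function(curie) {
    ax <- ld[[curie]]
    list(definedClassId = curie, genusIds = list(ax$genus),
         restrictions = lapply(seq_len(nrow(ax$differentia)), function(i)
           list(propertyId = ax$differentia$predicate[[i]],
                fillerId = ax$differentia$target[[i]])))
  })
  doc <- list(graphs = list(list(nodes = nodes, edges = edges,
                                 logicalDefinitionAxioms = axioms)))
  writeLines(.toStableJSON(doc), path)
  invisible(path)
}
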