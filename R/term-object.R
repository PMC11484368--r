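#' Construct a term object
#'
#' A term object is the JSON-friendly representation of one ontology
#' class: a camel-case symbol `id`, the original CURIE, the label, an
#' optional textual definition, a list of `(predicate, target)`
#' relationships in symbol space, and an optional genus--differentia
#' logical definition (the entry with predicate `SubClassOf` is the
#' genus; all others are differentia).
#'
#' @param id camel-case symbol (optional).
#' @param label term label.
#' @param definition textual definition, or `NULL`.
#' @param relationships data.frame with `predicate` and `target` columns.
#' @param logicalDefinitions data.frame with `predicate` and `target`
#'   columns containing exactly one `SubClassOf` row when non-empty.
#' @param originalId the untranslated CURIE (optional).
#' @return a `TermObject`.
#' @export
TermObject <- function(label = NULL, definition = NULL,
                       relationships = NULL, logicalDefinitions = NULL,
                       id = NULL, originalId = NULL) {
  new("TermObject",
      id = as.character(id %||% character(0)),
      originalId = as.character(originalId %||% character(0)),
      label = as.character(label %||% character(0)),
      definition = as.character(definition %||% character(0)),
      relationships = if (is.null(relationships)) .relFrame()
                      else .relFrame(relationships$predicate,
                                     relationships$target),
      logicalDefinitions = if (is.null(logicalDefinitions)) .relFrame()
                           else .relFrame(logicalDefinitions$predicate,
                                          logicalDefinitions$target))
}

.edgePredicateSymbol <- function(predicate, table) {
  if (predicate == "SubClassOf") "SubClassOf" else symbolOf(table, predicate)
}

#' Translate a graph term into its term-object form
#'
#' All outgoing edges of the term become relationship entries with
#' symbolized predicate and target; the is-a predicate is rendered
#' literally as `SubClassOf`. Definition provenance (xrefs) is never
#' emitted. A genus--differentia logical definition, when present, is
#' rendered with the genus as the single `SubClassOf` entry.
#'
#' @param graph an [OntologyGraph()].
#' @param curie the term's CURIE.
#' @param table a [SymbolTable()] covering the graph (see
#'   [buildSymbolTable()]).
#' @return a [TermObject()].
#' @export
termToObject <- function(graph, curie, table) {
  tm <- graph@terms
  i <- match(curie, tm$curie)
  if (is.na(i))
    .ontoragError(paste("unknown term:", curie), "unknownTerm")
  out <- graph@edges[graph@edges$subject == curie, , drop = FALSE]
  rels <- .relFrame(
    vapply(out$predicate, .edgePredicateSymbol, character(1), table = table),
    vapply(out$object, function(o) symbolOf(table, o), character(1)))
  ld <- .relFrame()
  axiom <- graph@logicalDefinitions[[curie]]
  if (!is.null(axiom)) {
    preds <- c("SubClassOf",
               vapply(axiom$differentia$predicate, .edgePredicateSymbol,
                      character(1), table = table))
    targets <- c(symbolOf(table, axiom$genus),
                 vapply(axiom$differentia$target,
                        function(o) symbolOf(table, o), character(1)))
    ld <- .relFrame(preds, targets)
  }
  def <- tm$definition[[i]]
  TermObject(label = tm$label[[i]],
             definition = if (is.na(def)) NULL else def,
             relationships = rels,
             logicalDefinitions = ld,
             id = symbolOf(table, curie),
             originalId = curie)
}

#' Serialize a term object to embedding text
#'
#' Deterministic key-value text used as embedding input: one line per
#' present field in fixed order (label, definition, relationships), with
#' relationships rendered as `predicate: target` pairs. Identical terms
#' always yield byte-identical strings.
#'
#' @param x a [TermObject()] (or `PartialTerm`).
#' @return a single string.
#' @export
setMethod("serializeForEmbedding", "TermObject", function(x) {
  if (!length(x@label))
    .ontoragError("term must have at least a label", "emptyLabel")
  lines <- paste0("label: ", x@label)
  if (length(x@definition))
    lines <- c(lines, paste0("definition: ", x@definition))
  if (nrow(x@relationships)) {
    pairs <- paste0(x@relationships$predicate, ": ", x@relationships$target)
    lines <- c(lines, paste0("relationships: ", paste(pairs, collapse = "; ")))
  }
  paste(lines, collapse = "\n")
})

#' Mask a term field for a prediction task
#'
#' Removes the field to be predicted (recording it in
#' `fieldsToComplete`) and always removes the term identifiers, which are
#' a source of training-data leakage. For the relationships task only the
#' label and textual definition remain in the input.
#'
#' @param term a complete [TermObject()].
#' @param task one of `"relationships"`, `"definition"`,
#'   `"logical_definitions"`.
#' @return a `PartialTerm`.
#' @export
maskTerm <- function(term,
                     task = c("relationships", "definition",
                              "logical_definitions")) {
  task <- match.arg(task)
  goldPresent <- switch(task,
    relationships = nrow(term@relationships) > 0L,
    definition = length(term@definition) > 0L,
    logical_definitions = nrow(term@logicalDefinitions) > 0L)
  if (!goldPresent)
    .ontoragError(paste("term lacks the gold field for task", task),
                  "missingGoldField")
  label <- term@label
  definition <- term@definition
  relationships <- term@relationships
  logicalDefs <- term@logicalDefinitions
  if (task == "relationships") {
    # input carries only label and textual definition
    relationships <- .relFrame()
    logicalDefs <- .relFrame()
  } else if (task == "definition") {
    definition <- character(0)
  } else {
    logicalDefs <- .relFrame()
  }
  new("PartialTerm",
      id = character(0), originalId = character(0),
      label = label, definition = definition,
      relationships = relationships, logicalDefinitions = logicalDefs,
      fieldsToComplete = task)
}

## ---- JSON / YAML round-trip ----------------------------------------------

.termToList <- function(term, fields = NULL) {
  all <- list()
  if (length(term@id)) all$id <- term@id
  if (length(term@originalId)) all$original_id <- term@originalId
  if (length(term@label)) all$label <- term@label
  if (length(term@definition)) all$definition <- term@definition
  if (nrow(term@relationships))
    all$relationships <- lapply(seq_len(nrow(term@relationships)), function(i)
      list(predicate = term@relationships$predicate[[i]],
           target = term@relationships$target[[i]]))
  if (nrow(term@logicalDefinitions))
    all$logical_definitions <-
      lapply(seq_len(nrow(term@logicalDefinitions)), function(i)
        list(predicate = term@logicalDefinitions$predicate[[i]],
             target = term@logicalDefinitions$target[[i]]))
  if (!is.null(fields)) all <- all[intersect(names(all), fields)]
  all
}

.relsFromList <- function(entries) {
  if (is.null(entries) || !length(entries)) return(NULL)
  keep <- vapply(entries, function(e)
    is.list(e) && !is.null(e$predicate) && !is.null(e$target), logical(1))
  entries <- entries[keep]
  if (!length(entries)) return(NULL)
  .relFrame(vapply(entries, function(e) as.character(e$predicate), character(1)),
            vapply(entries, function(e) as.character(e$target), character(1)))
}

.termFromList <- function(x) {
  TermObject(label = x$label, definition = x$definition,
             relationships = .relsFromList(x$relationships),
             logicalDefinitions = .relsFromList(x$logical_definitions),
             id = x$id, originalId = x$original_id)
}

#' Read and write term objects as JSON or YAML
#'
#' Both dialects round-trip: `readTermObject(writeTermObject(x, f), ...)`
#' recovers `x` field for field.
#'
#' @param term a [TermObject()].
#' @param path file path; the format is inferred from the extension
#'   (`.json` vs `.yaml`/`.yml`) unless given explicitly.
#' @param format `"json"` or `"yaml"`.
#' @return `writeTermObject` returns `path` invisibly; `readTermObject`
#'   returns a [TermObject()].
#' @export
writeTermObject <- function(term, path, format = NULL) {
  format <- format %||% if (grepl("\\.ya?ml$", path)) "yaml" else "json"
  x <- .termToList(term)
  if (format == "yaml") {
    yaml::write_yaml(x, path)
  } else {
    writeLines(.toStableJSON(x), path)
  }
  invisible(path)
}

#' @rdname writeTermObject
#' @export
readTermObject <- function(path, format = NULL) {
  format <- format %||% if (grepl("\\.ya?ml$", path)) "yaml" else "json"
  x <- if (format == "yaml") yaml::read_yaml(path)
       else jsonlite::fromJSON(path, simplifyVector = FALSE)
  .termFromList(x)
}

#' Construct a partial term directly
#'
#' @param fieldsToComplete which fields the completion should fill.
#' @inheritParams TermObject
#' @return a `PartialTerm`.
#' @export
PartialTerm <- function(label = NULL, definition = NULL,
                        relationships = NULL, logicalDefinitions = NULL,
                        fieldsToComplete = "relationships") {
  base <- TermObject(label = label, definition = definition,
                     relationships = relationships,
                     logicalDefinitions = logicalDefinitions)
  new("PartialTerm", base, fieldsToComplete = fieldsToComplete)
}
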