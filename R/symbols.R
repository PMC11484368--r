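#' Create an empty symbol table
#'
#' A symbol table maintains a bijection between ontology CURIEs (e.g.
#' `CL:1001502`) and human-readable camel-case symbols (e.g. `MitralCell`).
#' Numeric identifiers are notoriously easy for language models to
#' hallucinate, so every identifier shown to, or accepted from, a
#' generation backend goes through this table.
#'
#' @return a `SymbolTable` object.
#' @export
SymbolTable <- function() {
  new("SymbolTable",
      forward = new.env(parent = emptyenv()),
      reverse = new.env(parent = emptyenv()))
}

## Predicate symbol for is-a; reserved, never assigned to a term.
.RESERVED_SYMBOLS <- "SubClassOf"

.camelCase <- function(label) {
  words <- strsplit(label, "[^A-Za-z0-9]+")[[1L]]
  words <- words[nzchar(words)]
  if (!length(words)) return("")
  sym <- paste(vapply(words, function(w) {
    paste0(toupper(substr(w, 1L, 1L)), substring(w, 2L))
  }, character(1)), collapse = "")
  # symbols must start with a letter
  if (grepl("^[0-9]", sym)) sym <- paste0("X", sym)
  sym
}

#' Translate a label to a camel-case symbol
#'
#' Words are split on whitespace, hyphens and other punctuation, each word
#' is capitalized, the words are concatenated, and non-alphanumeric
#' characters are removed ("mitral cell" becomes `MitralCell`). When a
#' `table` and `curie` are supplied the symbol is registered bijectively:
#' if a distinct CURIE already owns the symbol, a numeric suffix (2, 3,
#' ...) is appended. `SubClassOf` is reserved for the is-a predicate and
#' is never assigned to a term.
#'
#' @param label term label; must contain at least one alphanumeric character.
#' @param table optional `SymbolTable` to register the symbol in.
#' @param curie the CURIE the symbol stands for (required with `table`).
#' @return the symbol, a string matching `[A-Za-z][A-Za-z0-9]*`.
#' @examples
#' symbolize("mitral cell")
#' @export
symbolize <- function(label, table = NULL, curie = NULL) {
  if (!is.character(label) || length(label) != 1L || !nzchar(trimws(label)))
    .ontoragError("label must be a non-empty string", "emptyLabel")
  base <- .camelCase(label)
  if (!nzchar(base))
    .ontoragError("label has no alphanumeric content", "emptyLabel")
  if (is.null(table)) return(base)
  if (is.null(curie))
    .ontoragError("curie is required when registering in a table", "missingCurie")
  existing <- get0(curie, envir = table@forward, inherits = FALSE)
  if (!is.null(existing)) return(existing)
  candidate <- base
  suffix <- 1L
  while (candidate %in% .RESERVED_SYMBOLS ||
         !is.null(get0(candidate, envir = table@reverse, inherits = FALSE))) {
    suffix <- suffix + 1L
    candidate <- paste0(base, suffix)
  }
  assign(curie, candidate, envir = table@forward)
  assign(candidate, curie, envir = table@reverse)
  candidate
}

#' @rdname accessors
#' @export
setMethod("symbolOf", "SymbolTable", function(table, curie) {
  out <- get0(curie, envir = table@forward, inherits = FALSE)
  if (is.null(out))
    .ontoragError(paste("no symbol registered for", curie), "unknownTerm")
  out
})

#' @rdname accessors
#' @export
setMethod("resolveSymbol", "SymbolTable", function(table, symbol) {
  out <- get0(symbol, envir = table@reverse, inherits = FALSE)
  if (is.null(out))
    .ontoragError(paste("unknown symbol:", symbol), "unknownSymbol")
  out
})

#' @rdname accessors
#' @export
setMethod("hasSymbol", "SymbolTable", function(table, symbol) {
  !is.null(get0(symbol, envir = table@reverse, inherits = FALSE))
})

#' Build a symbol table for a whole ontology graph
#'
#' Registers every term label and every relationship-type label, in graph
#' order, so repeated builds over the same graph yield identical symbols.
#'
#' @param graph an `OntologyGraph`.
#' @return a populated `SymbolTable`.
#' @export
buildSymbolTable <- function(graph) {
  table <- SymbolTable()
  tm <- graph@terms
  for (i in seq_len(nrow(tm))) {
    symbolize(tm$label[[i]], table, tm$curie[[i]])
  }
  pl <- graph@predicateLabels
  for (curie in names(pl)) {
    symbolize(pl[[curie]], table, curie)
  }
  table
}
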