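## Internal helpers shared across modules.

.ontoragError <- function(message, class) {
  stop(errorCondition(message, class = c(class, "ontoragError")))
}

## Lower-case alphanumeric word tokens; the unit for both the hashing
## embedding backend and the greedy definition-similarity matcher.
.tokenize <- function(text) {
  tokens <- strsplit(tolower(text), "[^a-z0-9]+")[[1L]]
  tokens[nzchar(tokens)]
}

## Largest prime below 2^26: guarantees h * 131 + code < 2^53, so the
## rolling hash is exact in doubles and identical on every platform,
## independent of R's RNG state.
.HASH_PRIME <- 67108859

.stableHash <- function(token, seed = 0L) {
  h <- as.numeric(seed) %% .HASH_PRIME
  for (code in utf8ToInt(token)) {
    h <- (h * 131 + code) %% .HASH_PRIME
  }
  h
}

.l2normalize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) v else v / n
}

.cosine <- function(a, b) {
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

## Evaluate expr under a fixed RNG seed, restoring the caller's stream.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

## Stable JSON serialization used wherever byte-identical output matters.
.toStableJSON <- function(x) {
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null"))
}

## Extract top-level balanced {...} substrings from free text, honouring
## JSON string literals and escapes, so replies wrapped in prose or code
## fences can still be parsed.
.extractBalancedObjects <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  out <- character(0)
  depth <- 0L
  start <- NA_integer_
  inString <- FALSE
  escaped <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[[i]]
    if (inString) {
      if (escaped) {
        escaped <- FALSE
      } else if (ch == "\\") {
        escaped <- TRUE
      } else if (ch == "\"") {
        inString <- FALSE
      }
      next
    }
    if (ch == "\"" && depth > 0L) {
      inString <- TRUE
    } else if (ch == "{") {
      if (depth == 0L) start <- i
      depth <- depth + 1L
    } else if (ch == "}") {
      if (depth > 0L) {
        depth <- depth - 1L
        if (depth == 0L) {
          out <- c(out, substr(text, start, i))
          start <- NA_integer_
        }
      }
    }
  }
  out
}

## data.frame(predicate, target) constructor used for relationship sets.
.relFrame <- function(predicate = character(0), target = character(0)) {
  data.frame(predicate = as.character(predicate), target = as.character(target),
             stringsAsFactors = FALSE)
}
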