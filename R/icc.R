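#' Read and write rating sheets
#'
#' Rating sheets are CSV files with columns `term_id`, `source`,
#' `metric`, `value`, `confidence`, `evaluator_id`, `notes`, mirroring
#' the spreadsheets evaluators fill in: one row per 1--5 ordinal score
#' (metric `accuracy`, `consistency` or `score`) given by one evaluator
#' to one definition, with an optional 1--5 confidence.
#'
#' @param path CSV file path.
#' @param ratings a ratings data.frame.
#' @return `readRatings` returns the ratings data.frame.
#' @export
readRatings <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("term_id", "source", "metric", "value", "evaluator_id")
  missing <- setdiff(need, names(df))
  if (length(missing))
    .ontoragError(paste("rating sheet lacks columns:",
                        paste(missing, collapse = ", ")), "malformedFile")
  if (!"confidence" %in% names(df)) df$confidence <- NA_integer_
  df
}

#' @rdname readRatings
#' @export
writeRatings <- function(ratings, path) {
  utils::write.csv(ratings, path, row.names = FALSE)
  invisible(path)
}

#' Intraclass correlation coefficient from a one-way ANOVA
#'
#' Inter-rater reliability of ordinal ratings, treating the evaluator as
#' a random grouping factor: from the one-way ANOVA mean squares between
#' evaluators (MSB) and within evaluators (MSE),
#' `ICC = (MSB - MSE) / (MSB + (k - 1) * MSE)`, with `k` the (mean, if
#' unbalanced) number of ratings per evaluator. Ratings can first be
#' filtered to a minimum confidence, which probes how reliability moves
#' with evaluator confidence.
#'
#' @param ratings ratings data.frame (see [readRatings()]).
#' @param metric which metric to analyse (`"accuracy"`, `"consistency"`
#'   or `"score"`).
#' @param minConfidence keep ratings with `confidence >= minConfidence`;
#'   at the default 1, ratings without a confidence are kept too.
#' @return an `ICCResult`.
#' @export
icc <- function(ratings, metric = c("score", "accuracy", "consistency"),
                minConfidence = 1L) {
  metric <- match.arg(metric)
  df <- ratings[ratings$metric == metric, , drop = FALSE]
  conf <- df$confidence
  if (minConfidence > 1L) {
    df <- df[!is.na(conf) & conf >= minConfidence, , drop = FALSE]
  }
  groups <- split(as.numeric(df$value), df$evaluator_id)
  groups <- groups[vapply(groups, length, integer(1)) >= 2L]
  if (length(groups) < 2L)
    .ontoragError("need at least 2 evaluators with at least 2 ratings each",
                  "insufficientData")
  sizes <- vapply(groups, length, integer(1))
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(sizes * means) / sum(sizes)
  ssb <- sum(sizes * (means - grand)^2)
  sse <- sum(vapply(seq_along(groups), function(i)
    sum((groups[[i]] - means[[i]])^2), numeric(1)))
  dfb <- length(groups) - 1L
  dfe <- sum(sizes) - length(groups)
  msb <- ssb / dfb
  mse <- sse / dfe
  k <- mean(sizes)
  if (msb == 0 && mse == 0)
    .ontoragError("no variance between or within evaluators",
                  "degenerateVariance")
  iccValue <- (msb - mse) / (msb + (k - 1) * mse)
  new("ICCResult", metric = metric, icc = iccValue, msb = msb, mse = mse,
      k = k, nGroups = length(groups), nRatings = as.integer(sum(sizes)))
}

#' Performance gap between human and model ratings by confidence level
#'
#' For each confidence level `c` in 1..5 the gap is the mean human score
#' minus the mean model score among ratings given with that confidence;
#' the Pearson correlation between level and gap measures whether more
#' confident evaluators discriminate more sharply between human-authored
#' and generated definitions.
#'
#' @param ratings ratings data.frame (see [readRatings()]).
#' @param humanSource,modelSource values of the `source` column to
#'   compare.
#' @param metric which metric's values to use.
#' @return list with `levels`, `gaps`, `pearsonR` and `flagged` (`TRUE`
#'   with `pearsonR = NA` when the gaps have zero variance).
#' @export
confidenceGapCorrelation <- function(ratings, humanSource, modelSource,
                                     metric = "score") {
  df <- ratings[ratings$metric == metric & !is.na(ratings$confidence), ,
                drop = FALSE]
  levels <- sort(unique(df$confidence))
  gaps <- numeric(0)
  keptLevels <- integer(0)
  for (cl in levels) {
    atLevel <- df[df$confidence == cl, , drop = FALSE]
    hv <- as.numeric(atLevel$value[atLevel$source == humanSource])
    mv <- as.numeric(atLevel$value[atLevel$source == modelSource])
    if (!length(hv) || !length(mv)) next
    keptLevels <- c(keptLevels, cl)
    gaps <- c(gaps, mean(hv) - mean(mv))
  }
  if (length(keptLevels) < 3L)
    .ontoragError("need at least 3 confidence levels with both sources",
                  "insufficientLevels")
  if (stats::sd(gaps) == 0) {
    return(list(levels = keptLevels, gaps = gaps, pearsonR = NA_real_,
                flagged = TRUE))
  }
  list(levels = keptLevels, gaps = gaps,
       pearsonR = stats::cor(keptLevels, gaps), flagged = FALSE)
}
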