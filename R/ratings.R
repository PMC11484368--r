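#' Generate a synthetic rating sheet
#'
#' Draws 1--5 ordinal ratings for human-curated and model-generated
#' definitions from configurable distributions, so the inter-rater (ICC)
#' and confidence-gap analyses can be exercised offline. Each evaluator
#' rates every term for both sources. Model scores are pulled down as
#' the evaluator's confidence rises (`gapSlope` points per confidence
#' level), emulating the pattern that confident domain experts are
#' better at spotting flaws in generated definitions.
#'
#' @param nTerms number of rated definitions per source.
#' @param evaluators character vector of evaluator ids (>= 2 for ICC).
#' @param humanMean latent mean score of human-curated definitions.
#' @param modelMean latent mean score of generated definitions at the
#'   lowest confidence level.
#' @param gapSlope additional downward shift of model scores per
#'   confidence level above 1.
#' @param sd latent score standard deviation before rounding/clamping.
#' @param consistencyRate probability that the optional consistency
#'   metric is scored.
#' @param seed RNG seed.
#' @return a ratings data.frame (see [readRatings()] for the columns).
#' @export
generateRatings <- function(nTerms = 25L, evaluators = c("ev1", "ev2"),
                            humanMean = 4.4, modelMean = 4.2,
                            gapSlope = 0.35, sd = 0.7,
                            consistencyRate = 0.7, seed = 1L) {
  .withSeed(seed, {
    rows <- list()
    clamp <- function(x) pmin(5L, pmax(1L, as.integer(round(x))))
    for (ev in evaluators) {
      for (term in seq_len(nTerms)) {
        confidence <- sample(1:5, 1L)
        for (source in c("human", "model")) {
          latentMean <- if (source == "human") humanMean
                        else modelMean - gapSlope * (confidence - 1L)
          for (metric in c("accuracy", "score",
                           if (stats::runif(1L) < consistencyRate)
                             "consistency")) {
            rows[[length(rows) + 1L]] <- data.frame(
              term_id = sprintf("T%03d", term), source = source,
              metric = metric,
              value = clamp(stats::rnorm(1L, latentMean, sd)),
              confidence = confidence, evaluator_id = ev, notes = "",
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    do.call(rbind, rows)
  })
}
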