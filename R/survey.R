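# Synthetic ordinal survey generator: census-style ensembles with dominant
# period-3 cycling, for exercising the analysis stack when no field tables
# are available.

#' Configure the synthetic survey generator
#'
#' Defaults emulate a 15-year visual census of ~100 trees scored in 10
#' ordinal production classes: dominant ON-OFF-OFF (period-3) cycling with
#' a small per-tree phase jitter, occasional period-2 slips, a per-tree
#' chance of a failed (fruitless) on-year, and one population-wide
#' desynchronised year. Off-years and failed on-years draw from the two
#' lowest classes, successful on-years from the upper classes; with the
#' default period-3 timing this puts about 70% of all scores in the two
#' lowest classes.
#'
#' @param N,T trees and years.
#' @param nClasses ordinal classes (labels `0 .. nClasses-1`).
#' @param pSlip probability that a cycle shortens to period-2 (per cycle).
#' @param pFail probability that a tree fails to fruit in an on-year and is
#'   scored like an off-year.
#' @param phaseJitter probability a tree runs one year early/late.
#' @param desyncYears years (1-based) whose per-tree phases are scrambled
#'   (a +-2 year window around each is re-drawn per tree); mid-series years
#'   give the cleanest coherence collapse.
#' @param offClassProbs sampling weights of classes 0 and 1 in off-years.
#' @param onClassProbs sampling weights over all classes in on-years.
#' @param seed RNG seed.
#' @return a validated [SurveyConfig-class].
#' @export
surveyConfig <- function(N = 106, T = 15, nClasses = 10, pSlip = 0.08,
                         pFail = 0.12, phaseJitter = 0.1, desyncYears = 8L,
                         offClassProbs = c(0.6, 0.4),
                         onClassProbs = c(0, 0, 0, 0, 0.12, 0.16, 0.19,
                                          0.19, 0.18, 0.16),
                         seed = 1) {
  new("SurveyConfig", N = as.integer(N), T = as.integer(T),
      nClasses = as.integer(nClasses), pSlip = pSlip, pFail = pFail,
      phaseJitter = phaseJitter, desyncYears = as.integer(desyncYears),
      offClassProbs = offClassProbs / sum(offClassProbs),
      onClassProbs = onClassProbs / sum(onClassProbs),
      seed = as.integer(seed))
}

setMethod("show", "SurveyConfig", function(object) {
  cat(sprintf("SurveyConfig: %d trees x %d years, %d classes\n",
              object@N, object@T, object@nClasses))
  cat(sprintf("  pSlip = %g, pFail = %g, phaseJitter = %g, desync: %s, seed %d\n",
              object@pSlip, object@pFail, object@phaseJitter,
              paste(object@desyncYears, collapse = ", "), object@seed))
})

#' Generate a synthetic ordinal survey
#'
#' Each tree follows the ON-OFF-OFF template at a per-tree phase offset
#' (0, or +-1 year with probability `phaseJitter`); after each on-year the
#' next cycle is shortened to period-2 with probability `pSlip`. Successful
#' on-years take the year's shared on-class (drawn once per year from
#' `onClassProbs`: year quality is common to the population), but each tree
#' independently fails to fruit with probability `pFail` and is then scored
#' like an off-year; off-years draw the year's shared low class. Around
#' each desynchronised year every tree's cycle offset is redrawn
#' independently over a +-2 year window, which collapses the phase order
#' parameter at that year while the rest of the record stays coherent.
#' Output is reproducible from the seed.
#'
#' @param config a [SurveyConfig-class].
#' @return an [EnsembleSeries-class] of ordinal class values.
#' @examples
#' sv <- generateSurvey(surveyConfig(N = 20, T = 15, seed = 42))
#' table(seriesMatrix(sv) <= 1)  # roughly 70% in the two lowest classes
#' @export
generateSurvey <- function(config) {
  stopifnot(is(config, "SurveyConfig"))
  set.seed(config@seed)
  N <- config@N; T <- config@T; K <- config@nClasses
  j <- config@phaseJitter
  offsets <- sample(c(-1L, 0L, 1L), N, replace = TRUE,
                    prob = c(j / 2, 1 - j, j / 2))
  on <- matrix(0L, N, T)
  for (i in seq_len(N)) {
    t <- 1L + offsets[i]
    if (t < 1L) t <- t + 3L
    while (t <= T) {
      on[i, t] <- 1L
      t <- t + if (runif(1) < config@pSlip) 2L else 3L
    }
  }
  # desynchronised years: every tree runs at an independently drawn cycle
  # offset throughout a +-2 year window around the year. The window is
  # needed because the short-series Hilbert phase at a single year is
  # anchored by its neighbourhood; scrambling one isolated year barely
  # moves the phases, scrambling the local pattern collapses coherence.
  scrambleOffset <- vector("list", length(config@desyncYears))
  for (k in seq_along(config@desyncYears))
    scrambleOffset[[k]] <- sample(0:2, N, replace = TRUE)
  # one on-value and one off-value per year, shared by all trees in the same
  # cycle position: year-quality variation is common to the population, so a
  # noise-free configuration yields literally identical trees
  onVals <- sample.int(K, T, replace = TRUE, prob = config@onClassProbs) - 1L
  offVals <- sample.int(2L, T, replace = TRUE, prob = config@offClassProbs) - 1L
  cls <- matrix(rep(offVals, each = N), N, T)
  cls[on == 1L] <- rep(onVals, each = N)[on == 1L]
  # per-tree fruiting failure: an on-year scored like an off-year
  if (config@pFail > 0) {
    onIdx <- which(on == 1L)
    failed <- onIdx[runif(length(onIdx)) < config@pFail]
    cls[failed] <- sample.int(2L, length(failed), replace = TRUE,
                              prob = config@offClassProbs) - 1L
  }
  for (k in seq_along(config@desyncYears)) {
    y <- config@desyncYears[k]
    so <- scrambleOffset[[k]]
    for (t in max(1L, y - 2L):min(T, y + 2L)) {
      isOn <- (t - 1L + so) %% 3L == 0L
      cls[isOn, t] <- sample.int(K, sum(isOn), replace = TRUE,
                                 prob = config@onClassProbs) - 1L
      cls[!isOn, t] <- sample.int(2L, sum(!isOn), replace = TRUE,
                                  prob = config@offClassProbs) - 1L
    }
  }
  ensembleSeries(cls, treeIds = sprintf("tree%03d", seq_len(N)),
                 years = seq_len(T))
}

#' Quantize continuous production into ordinal classes
#'
#' Equal-width bins on `[0, max(values)]`, labelled `0 .. nClasses-1`, with
#' the maximum mapped to the top class. Bridges simulated seed production
#' to survey-style class data. An all-zero input maps to class 0
#' throughout.
#'
#' @param values non-negative numeric matrix or vector.
#' @param nClasses number of classes (default 10).
#' @return integer matrix/vector of class labels.
#' @examples
#' quantizeToClasses(c(0, 50, 99), 10)  # 0, 5, 9
#' @export
quantizeToClasses <- function(values, nClasses = 10L) {
  v <- if (is(values, "EnsembleSeries")) values@values else values
  if (any(v < 0) || any(!is.finite(v))) stop("values must be finite and non-negative")
  mx <- max(v)
  if (mx == 0) {
    cls <- v
    cls[] <- 0L
    return(cls)
  }
  cls <- pmin(as.integer(floor(v / mx * nClasses)), nClasses - 1L)
  if (is.matrix(v)) cls <- matrix(cls, nrow(v), dimnames = dimnames(v))
  cls
}
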