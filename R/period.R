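# Period-composition statistic FP(Q) and the pairwise in-phase fraction.

#' Fraction of period-Q motifs in one on/off sequence
#'
#' A period-Q motif is one on-year followed by Q-1 off-years and another
#' on-year at lag Q. The motif count over `t = 1..T-Q` is scaled by
#' `Q / ((T-1) - (T-1) mod Q)` so a perfect period-Q train scores 1, and the
#' result is clipped to `[0, 1]`.
#'
#' The intermediate off-year requirement spans all lags `1..Q-1`. A `strict`
#' variant restricts the off-year product to lags `2..Q-1` (leaving the year
#' immediately after the on-year unconstrained), retained for comparison
#' with the more permissive formula sometimes written down; the default
#' matches the verbal "one on-year followed by Q-1 off-years" definition.
#'
#' @param flags binary vector of length T (or an [OnOffFlags-class] row).
#' @param Q target period, >= 2.
#' @param strict use the permissive lag-2..Q-1 off-year product.
#' @return fraction in `[0, 1]`; 0 with a warning when `T <= Q`.
#' @examples
#' fractionPeriod(c(1, 0, 0, 1, 0, 0, 1), 3)  # perfect period-3: 1
#' fractionPeriod(c(1, 0, 1, 0, 1, 0, 1), 2)  # perfect period-2: 1
#' @export
fractionPeriod <- function(flags, Q, strict = FALSE) {
  stopifnot(Q >= 2)
  on <- as.integer(flags)
  T <- length(on)
  if (T <= Q) {
    warning(sprintf("series length %d too short for period %d", T, Q))
    return(0)
  }
  offLags <- if (strict) {
    if (Q > 2L) 2L:(Q - 1L) else integer(0)
  } else seq_len(Q - 1L)
  cnt <- 0L
  for (t in seq_len(T - Q)) {
    if (on[t] == 1L && on[t + Q] == 1L && all(on[t + offLags] == 0L))
      cnt <- cnt + 1L
  }
  min(1, max(0, cnt * Q / ((T - 1L) - (T - 1L) %% Q)))
}

#' Period composition of a population
#'
#' Applies [fractionPeriod()] per tree and period, then pools over trees
#' (mean by default; median and mode are available as alternative
#' population summaries).
#'
#' @param flags an [OnOffFlags-class] or binary N x T matrix.
#' @param Q integer vector of periods to evaluate (default 2:6).
#' @param reducer "mean", "median" or "mode".
#' @param strict see [fractionPeriod()].
#' @return a [PeriodFractions-class].
#' @examples
#' f <- matrix(rep(c(1, 0, 0), 5), nrow = 3, ncol = 15, byrow = TRUE)
#' populationFractions(periodFractions(f))
#' @export
periodFractions <- function(flags, Q = 2:6, reducer = c("mean", "median", "mode"),
                            strict = FALSE) {
  reducer <- match.arg(reducer)
  f <- if (is(flags, "OnOffFlags")) flags@flags else as.matrix(flags)
  Q <- as.integer(Q)
  perTree <- vapply(Q, function(q)
    apply(f, 1L, fractionPeriod, Q = q, strict = strict),
    numeric(nrow(f)))
  perTree <- matrix(perTree, nrow = nrow(f),
                    dimnames = list(rownames(f), Q))
  pop <- switch(reducer,
    mean = colMeans(perTree),
    median = apply(perTree, 2L, median),
    mode = apply(perTree, 2L, function(v) {
      d <- density(v, from = 0, to = 1)
      d$x[which.max(d$y)]
    }))
  new("PeriodFractions", perTree = perTree, population = pop, Q = Q,
      reducer = reducer)
}

#' @rdname PeriodFractions-class
#' @export
setMethod("perTreeFractions", "PeriodFractions", function(x) x@perTree)

#' @rdname PeriodFractions-class
#' @export
setMethod("populationFractions", "PeriodFractions", function(x)
  setNames(x@population, x@Q))

setMethod("show", "PeriodFractions", function(object) {
  cat(sprintf("PeriodFractions (%s over %d trees):\n",
              object@reducer, nrow(object@perTree)))
  print(round(setNames(object@population, paste0("FP(", object@Q, ")")), 4))
})

#' Pairwise in-phase synchrony fraction
#'
#' For each pair of trees and each year transition, the product of the two
#' year-on-year production changes classifies the pair as in-phase (positive
#' product, or both changes exactly zero) or out-of-phase. `fInT` averages
#' over all pairs per transition; `FIN` is the time mean. A pair with
#' exactly one zero change counts as out-of-phase.
#'
#' The per-year value is accumulated by sign counts, which is algebraically
#' identical to the literal double sum over ordered pairs.
#'
#' @param series an [EnsembleSeries-class] or numeric N x T matrix, N >= 2,
#'   T >= 2.
#' @return a [SyncFractions-class].
#' @examples
#' x <- rbind(c(1, 5, 1, 5), c(2, 9, 2, 9))  # locked pair
#' inPhaseMean(inPhaseFraction(x))           # 1
#' @export
inPhaseFraction <- function(series) {
  v <- if (is(series, "EnsembleSeries")) series@values else as.matrix(series)
  N <- nrow(v)
  if (N < 2L || ncol(v) < 2L) stop("need at least 2 trees and 2 years")
  D <- v[, -1L, drop = FALSE] - v[, -ncol(v), drop = FALSE]
  fInT <- vapply(seq_len(ncol(D)), function(t) {
    d <- D[, t]
    np <- sum(d > 0); nn <- sum(d < 0); nz <- sum(d == 0)
    (np * (np - 1) + nn * (nn - 1) + nz * (nz - 1)) / (N * (N - 1))
  }, numeric(1))
  new("SyncFractions", fInT = fInT, FIN = mean(fInT))
}

#' @rdname SyncFractions-class
#' @export
setMethod("inPhasePerYear", "SyncFractions", function(x) x@fInT)

#' @rdname SyncFractions-class
#' @export
setMethod("inPhaseMean", "SyncFractions", function(x) x@FIN)

setMethod("show", "SyncFractions", function(object) {
  cat(sprintf("SyncFractions: F_IN = %.4f over %d year transitions\n",
              object@FIN, length(object@fInT)))
})
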