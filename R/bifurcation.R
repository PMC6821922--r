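# Orbit and bifurcation analysis of the reduced map and the full ensemble:
# iterated maps, tangency finding, periodic-window edges, density diagrams,
# two-parameter sweeps and synchronisation-state classification.

#' n-th iterate of the reduced map
#'
#' @param S reserve(s), vectorised.
#' @param n iteration count, >= 1.
#' @param RC,beta,P0,LT map parameters, see [reducedMap()].
#' @return the reserve after `n` applications of the map.
#' @export
nthIterate <- function(S, n, RC, beta, P0 = 10, LT = 100) {
  stopifnot(n >= 1)
  for (k in seq_len(n)) S <- reducedMap(S, RC, beta, P0, LT)
  S
}

#' Detect the period of a recorded orbit
#'
#' Finds the smallest lag `q <= qMax` such that the orbit repeats to within
#' `tol` at every recorded point; the orbit is reported aperiodic (period
#' NA) when no lag qualifies. Intended for post-transient, noise-free
#' orbits; noisy runs are characterised with [periodFractions()] instead.
#'
#' @param orbit numeric vector of post-transient values.
#' @param tol absolute tolerance (default 1e-6).
#' @param qMax largest period considered.
#' @return an [OrbitSummary-class].
#' @examples
#' orbitPeriod(detectPeriod(rep(c(84.45, 94.45, 99.94), 10)))
#' @export
detectPeriod <- function(orbit, tol = 1e-6, qMax = 16L) {
  n <- length(orbit)
  if (n == 0L) stop("empty orbit")
  for (q in seq_len(min(qMax, n - 1L))) {
    if (all(abs(orbit[(1L + q):n] - orbit[seq_len(n - q)]) < tol))
      return(new("OrbitSummary", period = as.integer(q),
                 points = sort(orbit[seq_len(q)])))
  }
  new("OrbitSummary", period = NA_integer_, points = sort(unique(orbit)))
}

#' Post-transient attractor of the reduced map
#'
#' Iterates the reduced map from `S0` through a long transient and runs
#' period detection on the recorded tail.
#'
#' @param RC,beta,P0,LT map parameters.
#' @param S0 initial reserve (default `LT - P0/2`, inside the basin of the
#'   recurrent set).
#' @param nTransient,nRecord transient and recorded lengths.
#' @param tol,qMax passed to [detectPeriod()].
#' @return an [OrbitSummary-class] with `RC` and `beta` filled in.
#' @export
reducedAttractor <- function(RC, beta, P0 = 10, LT = 100, S0 = LT - P0 / 2,
                             nTransient = 20000L, nRecord = 64L,
                             tol = 1e-6, qMax = 16L) {
  orb <- .cppReducedOrbit(S0, as.integer(nTransient), as.integer(nRecord),
                          RC, beta, P0, LT)
  res <- detectPeriod(orb, tol = tol, qMax = qMax)
  res@RC <- RC
  res@beta <- beta
  res
}

#' @rdname OrbitSummary-class
#' @export
setMethod("orbitPeriod", "OrbitSummary", function(x) x@period)

#' @rdname OrbitSummary-class
#' @export
setMethod("orbitPoints", "OrbitSummary", function(x) x@points)

setMethod("show", "OrbitSummary", function(object) {
  if (is.na(object@period)) {
    cat("OrbitSummary: aperiodic orbit,", length(object@points),
        "recorded values\n")
  } else {
    cat(sprintf("OrbitSummary: period %d, points {%s}\n", object@period,
                paste(sprintf("%.4f", object@points), collapse = ", ")))
  }
})

#' Near-tangency and crossing points of an iterated map
#'
#' Locates the local minimisers of `|f^n(S) - S|` on the flowering side of
#' the state space. Each minimiser is refined by bracketed minimisation and
#' tagged: a sign change of `f^n(S) - S` within the bracket marks a true
#' crossing (a genuine periodic point, refined by root bracketing), while a
#' positive minimum gap marks a near-tangency, where the graph of the
#' iterate approaches the diagonal without touching it -- the signature of
#' an imminent tangent (saddle-node) bifurcation.
#'
#' @param RC,beta,P0,LT map parameters.
#' @param n iterate order (3 for the period-3 structure).
#' @param range search interval; default `[LT - n*P0, LT + P0/2]` covers the
#'   recurrent set of an n-cycle.
#' @param gridStep scan resolution used to bracket candidates.
#' @param gapMax discard shallow minima with a diagonal gap above this.
#' @param tol refinement tolerance on S.
#' @return data.frame with columns `S` (sorted ascending), `gap`
#'   (`|f^n(S) - S|` at the point) and `crossing` (logical).
#' @examples
#' findTangencyPoints(RC = 0.5, beta = 0, n = 1)   # stable fixed point
#' @export
findTangencyPoints <- function(RC, beta, P0 = 10, LT = 100, n = 3,
                               range = NULL, gridStep = 1e-3,
                               gapMax = P0 / 2, tol = 1e-9) {
  if (is.null(range)) range <- c(LT - n * P0, LT + P0 / 2)
  Sg <- seq(range[1], range[2], by = gridStep)
  g <- function(S) nthIterate(S, n, RC, beta, P0, LT) - S
  gv <- g(Sg)
  agv <- abs(gv)
  # interior local minima of |g| on the grid
  idx <- which(diff(sign(diff(agv))) > 0) + 1L
  out <- data.frame(S = numeric(0), gap = numeric(0), crossing = logical(0))
  for (i in idx) {
    lo <- Sg[i - 1L]; hi <- Sg[i + 1L]
    if (agv[i] > gapMax) next
    glo <- gv[i - 1L]; ghi <- gv[i + 1L]
    if (sign(glo) != sign(ghi) || gv[i] == 0) {
      root <- uniroot(g, c(lo, hi), tol = tol)$root
      out <- rbind(out, data.frame(S = root, gap = abs(g(root)), crossing = TRUE))
    } else {
      opt <- optimize(function(S) abs(g(S)), c(lo, hi), tol = tol)
      out <- rbind(out, data.frame(S = opt$minimum, gap = opt$objective,
                                   crossing = FALSE))
    }
  }
  out <- out[order(out$S), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Lower edge of a periodic window of the reduced map
#'
#' Scans `RC` on an ascending grid and reports the first value whose
#' post-transient attractor has exactly period `Q`. The window-edge
#' convention is therefore "first grid point with a stable period-Q orbit";
#' at the default 1e-4 resolution this resolves the tangent-bifurcation
#' opening of the period-3 window at coupling `beta = 6`.
#'
#' @param Q target period.
#' @param beta coupling strength.
#' @param P0,LT model constants.
#' @param RCrange scanned interval.
#' @param resolution grid step (1e-4 or finer for publication-grade edges).
#' @param nTransient,nRecord,tol orbit settings per grid point; the long
#'   default transient absorbs the slow escape from the intermittent ghost
#'   channel just past the tangency.
#' @return list with `RC` (the edge), `attractor` (its [OrbitSummary-class])
#'   and `scanned` (number of grid points evaluated).
#' @export
periodWindowEdge <- function(Q, beta, P0 = 10, LT = 100,
                             RCrange = c(1.55, 2.0), resolution = 1e-4,
                             nTransient = 20000L, nRecord = 64L, tol = 1e-6) {
  grid <- seq(RCrange[1], RCrange[2], by = resolution)
  for (k in seq_along(grid)) {
    att <- reducedAttractor(grid[k], beta, P0, LT,
                            nTransient = nTransient, nRecord = nRecord,
                            tol = tol, qMax = max(16L, Q + 1L))
    if (!is.na(att@period) && att@period == Q)
      return(list(RC = grid[k], attractor = att, scanned = k))
  }
  stop(sprintf("no period-%d window found in [%g, %g]", Q,
               RCrange[1], RCrange[2]))
}

#' Critical cost ratio of the uncoupled model
#'
#' The uncoupled map has fixed point `S* = LT - RC * P0 / (1 + RC)` on the
#' flowering branch, where the slope is `-RC`; the fixed point loses
#' stability when the slope magnitude reaches 1. The crossing is located
#' numerically: the slope at the fixed point is measured by central
#' differencing and the unit-magnitude condition solved by root bracketing
#' over `RCrange`.
#'
#' @param P0,LT model constants.
#' @param RCrange bracketing interval for the root search.
#' @return list with `RC` (critical cost ratio) and `slope` (measured slope
#'   at the fixed point there).
#' @export
criticalCostRatio <- function(P0 = 10, LT = 100, RCrange = c(0.5, 1.5)) {
  slopeAt <- function(RC) {
    Sstar <- LT - RC * P0 / (1 + RC)
    h <- 1e-6
    (reducedMap(Sstar + h, RC, 0, P0, LT) -
     reducedMap(Sstar - h, RC, 0, P0, LT)) / (2 * h)
  }
  root <- uniroot(function(RC) abs(slopeAt(RC)) - 1, RCrange, tol = 1e-10)$root
  list(RC = root, slope = slopeAt(root))
}

#' One-sided derivatives of the reduced map at the flowering border
#'
#' The border `S_b = LT - P0` separates the accumulation branch (slope 1)
#' from the flowering branch. The one-sided derivatives are measured by
#' one-sided finite differences shrinking onto the border; analytically the
#' right derivative is `-RC * (beta + 1) * (h / P0)^beta` as `h -> 0`, i.e.
#' `-RC` for `beta = 0` and exactly 0 for any `beta > 0`: coupling flattens
#' the map at the kink, which is what reshapes the border collision.
#'
#' @param RC,beta,P0,LT map parameters.
#' @param h finite-difference step; the default is a power of two so the
#'   difference quotient on the linear branch is exact.
#' @return list with `left` and `right` slopes at the border.
#' @examples
#' borderDerivatives(RC = 2, beta = 0)  # left 1, right -2
#' borderDerivatives(RC = 2, beta = 6)  # left 1, right 0
#' @export
borderDerivatives <- function(RC, beta, P0 = 10, LT = 100, h = 2^-10) {
  Sb <- LT - P0
  fb <- reducedMap(Sb, RC, beta, P0, LT)
  list(left = (fb - reducedMap(Sb - h, RC, beta, P0, LT)) / h,
       right = (reducedMap(Sb + h, RC, beta, P0, LT) - fb) / h)
}

#' Density bifurcation diagram of the full ensemble
#'
#' For each cost ratio on a grid, the full coupled model is simulated and a
#' normalised histogram of the recorded variable is accumulated over all
#' trees and recorded years: reserves `S`, or the Hilbert phase `thetaCs` of
#' seed production (the observable accessible in the field). Columns sum
#' to 1. A failed cell (diverged simulation) yields an NA column rather
#' than aborting the scan.
#'
#' @param params a [ModelParams-class] template; its `RC` is overridden by
#'   the grid, its seed is reused for every cell so that columns differ only
#'   through `RC`.
#' @param RCgrid numeric vector of cost ratios.
#' @param variable "S" or "thetaCs".
#' @param nBins histogram resolution.
#' @return a [ScanResult-class] with the density matrix, bin edges and a
#'   per-cell stats frame (RC, attractor support size).
#' @export
densityBifurcation <- function(params, RCgrid, variable = c("S", "thetaCs"),
                               nBins = 100L) {
  variable <- match.arg(variable)
  vals <- vector("list", length(RCgrid))
  for (k in seq_along(RCgrid)) {
    p <- params
    p@RC <- RCgrid[k]
    vals[[k]] <- tryCatch({
      traj <- simulateGCM(p)
      if (variable == "S") as.numeric(traj@S)
      else as.numeric(hilbertPhase(traj@Cs)@theta)
    }, error = function(e) NULL)
  }
  if (variable == "thetaCs") {
    breaks <- seq(-pi, pi, length.out = nBins + 1L)
  } else {
    rng <- range(unlist(vals), finite = TRUE)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    breaks <- seq(rng[1], rng[2], length.out = nBins + 1L)
  }
  dens <- matrix(NA_real_, nBins, length(RCgrid),
                 dimnames = list(NULL, signif(RCgrid, 8)))
  support <- rep(NA_integer_, length(RCgrid))
  for (k in seq_along(RCgrid)) {
    v <- vals[[k]]
    if (is.null(v)) next
    h <- hist(pmin(pmax(v, breaks[1]), breaks[nBins + 1L]),
              breaks = breaks, plot = FALSE)
    dens[, k] <- h$counts / sum(h$counts)
    support[k] <- sum(h$counts > 0)
  }
  new("ScanResult", stats = data.frame(RC = RCgrid, support = support),
      densities = dens, breaks = breaks, variable = variable,
      meta = list(params = params, nBins = nBins))
}

#' Two-parameter sweep of coupling strength and cost ratio
#'
#' Simulates the full model over a `beta x RC` grid (optionally replicated
#' over seeds) and records, per cell, the population period fractions
#' FP(Q), the in-phase fraction F_IN, the FP(3)/FP(2) dominance ratio and a
#' synchronisation-state label from [classifyState()].
#'
#' @param betaGrid,RCgrid grid axes (defaults: 40 values over `[0, 8]` and
#'   `[0.5, 4]`).
#' @param eI,eC noise amplitudes applied in every cell.
#' @param replicates independent seeds averaged per cell.
#' @param seed base seed; cell seeds are derived deterministically.
#' @param N,Ttransient,Trecord run controls per cell.
#' @param Q periods evaluated.
#' @param syncThreshold F_IN threshold of [classifyState()].
#' @return a [ScanResult-class]; `scanStats()` has one row per cell with
#'   columns beta, RC, FP<q>..., FIN, ratio32, state.
#' @export
sweepBetaRc <- function(betaGrid = seq(0, 8, length.out = 40),
                        RCgrid = seq(0.5, 4, length.out = 40),
                        eI = 0.2, eC = 0, replicates = 1L, seed = 1L,
                        N = 106L, Ttransient = 1000L, Trecord = 15L,
                        Q = 2:6, syncThreshold = 0.9) {
  cells <- expand.grid(beta = betaGrid, RC = RCgrid,
                       KEEP.OUT.ATTRS = FALSE)
  qn <- paste0("FP", Q)
  stats <- cbind(cells,
                 matrix(NA_real_, nrow(cells), length(Q) + 2L,
                        dimnames = list(NULL, c(qn, "FIN", "ratio32"))))
  stats$state <- NA_character_
  cellSeed <- function(i, r) (seed * 2049L + i * 7L + r) %% .Machine$integer.max
  for (i in seq_len(nrow(cells))) {
    fp <- matrix(NA_real_, replicates, length(Q))
    fin <- rep(NA_real_, replicates)
    for (r in seq_len(replicates)) {
      ok <- tryCatch({
        p <- modelParams(RC = cells$RC[i], beta = cells$beta[i], eI = eI,
                         eC = eC, N = N, Ttransient = Ttransient,
                         Trecord = Trecord, seed = cellSeed(i, r))
        traj <- simulateGCM(p)
        flags <- suppressWarnings(onFlagsPhase(hilbertPhase(traj@Cs)))
        fp[r, ] <- periodFractions(flags, Q = Q)@population
        fin[r] <- inPhaseFraction(traj@Cs)@FIN
        TRUE
      }, error = function(e) FALSE)
      if (!ok) break
    }
    if (anyNA(fp) || anyNA(fin)) next
    fpm <- colMeans(fp)
    stats[i, qn] <- fpm
    stats$FIN[i] <- mean(fin)
    stats$ratio32[i] <- if (fpm[Q == 2L] > 0) fpm[Q == 3L] / fpm[Q == 2L] else Inf
    stats$state[i] <- classifyState(mean(fin), setNames(fpm, Q),
                                    threshold = syncThreshold)
  }
  new("ScanResult", stats = stats, variable = "",
      meta = list(eI = eI, eC = eC, replicates = replicates, seed = seed,
                  N = N, Ttransient = Ttransient, Trecord = Trecord,
                  syncThreshold = syncThreshold,
                  note = "grid axes and replicate count are package defaults"))
}

#' Classify the synchronisation state of a population
#'
#' Three regimes are distinguished: state I, desynchronised (`F_IN` below
#' the synchrony threshold); state II, synchronised with a dominant
#' period-2 (alternate-bearing-like) composition; state III, synchronised
#' with period-3 or a longer period dominating over period-2 (masting-like
#' composition born of the period-adding structure).
#'
#' @param FIN time-averaged in-phase fraction.
#' @param FP named numeric vector of population period fractions, names
#'   giving Q (must include "2").
#' @param threshold synchrony threshold on `FIN` (default 0.9).
#' @return "I", "II" or "III".
#' @examples
#' classifyState(0.95, c(`2` = 0.26, `3` = 0.73))  # "III"
#' @export
classifyState <- function(FIN, FP, threshold = 0.9) {
  stopifnot(!is.null(names(FP)), "2" %in% names(FP))
  if (FIN < threshold) return("I")
  higher <- FP[names(FP) != "2"]
  if (length(higher) && max(higher) > FP[["2"]]) "III" else "II"
}

#' @rdname ScanResult-class
#' @export
setMethod("scanStats", "ScanResult", function(x) x@stats)

#' @rdname ScanResult-class
#' @export
setMethod("scanDensities", "ScanResult", function(x) x@densities)

setMethod("show", "ScanResult", function(object) {
  cat(sprintf("ScanResult: %d cells", nrow(object@stats)))
  if (length(object@densities))
    cat(sprintf(", %s densities (%d bins)", object@variable,
                nrow(object@densities)))
  cat("\n")
})
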