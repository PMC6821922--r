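#' @import methods
NULL

# ---------------------------------------------------------------------------
# ModelParams
# ---------------------------------------------------------------------------

#' Parameters of the globally coupled resource budget model
#'
#' Container for all constants of the coupled map together with run controls.
#' The biological constants are the intrinsic annual surplus `P0`, the reserve
#' threshold `LT`, the cost ratio `RC` (ratio of pollination/fruiting cost to
#' flowering cost), the pollen-coupling exponent `beta`, and the two noise
#' amplitudes `eI` (individual, tree-by-tree) and `eC` (common, shared by the
#' whole population in a given year, i.e. a Moran-effect channel). Run
#' controls are the population size `N`, the discarded transient length, the
#' number of recorded years and the RNG seed.
#'
#' @slot P0 intrinsic annual resource surplus (resource units), > 0.
#' @slot LT reserve threshold triggering flowering (resource units), > 0.
#' @slot RC cost ratio \eqn{C_a/C_f}, dimensionless, >= 0.
#' @slot beta pollen coupling strength (dimensionless exponent), >= 0.
#' @slot eI individual noise amplitude, >= 0.
#' @slot eC common noise amplitude, >= 0.
#' @slot N population size (number of trees).
#' @slot Ttransient discarded burn-in iterations.
#' @slot Trecord recorded years.
#' @slot seed integer RNG seed.
#'
#' @seealso [modelParams()] for the user constructor, [simulateGCM()].
#' @name ModelParams-class
#' @rdname ModelParams-class
#' @exportClass ModelParams
setClass("ModelParams",
  representation(
    P0 = "numeric", LT = "numeric", RC = "numeric", beta = "numeric",
    eI = "numeric", eC = "numeric", N = "integer",
    Ttransient = "integer", Trecord = "integer", seed = "integer"
  ),
  prototype(
    P0 = 10, LT = 100, RC = 2, beta = 6, eI = 0, eC = 0,
    N = 106L, Ttransient = 1000L, Trecord = 15L, seed = 1L
  )
)

setValidity("ModelParams", function(object) {
  msg <- character(0)
  sc <- function(x) length(x) == 1L && is.finite(x)
  if (!sc(object@P0) || object@P0 <= 0) msg <- c(msg, "P0 must be a single value > 0")
  if (!sc(object@LT) || object@LT <= 0) msg <- c(msg, "LT must be a single value > 0")
  if (!sc(object@RC) || object@RC < 0) msg <- c(msg, "RC must be >= 0")
  if (!sc(object@beta) || object@beta < 0) msg <- c(msg, "beta must be >= 0")
  if (!sc(object@eI) || object@eI < 0) msg <- c(msg, "eI must be >= 0")
  if (!sc(object@eC) || object@eC < 0) msg <- c(msg, "eC must be >= 0")
  if (object@N < 1L) msg <- c(msg, "N must be >= 1")
  if (object@beta > 0 && object@N < 2L)
    msg <- c(msg, "pollen coupling (beta > 0) needs N >= 2")
  if (object@Ttransient < 0L) msg <- c(msg, "Ttransient must be >= 0")
  if (object@Trecord < 1L) msg <- c(msg, "Trecord must be >= 1")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# EnsembleSeries
# ---------------------------------------------------------------------------

#' Ensemble of annual production time series
#'
#' An N-trees-by-T-years matrix of non-negative production values (ordinal
#' survey classes or simulated seed production), with tree identifiers and
#' year labels. This is the common currency of the analysis stack: every
#' phase, flag and synchrony statistic consumes it.
#'
#' @slot values numeric N x T matrix, non-negative, no missing cells.
#' @slot treeIds character vector of N unique tree identifiers.
#' @slot years numeric vector of T year labels.
#'
#' @seealso [ensembleSeries()], [readEnsemble()], [hilbertPhase()].
#' @name EnsembleSeries-class
#' @rdname EnsembleSeries-class
#' @exportClass EnsembleSeries
setClass("EnsembleSeries",
  representation(values = "matrix", treeIds = "character", years = "numeric")
)

setValidity("EnsembleSeries", function(object) {
  v <- object@values
  msg <- character(0)
  if (!is.numeric(v)) msg <- c(msg, "values must be a numeric matrix")
  if (anyNA(v) || any(!is.finite(v))) msg <- c(msg, "missing or non-finite cells are not supported")
  else if (any(v < 0)) msg <- c(msg, "production values must be non-negative")
  if (length(object@treeIds) != nrow(v)) msg <- c(msg, "treeIds length must equal nrow(values)")
  if (anyDuplicated(object@treeIds)) msg <- c(msg, "duplicate tree identifiers")
  if (length(object@years) != ncol(v)) msg <- c(msg, "years length must equal ncol(values)")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# EnsembleTrajectory
# ---------------------------------------------------------------------------

#' Recorded state of a coupled-map simulation
#'
#' Per-tree, per-year matrices of the model state over the recorded window:
#' reserves `S`, flowering cost `Cf`, pollination/fruiting cost `Ca`, seed
#' production `Cs` (= Cf * Y, the observable proxied by field survey classes)
#' and the pollen coupling term `Y`. All matrices are N x Trecord.
#'
#' @slot S,Cf,Ca,Cs,Y numeric N x T matrices.
#' @slot params the [ModelParams-class] that generated the run.
#' @seealso [simulateGCM()], [seedProduction()].
#' @name EnsembleTrajectory-class
#' @rdname EnsembleTrajectory-class
#' @exportClass EnsembleTrajectory
setClass("EnsembleTrajectory",
  representation(S = "matrix", Cf = "matrix", Ca = "matrix",
                 Cs = "matrix", Y = "matrix", params = "ModelParams")
)

setValidity("EnsembleTrajectory", function(object) {
  d <- dim(object@S)
  for (nm in c("Cf", "Ca", "Cs", "Y"))
    if (!identical(dim(slot(object, nm)), d))
      return("all state matrices must share the same dimensions")
  if (any(object@Cf < 0)) return("flowering cost must be non-negative")
  if (any(object@Cs < 0)) return("seed production must be non-negative")
  TRUE
})

# ---------------------------------------------------------------------------
# PhaseEnsemble
# ---------------------------------------------------------------------------

#' Instantaneous phases of an ensemble
#'
#' Wrapped Hilbert phases theta in (-pi, pi] and the analytic-signal modulus
#' for each tree and year, plus a validity mask: a tree whose series is
#' constant carries no phase information and is marked invalid.
#'
#' @slot theta numeric N x T matrix of wrapped phases (radians).
#' @slot amplitude numeric N x T matrix of analytic-signal moduli.
#' @slot valid logical N x T matrix; FALSE where the phase is undefined.
#' @seealso [hilbertPhase()], [onFlagsPhase()], [populationPhase()].
#' @name PhaseEnsemble-class
#' @rdname PhaseEnsemble-class
#' @exportClass PhaseEnsemble
setClass("PhaseEnsemble",
  representation(theta = "matrix", amplitude = "matrix", valid = "matrix")
)

setValidity("PhaseEnsemble", function(object) {
  th <- object@theta
  if (!identical(dim(th), dim(object@amplitude)) ||
      !identical(dim(th), dim(object@valid)))
    return("theta, amplitude and valid must share dimensions")
  if (any(abs(th[object@valid]) > pi + 1e-12))
    return("phases must lie in (-pi, pi]")
  if (any(object@amplitude < 0)) return("amplitudes must be non-negative")
  TRUE
})

# ---------------------------------------------------------------------------
# OnOffFlags
# ---------------------------------------------------------------------------

#' Binary on-year / off-year flags
#'
#' @slot flags integer N x T matrix with entries 0 (off-year) or 1 (on-year).
#' @slot rule character, "amplitude" or "phase": which definition produced
#'   the flags.
#' @seealso [onFlagsAmplitude()], [onFlagsPhase()], [flagAgreement()].
#' @name OnOffFlags-class
#' @rdname OnOffFlags-class
#' @exportClass OnOffFlags
setClass("OnOffFlags",
  representation(flags = "matrix", rule = "character")
)

setValidity("OnOffFlags", function(object) {
  if (!all(object@flags %in% c(0L, 1L))) return("flags must be 0 or 1")
  if (!object@rule %in% c("amplitude", "phase"))
    return("rule must be 'amplitude' or 'phase'")
  TRUE
})

# ---------------------------------------------------------------------------
# PeriodFractions
# ---------------------------------------------------------------------------

#' Period-composition statistics
#'
#' Fractions of period-Q motifs (one on-year, Q-1 off-years, then an on-year)
#' per tree and for the population.
#'
#' @slot perTree numeric N x length(Q) matrix of per-tree fractions.
#' @slot population numeric vector of population fractions, one per Q.
#' @slot Q integer vector of evaluated periods.
#' @slot reducer character: how per-tree values were pooled ("mean",
#'   "median" or "mode").
#' @seealso [periodFractions()], [fractionPeriod()].
#' @name PeriodFractions-class
#' @rdname PeriodFractions-class
#' @exportClass PeriodFractions
setClass("PeriodFractions",
  representation(perTree = "matrix", population = "numeric",
                 Q = "integer", reducer = "character")
)

setValidity("PeriodFractions", function(object) {
  if (any(object@perTree < -1e-12) || any(object@perTree > 1 + 1e-12))
    return("per-tree fractions must lie in [0, 1]")
  if (ncol(object@perTree) != length(object@Q) ||
      length(object@population) != length(object@Q))
    return("Q, perTree and population are inconsistent")
  TRUE
})

# ---------------------------------------------------------------------------
# SyncFractions
# ---------------------------------------------------------------------------

#' Pairwise in-phase synchrony fractions
#'
#' The per-year fraction of tree pairs whose year-on-year production changes
#' share sign (with two simultaneous zero changes counted as in-phase), and
#' its time average.
#'
#' @slot fInT numeric vector of length T-1 (one value per year transition).
#' @slot FIN numeric scalar, the time average of `fInT`.
#' @seealso [inPhaseFraction()].
#' @name SyncFractions-class
#' @rdname SyncFractions-class
#' @exportClass SyncFractions
setClass("SyncFractions",
  representation(fInT = "numeric", FIN = "numeric")
)

setValidity("SyncFractions", function(object) {
  if (any(object@fInT < -1e-12 | object@fInT > 1 + 1e-12))
    return("in-phase fractions must lie in [0, 1]")
  if (length(object@FIN) != 1L) return("FIN must be a scalar")
  TRUE
})

# ---------------------------------------------------------------------------
# OrbitSummary
# ---------------------------------------------------------------------------

#' Summary of a post-transient orbit
#'
#' @slot period integer; NA for an aperiodic (chaotic) orbit.
#' @slot points sorted distinct attractor values (one per cycle point for a
#'   periodic orbit, the recorded values otherwise).
#' @slot RC,beta parameters of the map that produced the orbit (NA when
#'   detection was run on a bare sequence).
#' @seealso [detectPeriod()], [reducedAttractor()].
#' @name OrbitSummary-class
#' @rdname OrbitSummary-class
#' @exportClass OrbitSummary
setClass("OrbitSummary",
  representation(period = "integer", points = "numeric",
                 RC = "numeric", beta = "numeric"),
  prototype(RC = NA_real_, beta = NA_real_)
)

# ---------------------------------------------------------------------------
# ScanResult
# ---------------------------------------------------------------------------

#' Gridded scan summaries
#'
#' Result container for parameter scans: a long-format data frame of per-cell
#' statistics and, for density bifurcation diagrams, a matrix of normalised
#' histograms (one column per parameter value, columns sum to 1).
#'
#' @slot stats data.frame of per-cell statistics.
#' @slot densities numeric matrix (bins x parameter values) or a 0 x 0 matrix
#'   when the scan computed no densities.
#' @slot breaks numeric histogram bin edges (length nrow(densities) + 1).
#' @slot variable character: scanned variable ("S", "thetaCs" or "").
#' @slot meta list of scan settings (grids, noise levels, seeds).
#' @seealso [densityBifurcation()], [sweepBetaRc()].
#' @name ScanResult-class
#' @rdname ScanResult-class
#' @exportClass ScanResult
setClass("ScanResult",
  representation(stats = "data.frame", densities = "matrix",
                 breaks = "numeric", variable = "character", meta = "list"),
  prototype(densities = matrix(numeric(0), 0, 0), breaks = numeric(0),
            variable = "", meta = list())
)

# ---------------------------------------------------------------------------
# SurveyConfig
# ---------------------------------------------------------------------------

#' Configuration of the synthetic ordinal survey generator
#'
#' @slot N number of trees.
#' @slot T number of survey years.
#' @slot nClasses number of ordinal production classes (>= 2).
#' @slot pSlip per-tree probability that a cycle is shortened to period-2.
#' @slot pFail per-tree probability that an on-year fails to fruit and is
#'   scored like an off-year.
#' @slot phaseJitter probability that a tree runs one year out of phase.
#' @slot desyncYears integer years (1-based) forced to population-wide
#'   desynchronisation.
#' @slot offClassProbs sampling probabilities of the two lowest classes in an
#'   off-year.
#' @slot onClassProbs sampling probabilities over all classes in an on-year.
#' @slot seed integer RNG seed.
#' @seealso [surveyConfig()], [generateSurvey()].
#' @name SurveyConfig-class
#' @rdname SurveyConfig-class
#' @exportClass SurveyConfig
setClass("SurveyConfig",
  representation(N = "integer", T = "integer", nClasses = "integer",
                 pSlip = "numeric", pFail = "numeric",
                 phaseJitter = "numeric",
                 desyncYears = "integer", offClassProbs = "numeric",
                 onClassProbs = "numeric", seed = "integer")
)

setValidity("SurveyConfig", function(object) {
  msg <- character(0)
  if (object@nClasses < 2L) msg <- c(msg, "need at least 2 classes")
  for (nm in c("pSlip", "pFail", "phaseJitter"))
    if (slot(object, nm) < 0 || slot(object, nm) > 1)
      msg <- c(msg, sprintf("%s must lie in [0, 1]", nm))
  if (length(object@offClassProbs) != 2L)
    msg <- c(msg, "offClassProbs must have length 2 (the two lowest classes)")
  if (length(object@onClassProbs) != object@nClasses)
    msg <- c(msg, "onClassProbs must have one entry per class")
  if (any(object@desyncYears < 1L) || any(object@desyncYears > object@T))
    msg <- c(msg, "desyncYears out of range")
  if (length(msg)) msg else TRUE
})
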