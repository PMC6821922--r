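# Hilbert-transform phase analysis of ensemble production series.

# Discrete analytic signal of one series via the one-sided FFT spectrum,
# matching the MATLAB/scipy 'hilbert' convention: no padding, detrending or
# tapering, full series length.
.analyticSignal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  h[1L] <- 1
  if (n %% 2L == 0L) {
    h[n / 2L + 1L] <- 1
    if (n > 2L) h[2L:(n / 2L)] <- 2
  } else {
    h[2L:((n + 1L) / 2L)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Instantaneous Hilbert phases of an ensemble
#'
#' For each tree the temporal mean is removed and the discrete analytic
#' signal is formed over the full recorded window (no padding or tapering);
#' the wrapped argument in (-pi, pi] is the instantaneous phase. For a
#' dominant period-3 on/off/off cycle the phase steps through the three
#' fundamental values 0 (on-year), 2*pi/3 (first off-year) and -2*pi/3
#' (second off-year). A constant series carries no phase; such trees are
#' marked invalid (with a warning) and their phase is set to 0 by convention.
#'
#' @param series an [EnsembleSeries-class] or a numeric N x T matrix.
#' @return a [PhaseEnsemble-class] with phases, analytic amplitudes and a
#'   validity mask.
#' @examples
#' x <- matrix(rep(c(9, 0, 0), 5), nrow = 1)  # period-3 on/off/off
#' round(phaseMatrix(hilbertPhase(x)) / pi, 3) # 0, 2/3, -2/3 cycling
#' @export
hilbertPhase <- function(series) {
  v <- if (is(series, "EnsembleSeries")) series@values else as.matrix(series)
  if (ncol(v) < 3L) stop("need at least 3 years to define a phase")
  theta <- matrix(0, nrow(v), ncol(v), dimnames = dimnames(v))
  amp <- theta
  valid <- matrix(TRUE, nrow(v), ncol(v), dimnames = dimnames(v))
  nConst <- 0L
  for (i in seq_len(nrow(v))) {
    xc <- v[i, ] - mean(v[i, ])
    if (all(xc == 0)) {
      valid[i, ] <- FALSE
      nConst <- nConst + 1L
      next
    }
    a <- .analyticSignal(xc)
    theta[i, ] <- Arg(a)
    amp[i, ] <- Mod(a)
  }
  if (nConst > 0L)
    warning(sprintf("%d constant series carry no phase; marked invalid", nConst))
  new("PhaseEnsemble", theta = theta, amplitude = amp, valid = valid)
}

#' @rdname PhaseEnsemble-class
#' @export
setMethod("phaseMatrix", "PhaseEnsemble", function(x) x@theta)

#' @rdname PhaseEnsemble-class
#' @export
setMethod("amplitudeMatrix", "PhaseEnsemble", function(x) x@amplitude)

#' @rdname PhaseEnsemble-class
#' @export
setMethod("validMask", "PhaseEnsemble", function(x) x@valid)

setMethod("show", "PhaseEnsemble", function(object) {
  cat(sprintf("PhaseEnsemble: %d trees x %d years (%d invalid cells)\n",
              nrow(object@theta), ncol(object@theta), sum(!object@valid)))
})

#' Amplitude-based on-year flags
#'
#' A year is an on-year for a tree when its production is strictly above
#' that tree's temporal mean; ties resolve to off.
#'
#' @param series an [EnsembleSeries-class] or numeric matrix.
#' @return an [OnOffFlags-class] with `rule = "amplitude"`.
#' @examples
#' flagsMatrix(onFlagsAmplitude(matrix(c(3, 0, 0, 3, 0, 0), nrow = 1)))
#' @export
onFlagsAmplitude <- function(series) {
  v <- if (is(series, "EnsembleSeries")) series@values else as.matrix(series)
  f <- 1L * (v > rowMeans(v))
  new("OnOffFlags", flags = f, rule = "amplitude")
}

#' Phase-based on-year flags
#'
#' A year is an on-year when the instantaneous phase lies strictly inside
#' (-pi/2, pi/2); the boundary resolves to off. Invalid phases (constant
#' series) propagate as off-years with a warning.
#'
#' @param phases a [PhaseEnsemble-class], or anything accepted by
#'   [hilbertPhase()] (phases are then computed first).
#' @return an [OnOffFlags-class] with `rule = "phase"`.
#' @export
onFlagsPhase <- function(phases) {
  if (!is(phases, "PhaseEnsemble")) phases <- hilbertPhase(phases)
  f <- 1L * (abs(phases@theta) < pi / 2)
  if (any(!phases@valid)) {
    warning("invalid phases flagged as off-years")
    f[!phases@valid] <- 0L
  }
  new("OnOffFlags", flags = f, rule = "phase")
}

#' @rdname OnOffFlags-class
#' @export
setMethod("flagsMatrix", "OnOffFlags", function(x) x@flags)

#' @rdname OnOffFlags-class
#' @export
setMethod("flagRule", "OnOffFlags", function(x) x@rule)

setMethod("show", "OnOffFlags", function(object) {
  cat(sprintf("OnOffFlags (%s rule): %d trees x %d years, %.1f%% on-years\n",
              object@rule, nrow(object@flags), ncol(object@flags),
              100 * mean(object@flags)))
})

#' Agreement between two flag matrices
#'
#' Fraction of matching entries; used to confirm that the amplitude and
#' phase definitions of the on-year coincide on model output.
#'
#' @param a,b [OnOffFlags-class] objects (or bare binary matrices) of the
#'   same shape.
#' @return scalar in `[0, 1]`.
#' @export
flagAgreement <- function(a, b) {
  fa <- if (is(a, "OnOffFlags")) a@flags else as.matrix(a)
  fb <- if (is(b, "OnOffFlags")) b@flags else as.matrix(b)
  if (!identical(dim(fa), dim(fb))) stop("flag matrices differ in shape")
  mean(fa == fb)
}

#' Representative population phase
#'
#' The per-year median over trees of the wrapped phases. The ordinary
#' (non-circular) median of values in (-pi, pi] is used; this matches common
#' field practice and is adequate when phases cluster away from the +-pi
#' seam, but is not a circular median.
#'
#' @param phases a [PhaseEnsemble-class].
#' @return numeric vector of length T.
#' @export
populationPhase <- function(phases) {
  stopifnot(is(phases, "PhaseEnsemble"))
  apply(phases@theta, 2L, median)
}

#' Kuramoto order parameter of a phase sample
#'
#' Magnitude and argument of the mean unit phasor: `r = 1` for perfect phase
#' synchrony, `r = 0` for complete incoherence (e.g. phases balanced over
#' the three fundamental values).
#'
#' @param theta numeric vector of phases (radians).
#' @return list with elements `r` (magnitude in `[0,1]`) and `psi` (mean
#'   angle).
#' @examples
#' orderParameter(c(0, 2 * pi / 3, -2 * pi / 3))$r   # cancels to 0
#' @export
orderParameter <- function(theta) {
  if (length(theta) == 0L) stop("empty phase vector")
  z <- mean(exp(1i * theta))
  list(r = Mod(z), psi = Arg(z))
}
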