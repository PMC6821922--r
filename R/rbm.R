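# Resource budget model: single-tree map, globally coupled ensemble, and the
# reduced one-dimensional map of the fully synchronised population.

#' Construct model parameters
#'
#' The resource budget model (RBM) lets each tree accumulate an annual
#' surplus `P0` until its reserve exceeds the threshold `LT`; the excess is
#' spent on flowering (cost `Cf`) and, scaled by the cost ratio `RC` and the
#' pollen coupling term `Y`, on pollination and fruiting (cost `Ca`).
#' Coupling strength `beta` is the exponent applied to the mean flowering
#' effort of the other trees; `beta = 0` switches coupling off. Two noise
#' channels perturb the annual surplus multiplicatively:
#' \deqn{P_S^i(t) = P_0 \{1 + e_C \sigma(t)\}\{1 + e_I \delta^i(t)\},}
#' with standard-normal draws, one common \eqn{\sigma(t)} per year and one
#' individual \eqn{\delta^i(t)} per tree and year.
#'
#' @param P0 intrinsic annual surplus (default 10).
#' @param LT reserve threshold (default 100).
#' @param RC cost ratio, >= 0.
#' @param beta pollen coupling strength, >= 0.
#' @param eI individual noise amplitude.
#' @param eC common noise amplitude.
#' @param N population size.
#' @param Ttransient burn-in iterations discarded before recording.
#' @param Trecord recorded years (default 15, a typical survey span).
#' @param seed integer RNG seed.
#' @return a validated [ModelParams-class] object.
#' @examples
#' p <- modelParams(RC = 2, beta = 6, eI = 0.2)
#' p
#' @export
modelParams <- function(P0 = 10, LT = 100, RC = 2, beta = 6, eI = 0, eC = 0,
                        N = 106, Ttransient = 1000, Trecord = 15, seed = 1) {
  new("ModelParams", P0 = as.numeric(P0), LT = as.numeric(LT),
      RC = as.numeric(RC), beta = as.numeric(beta), eI = as.numeric(eI),
      eC = as.numeric(eC), N = as.integer(N),
      Ttransient = as.integer(Ttransient), Trecord = as.integer(Trecord),
      seed = as.integer(seed))
}

setMethod("show", "ModelParams", function(object) {
  cat("ModelParams\n")
  cat(sprintf("  P0 = %g, LT = %g, RC = %g, beta = %g\n",
              object@P0, object@LT, object@RC, object@beta))
  cat(sprintf("  noise: eI = %g, eC = %g\n", object@eI, object@eC))
  cat(sprintf("  run: N = %d trees, transient %d, record %d years, seed %d\n",
              object@N, object@Ttransient, object@Trecord, object@seed))
})

#' Single step of the uncoupled resource budget model
#'
#' One deterministic year of the single-tree map: the reserve grows by `P0`;
#' if it exceeds `LT` the excess is spent as flowering cost `Cf` and the
#' reserve is reset to `LT - RC * Cf`.
#'
#' @param S reserve(s) at the start of the year (vectorised).
#' @param params a [ModelParams-class]; only `P0`, `LT`, `RC` are used.
#' @return list with elements `S` (next reserve) and `Cf` (flowering cost).
#' @examples
#' p <- modelParams(RC = 1)
#' stepUncoupled(50, p)   # below threshold: pure accumulation
#' stepUncoupled(95, p)   # flowers with Cf = 5
#' @export
stepUncoupled <- function(S, params) {
  stopifnot(is(params, "ModelParams"))
  acc <- S + params@P0
  Cf <- pmax(0, acc - params@LT)
  list(S = ifelse(Cf > 0, params@LT - params@RC * Cf, acc), Cf = Cf)
}

#' Single step of the globally coupled ensemble
#'
#' One year of the coupled map with injectable noise draws, the reference
#' (non-compiled) implementation of the update. Per tree `i`:
#' \deqn{P_S^i = P_0(1 + e_C\sigma)(1 + e_I\delta^i),\quad
#'       C_f^i = \max(0,\, S^i + P_S^i - L_T),}
#' \deqn{Y^i = \Big[\frac{1}{(N-1)P_0}\sum_{j \ne i} C_f^j\Big]^\beta,\quad
#'       C_a^i = R_C C_f^i Y^i,}
#' and the reserve update \eqn{S^i \leftarrow S^i + P_S^i - C_f^i - C_a^i}
#' (which reduces to pure accumulation when the threshold is not crossed).
#' The focal tree is excluded from its own pollen term, so a tree flowering
#' alone sets no seed. Noise can drive \eqn{P_S} negative; \eqn{P_S} is not
#' clamped, only `Cf` is floored at zero. Reserves may go negative after a
#' heavy reproductive year; no floor is applied.
#'
#' @param S numeric vector of N reserves.
#' @param params a [ModelParams-class].
#' @param sigma single common standard-normal draw for the year.
#' @param delta numeric vector of N individual standard-normal draws.
#' @return list with elements `S`, `Cf`, `Ca`, `Cs`, `Y`, each length N.
#' @examples
#' p <- modelParams(N = 4, beta = 6, RC = 1.6171)
#' stepCoupled(rep(99.9438, 4), p, sigma = 0, delta = rep(0, 4))
#' @export
stepCoupled <- function(S, params, sigma = 0, delta = numeric(length(S))) {
  stopifnot(is(params, "ModelParams"))
  N <- length(S)
  if (length(delta) != N) stop("delta must have one draw per tree")
  if (params@beta > 0 && N < 2)
    stop("pollen coupling is undefined for N < 2 when beta > 0")
  PS <- params@P0 * (1 + params@eC * sigma) * (1 + params@eI * delta)
  Cf <- pmax(0, S + PS - params@LT)
  Y <- if (params@beta == 0) rep(1, N)
       else ((sum(Cf) - Cf) / ((N - 1) * params@P0))^params@beta
  Ca <- params@RC * Cf * Y
  list(S = S + PS - Cf - Ca, Cf = Cf, Ca = Ca, Cs = Cf * Y, Y = Y)
}

#' Reduced map of the fully synchronised population
#'
#' When every tree carries the same reserve the coupled map collapses to a
#' piecewise smooth, piecewise monotonic one-dimensional map:
#' \deqn{f(S) = \begin{cases} S + P_0, & S + P_0 \le L_T\\
#'   L_T - R_C (S + P_0 - L_T)^{\beta+1} / P_0^\beta, & S + P_0 > L_T
#'   \end{cases}}
#' At `beta = 0` this is exactly the uncoupled tent-like map; for large
#' `beta` the flowering branch flattens at the border, the source of the
#' border-collision period-adding structure and the tangent-bifurcation
#' period-3 window.
#'
#' @param S reserve(s), vectorised.
#' @param RC cost ratio.
#' @param beta coupling strength.
#' @param P0,LT model constants.
#' @return next reserve value(s).
#' @examples
#' reducedMap(50, RC = 2, beta = 6)           # sub-threshold: 60
#' reducedMap(99.9438, RC = 1.6171, beta = 6) # crash of the 3-cycle
#' @export
reducedMap <- function(S, RC, beta, P0 = 10, LT = 100) {
  acc <- S + P0
  ifelse(acc <= LT, acc, LT - RC * (acc - LT)^(beta + 1) / P0^beta)
}

#' Simulate the globally coupled resource budget model
#'
#' Runs N trees for `Ttransient + Trecord` years and keeps the last
#' `Trecord`. Initial reserves are drawn uniformly on `[0, LT]` (one draw per
#' tree); noise draws come from the same seeded generator with a fixed fill
#' order (per year: the common draw first, then the individual draws in tree
#' index order), so identical seeds give bitwise-identical trajectories.
#'
#' @param params a [ModelParams-class].
#' @param S0 optional vector of initial reserves overriding the uniform
#'   draw (length N).
#' @return an [EnsembleTrajectory-class].
#' @examples
#' traj <- simulateGCM(modelParams(RC = 2, beta = 6, N = 20, seed = 7))
#' seedProduction(traj)
#' @export
simulateGCM <- function(params, S0 = NULL) {
  stopifnot(is(params, "ModelParams"))
  N <- params@N
  if (params@beta > 0 && N < 2)
    stop("pollen coupling is undefined for N < 2 when beta > 0")
  Ttot <- params@Ttransient + params@Trecord
  set.seed(params@seed)
  if (is.null(S0)) {
    S0 <- runif(N, 0, params@LT)
  } else {
    if (length(S0) == 1L) S0 <- rep(S0, N)
    stopifnot(length(S0) == N)
  }
  draws <- matrix(rnorm(Ttot * (N + 1L)), nrow = Ttot, byrow = TRUE)
  res <- .cppSimulateGCM(as.numeric(S0), draws[, 1L], draws[, -1L, drop = FALSE],
                         params@RC, params@beta, params@P0, params@LT,
                         params@eI, params@eC, params@Ttransient)
  ids <- sprintf("tree%03d", seq_len(N))
  yrs <- seq_len(params@Trecord)
  for (nm in names(res)) dimnames(res[[nm]]) <- list(ids, yrs)
  new("EnsembleTrajectory", S = res$S, Cf = res$Cf, Ca = res$Ca,
      Cs = res$Cs, Y = res$Y, params = params)
}

#' @rdname EnsembleTrajectory-class
#' @export
setMethod("seedProduction", "EnsembleTrajectory", function(x)
  ensembleSeries(x@Cs, treeIds = rownames(x@Cs),
                 years = as.numeric(colnames(x@Cs))))

#' @rdname EnsembleTrajectory-class
#' @export
setMethod("reserves", "EnsembleTrajectory", function(x) x@S)

setMethod("show", "EnsembleTrajectory", function(object) {
  cat(sprintf("EnsembleTrajectory: %d trees x %d recorded years\n",
              nrow(object@S), ncol(object@S)))
  cat(sprintf("  RC = %g, beta = %g, eI = %g, eC = %g, seed = %d\n",
              object@params@RC, object@params@beta, object@params@eI,
              object@params@eC, object@params@seed))
})
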