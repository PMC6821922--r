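# End-to-end analysis pipeline: phases, flags, period composition,
# synchrony, per-year order parameters, optional figure panels and a
# machine-readable statistics bundle.

#' Run the full masting-synchrony analysis
#'
#' Accepts either observed/synthetic class data (an
#' [EnsembleSeries-class]) or a [ModelParams-class] (the coupled model is
#' then simulated first and its seed production analysed). Computes
#' Hilbert phases, on-year flags under both the amplitude and the phase
#' rule, population period fractions FP(Q), the in-phase fraction F_IN,
#' the per-year Kuramoto order parameter, and the representative
#' (median) population phase. With `outDir` set, writes `stats.json`, the
#' series CSV and a six-panel figure (production traces, production
#' histogram, FP plots, phase traces, phase histogram with the three
#' fundamental phases marked, and a circle map with the order-parameter
#' arrow).
#'
#' @param x an [EnsembleSeries-class] or [ModelParams-class].
#' @param outDir optional output directory (created if needed).
#' @param Q periods evaluated (default 2:6).
#' @param figures write the PDF panel when `outDir` is set.
#' @return list with elements `series`, `phases`, `flagsPhase`,
#'   `flagsAmplitude`, `fp` ([PeriodFractions-class]), `sync`
#'   ([SyncFractions-class]), `orderParameter` (per-year data.frame),
#'   `populationPhase`, and `stats` (the JSON-ready summary list).
#' @examples
#' res <- runPipeline(generateSurvey(surveyConfig(N = 20, seed = 3)))
#' res$stats$FP
#' @export
runPipeline <- function(x, outDir = NULL, Q = 2:6, figures = TRUE) {
  if (is(x, "ModelParams")) {
    series <- withStage("simulate", seedProduction(simulateGCM(x)))
    provenance <- list(source = "simulateGCM", seed = x@seed,
                       RC = x@RC, beta = x@beta, eI = x@eI, eC = x@eC,
                       N = x@N, Ttransient = x@Ttransient,
                       Trecord = x@Trecord)
  } else if (is(x, "EnsembleSeries")) {
    series <- x
    provenance <- list(source = "series")
  } else stop("x must be an EnsembleSeries or ModelParams")

  phases <- withStage("hilbertPhase", hilbertPhase(series))
  flagsP <- withStage("onFlagsPhase", suppressWarnings(onFlagsPhase(phases)))
  flagsA <- withStage("onFlagsAmplitude", onFlagsAmplitude(series))
  fp <- withStage("periodFractions", periodFractions(flagsP, Q = Q))
  sync <- withStage("inPhaseFraction", inPhaseFraction(series))
  Theta <- populationPhase(phases)
  op <- data.frame(year = series@years,
                   t(apply(phases@theta, 2L, function(th) {
                     o <- orderParameter(th)
                     c(r = o$r, psi = o$psi)
                   })))

  stats <- list(
    nTrees = nTrees(series), nYears = nYears(series),
    FP = as.list(setNames(fp@population, paste0("FP", fp@Q))),
    FIN = sync@FIN,
    flagAgreement = flagAgreement(flagsP, flagsA),
    orderParameter = setNames(op$r, op$year),
    populationPhase = setNames(Theta, series@years),
    provenance = provenance
  )

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(stats, file.path(outDir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeEnsemble(series, file.path(outDir, "series.csv"),
                  metadata = provenance)
    if (figures) {
      grDevices::pdf(file.path(outDir, "panels.pdf"), width = 10, height = 7)
      on.exit(grDevices::dev.off(), add = TRUE)
      .plotPanels(series, phases, fp, op)
    }
  }

  list(series = series, phases = phases, flagsPhase = flagsP,
       flagsAmplitude = flagsA, fp = fp, sync = sync,
       orderParameter = op, populationPhase = Theta, stats = stats)
}

# run a pipeline stage, prefixing errors with the stage name
withStage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))
}

.plotPanels <- function(series, phases, fp, op) {
  v <- series@values
  yrs <- series@years
  op_par <- graphics::par(mfrow = c(2, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op_par), add = TRUE)

  # (a) production traces with ensemble mean
  graphics::matplot(yrs, t(v), type = "l", lty = 1,
                    col = grDevices::adjustcolor("grey40", 0.3),
                    xlab = "year", ylab = "production",
                    main = "seed production")
  graphics::lines(yrs, colMeans(v), col = "magenta", lwd = 2)

  # (b) pooled production histogram
  graphics::hist(v, breaks = 20, col = "firebrick", border = "white",
                 xlab = "production level", main = "production histogram")

  # (c) period fractions: per-tree spread and population value
  graphics::boxplot(fp@perTree, names = fp@Q, xlab = "period Q",
                    ylab = "FP(Q)", main = "period composition",
                    col = "lightsteelblue")
  graphics::points(seq_along(fp@Q), fp@population, pch = 19, col = "red")

  # (d) phase traces with population median
  graphics::matplot(yrs, t(phases@theta), type = "l", lty = 1,
                    col = grDevices::adjustcolor("grey40", 0.3),
                    ylim = c(-pi, pi), xlab = "year", ylab = expression(theta),
                    main = "instantaneous phase")
  graphics::lines(yrs, apply(phases@theta, 2, median), col = "magenta", lwd = 2)
  graphics::abline(h = c(0, 2 * pi / 3, -2 * pi / 3), lty = 3)

  # (e) phase histogram with the three fundamental phases
  graphics::hist(phases@theta[phases@valid], breaks = 30, col = "firebrick",
                 border = "white", xlim = c(-pi, pi),
                 xlab = expression(theta), main = "phase histogram")
  graphics::abline(v = c(0, 2 * pi / 3, -2 * pi / 3), lty = 2)

  # (f) circle map of the final year with order-parameter arrow
  thLast <- phases@theta[, ncol(phases@theta)]
  graphics::plot(cos(thLast), sin(thLast), asp = 1, xlim = c(-1, 1),
                 ylim = c(-1, 1), pch = 19,
                 col = grDevices::adjustcolor("blue", 0.5),
                 xlab = "cos", ylab = "sin",
                 main = sprintf("circle map, year %s", format(max(yrs))))
  o <- orderParameter(thLast)
  graphics::arrows(0, 0, o$r * cos(o$psi), o$r * sin(o$psi),
                   lwd = 2, col = "red", length = 0.1)
  graphics::symbols(0, 0, circles = 1, inches = FALSE, add = TRUE)
}
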