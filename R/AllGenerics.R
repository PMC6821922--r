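# Accessor generics. Slot access from user code goes through these.

#' @rdname EnsembleSeries-class
#' @param x an object.
#' @export
setGeneric("seriesMatrix", function(x) standardGeneric("seriesMatrix"))

#' @rdname EnsembleSeries-class
#' @export
setGeneric("treeIds", function(x) standardGeneric("treeIds"))

#' @rdname EnsembleSeries-class
#' @export
setGeneric("years", function(x) standardGeneric("years"))

#' @rdname EnsembleSeries-class
#' @export
setGeneric("nTrees", function(x) standardGeneric("nTrees"))

#' @rdname EnsembleSeries-class
#' @export
setGeneric("nYears", function(x) standardGeneric("nYears"))

#' @rdname EnsembleTrajectory-class
#' @param x an object.
#' @export
setGeneric("seedProduction", function(x) standardGeneric("seedProduction"))

#' @rdname EnsembleTrajectory-class
#' @export
setGeneric("reserves", function(x) standardGeneric("reserves"))

#' @rdname PhaseEnsemble-class
#' @param x an object.
#' @export
setGeneric("phaseMatrix", function(x) standardGeneric("phaseMatrix"))

#' @rdname PhaseEnsemble-class
#' @export
setGeneric("amplitudeMatrix", function(x) standardGeneric("amplitudeMatrix"))

#' @rdname PhaseEnsemble-class
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' @rdname OnOffFlags-class
#' @param x an object.
#' @export
setGeneric("flagsMatrix", function(x) standardGeneric("flagsMatrix"))

#' @rdname OnOffFlags-class
#' @export
setGeneric("flagRule", function(x) standardGeneric("flagRule"))

#' @rdname PeriodFractions-class
#' @param x an object.
#' @export
setGeneric("perTreeFractions", function(x) standardGeneric("perTreeFractions"))

#' @rdname PeriodFractions-class
#' @export
setGeneric("populationFractions", function(x) standardGeneric("populationFractions"))

#' @rdname SyncFractions-class
#' @param x an object.
#' @export
setGeneric("inPhasePerYear", function(x) standardGeneric("inPhasePerYear"))

#' @rdname SyncFractions-class
#' @export
setGeneric("inPhaseMean", function(x) standardGeneric("inPhaseMean"))

#' @rdname OrbitSummary-class
#' @param x an object.
#' @export
setGeneric("orbitPeriod", function(x) standardGeneric("orbitPeriod"))

#' @rdname OrbitSummary-class
#' @export
setGeneric("orbitPoints", function(x) standardGeneric("orbitPoints"))

#' @rdname ScanResult-class
#' @param x an object.
#' @export
setGeneric("scanStats", function(x) standardGeneric("scanStats"))

#' @rdname ScanResult-class
#' @export
setGeneric("scanDensities", function(x) standardGeneric("scanDensities"))
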