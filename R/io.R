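# Data container construction and file I/O. The on-disk format is plain
# CSV: first column the year label, remaining columns one tree each, plus
# an optional JSON sidecar with provenance.

#' Construct an ensemble series
#'
#' @param values numeric N x T matrix (trees in rows, years in columns).
#' @param treeIds unique identifiers, default `tree001, ...`.
#' @param years year labels, default `1..T`.
#' @return an [EnsembleSeries-class].
#' @examples
#' es <- ensembleSeries(matrix(c(5, 0, 0, 5, 0, 0), nrow = 2, ncol = 3))
#' nTrees(es); nYears(es)
#' @export
ensembleSeries <- function(values, treeIds = NULL, years = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(treeIds)) treeIds <- rownames(values)
  if (is.null(treeIds)) treeIds <- sprintf("tree%03d", seq_len(nrow(values)))
  if (is.null(years)) years <- suppressWarnings(as.numeric(colnames(values)))
  if (length(years) != ncol(values) || anyNA(years))
    years <- seq_len(ncol(values))
  dimnames(values) <- list(treeIds, years)
  new("EnsembleSeries", values = values, treeIds = as.character(treeIds),
      years = as.numeric(years))
}

#' @rdname EnsembleSeries-class
#' @export
setMethod("seriesMatrix", "EnsembleSeries", function(x) x@values)

#' @rdname EnsembleSeries-class
#' @export
setMethod("treeIds", "EnsembleSeries", function(x) x@treeIds)

#' @rdname EnsembleSeries-class
#' @export
setMethod("years", "EnsembleSeries", function(x) x@years)

#' @rdname EnsembleSeries-class
#' @export
setMethod("nTrees", "EnsembleSeries", function(x) nrow(x@values))

#' @rdname EnsembleSeries-class
#' @export
setMethod("nYears", "EnsembleSeries", function(x) ncol(x@values))

setMethod("show", "EnsembleSeries", function(object) {
  cat(sprintf("EnsembleSeries: %d trees x %d years (%s - %s)\n",
              nrow(object@values), ncol(object@values),
              format(min(object@years)), format(max(object@years))))
  cat(sprintf("  values in [%g, %g]\n", min(object@values),
              max(object@values)))
})

#' Read an ensemble series from CSV
#'
#' Expects a header row of tree identifiers, a first column of year labels
#' and numeric cells; years in rows, trees in columns. Ragged rows,
#' non-numeric or missing cells and duplicate identifiers are load errors
#' naming the offending cell -- missing data are not imputed.
#'
#' @param path CSV file path.
#' @return an [EnsembleSeries-class].
#' @export
readEnsemble <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("expected a year column plus at least one tree")
  ids <- colnames(df)[-1L]
  if (anyDuplicated(ids))
    stop("duplicate tree identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  yrs <- suppressWarnings(as.numeric(df[[1L]]))
  if (anyNA(yrs)) stop("non-numeric year label in row ", which(is.na(yrs))[1L])
  num <- suppressWarnings(vapply(df[-1L], as.numeric, numeric(nrow(df))))
  num <- matrix(num, nrow = nrow(df), dimnames = list(NULL, ids))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing or non-numeric cell at year row %d, tree '%s'",
                 bad[1L], ids[bad[2L]]))
  }
  ensembleSeries(t(num), treeIds = ids, years = yrs)
}

#' Write an ensemble series to CSV
#'
#' Inverse of [readEnsemble()]: years in rows, trees in columns. When
#' `metadata` is supplied it is written as a JSON sidecar next to the CSV
#' (same name, `.json` extension) recording provenance such as seeds and
#' parameters.
#'
#' @param series an [EnsembleSeries-class].
#' @param path output CSV path.
#' @param metadata optional list of provenance fields.
#' @return `path`, invisibly.
#' @export
writeEnsemble <- function(series, path, metadata = NULL) {
  stopifnot(is(series, "EnsembleSeries"))
  df <- data.frame(year = series@years, t(series@values),
                   check.names = FALSE)
  colnames(df) <- c("year", series@treeIds)
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(metadata)) {
    side <- sub("\\.[^.]*$", ".json", path)
    metadata$package <- as.character(utils::packageVersion("mastSync"))
    jsonlite::write_json(metadata, side, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Read model parameters from a key-value config file
#'
#' Plain `key = value` lines (comments with `#`) mirroring the
#' [modelParams()] argument names, e.g. `RC = 2`, `beta = 6`, `eI = 0.2`.
#' Unknown keys are an error.
#'
#' @param path config file path.
#' @return a [ModelParams-class].
#' @export
readParamsConfig <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line: ", lines[bad][1L])
  keys <- vapply(kv, `[`, "", 1L)
  vals <- as.numeric(vapply(kv, `[`, "", 2L))
  known <- names(formals(modelParams))
  if (!all(keys %in% known))
    stop("unknown parameter(s): ", paste(setdiff(keys, known), collapse = ", "))
  if (anyNA(vals)) stop("non-numeric value for key ", keys[is.na(vals)][1L])
  do.call(modelParams, as.list(setNames(vals, keys)))
}
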