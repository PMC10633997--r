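#' Write and read a MoleculeSet as delimited text
#'
#' Comma-separated file with a header row and columns `id`, `f_000...`
#' (descriptors), `e_000...` (embeddings), `y`, `cluster`, `sigma_true`,
#' plus an optional JSON sidecar (`<path>.json`) holding the generating
#' configuration.
#'
#' @param object a [MoleculeSet].
#' @param path CSV file path.
#' @param config optional `SyntheticConfig` to store in the sidecar.
#' @return `path`, invisibly.
#' @export
writeMoleculeSet <- function(object, path, config = NULL) {
  stopifnot(is(object, "MoleculeSet"))
  X <- descriptors(object); E <- embeddings(object)
  colnames(X) <- sprintf("f_%03d", seq_len(ncol(X)) - 1L)
  df <- data.frame(id = molIds(object), X, check.names = FALSE)
  if (ncol(E) > 0) {
    colnames(E) <- sprintf("e_%03d", seq_len(ncol(E)) - 1L)
    df <- cbind(df, E)
  }
  df$y <- targets(object)
  df$cluster <- clusterLabels(object)
  df$sigma_true <- trueNoise(object)
  write.csv(df, path, row.names = FALSE)
  if (!is.null(config))
    jsonlite::write_json(unclass(config), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeMoleculeSet
#' @export
readMoleculeSet <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  fCols <- grep("^f_", names(df), value = TRUE)
  eCols <- grep("^e_", names(df), value = TRUE)
  new("MoleculeSet", ids = as.character(df$id),
      X = as.matrix(df[fCols]),
      E = if (length(eCols)) as.matrix(df[eCols])
          else matrix(numeric(0), nrow(df), 0),
      y = df$y, cluster = as.integer(df$cluster),
      sigmaTrue = as.numeric(df$sigma_true))
}

#' Serialize an uncertainty estimate to delimited text
#'
#' Columns: `id`, `mean`, `sigma`, `method`, `calibrated`.
#'
#' @param estimate a [UQEstimate].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
writeUQEstimate <- function(estimate, path) {
  stopifnot(is(estimate, "UQEstimate"))
  write.csv(data.frame(id = molIds(estimate), mean = uqMean(estimate),
                       sigma = uqSigma(estimate), method = uqMethod(estimate),
                       calibrated = isCalibrated(estimate)),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeUQEstimate
#' @export
readUQEstimate <- function(path) {
  df <- read.csv(path)
  new("UQEstimate", ids = as.character(df$id), mean = df$mean,
      sigma = df$sigma, calibrated = df$calibrated[1],
      method = as.character(df$method[1]))
}

#' Serialize a leave-bin-out split as JSON
#'
#' Index lists plus provenance (component, bin).
#'
#' @param split a [LeaveBinOutSplit].
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
writeSplit <- function(split, path) {
  stopifnot(is(split, "LeaveBinOutSplit"))
  jsonlite::write_json(
    list(pcIndex = split@pcIndex, binIndex = split@binIndex,
         trainIdx = split@trainIdx, valIdx = split@valIdx,
         testIdx = split@testIdx, removedIdx = split@removedIdx),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSplit
#' @export
readSplit <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("LeaveBinOutSplit", pcIndex = as.integer(j$pcIndex),
      binIndex = as.integer(j$binIndex), trainIdx = as.integer(j$trainIdx),
      valIdx = as.integer(j$valIdx), testIdx = as.integer(j$testIdx),
      removedIdx = as.integer(j$removedIdx))
}
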