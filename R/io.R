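# File-format plumbing: delimited-text traces with JSON sidecars, CSV
# tables, provenance stamping.

provenance <- function(seed = NULL, hash = NULL) {
  out <- list(package = "flowLadder",
              version = as.character(packageVersion("flowLadder")))
  if (!is.null(seed)) out$seed <- seed
  if (!is.null(hash)) out$configHash <- hash
  out
}

writeSidecar <- function(path, meta) {
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

#' Write a trace as delimited text with a JSON sidecar
#'
#' One time column (seconds) plus one mV column per channel, tab-separated;
#' sampling rate, channel names, seed and configuration hash go to
#' `<path>.json`.
#'
#' @param trace A [RawTrace-class].
#' @param path Output file path.
#' @param seed Seed recorded in the sidecar (optional).
#' @param configHash Configuration hash recorded in the sidecar (optional).
#' @return `path`, invisibly.
#' @export
writeTrace <- function(trace, path, seed = NULL, configHash = NULL) {
  x <- traceValues(trace)
  df <- data.frame(time_s = (seq_len(nrow(x)) - 1) / sampleRate(trace), x)
  names(df) <- c("time_s", paste0(colnames(x), "_mV"))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  writeSidecar(path, c(provenance(seed, configHash),
                       list(sampleRateHz = sampleRate(trace),
                            channels = colnames(x),
                            nSamples = nrow(x))))
  invisible(path)
}

#' Read a delimited-text trace
#'
#' Uses the `<path>.json` sidecar for the sampling rate when present,
#' otherwise infers it from the time column.
#'
#' @param path File written by [writeTrace()] (or the same layout).
#' @return A [RawTrace-class].
#' @export
readTrace <- function(path) {
  df <- read.csv(path, sep = "\t", check.names = FALSE)
  side <- paste0(path, ".json")
  fs <- if (file.exists(side)) {
    jsonlite::read_json(side)$sampleRateHz
  } else if (nrow(df) > 1) {
    1 / mean(diff(df$time_s))
  } else {
    stop("cannot infer sampling rate from a single sample")
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  colnames(vals) <- sub("_mV$", "", colnames(vals))
  RawTrace(vals, sampleRateHz = as.numeric(fs))
}

#' Write a table as CSV with a provenance sidecar
#'
#' @param df A data.frame.
#' @param path Output path.
#' @param seed,configHash Recorded in the `<path>.json` sidecar.
#' @return `path`, invisibly.
#' @export
writeTableWithProvenance <- function(df, path, seed = NULL,
                                     configHash = NULL) {
  write.csv(df, path, row.names = FALSE)
  writeSidecar(path, c(provenance(seed, configHash), list(rows = nrow(df))))
  invisible(path)
}

#' Write a calibration curve to JSON
#' @param curve A [CalibrationCurve-class].
#' @param path Output path.
#' @param seed,configHash Provenance fields.
#' @return `path`, invisibly.
#' @export
writeCalibrationCurve <- function(curve, path, seed = NULL,
                                  configHash = NULL) {
  jsonlite::write_json(
    c(list(channel = curve@channel, slope = curve@slope,
           intercept = curve@intercept, rSquared = curve@rSquared,
           points = curve@points),
      provenance(seed, configHash)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
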