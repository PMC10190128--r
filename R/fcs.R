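# Minimal FCS 3.1 writer/reader: list-mode float32 data, little-endian,
# one TEXT segment. Enough for cytometry software to ingest per-cell
# parameter tables; not a general-purpose FCS implementation.

fcsPad <- function(n) sprintf("%8d", n)

#' Export cell records to an FCS 3.1 file
#'
#' Writes the quantified per-cell parameters as list-mode float32 events
#' with parameters `FITC-A`, `PE-A`, `PerCP-A` (copy numbers), `Width`
#' (transit time, ms) and `Diameter` (um). The number of records with
#' clipped-negative copies is recorded in the custom `FLOWLADDER_CLIPPED`
#' keyword.
#'
#' @param cellRecords Cell-record `data.frame` from [quantifyCells()]
#'   (>= 1 row).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFCS <- function(cellRecords, path) {
  if (nrow(cellRecords) == 0) stop("cannot write an FCS file with 0 records")
  mat <- cbind(
    `FITC-A` = cellRecords$copiesFitc,
    `PE-A` = cellRecords$copiesPe,
    `PerCP-A` = cellRecords$copiesPercp,
    Width = cellRecords$transitMs,
    Diameter = cellRecords$diameterUm
  )
  mat[!is.finite(mat)] <- 0
  nPar <- ncol(mat)
  nTot <- nrow(mat)
  dataBytes <- 4L * nPar * nTot

  kw <- c(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
    "$NEXTDATA" = "0",
    "$PAR" = as.character(nPar), "$TOT" = as.character(nTot),
    "FLOWLADDER_CLIPPED" = as.character(sum(cellRecords$clipped))
  )
  for (p in seq_len(nPar)) {
    kw[sprintf("$P%dN", p)] <- colnames(mat)[p]
    kw[sprintf("$P%dB", p)] <- "32"
    kw[sprintf("$P%dE", p)] <- "0,0"
    kw[sprintf("$P%dR", p)] <- as.character(max(1, ceiling(max(mat[, p]))))
  }
  # fixed-width data offsets so TEXT length is known before writing
  kw <- c("$BEGINDATA" = "00000000", "$ENDDATA" = "00000000", kw)
  textOf <- function(kv) {
    paste0("/", paste(rbind(names(kv), unname(kv)), collapse = "/"), "/")
  }
  textStart <- 58L
  textLen <- nchar(textOf(kw), type = "bytes")
  dataStart <- textStart + textLen
  kw["$BEGINDATA"] <- sprintf("%08d", dataStart)
  kw["$ENDDATA"] <- sprintf("%08d", dataStart + dataBytes - 1L)
  text <- textOf(kw)

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("FCS3.1    ", con, eos = NULL)
  writeChar(paste0(fcsPad(textStart), fcsPad(textStart + textLen - 1L),
                   fcsPad(dataStart), fcsPad(dataStart + dataBytes - 1L),
                   fcsPad(0), fcsPad(0)), con, eos = NULL)
  writeChar(text, con, eos = NULL)
  writeBin(as.numeric(t(mat)), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an FCS file written by [writeFCS()]
#'
#' Minimal reader for list-mode float32 FCS 3.x: parses the header offsets
#' and TEXT segment, then the event matrix.
#'
#' @param path FCS file path.
#' @return List with `data` (events x parameters matrix, `$PnN` names) and
#'   `keywords` (named character vector).
#' @export
readFCS <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  header <- rawToChar(raw[1:58])
  if (substr(header, 1, 3) != "FCS") stop("not an FCS file")
  offs <- as.integer(substring(header, 10 + 8 * (0:5) + 1, 10 + 8 * (1:6)))
  text <- rawToChar(raw[(offs[1] + 1):(offs[2] + 1)])
  delim <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  keys <- parts[seq(1, length(parts), by = 2)]
  vals <- parts[seq(2, length(parts), by = 2)]
  kw <- setNames(vals, keys)
  nPar <- as.integer(kw[["$PAR"]])
  nTot <- as.integer(kw[["$TOT"]])
  dataStart <- as.integer(kw[["$BEGINDATA"]])
  dat <- readBin(raw[(dataStart + 1):length(raw)], "numeric",
                 n = nPar * nTot, size = 4, endian = "little")
  mat <- matrix(dat, ncol = nPar, byrow = TRUE)
  colnames(mat) <- vapply(seq_len(nPar),
                          function(p) kw[[sprintf("$P%dN", p)]], "")
  list(data = mat, keywords = kw)
}
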