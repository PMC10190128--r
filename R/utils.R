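#' @importFrom methods new validObject is slot slotNames
#' @importFrom stats rnorm rlnorm rexp runmed lm coef median mad quantile
#'   optim approx predict sd setNames complete.cases
#' @importFrom utils write.csv read.csv packageVersion head tail
NULL

# Avogadro constant, molecules per mole (2019 SI exact value)
AVOGADRO <- 6.02214076e23

CHANNELS <- c("FITC", "PE", "PerCP")

#' Moment-matched lognormal parameters
#'
#' Converts a target arithmetic mean and standard deviation into the
#' `meanlog`/`sdlog` parameters of the lognormal distribution with exactly
#' those first two moments. Used throughout the synthetic generator so that
#' printed population means are generator means without truncation bias.
#'
#' @param mean Target arithmetic mean (must be > 0).
#' @param sd Target arithmetic standard deviation (must be > 0).
#' @return A list with elements `meanlog` and `sdlog`.
#' @examples
#' p <- lognormalMoments(15.2, 4.0)
#' exp(p$meanlog + p$sdlog^2 / 2)  # 15.2
#' @export
lognormalMoments <- function(mean, sd) {
  if (!is.numeric(mean) || !is.numeric(sd) || mean <= 0 || sd <= 0) {
    stop("lognormal moment matching requires mean > 0 and sd > 0")
  }
  s2 <- log1p((sd / mean)^2)
  list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

# Draw n moment-matched lognormal deviates.
rlnormMoments <- function(n, mean, sd) {
  p <- lognormalMoments(mean, sd)
  rlnorm(n, meanlog = p$meanlog, sdlog = p$sdlog)
}

#' Derive a per-stage child seed from a global seed
#'
#' Expands one global seed into reproducible per-stage seeds so that pipeline
#' stages are independently re-runnable. A fixed-multiplier congruential mix
#' keeps results inside the 32-bit integer range `set.seed()` accepts.
#'
#' @param seed Global integer seed.
#' @param stage Integer stage index (0, 1, 2, ...).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
childSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(stage))
  m <- 2147483647 # 2^31 - 1, Mersenne prime modulus
  x <- (abs(seed) %% m)
  for (k in seq_len(stage + 1)) {
    x <- (48271 * ((x + stage + 12345) %% 44488)) %% m
  }
  as.integer(x)
}

# FNV-1a 32-bit hash over raw bytes, returned as 8 hex digits. Used to stamp
# outputs with a configuration fingerprint (no hashing package is required).
fnv1a32 <- function(bytes) {
  h <- 2166136261
  for (b in as.integer(bytes)) {
    low <- bitwXor(h %% 256, b) # xor touches only the low byte
    h <- h - (h %% 256) + low
    # 32-bit modular multiply, split to keep doubles exact (< 2^53)
    hi <- floor(h / 65536)
    lo <- h %% 65536
    h <- ((hi * 16777619) %% 65536 * 65536 + lo * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Fingerprint an R object
#'
#' Stable short hash of any serializable object (FNV-1a over its canonical
#' serialization). Stamped into every output file for provenance.
#'
#' @param x Any R object.
#' @return An 8-character hexadecimal string.
#' @export
configHash <- function(x) {
  fnv1a32(serialize(x, NULL, version = 2)[-(1:14)]) # drop header (R version bytes)
}

# Validate a strictly positive scalar; returns error string or NULL.
checkPositive <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
    return(sprintf("'%s' must be a single positive finite number", what))
  }
  NULL
}
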