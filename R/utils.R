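# Shared internal helpers: channel layout, seed streams, small numerics.

SAMPLING_RATE <- 500L
WINDOW_FRAMES <- 250L

SENSOR_LOCATIONS <- c("lhip", "rhip", "back")
MODALITIES <- c("acc", "gyr")
AXES <- c("x", "y", "z")

ACCEL_RANGE_G <- 16
GYRO_RANGE_DPS <- 2000

#' Canonical IMU channel names
#'
#' The 18 channels of a recording, ordered location (`lhip`, `rhip`, `back`)
#' by modality (`acc` in g, `gyr` in deg/s) by axis (`x`, `y`, `z`).
#'
#' @return Character vector of length 18.
#' @export
#' @examples
#' channel_names()
channel_names <- function() {
  as.vector(vapply(SENSOR_LOCATIONS, function(loc) {
    as.vector(vapply(MODALITIES, function(m) paste(loc, m, AXES, sep = "_"),
                     character(3)))
  }, character(6)))
}

accel_channels <- function() grep("_acc_", channel_names(), value = TRUE)
gyro_channels <- function() grep("_gyr_", channel_names(), value = TRUE)

# Deterministic child seed from a master seed and a stream index, kept below
# 2^31 so it is a valid R integer seed.  Subjects get independent streams
# whose identity does not depend on dataset-level counts.
derive_seed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647) + 1
  x <- (s * 48271 + as.double(index) * 104729 + 12345) %% 2147483647
  as.integer(x)
}

# Column-wise cumulative sums of a matrix via one long cumsum.
col_cumsum <- function(m) {
  n <- nrow(m)
  p <- ncol(m)
  cs <- cumsum(as.numeric(m))
  if (p > 1L) {
    off <- rep(c(0, cs[n * seq_len(p - 1L)]), each = n)
    cs <- cs - off
  }
  matrix(cs, n, p)
}

# FNV-1a hash of an R object's serialised bytes; used to stamp outputs with a
# reproducible configuration fingerprint.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L)[-(1:14)])  # skip header
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (as.double(h) * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

vec_mag <- function(m) sqrt(rowSums(m^2))

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
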