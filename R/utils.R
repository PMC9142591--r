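# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Canonical channel montage: six scalp electrodes (report order matches the
# standard frontal-to-parietal reading) plus two periocular EOG channels.
eeg_channels <- function() c("F7", "Fz", "F8", "Cz", "CP5", "Pz")
eog_channels <- function() c("EOG1", "EOG2")
all_channels <- function() c(eeg_channels(), eog_channels())

condition_levels <- function() {
  c("congruent", "incongruent-semantic", "incongruent-pragmatic")
}
group_levels <- function() c("ASD", "TD")
component_levels <- function() c("N400", "P600")

# Evaluate `code` under a temporary RNG state so callers' streams are
# untouched and identical seeds give identical draws.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Derive a child seed from a master seed
#'
#' Child seeds come from a fixed multiplicative mixing scheme over
#' `(seed, counter)` (two Lehmer steps modulo `2^31 - 1`), so any single
#' analysis or subject can be regenerated in isolation from the master seed
#' and its position, and child streams for nearby counters do not collide.
#' Results stay within the positive 32-bit integer range; all arithmetic is
#' exact in double precision.
#'
#' @param seed Master seed (integer).
#' @param counter Non-negative integer position in the derivation sequence.
#' @return A positive integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, counter) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed),
            is.numeric(counter), all(counter >= 0))
  m <- 2147483647
  s <- (abs(seed) %% m) + 1
  s <- (s * 48271) %% m
  s <- (s + counter) %% m
  s <- (s * 69621) %% m
  s <- (s * 48271) %% m
  as.integer(s %% (m - 1) + 1)
}

# Half-open [start, end) index set on a time grid in ms.
window_index <- function(times, window) {
  stopifnot(length(window) == 2, window[1] < window[2])
  which(times >= window[1] & times < window[2])
}

# Gaussian-shaped spectrally coloured noise, one column per series.
# Amplitude spectrum ~ f^(-exponent/2) ("pink" for exponent = 1); optionally
# multiplied by a 4th-order Butterworth band magnitude so that noise drawn
# directly at the epoch level resembles band-pass-filtered background EEG.
# Each column is rescaled to standard deviation `sd` exactly.
shaped_noise <- function(n, m, sd = 1, rate = 500, band = NULL, exponent = 1) {
  if (sd == 0 || m == 0) return(matrix(0, n, m))
  k <- 0:(n - 1)
  f <- k * rate / n
  f <- pmin(f, rate - f)            # two-sided spectrum
  amp <- ifelse(f > 0, f^(-exponent / 2), 0)
  if (!is.null(band)) {
    # order-4 Butterworth magnitude, high-pass times low-pass
    hp <- ifelse(f > 0, 1 / sqrt(1 + (band[1] / f)^8), 0)
    lp <- 1 / sqrt(1 + (f / band[2])^8)
    amp <- amp * hp * lp
  }
  w <- matrix(stats::rnorm(n * m), n, m)
  x <- Re(stats::mvfft(stats::mvfft(w) * amp, inverse = TRUE)) / n
  sds <- apply(x, 2, stats::sd)
  sds[sds == 0] <- 1
  sweep(x, 2, sds, "/") * sd
}

# Truncated-normal draws by rejection (narrow use: synthetic IQ scores).
rnorm_trunc <- function(n, mean, sd, lower, upper) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    x <- stats::rnorm(length(need), mean, sd)
    ok <- x >= lower & x <= upper
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}
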