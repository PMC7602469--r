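# Internal helpers shared across the pipeline.

rv_abort <- function(message, class) {
  stop(errorCondition(message, class = c(class, "radarvitals_error")))
}

rv_warn <- function(message, class) {
  warning(warningCondition(message, class = c(class, "radarvitals_warning")))
}

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded simulator calls do not
#' disturb the caller's random stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Reshape a vector into non-overlapping windows (columns), dropping the
# trailing partial window.
window_matrix <- function(x, n_per_window) {
  k <- floor(length(x) / n_per_window)
  if (k < 1L) {
    rv_abort("fewer samples than one window", "radarvitals_empty_input")
  }
  matrix(x[seq_len(k * n_per_window)], nrow = n_per_window, ncol = k)
}

# Centered moving average of span `k` with symmetric shrinking at the edges.
# For even spans the window extends one sample further to the right
# (offsets -(k/2 - 1) .. k/2), mirroring the common boxcar smoother.
moving_average <- function(x, k) {
  n <- length(x)
  if (k <= 1L || n == 0L) return(x)
  left <- floor((k - 1) / 2)
  right <- k - 1L - left
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - left):min(n, i + right)])
  }, numeric(1))
}

# Median filter of odd span `k`, shrinking at the edges (stats::runmed with
# endrule = "median"); spans larger than the series fall back to the largest
# odd feasible span.
median_filter <- function(x, k) {
  n <- length(x)
  if (k <= 1L || n <= 2L) return(x)
  k <- min(k, if (n %% 2L == 1L) n else n - 1L)
  if (k %% 2L == 0L) k <- k - 1L
  if (k <= 1L) return(x)
  as.numeric(stats::runmed(x, k, endrule = "median"))
}

# Z-score with a guard for constant input (returns zeros).
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# Magnitude of the analytic signal computed through the FFT.
hilbert_envelope <- function(x) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n / 2L + 1L] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    if (n > 1L) h[2:((n + 1L) / 2L)] <- 2
  }
  Mod(stats::fft(stats::fft(x) * h, inverse = TRUE) / n)
}

# Block-mean decimation by integer factor q (boxcar anti-alias filter).
block_decimate <- function(x, q) {
  if (q <= 1L) return(x)
  k <- floor(length(x) / q)
  if (k < 1L) return(mean(x))
  colMeans(matrix(x[seq_len(k * q)], nrow = q))
}

#' Carrier wavelength in millimetres
#'
#' Free-space wavelength `c / f` for a carrier frequency in GHz; 24 GHz
#' corresponds to about 12.49 mm.
#'
#' @param carrier_ghz Carrier frequency in GHz.
#' @return Wavelength in mm.
#' @export
carrier_wavelength_mm <- function(carrier_ghz) 299.792458 / carrier_ghz
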