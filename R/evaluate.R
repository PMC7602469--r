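#' RMSE between two 1 Hz interval series
#'
#' `sqrt(sum((I_ref - I)^2) / N)` over the overlapping part of the two
#' resampled grids.
#'
#' @param pred,ref [interval_series()] objects with 1 Hz resampled values.
#' @return RMSE in seconds.
#' @export
rmse_intervals <- function(pred, ref) {
  common <- intersect(pred$time, ref$time)
  if (!length(common)) {
    rv_abort("interval series have no overlapping grid points",
             "radarvitals_undefined_result")
  }
  p <- pred$resampled[match(common, pred$time)]
  r <- ref$resampled[match(common, ref$time)]
  sqrt(sum((r - p)^2) / length(common))
}

#' Majority-vote windowed state confusion matrix
#'
#' Both state vectors are expanded to a fine time grid, re-windowed into
#' `eval_window_s` sections, each section assigned its most common state
#' (ties resolve to the higher state code, preferring movement over rest),
#' and corresponding windows accumulated into a 5-by-5 confusion matrix.
#' A trailing partial evaluation window is dropped.
#'
#' @param true_states,pred_states [state_vector()] objects covering the same
#'   recording.
#' @param eval_window_s Evaluation window length in seconds.
#' @return An object of class `confusion_matrix` with integer `counts`
#'   (true states in rows), `accuracy`, and the voted window labels.
#' @export
windowed_confusion <- function(true_states, pred_states, eval_window_s = 5) {
  vt <- vote_windows(true_states, eval_window_s)
  vp <- vote_windows(pred_states, eval_window_s)
  k <- min(length(vt), length(vp))
  if (k < 1L) {
    rv_abort("state vectors too short for one evaluation window",
             "radarvitals_alignment_error")
  }
  if (abs(length(vt) - length(vp)) > 1L) {
    rv_abort("state vectors cover different spans", "radarvitals_alignment_error")
  }
  vt <- vt[seq_len(k)]
  vp <- vp[seq_len(k)]
  counts <- table(factor(vt, levels = 0:4), factor(vp, levels = 0:4))
  counts <- matrix(as.integer(counts), 5, 5,
                   dimnames = list(true = 0:4, predicted = 0:4))
  structure(list(counts = counts,
                 accuracy = sum(diag(counts)) / sum(counts),
                 eval_window_s = eval_window_s,
                 true_windows = vt, pred_windows = vp),
            class = "confusion_matrix")
}

# Expand a state vector to a 0.1 s grid and majority-vote eval windows.
vote_windows <- function(sv, eval_window_s, step = 0.1) {
  per <- round(sv$window_s / step)
  fine <- rep(sv$states, each = per)
  n_per_eval <- round(eval_window_s / step)
  k <- floor(length(fine) / n_per_eval)
  vapply(seq_len(k), function(w) {
    majority_label(fine[(w - 1L) * n_per_eval + seq_len(n_per_eval)])
  }, integer(1))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> %g s windows, accuracy %.1f%% (%d/%d)\n",
              x$eval_window_s, 100 * x$accuracy, sum(diag(x$counts)),
              sum(x$counts)))
  print(x$counts)
  invisible(x)
}

#' Maximal-length sequence from a Fibonacci LFSR
#'
#' @param taps Feedback tap positions (the polynomial exponents, including
#'   the degree itself).
#' @param degree Register length.
#' @param seed_bits Initial register fill (0/1), not all zero.
#' @return A 0/1 vector of length `2^degree - 1`.
#' @export
m_sequence <- function(taps, degree = 10L, seed_bits = rep(1L, degree)) {
  if (all(seed_bits == 0L)) {
    rv_abort("the all-zero register seed is invalid", "radarvitals_invalid_seed")
  }
  reg <- as.integer(seed_bits)
  n <- 2L^degree - 1L
  out <- integer(n)
  for (i in seq_len(n)) {
    out[i] <- reg[degree]
    fb <- Reduce(bitwXor, reg[taps])
    reg <- c(fb, reg[-degree])
  }
  out
}

#' Generate a Gold code
#'
#' XOR combination of the outputs of two maximal-length registers built on a
#' preferred pair of primitive polynomials, mapped `{0, 1} -> {+1, -1}`.
#' The default degree-10 pair (`x^10 + x^3 + 1` and
#' `x^10 + x^9 + x^8 + x^6 + x^3 + x^2 + 1`, the GPS C/A pair) produces
#' length-1023 sequences whose off-peak circular autocorrelation takes only
#' the three values `{-65, -1, 63}`.
#'
#' @param degree Register degree.
#' @param taps_a,taps_b Tap sets of the preferred pair.
#' @param seed_a,seed_b Initial register fills (0/1, not all zero).
#' @return A +/-1 sequence of length `2^degree - 1`.
#' @export
generate_gold_code <- function(degree = 10L,
                               taps_a = c(3L, 10L),
                               taps_b = c(2L, 3L, 6L, 8L, 9L, 10L),
                               seed_a = rep(1L, degree),
                               seed_b = rep(1L, degree)) {
  a <- m_sequence(taps_a, degree, seed_a)
  b <- m_sequence(taps_b, degree, seed_b)
  1L - 2L * bitwXor(a, b)
}

#' Synchronization lag between two sequences
#'
#' Normalized cross-correlation over all lags with sufficient overlap. A
#' positive lag means `seq_b` is delayed against `seq_a`; shifting `seq_b`
#' forward by `-lag` aligns the embedded common code.
#'
#' @param seq_a,seq_b Numeric sequences sharing an embedded code.
#' @param min_overlap Minimum overlap in samples for a lag to be considered.
#' @param min_peak Peak correlation below which synchronization is declared
#'   failed.
#' @return A list with integer `lag` and normalized `peak_correlation`.
#' @export
estimate_lag <- function(seq_a, seq_b, min_overlap = 32L, min_peak = 0.5) {
  na <- length(seq_a); nb <- length(seq_b)
  lags <- (-(na - min_overlap)):(nb - min_overlap)
  best <- -Inf; best_lag <- 0L
  for (k in lags) {
    # delayed-by-k model: b[i + k] carries a[i]
    i0 <- max(1L, 1L - k); i1 <- min(na, nb - k)
    if (i1 - i0 + 1L < min_overlap) next
    av <- seq_a[i0:i1]
    bv <- seq_b[(i0 + k):(i1 + k)]
    den <- sqrt(sum(av^2) * sum(bv^2))
    if (den <= 0) next
    r <- sum(av * bv) / den
    if (r > best) { best <- r; best_lag <- k }
  }
  if (!is.finite(best) || best < min_peak) {
    rv_abort(sprintf("synchronization failed (peak correlation %.3f)", best),
             "radarvitals_sync_failure")
  }
  list(lag = as.integer(best_lag), peak_correlation = best)
}
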