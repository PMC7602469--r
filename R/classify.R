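#' Classifier thresholds and windowing
#'
#' Empirically determined thresholds of the presence and movement
#' classifier. Presence: a 2 s window is occupied when the standard
#' deviation of more than four of the eight raw channels exceeds
#' `sd_threshold`. Movement: a channel flags a window when the variance of
#' the normalized absolute first derivative exceeds `var_threshold` or the
#' absolute change of the window mean against the previous window reaches
#' `mean_change_threshold`; the window is movement when every module flags.
#'
#' @param sd_threshold Presence SD threshold in mV.
#' @param min_channels_over Channels that must exceed it (strictly "more
#'   than four out of eight" reads as 5).
#' @param var_threshold Dimensionless movement variance threshold.
#' @param mean_change_threshold Dimensionless adjacent-window mean-change
#'   threshold.
#' @param window_s Analysis window length in seconds.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(sd_threshold = 0.7,
                              min_channels_over = 5L,
                              var_threshold = 4e-8,
                              mean_change_threshold = 4e-4,
                              window_s = 2) {
  if (sd_threshold <= 0 || var_threshold <= 0 || mean_change_threshold <= 0 ||
      window_s <= 0) {
    rv_abort("thresholds and window length must be positive",
             "radarvitals_invalid_argument")
  }
  structure(list(sd_threshold = sd_threshold,
                 min_channels_over = as.integer(min_channels_over),
                 var_threshold = var_threshold,
                 mean_change_threshold = mean_change_threshold,
                 window_s = window_s),
            class = "classifier_config")
}

#' Per-window state vector
#'
#' States follow the coding 0 = no person present, 1 = calm (resting),
#' 2 = bed entry, 3 = bed exit, 4 = on-bed movement.
#'
#' @param states Integer vector over `{0..4}`.
#' @param window_s Window length in seconds.
#' @param t0 Start time of the first window in seconds.
#' @return An object of class `state_vector`.
#' @export
state_vector <- function(states, window_s = 2, t0 = 0) {
  states <- as.integer(states)
  if (length(states) && (min(states) < 0L || max(states) > 4L)) {
    rv_abort("states must lie in {0..4}", "radarvitals_invalid_argument")
  }
  structure(list(states = states, window_s = window_s, t0 = t0),
            class = "state_vector")
}

#' @export
print.state_vector <- function(x, ...) {
  cat(sprintf("<state_vector> %d windows of %g s\n", length(x$states),
              x$window_s))
  cat("  counts:", paste(sprintf("%d:%d", 0:4,
                                 tabulate(x$states + 1L, 5L)), collapse = " "),
      "\n")
  invisible(x)
}

#' Per-window standard deviation of a raw channel
#'
#' Splits the channel into consecutive non-overlapping windows and computes
#' `sqrt(sum(|X - mean(X)|^2) / (N - 1))` per window; a trailing partial
#' window is dropped.
#'
#' @param channel Raw samples in mV.
#' @param fs Sampling rate in Hz.
#' @param window_s Window length in seconds.
#' @return Numeric vector of per-window SDs in mV.
#' @export
window_sd <- function(channel, fs, window_s = 2) {
  w <- window_matrix(channel, floor(window_s * fs))
  n <- nrow(w)
  mu <- colMeans(w)
  sqrt(colSums((w - rep(mu, each = n))^2) / (n - 1))
}

#' Presence detection from per-channel window SDs
#'
#' @param sd_mat Matrix of per-window SDs, windows in rows, channels in
#'   columns (8 channels in the full setup).
#' @param config A [classifier_config()].
#' @return Logical vector: person present per window.
#' @export
detect_presence <- function(sd_mat, config = classifier_config()) {
  sd_mat <- as.matrix(sd_mat)
  if (config$min_channels_over > ncol(sd_mat)) {
    rv_abort("min_channels_over exceeds channel count", "radarvitals_shape_error")
  }
  rowSums(sd_mat > config$sd_threshold) >= config$min_channels_over
}

#' Movement pre-processing of a raw channel
#'
#' Normalizes the signal to its first measured value and takes absolute
#' values of the first derivative: `y = |diff(x / x[1])|`. When the first
#' sample is below a machine-scale floor, the first sample of sufficient
#' magnitude is used instead (with a warning) so the dimensionless movement
#' thresholds stay meaningful.
#'
#' @param channel Raw samples in mV.
#' @param floor Magnitude floor for the normalizer.
#' @return Dimensionless series, one sample shorter than the input.
#' @export
movement_preprocess <- function(channel, floor = 1e-9) {
  x1 <- channel[1]
  if (!is.finite(x1) || abs(x1) <= floor) {
    cand <- which(abs(channel) > floor)
    if (!length(cand)) {
      rv_abort("no sample above the normalization floor",
               "radarvitals_invalid_argument")
    }
    x1 <- channel[cand[1]]
    rv_warn("first sample near zero; normalizing by first sample above floor",
            "radarvitals_normalizer_fallback")
  }
  abs(diff(channel / x1))
}

#' Movement features per window
#'
#' Per non-overlapping window of the pre-processed series: the variance
#' `sum(|X - mean(X)|^2) / (N - 1)` and the absolute change of the window
#' mean against the previous window (`delta[1] = 0`).
#'
#' @param preprocessed Output of [movement_preprocess()].
#' @param fs Sampling rate in Hz.
#' @param window_s Window length in seconds.
#' @return A list with numeric vectors `variance` and `mean_change`.
#' @export
movement_features <- function(preprocessed, fs, window_s = 2) {
  w <- window_matrix(preprocessed, floor(window_s * fs))
  n <- nrow(w)
  mu <- colMeans(w)
  v <- colSums((w - rep(mu, each = n))^2) / (n - 1)
  list(variance = v, mean_change = c(0, abs(diff(mu))))
}

#' Movement detection across modules
#'
#' A channel flags a window when `variance > var_threshold` or
#' `mean_change >= mean_change_threshold`; a module flags when any of its
#' channels flags; the window is movement only when all modules flag.
#'
#' @param var_mat,delta_mat Matrices of per-window features (windows in
#'   rows, channels in columns).
#' @param module_map Character or factor vector assigning each channel
#'   column to a module.
#' @param config A [classifier_config()].
#' @return Logical vector: movement per window.
#' @export
detect_movement <- function(var_mat, delta_mat, module_map,
                            config = classifier_config()) {
  var_mat <- as.matrix(var_mat)
  delta_mat <- as.matrix(delta_mat)
  if (length(module_map) != ncol(var_mat) || anyNA(module_map)) {
    rv_abort("module_map must assign every channel to a module",
             "radarvitals_config_error")
  }
  chan_flag <- var_mat > config$var_threshold |
    delta_mat >= config$mean_change_threshold
  modules <- unique(module_map)
  mod_flag <- vapply(modules, function(m) {
    rowSums(chan_flag[, module_map == m, drop = FALSE]) > 0
  }, logical(nrow(var_mat)))
  mod_flag <- matrix(mod_flag, nrow = nrow(var_mat))
  rowSums(mod_flag) == length(modules)
}

#' Assemble the per-window state vector
#'
#' Non-moving windows become 0 (absent) or 1 (calm). Every maximal run of
#' movement windows is classified by context: absence before and presence
#' after is a bed entry (2), presence before and absence after a bed exit
#' (3), presence on both sides an on-bed movement (4). At a recording
#' boundary the missing side counts as absent; a movement run with absence
#' on both sides (a transient with nobody in bed, which the all-module rule
#' makes very unlikely) is kept as on-bed movement.
#'
#' @param present,moving Aligned logical flag vectors per window.
#' @param window_s Window length in seconds.
#' @param t0 Start time of the first window.
#' @return A [state_vector()].
#' @export
assemble_states <- function(present, moving, window_s = 2, t0 = 0) {
  if (length(present) != length(moving)) {
    rv_abort("present and moving must be aligned", "radarvitals_shape_error")
  }
  states <- ifelse(present, 1L, 0L)
  r <- rle(as.logical(moving))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    i <- starts[k]; j <- ends[k]
    left <- if (i > 1L) isTRUE(present[i - 1L]) else FALSE
    right <- if (j < length(present)) isTRUE(present[j + 1L]) else FALSE
    code <- if (!left && right) 2L else if (left && !right) 3L else 4L
    states[i:j] <- code
  }
  state_vector(states, window_s = window_s, t0 = t0)
}

#' Presence and movement classification of a recording
#'
#' Full first stage of the pipeline: per-channel window SDs feed the
#' presence rule, the normalized-derivative features feed the movement
#' rule, and both flag sequences are assembled into the state vector.
#' The derivative series (one sample shorter than the raw channel) is
#' padded with a leading zero so movement and presence windows align.
#'
#' @param recording A `radar_recording` (see [simulate_scenario()] and
#'   [read_recording()]).
#' @param config A [classifier_config()].
#' @return A [state_vector()].
#' @export
classify_states <- function(recording, config = classifier_config()) {
  data <- recording$data
  fs <- recording$fs
  sd_mat <- apply(data, 2, window_sd, fs = fs, window_s = config$window_s)
  present <- detect_presence(sd_mat, config)
  feats <- apply(data, 2, function(ch) {
    y <- c(0, movement_preprocess(ch))
    f <- movement_features(y, fs, config$window_s)
    cbind(f$variance, f$mean_change)
  })
  k <- length(present)
  var_mat <- matrix(feats[seq_len(k), ], nrow = k)
  delta_mat <- matrix(feats[k + seq_len(k), ], nrow = k)
  module_map <- sub("_[IQ]$", "", colnames(data))
  moving <- detect_movement(var_mat, delta_mat, module_map, config)
  assemble_states(present, moving, window_s = config$window_s, t0 = 0)
}
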