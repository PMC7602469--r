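#' Band-pass filter for the heart-sound component
#'
#' Zero-phase 4th-order Butterworth band-pass isolating the micrometre-scale
#' heart-sound vibrations. Defaults to 16--80 Hz, the band in which S1/S2
#' chest-wall vibrations concentrate.
#'
#' @param d Displacement series in mm.
#' @param fs Sampling rate in Hz (> `2 * high`).
#' @param low,high Corner frequencies in Hz.
#' @param order Filter design order.
#' @return Filtered series of the same length.
#' @export
bandpass_heartsound <- function(d, fs, low = 16, high = 80, order = 4) {
  if (fs <= 2 * high) {
    rv_abort("fs must exceed twice the upper corner frequency",
             "radarvitals_invalid_argument")
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, d))
}

#' Envelope features for heart-sound segmentation
#'
#' Per feature frame: (a) the Hilbert envelope and (b) the homomorphic
#' envelope (low-passed log envelope, exponentiated back), both low-passed,
#' downsampled to `feature_fs` and normalized to zero mean / unit variance
#' over the section (constant channels are guarded to zeros).
#'
#' @param x Band-passed heart-sound signal.
#' @param fs Sampling rate in Hz.
#' @param feature_fs Feature frame rate in Hz.
#' @param t0 Time of the first sample in seconds.
#' @return A frames-by-2 matrix with attributes `feature_fs` and `t_s`
#'   (frame times).
#' @export
heartsound_features <- function(x, fs, feature_fs = 50, t0 = 0) {
  if (length(x) / fs < 3) {
    rv_abort("section shorter than 3 s", "radarvitals_too_short")
  }
  env <- hilbert_envelope(x)
  lp <- signal::butter(2, min(0.45, 15 / (fs / 2)), type = "low")
  env_lp <- as.numeric(signal::filtfilt(lp, env))
  mx <- max(env)
  if (mx <= 0) {
    hom_lp <- rep(0, length(x))
  } else {
    lp8 <- signal::butter(2, min(0.45, 8 / (fs / 2)), type = "low")
    hom_lp <- exp(as.numeric(signal::filtfilt(lp8, log(env / mx + 1e-4))))
  }
  q <- max(1L, round(fs / feature_fs))
  idx <- seq(1L, length(x), by = q)
  feats <- cbind(hilbert = zscore(env_lp[idx]),
                 homomorphic = zscore(hom_lp[idx]))
  attr(feats, "feature_fs") <- fs / q
  attr(feats, "t_s") <- t0 + (idx - 1) / fs
  feats
}

#' Duration-explicit HSMM parameters for heart-sound segmentation
#'
#' Four states in strict cyclic order S1, systole, S2, diastole. Each state
#' carries a Gaussian emission model over the feature space and a
#' discretized Gaussian duration model truncated to `[min_s, max_s]`.
#'
#' @param emission_mean 4-by-F matrix of per-state feature means.
#' @param emission_cov List of four F-by-F covariance matrices.
#' @param duration Data frame with columns `mean_s`, `sd_s`, `min_s`,
#'   `max_s` (seconds), one row per state.
#' @param feature_fs Feature frame rate the durations are discretized at.
#' @return An object of class `hsmm_params`.
#' @export
hsmm_params <- function(emission_mean, emission_cov, duration,
                        feature_fs = 50) {
  states <- c("S1", "systole", "S2", "diastole")
  emission_mean <- as.matrix(emission_mean)
  if (nrow(emission_mean) != 4L || length(emission_cov) != 4L ||
      nrow(duration) != 4L) {
    rv_abort("need parameters for the four states", "radarvitals_invalid_argument")
  }
  if (any(duration$mean_s <= 0) || any(duration$sd_s <= 0) ||
      any(duration$min_s <= 0) || any(duration$max_s < duration$min_s)) {
    rv_abort("invalid duration model", "radarvitals_invalid_argument")
  }
  for (cv in emission_cov) {
    if (any(eigen(as.matrix(cv), symmetric = TRUE,
                  only.values = TRUE)$values <= 0)) {
      rv_abort("emission covariances must be positive definite",
               "radarvitals_invalid_argument")
    }
  }
  rownames(emission_mean) <- states
  rownames(duration) <- states
  structure(list(states = states,
                 emission_mean = emission_mean,
                 emission_cov = lapply(emission_cov, as.matrix),
                 duration = duration,
                 feature_fs = feature_fs),
            class = "hsmm_params")
}

#' @export
print.hsmm_params <- function(x, ...) {
  cat("<hsmm_params> cyclic S1 -> systole -> S2 -> diastole\n")
  d <- x$duration
  for (i in 1:4) {
    cat(sprintf("  %-8s duration %.0f +/- %.0f ms [%.0f, %.0f]\n",
                x$states[i], 1000 * d$mean_s[i], 1000 * d$sd_s[i],
                1000 * d$min_s[i], 1000 * d$max_s[i]))
  }
  invisible(x)
}

# Discretized truncated-Gaussian duration log-pmf and log-survivor for one
# state, in frames. Returns list(logp, logS, dmin, dmax).
duration_tables <- function(mean_s, sd_s, min_s, max_s, feature_fs) {
  dmin <- max(1L, round(min_s * feature_fs))
  dmax <- max(dmin, round(max_s * feature_fs))
  mu <- mean_s * feature_fs
  sg <- max(sd_s * feature_fs, 0.5)
  d <- dmin:dmax
  p <- stats::pnorm(d + 0.5, mu, sg) - stats::pnorm(d - 0.5, mu, sg)
  p <- pmax(p, 1e-300)
  p <- p / sum(p)
  logp <- rep(-Inf, dmax)
  logp[d] <- log(p)
  surv <- rev(cumsum(rev(p)))  # P(D >= d) within the truncation
  logS <- rep(-Inf, dmax)
  logS[d] <- log(pmax(surv, 1e-300))
  if (dmin > 1L) logS[seq_len(dmin - 1L)] <- 0  # P(D >= d) = 1 below the minimum
  list(logp = logp, logS = logS, dmin = dmin, dmax = dmax)
}

# Gaussian log-density of feature rows under state s.
emission_loglik <- function(features, mean_vec, cov_mat) {
  ch <- chol(cov_mat)
  z <- forwardsolve(t(ch), t(features) - mean_vec)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) -
    0.5 * length(mean_vec) * log(2 * pi)
}

#' Duration-explicit Viterbi decoding of heart-sound states
#'
#' Maximum a-posteriori state sequence under the cyclic four-state hidden
#' semi-Markov model: transitions are deterministic (S1 to systole to S2 to
#' diastole and back), each run is scored by its truncated-Gaussian duration
#' probability, and the first and last (boundary-censored) runs by the
#' duration survivor function. The start state is uniform.
#'
#' @param features Frames-by-F feature matrix (see [heartsound_features()]).
#' @param params An [hsmm_params()].
#' @return An object of class `beat_segmentation` with per-frame `labels`
#'   (factor over the four states), `s1_onsets` (seconds; an S1 run starting
#'   at the first frame is censored and excluded), `ibis` (seconds) and the
#'   decoding `logLik`.
#' @export
hsmm_viterbi <- function(features, params) {
  features <- as.matrix(features)
  if (!all(is.finite(features))) {
    rv_abort("features must be finite", "radarvitals_invalid_argument")
  }
  Tn <- nrow(features)
  S <- 4L
  feature_fs <- attr(features, "feature_fs")
  if (is.null(feature_fs)) feature_fs <- params$feature_fs
  t_s <- attr(features, "t_s")
  if (is.null(t_s)) t_s <- (seq_len(Tn) - 1) / feature_fs

  dur <- lapply(1:S, function(s) {
    duration_tables(params$duration$mean_s[s], params$duration$sd_s[s],
                    params$duration$min_s[s], params$duration$max_s[s],
                    feature_fs)
  })
  # cumulative emission log-likelihoods: C[[s]][t + 1] = sum over frames 1..t
  Cum <- lapply(1:S, function(s) {
    c(0, cumsum(emission_loglik(features, params$emission_mean[s, ],
                                params$emission_cov[[s]])))
  })
  prev <- c(4L, 1L, 2L, 3L)
  log_start <- -log(S)

  delta <- matrix(-Inf, Tn, S)
  psi_d <- matrix(0L, Tn, S)
  for (t in seq_len(Tn)) {
    for (s in 1:S) {
      dmax <- dur[[s]]$dmax
      best <- -Inf; best_d <- 0L
      # run continuing from a previous state, interior duration scoring
      dmx <- min(dmax, t - 1L)
      if (dmx >= 1L) {
        ds <- seq_len(dmx)
        cand <- delta[t - ds, prev[s]] + dur[[s]]$logp[ds] +
          (Cum[[s]][t + 1L] - Cum[[s]][t + 1L - ds])
        i <- which.max(cand)
        if (length(i) && cand[i] > best) { best <- cand[i]; best_d <- ds[i] }
      }
      # left-censored first run covering frames 1..t
      if (t <= dmax) {
        cand0 <- log_start + dur[[s]]$logS[t] + (Cum[[s]][t + 1L] - Cum[[s]][1L])
        if (cand0 > best) { best <- cand0; best_d <- t }
      }
      delta[t, s] <- best
      psi_d[t, s] <- best_d
    }
  }

  # termination: the last run is right-censored (survivor scoring)
  best <- -Inf; best_s <- 1L; best_d <- Tn
  for (s in 1:S) {
    dmax <- dur[[s]]$dmax
    dmx <- min(dmax, Tn - 1L)
    if (dmx >= 1L) {
      ds <- seq_len(dmx)
      cand <- delta[Tn - ds, prev[s]] + dur[[s]]$logS[ds] +
        (Cum[[s]][Tn + 1L] - Cum[[s]][Tn + 1L - ds])
      i <- which.max(cand)
      if (length(i) && cand[i] > best) { best <- cand[i]; best_s <- s; best_d <- ds[i] }
    }
    if (Tn <= dmax) {  # whole sequence one censored run
      cand0 <- log_start + dur[[s]]$logS[Tn] + (Cum[[s]][Tn + 1L] - Cum[[s]][1L])
      if (cand0 > best) { best <- cand0; best_s <- s; best_d <- Tn }
    }
  }

  labels <- integer(Tn)
  t <- Tn; s <- best_s; d <- best_d
  labels[(t - d + 1L):t] <- s
  t <- t - d
  while (t > 0L) {
    s <- prev[s]
    d <- psi_d[t, s]
    labels[(t - d + 1L):t] <- s
    t <- t - d
  }

  runs <- rle(labels)
  run_start <- cumsum(c(1L, runs$lengths[-length(runs$lengths)]))
  s1_starts <- run_start[runs$values == 1L]
  s1_starts <- s1_starts[s1_starts > 1L]  # a run at frame 1 is censored
  onsets <- t_s[s1_starts]
  ibis <- diff(onsets)
  if (length(ibis) < 1L) {
    rv_warn("decoding yielded fewer than 2 S1 runs", "radarvitals_few_beats")
  }
  structure(list(labels = factor(params$states[labels],
                                 levels = params$states),
                 s1_onsets = onsets,
                 ibis = ibis,
                 logLik = best,
                 feature_fs = feature_fs),
            class = "beat_segmentation")
}

#' @export
print.beat_segmentation <- function(x, ...) {
  cat(sprintf("<beat_segmentation> %d frames, %d S1 onsets",
              length(x$labels), length(x$s1_onsets)))
  if (length(x$ibis)) cat(sprintf(", mean IBI %.3f s", mean(x$ibis)))
  cat("\n")
  invisible(x)
}

#' Supervised moment estimation of HSMM parameters
#'
#' Estimates per-state emission mean/covariance from labeled frames and the
#' duration mean/SD from labeled run lengths (boundary runs are censored and
#' excluded from the duration statistics). SD floors keep degenerate inputs
#' decodable; the truncation range defaults to `mean +/- 4 SD`.
#'
#' @param features Frames-by-F feature matrix.
#' @param labels Per-frame labels (integers 1..4 or the state names).
#' @param feature_fs Feature frame rate in Hz.
#' @param sd_floor_s Minimum duration SD in seconds.
#' @param cov_ridge Ridge added to the emission covariance diagonal.
#' @return An [hsmm_params()].
#' @export
fit_hsmm_params <- function(features, labels, feature_fs = 50,
                            sd_floor_s = 0.02, cov_ridge = 1e-4) {
  features <- as.matrix(features)
  states <- c("S1", "systole", "S2", "diastole")
  if (is.character(labels) || is.factor(labels)) {
    labels <- match(as.character(labels), states)
  }
  labels <- as.integer(labels)
  if (!all(1:4 %in% labels)) {
    rv_abort("every state must be represented in the labels",
             "radarvitals_estimation_error")
  }
  runs <- rle(labels)
  nr <- length(runs$lengths)
  interior <- if (nr > 2L) 2L:(nr - 1L) else integer(0)
  emission_mean <- matrix(0, 4, ncol(features))
  emission_cov <- vector("list", 4)
  duration <- data.frame(mean_s = numeric(4), sd_s = numeric(4),
                         min_s = numeric(4), max_s = numeric(4))
  for (s in 1:4) {
    f <- features[labels == s, , drop = FALSE]
    emission_mean[s, ] <- colMeans(f)
    cv <- if (nrow(f) > 1L) stats::cov(f) else diag(ncol(features))
    emission_cov[[s]] <- cv + diag(cov_ridge, ncol(features))
    dl <- runs$lengths[runs$values == s &
                         seq_len(nr) %in% c(interior, 0L)]
    if (!length(dl)) dl <- runs$lengths[runs$values == s]
    mean_s <- mean(dl) / feature_fs
    sd_s <- max(stats::sd(dl) / feature_fs, sd_floor_s, 1 / feature_fs,
                na.rm = TRUE)
    duration$mean_s[s] <- mean_s
    duration$sd_s[s] <- sd_s
    duration$min_s[s] <- max(1 / feature_fs, mean_s - 4 * sd_s)
    duration$max_s[s] <- mean_s + 4 * sd_s
  }
  hsmm_params(emission_mean, emission_cov, duration, feature_fs)
}

#' Default HSMM parameters from a synthetic calibration recording
#'
#' Simulates one minute of noiseless heart-sound displacement at the given
#' heart-rate prior, computes envelope features, labels frames from the
#' generative S1/S2 onsets (S2 placed at 35% of the cycle) and fits the
#' model by supervised moment estimation. This makes the heartbeat chain
#' self-contained: no phonocardiogram training corpus is required.
#'
#' @param heart_rate Heart-rate prior in bpm.
#' @param feature_fs Feature frame rate in Hz.
#' @param fs Simulation sampling rate in Hz.
#' @param duration_s Calibration duration in seconds.
#' @param seed Integer seed for the calibration simulation.
#' @return An [hsmm_params()].
#' @export
default_hsmm_params <- function(heart_rate = 70, feature_fs = 50, fs = 500,
                                duration_s = 60, seed = 101L) {
  prof <- vital_profile(respiration_amplitude = 0, heart_rate = heart_rate,
                        rate_jitter = 0.02)
  sim <- simulate_displacement(prof, duration_s, fs, seed = seed)
  x <- bandpass_heartsound(sim$d, fs)
  feats <- heartsound_features(x, fs, feature_fs)
  t_f <- attr(feats, "t_s")
  ons <- c(sim$beat_onsets, duration_s)
  k <- findInterval(t_f, ons)
  k[k < 1L] <- 1L
  k[k >= length(ons)] <- length(ons) - 1L
  u <- t_f - ons[k]
  cyc <- ons[k + 1L] - ons[k]
  s1 <- prof$s1_duration / 1000
  s2 <- prof$s2_duration / 1000
  labels <- ifelse(u < s1, 1L,
                   ifelse(u < 0.35 * cyc, 2L,
                          ifelse(u < 0.35 * cyc + s2, 3L, 4L)))
  fit_hsmm_params(feats, labels, feature_fs)
}

#' Interbeat intervals as a 1 Hz interval series
#'
#' Applies the same conditioning chain as the respiration analysis (median
#' filter 5, smoother 6, linear interpolation onto the 1 s grid) to the
#' decoded S1 onsets.
#'
#' @param segmentation A `beat_segmentation` (or a numeric vector of S1
#'   onset times in seconds).
#' @return An [interval_series()] of interbeat intervals.
#' @export
ibis_to_series <- function(segmentation) {
  onsets <- if (inherits(segmentation, "beat_segmentation")) {
    segmentation$s1_onsets
  } else as.numeric(segmentation)
  condition_intervals(onsets)
}

#' Interbeat intervals from a displacement section
#'
#' The heartbeat chain: heart-sound band-pass, envelope features,
#' duration-explicit Viterbi segmentation and interval conditioning.
#'
#' @param d Displacement in mm, or a `displacement_signal`.
#' @param fs Sampling rate in Hz (taken from the object when applicable).
#' @param params An [hsmm_params()]; defaults to the synthetic calibration
#'   model at `heart_rate_prior`.
#' @param heart_rate_prior Heart-rate prior in bpm for the default model.
#' @param t0 Time of the first sample in seconds.
#' @param low,high Band-pass corners in Hz.
#' @param feature_fs Feature frame rate in Hz.
#' @return A list with `intervals` (an [interval_series()]) and the
#'   `segmentation`.
#' @export
heartbeat_intervals <- function(d, fs = NULL, params = NULL,
                                heart_rate_prior = 70, t0 = 0,
                                low = 16, high = 80, feature_fs = 50) {
  if (inherits(d, "displacement_signal")) {
    fs <- d$fs
    t0 <- d$t[1]
    d <- d$d
  }
  if (is.null(fs)) {
    rv_abort("fs is required", "radarvitals_invalid_argument")
  }
  if (is.null(params)) {
    params <- default_hsmm_params(heart_rate_prior, feature_fs)
  }
  x <- bandpass_heartsound(d, fs, low, high)
  feats <- heartsound_features(x, fs, feature_fs, t0 = t0)
  seg <- hsmm_viterbi(feats, params)
  list(intervals = ibis_to_series(seg), segmentation = seg)
}
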