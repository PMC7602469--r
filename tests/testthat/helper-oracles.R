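# Independent oracles and shared fixtures for the test suite.

# Direct-summation window SD/variance: naive loops over explicit windows.
oracle_window_sd <- function(x, n_per_window) {
  k <- floor(length(x) / n_per_window)
  out <- numeric(k)
  for (w in seq_len(k)) {
    v <- x[((w - 1) * n_per_window + 1):(w * n_per_window)]
    m <- sum(v) / length(v)
    acc <- 0
    for (s in v) acc <- acc + abs(s - m)^2
    out[w] <- sqrt(acc / (length(v) - 1))
  }
  out
}

oracle_window_var <- function(x, n_per_window) {
  oracle_window_sd(x, n_per_window)^2
}

# Brute-force interval RMSE over the common 1 Hz grid.
oracle_rmse <- function(pred, ref) {
  common <- intersect(pred$time, ref$time)
  acc <- 0
  for (tt in common) {
    acc <- acc + (ref$resampled[ref$time == tt] - pred$resampled[pred$time == tt])^2
  }
  sqrt(acc / length(common))
}

# Manual per-sample atan2 + unwrap loop.
oracle_demodulate <- function(I, Q) {
  phi <- numeric(length(I))
  phi[1] <- atan2(Q[1], I[1])
  for (i in 2:length(I)) {
    raw <- atan2(Q[i], I[i])
    d <- raw - atan2(Q[i - 1], I[i - 1])
    d <- d - 2 * pi * round(d / (2 * pi))
    phi[i] <- phi[i - 1] + d
  }
  phi
}

# Exhaustive enumeration of every duration-feasible cyclic labeling of a
# short frame sequence, scored like the duration-explicit model (censored
# first/last runs use the duration survivor). Returns the best score.
oracle_hsmm <- function(features, params) {
  Tn <- nrow(features)
  ffs <- attr(features, "feature_fs")
  if (is.null(ffs)) ffs <- params$feature_fs
  dur <- lapply(1:4, function(s) radarvitals:::duration_tables(
    params$duration$mean_s[s], params$duration$sd_s[s],
    params$duration$min_s[s], params$duration$max_s[s], ffs))
  ll <- sapply(1:4, function(s) radarvitals:::emission_loglik(
    features, params$emission_mean[s, ], params$emission_cov[[s]]))
  ll <- matrix(ll, nrow = Tn)
  nxt <- c(2L, 3L, 4L, 1L)
  best <- -Inf
  rec <- function(t, s, score, first) {
    for (d in 1:(Tn - t + 1)) {
      if (d > dur[[s]]$dmax) break
      emis <- sum(ll[t:(t + d - 1), s])
      last <- (t + d - 1) == Tn
      dsc <- if (first || last) {
        dur[[s]]$logS[d]
      } else if (d < dur[[s]]$dmin) -Inf else dur[[s]]$logp[d]
      if (!is.finite(dsc)) next
      sc <- score + dsc + emis
      if (last) {
        if (sc > best) best <<- sc
      } else {
        rec(t + d, nxt[s], sc, FALSE)
      }
    }
  }
  for (s in 1:4) rec(1L, s, log(1 / 4), TRUE)
  best
}

random_hsmm_instance <- function(n_frames, feature_fs = 10) {
  mu <- matrix(rnorm(8), 4, 2)
  cv <- replicate(4, {
    A <- matrix(rnorm(4), 2)
    crossprod(A) + diag(0.5, 2)
  }, simplify = FALSE)
  durd <- data.frame(mean_s = runif(4, 0.1, 0.4), sd_s = runif(4, 0.05, 0.2))
  durd$min_s <- pmax(0.1, durd$mean_s - 0.2)
  durd$max_s <- durd$mean_s + 0.3
  p <- hsmm_params(mu, cv, durd, feature_fs)
  f <- matrix(rnorm(2 * n_frames), n_frames, 2)
  attr(f, "feature_fs") <- feature_fs
  list(features = f, params = p)
}

# One shared default scenario per test run (simulation at 2000 Sa/s is the
# expensive part; every consumer reads the same seeded realization).
scenario_cache <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      memo <<- simulate_scenario(default_scenario(), seed = 7)
    }
    memo
  }
})
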