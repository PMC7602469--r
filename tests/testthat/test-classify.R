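# Presence/movement classification: windowed features and state assembly.

test_that("window SD matches hand-computed and statistical expectations", {
  expect_equal(window_sd(rep(3.7, 40), fs = 10, window_s = 2), rep(0, 2))
  # one 4-sample window of [1, -1, 1, -1]: SD = sqrt(4/3)
  expect_equal(window_sd(c(1, -1, 1, -1), fs = 2, window_s = 2),
               sqrt(4 / 3))
  set.seed(1)
  sds <- window_sd(rnorm(40000, sd = 2.5), fs = 20000, window_s = 2)
  expect_lt(abs(sds[1] - 2.5) / 2.5, 0.05)
  expect_error(window_sd(c(1, 2), fs = 10, window_s = 2),
               class = "radarvitals_empty_input")
})

test_that("presence rule reads 'more than four of eight' strictly", {
  cfg <- classifier_config()
  five_over <- matrix(c(rep(1.0, 5), rep(0.1, 3)), nrow = 1)
  expect_true(detect_presence(five_over, cfg))
  four_over <- matrix(c(rep(1.0, 4), rep(0.1, 4)), nrow = 1)
  expect_false(detect_presence(four_over, cfg))
  expect_false(detect_presence(matrix(0, 1, 8), cfg))
  expect_error(detect_presence(matrix(1, 1, 4), cfg),
               class = "radarvitals_shape_error")
})

test_that("presence is monotone in the channel SDs", {
  set.seed(2)
  cfg <- classifier_config()
  for (i in 1:20) {
    m <- matrix(runif(8 * 6, 0, 1.5), ncol = 8)
    base <- detect_presence(m, cfg)
    m2 <- m
    j <- sample(8, 1)
    m2[, j] <- m2[, j] + runif(1, 0, 2)
    expect_true(all(detect_presence(m2, cfg) >= base))
  }
})

test_that("movement preprocessing normalizes by the first value and differentiates", {
  expect_equal(movement_preprocess(rep(5, 10)), rep(0, 9))
  expect_equal(movement_preprocess(c(2, 4, 2)), c(1, 1))
  # linear ramp x1 * (1 + k t) has constant normalized derivative k dt
  x <- 3 * (1 + 0.2 * seq(0, 1, by = 0.01))
  expect_equal(movement_preprocess(x), rep(0.2 * 0.01, 100))
  expect_warning(y <- movement_preprocess(c(0, 2, 4, 2)),
                 class = "radarvitals_normalizer_fallback")
  expect_equal(y, abs(diff(c(0, 2, 4, 2) / 2)))
})

test_that("movement features implement the variance and mean-change definitions", {
  f0 <- movement_features(rep(2e-4, 40), fs = 10, window_s = 2)
  expect_equal(f0$variance, rep(0, 2))
  expect_equal(f0$mean_change, rep(0, 2))
  # two windows with means 1e-4 and 6e-4
  y <- c(rep(1e-4, 20), rep(6e-4, 20))
  f <- movement_features(y, fs = 10, window_s = 2)
  expect_equal(f$mean_change, c(0, 5e-4))
  # brute-force agreement on an alternating series
  y2 <- rep(c(0, 2e-4), 30)
  f2 <- movement_features(y2, fs = 10, window_s = 2)
  expect_equal(f2$variance, oracle_window_var(y2, 20), tolerance = 1e-15)
})

test_that("movement requires every module to flag", {
  cfg <- classifier_config()
  map <- rep(c("A", "B", "C", "D"), each = 2)
  v <- matrix(0, 1, 8); d <- matrix(0, 1, 8)
  expect_false(detect_movement(v, d, map, cfg))
  v3 <- v; v3[1, c(1, 3, 5)] <- 5e-8   # module D quiet
  expect_false(detect_movement(v3, d, map, cfg))
  v4 <- v; v4[1, c(1, 3, 5, 7)] <- 5e-8
  expect_true(detect_movement(v4, d, map, cfg))
  # mean-change threshold is inclusive
  d4 <- d; d4[1, c(2, 4, 6, 8)] <- 4e-4
  expect_true(detect_movement(v, d4, map, cfg))
  expect_error(detect_movement(v, d, rep(NA, 8), cfg),
               class = "radarvitals_config_error")
})

test_that("state assembly classifies movement runs by their context", {
  sv <- assemble_states(present = c(FALSE, FALSE, TRUE, TRUE, TRUE),
                        moving = c(FALSE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(sv$states, c(0L, 2L, 2L, 1L, 1L))
  expect_equal(assemble_states(rep(FALSE, 4), rep(FALSE, 4))$states,
               rep(0L, 4))
  sv2 <- assemble_states(present = c(TRUE, TRUE, FALSE, FALSE),
                         moving = c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(sv2$states, c(1L, 3L, 3L, 0L))
  sv3 <- assemble_states(present = c(TRUE, TRUE, TRUE),
                         moving = c(FALSE, TRUE, FALSE))
  expect_equal(sv3$states, c(1L, 4L, 1L))
})

test_that("assembled state vectors obey the entry/exit grammar", {
  set.seed(3)
  for (i in 1:30) {
    n <- sample(6:40, 1)
    present <- runif(n) < 0.6
    moving <- runif(n) < 0.3
    st <- assemble_states(present, moving)$states
    expect_true(all(st %in% 0:4))
    r <- rle(st)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values == 2L)) {
      if (starts[k] > 1) expect_equal(st[starts[k] - 1], 0L)
      if (ends[k] < n) expect_equal(st[ends[k] + 1], 1L)
    }
    for (k in which(r$values == 3L)) {
      if (starts[k] > 1) expect_equal(st[starts[k] - 1], 1L)
      if (ends[k] < n) expect_equal(st[ends[k] + 1], 0L)
    }
  }
})

test_that("movement features ignore a global DC offset of the raw channel", {
  set.seed(4)
  x <- 30 + cumsum(rnorm(4000, sd = 1e-3))
  f1 <- movement_features(c(0, movement_preprocess(x)), fs = 1000, window_s = 2)
  f2 <- movement_features(c(0, movement_preprocess(x + 15)), fs = 1000,
                          window_s = 2)
  # normalizer changes (x1 differs) but the derivative removes the offset:
  # rescaling by x1/x1' makes the features identical
  ratio <- (x[1] / (x[1] + 15))^2
  expect_equal(f2$variance / f1$variance, rep(ratio, 2), tolerance = 1e-9)
})
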