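# Scenario simulator: displacement generator, I/Q forward model, scripts.

test_that("displacement generator honours rates, jitter and the zero case", {
  prof0 <- vital_profile(respiration_amplitude = 0, heartsound_amplitude = 0)
  sim0 <- simulate_displacement(prof0, 10, 200, seed = 1)
  expect_true(all(sim0$d == 0))
  expect_length(sim0$breath_onsets, 0)
  expect_length(sim0$beat_onsets, 0)

  prof <- vital_profile(respiration_rate = 15, heartsound_amplitude = 0,
                        rate_jitter = 0)
  sim <- simulate_displacement(prof, 60, 200, seed = 1)
  expect_length(sim$breath_onsets, 15)
  expect_equal(diff(sim$breath_onsets), rep(4, 14))

  prof_h <- vital_profile(respiration_amplitude = 0, heart_rate = 60,
                          rate_jitter = 0.02)
  sim_h <- simulate_displacement(prof_h, 120, 500, seed = 5)
  expect_lt(abs(mean(diff(sim_h$beat_onsets)) - 1.00), 0.03)

  expect_error(simulate_displacement(prof, -1, 200),
               class = "radarvitals_invalid_argument")
  expect_error(simulate_displacement(prof, 10, 0),
               class = "radarvitals_invalid_argument")
})

test_that("generator is bit-reproducible under a fixed seed", {
  prof <- vital_profile()
  a <- simulate_displacement(prof, 30, 500, seed = 42)
  b <- simulate_displacement(prof, 30, 500, seed = 42)
  expect_identical(a, b)
  sc1 <- simulate_scenario(default_scenario(), fs = 200, seed = 9)
  sc2 <- simulate_scenario(default_scenario(), fs = 200, seed = 9)
  expect_identical(sc1$recording$data, sc2$recording$data)
})

test_that("jitter-free respiration concentrates at the programmed frequency", {
  for (rate in c(10, 18)) {
    prof <- vital_profile(respiration_rate = rate, heartsound_amplitude = 0,
                          rate_jitter = 0)
    fs <- 50
    sim <- simulate_displacement(prof, 120, fs, seed = 2)
    spec <- Mod(stats::fft(sim$d - mean(sim$d)))^2
    n <- length(sim$d)
    freqs <- (seq_len(n) - 1) * fs / n
    half <- 2:floor(n / 2)
    peak <- freqs[half][which.max(spec[half])]
    expect_lt(abs(peak - rate / 60), fs / n + 1e-12)
  }
})

test_that("ideal I/Q samples lie on the unit circle and sweep it once per half wavelength", {
  lam <- carrier_wavelength_mm(24)
  # constant phase for zero displacement
  iq0 <- displacement_to_iq(rep(0, 100), lam, phi_static = 0.8)
  expect_equal(iq0$I, rep(cos(0.8), 100))
  expect_equal(iq0$Q, rep(sin(0.8), 100))
  # d sweeping 0 -> lambda/2 covers the full circle exactly once
  d <- seq(0, lam / 2, length.out = 2000)
  iq <- displacement_to_iq(d, lam, phi_static = 0)
  expect_equal(iq$I^2 + iq$Q^2, rep(1, 2000), tolerance = 1e-12)
  phi <- demodulate_phase(iq$I, iq$Q)
  expect_equal(phi[2000] - phi[1], 2 * pi, tolerance = 1e-9)
  expect_error(displacement_to_iq(d, -1), class = "radarvitals_invalid_argument")
})

test_that("scenario scripts enforce the entry/exit grammar", {
  seg <- function(l, d) list(label = l, duration = d)
  expect_error(scenario_script(list(seg("entry", 5))),
               class = "radarvitals_invalid_scenario")
  expect_error(scenario_script(list(seg("absent", 10), seg("rest", 20))),
               class = "radarvitals_invalid_scenario")
  expect_error(
    scenario_script(list(seg("absent", 10), seg("entry", 5), seg("rest", 20),
                         seg("exit", 5), seg("rest", 10))),
    class = "radarvitals_invalid_scenario")
  expect_error(scenario_script(list(seg("absent", 0))),
               class = "radarvitals_invalid_scenario")
  ok <- scenario_script(list(seg("absent", 10), seg("entry", 5),
                             seg("rest", 30), seg("exit", 5),
                             seg("absent", 10)))
  expect_s3_class(ok, "scenario_script")
})

test_that("simulated scenarios carry consistent ground truth", {
  seg <- function(l, d) list(label = l, duration = d)
  quiet <- scenario_script(list(seg("absent", 30)))
  sc <- simulate_scenario(quiet, fs = 200, seed = 3)
  expect_true(all(sc$truth$states$states == 0L))
  # absent channels are offset plus noise: tiny variability
  expect_true(all(apply(sc$recording$data, 2, sd) < 0.01))

  simple <- scenario_script(list(seg("absent", 10), seg("entry", 4),
                                 seg("rest", 30), seg("exit", 4),
                                 seg("absent", 10)))
  sc2 <- simulate_scenario(simple, fs = 200, seed = 4)
  st <- sc2$truth$states$states
  r <- rle(st)
  expect_equal(sum(r$values == 2L), 1L)
  expect_equal(sum(r$values == 3L), 1L)
  # state grammar: entries sit at absent->calm transitions, exits the reverse
  for (k in which(r$values == 2L)) {
    if (k > 1) expect_equal(r$values[k - 1], 0L)
    if (k < length(r$values)) expect_equal(r$values[k + 1], 1L)
  }
  for (k in which(r$values == 3L)) {
    if (k > 1) expect_equal(r$values[k - 1], 1L)
    if (k < length(r$values)) expect_equal(r$values[k + 1], 0L)
  }
  expect_true(all(diff(sc2$truth$breath_onsets) > 0))
  expect_true(all(diff(sc2$truth$beat_onsets) > 0))
})
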