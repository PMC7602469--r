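# Ellipse fitting, unit-circle normalization, arctangent demodulation.

make_ellipse <- function(theta, center = c(0, 0), axes = c(1, 1), tilt = 0) {
  list(I = center[1] + axes[1] * cos(theta) * cos(tilt) -
         axes[2] * sin(theta) * sin(tilt),
       Q = center[2] + axes[1] * cos(theta) * sin(tilt) +
         axes[2] * sin(theta) * cos(tilt))
}

test_that("direct fit recovers circles and ellipses exactly from exact points", {
  th <- seq(0, 2 * pi, length.out = 101)[-101]
  circ <- make_ellipse(th)
  p <- fit_ellipse(circ$I, circ$Q)
  expect_equal(p$center, c(0, 0), tolerance = 1e-9)
  expect_equal(p$semi_axes, c(1, 1), tolerance = 1e-9)

  ell <- make_ellipse(th, center = c(0.3, -0.2), axes = c(1.2, 0.8),
                      tilt = 30 * pi / 180)
  p2 <- fit_ellipse(ell$I, ell$Q)
  expect_equal(p2$center, c(0.3, -0.2), tolerance = 1e-6)
  expect_equal(p2$semi_axes, c(1.2, 0.8), tolerance = 1e-6)
  expect_equal(p2$tilt, 30 * pi / 180, tolerance = 1e-6)
})

test_that("degenerate point sets raise a degenerate-fit error", {
  x <- seq(0, 1, length.out = 10)
  expect_error(fit_ellipse(x, 2 * x + 1), class = "radarvitals_degenerate_fit")
  expect_error(fit_ellipse(rep(1, 20), rep(2, 20)),
               class = "radarvitals_degenerate_fit")
  expect_error(fit_ellipse(1:4, 1:4), class = "radarvitals_degenerate_fit")
})

test_that("fitting is equivariant under rotation of the point cloud", {
  th <- seq(0.2, 5.8, length.out = 200)
  ell <- make_ellipse(th, center = c(0.5, 0.1), axes = c(1.5, 0.9),
                      tilt = 10 * pi / 180)
  p0 <- fit_ellipse(ell$I, ell$Q)
  for (alpha in c(0.3, 1.1)) {
    I2 <- cos(alpha) * ell$I - sin(alpha) * ell$Q
    Q2 <- sin(alpha) * ell$I + cos(alpha) * ell$Q
    p <- fit_ellipse(I2, Q2)
    expect_equal(p$semi_axes, p0$semi_axes, tolerance = 1e-6)
    expect_equal(sqrt(sum(p$center^2)), sqrt(sum(p0$center^2)),
                 tolerance = 1e-6)
    dtilt <- (p$tilt - (p0$tilt + alpha)) %% pi
    expect_lt(min(dtilt, pi - dtilt), 1e-6)
  }
})

test_that("normalization maps on-ellipse points to the unit circle", {
  th <- seq(0, 2 * pi, length.out = 300)
  ell <- make_ellipse(th, center = c(0.3, -0.2), axes = c(1.2, 0.8),
                      tilt = 30 * pi / 180)
  p <- fit_ellipse(ell$I, ell$Q)
  nz <- normalize_to_unit_circle(ell$I, ell$Q, p)
  expect_equal(sqrt(nz$I^2 + nz$Q^2), rep(1, 300), tolerance = 1e-6)
  # identity parameters leave the data untouched
  id <- ellipse_params(c(0, 0), c(1, 1), 0)
  nz2 <- normalize_to_unit_circle(ell$I, ell$Q, id)
  expect_equal(nz2$I, ell$I)
  expect_equal(nz2$Q, ell$Q)
  # pure offset subtracts the center
  off <- ellipse_params(c(0.7, -1.2), c(1, 1), 0)
  nz3 <- normalize_to_unit_circle(ell$I, ell$Q, off)
  expect_equal(nz3$I, ell$I - 0.7)
  expect_equal(nz3$Q, ell$Q + 1.2)
})

test_that("normalize-then-refit yields the identity ellipse", {
  th <- seq(0, 2 * pi, length.out = 200)
  ell <- make_ellipse(th, center = c(-0.4, 0.25), axes = c(2.0, 1.1),
                      tilt = -0.7)
  p <- fit_ellipse(ell$I, ell$Q)
  nz <- normalize_to_unit_circle(ell$I, ell$Q, p)
  p2 <- fit_ellipse(nz$I, nz$Q)
  expect_equal(p2$center, c(0, 0), tolerance = 1e-6)
  expect_equal(p2$semi_axes, c(1, 1), tolerance = 1e-6)
})

test_that("demodulation unwraps multi-turn phase and matches the per-sample oracle", {
  th <- seq(0, 6 * pi, length.out = 3000)
  phi <- demodulate_phase(cos(th), sin(th))
  expect_equal(phi[1], 0)
  expect_equal(phi[3000], 6 * pi, tolerance = 1e-9)
  expect_true(all(abs(diff(phi)) < pi))
  expect_equal(demodulate_phase(rep(1, 50), rep(0, 50)), rep(0, 50))
  set.seed(5)
  ph_true <- cumsum(rnorm(500, 0, 0.8))
  I <- cos(ph_true); Q <- sin(ph_true)
  expect_equal(demodulate_phase(I, Q), oracle_demodulate(I, Q),
               tolerance = 1e-12)
})

test_that("low-radius samples are interpolated rather than demodulated", {
  th <- seq(0, pi, length.out = 100)
  I <- cos(th); Q <- sin(th)
  I[50] <- 0.001; Q[50] <- 0.001  # collapsed sample
  phi <- demodulate_phase(I, Q)
  expect_lt(abs(phi[50] - th[50]), 0.05)
})

test_that("phase scales to displacement by lambda / (4 pi)", {
  expect_equal(phase_to_displacement(rep(0, 5), 12.49), rep(0, 5))
  expect_equal(phase_to_displacement(4 * pi, 12.49), 12.49)
  expect_error(phase_to_displacement(1, 0), class = "radarvitals_invalid_argument")
})

test_that("reconstruction is linear in the simulated displacement", {
  fs <- 200
  lam <- carrier_wavelength_mm(24)
  tt <- seq(0, 30, by = 1 / fs)
  d1 <- 0.8 * (1 - cos(2 * pi * 0.25 * tt)) / 2  # arc stays below 2 pi
  dist <- channel_distortion(gain_I = 1.1, gain_Q = 0.9, offset_I = 0.2,
                             offset_Q = -0.1, phase_skew = 3)
  rec <- function(d) {
    iq <- displacement_to_iq(d, lam, dist, phi_static = 1.0)
    p <- fit_ellipse(iq$I, iq$Q)
    nz <- normalize_to_unit_circle(iq$I, iq$Q, p)
    phi <- demodulate_phase(nz$I, nz$Q)
    phase_to_displacement(phi - phi[1], lam)
  }
  r1 <- rec(d1)
  r2 <- rec(2 * d1)
  expect_lt(max(abs(r2 - 2 * r1)), 0.01 * max(abs(r2)))
})

test_that("section-wise reconstruction processes calm runs only", {
  sc <- scenario_cache()
  # empty result for an all-absent recording
  seg <- function(l, d) list(label = l, duration = d)
  quiet <- simulate_scenario(scenario_script(list(seg("absent", 20))),
                             fs = 200, seed = 1)
  empty <- reconstruct_sections(quiet$recording, quiet$truth$states)
  expect_length(empty, 0)

  states <- classify_states(sc$recording)
  secs <- reconstruct_sections(sc$recording, states)
  expect_equal(length(unique(vapply(secs, function(s) s$section_id,
                                    integer(1)))), 4L)
  expect_setequal(unique(vapply(secs, function(s) s$module, character(1))),
                  c("A", "B", "C", "D"))
  # reconstructed displacement tracks the generated truth on rest sections
  truth <- sc$truth
  for (s in secs[vapply(secs, function(s) s$module == "B", logical(1))]) {
    idx <- round(s$t * sc$recording$fs) + 1L
    dt <- truth$displacement[idx, "B"]
    expect_gt(abs(cor(s$d, dt - dt[1])), 0.99)
  }
})
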