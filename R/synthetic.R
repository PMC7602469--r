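#' Vital-sign profile for the scenario simulator
#'
#' Describes the quasi-periodic chest motion of a resting subject: a
#' respiration displacement on the millimetre scale and heart-sound
#' micro-vibrations (S1/S2 bursts) on the micrometre scale.
#'
#' @param respiration_rate Breaths per minute (4--40).
#' @param respiration_amplitude Peak respiration displacement in mm.
#' @param heart_rate Beats per minute (40--180).
#' @param heartsound_amplitude Peak S1 burst amplitude in micrometres.
#' @param s1_duration,s2_duration Durations of the S1 and S2 bursts in ms.
#' @param rate_jitter Fractional standard deviation of the cycle length,
#'   applied independently per respiration and cardiac cycle.
#' @return An object of class `vital_profile`.
#' @export
vital_profile <- function(respiration_rate = 15,
                          respiration_amplitude = 4,
                          heart_rate = 70,
                          heartsound_amplitude = 20,
                          s1_duration = 120,
                          s2_duration = 100,
                          rate_jitter = 0.03) {
  if (respiration_amplitude < 0 || heartsound_amplitude < 0) {
    rv_abort("amplitudes must be nonnegative", "radarvitals_invalid_argument")
  }
  if (respiration_rate < 4 || respiration_rate > 40) {
    rv_abort("respiration_rate must lie in 4..40 BrPM", "radarvitals_invalid_argument")
  }
  if (heart_rate < 40 || heart_rate > 180) {
    rv_abort("heart_rate must lie in 40..180 bpm", "radarvitals_invalid_argument")
  }
  structure(list(respiration_rate = respiration_rate,
                 respiration_amplitude = respiration_amplitude,
                 heart_rate = heart_rate,
                 heartsound_amplitude = heartsound_amplitude,
                 s1_duration = s1_duration,
                 s2_duration = s2_duration,
                 rate_jitter = rate_jitter),
            class = "vital_profile")
}

#' Per-channel I/Q distortion model
#'
#' Gain imbalance distorts the ideal unit circle into an ellipse, DC offsets
#' shift its centre, phase skew tilts it, and additive noise scatters the
#' samples around it.
#'
#' @param gain_I,gain_Q Channel amplitudes in mV (must be positive).
#' @param offset_I,offset_Q DC offsets in mV.
#' @param phase_skew Quadrature phase error in degrees.
#' @param noise_sd Additive white noise standard deviation in mV.
#' @return An object of class `channel_distortion`.
#' @export
channel_distortion <- function(gain_I = 1, gain_Q = 1,
                               offset_I = 0, offset_Q = 0,
                               phase_skew = 0, noise_sd = 0) {
  if (gain_I <= 0 || gain_Q <= 0) {
    rv_abort("gains must be positive", "radarvitals_invalid_argument")
  }
  if (noise_sd < 0) {
    rv_abort("noise_sd must be nonnegative", "radarvitals_invalid_argument")
  }
  structure(list(gain_I = gain_I, gain_Q = gain_Q,
                 offset_I = offset_I, offset_Q = offset_Q,
                 phase_skew = phase_skew, noise_sd = noise_sd),
            class = "channel_distortion")
}

# Generate quasi-periodic event times: onsets at 0, then successive periods
# 60/rate * (1 + jitter * z). Returns onsets inside [0, duration) plus one
# closing onset at or beyond `duration` so the last cycle has a length.
quasi_periodic_onsets <- function(rate, jitter, duration) {
  period <- 60 / rate
  onsets <- 0
  t <- 0
  repeat {
    t <- t + period * max(0.2, 1 + jitter * stats::rnorm(1))
    onsets <- c(onsets, t)
    if (t >= duration) break
  }
  onsets
}

#' Simulate resting chest displacement
#'
#' Generates the combined respiration and cardiac displacement seen by the
#' radar: raised-cosine respiration cycles plus Gaussian-windowed ~40 Hz
#' heart-sound bursts (S1 at the beat onset, S2 at 35% of the cardiac
#' cycle, at 60% of the S1 amplitude).
#'
#' @param profile A [vital_profile()].
#' @param duration Duration in seconds (> 0).
#' @param fs Sampling rate in Hz (>= 200 for heart-sound content).
#' @param seed Integer seed; the generator is bit-reproducible under a fixed
#'   seed.
#' @return A list with `d` (displacement in mm), `t` (time in s), `fs`,
#'   `breath_onsets` and `beat_onsets` (exact generative event times in s).
#' @export
simulate_displacement <- function(profile, duration, fs, seed = 1L) {
  if (duration <= 0 || fs <= 0) {
    rv_abort("duration and fs must be positive", "radarvitals_invalid_argument")
  }
  if (fs < 200 && profile$heartsound_amplitude > 0) {
    rv_warn("fs < 200 Hz under-resolves heart-sound bursts", "radarvitals_low_fs")
  }
  n <- floor(duration * fs)
  t <- (seq_len(n) - 1) / fs
  with_seed(seed, {
    d <- numeric(n)
    breath_onsets <- numeric(0)
    beat_onsets <- numeric(0)
    if (profile$respiration_amplitude > 0) {
      ons <- quasi_periodic_onsets(profile$respiration_rate, profile$rate_jitter,
                                   duration)
      k <- findInterval(t, ons)
      u <- (t - ons[k]) / (ons[k + 1] - ons[k])
      d <- d + profile$respiration_amplitude * (1 - cos(2 * pi * u)) / 2
      breath_onsets <- ons[ons < duration]
    }
    if (profile$heartsound_amplitude > 0) {
      ons <- quasi_periodic_onsets(profile$heart_rate, profile$rate_jitter,
                                   duration)
      amp_mm <- profile$heartsound_amplitude / 1000
      s1 <- profile$s1_duration / 1000
      s2 <- profile$s2_duration / 1000
      for (i in seq_len(length(ons) - 1)) {
        cyc <- ons[i + 1] - ons[i]
        d <- add_burst(d, t, fs, ons[i], s1, amp_mm)
        d <- add_burst(d, t, fs, ons[i] + 0.35 * cyc, s2, 0.6 * amp_mm)
      }
      beat_onsets <- ons[ons < duration]
    }
    list(d = d, t = t, fs = fs,
         breath_onsets = breath_onsets, beat_onsets = beat_onsets)
  })
}

# Add one Gaussian-windowed 40 Hz burst starting at `start` with the given
# duration (seconds) and peak amplitude (mm) into d.
add_burst <- function(d, t, fs, start, dur, amp, f0 = 40) {
  i0 <- max(1L, floor(start * fs) + 1L)
  i1 <- min(length(d), ceiling((start + dur) * fs) + 1L)
  if (i0 > i1) return(d)
  idx <- i0:i1
  tc <- start + dur / 2
  sigma <- dur / 6
  d[idx] <- d[idx] +
    amp * exp(-((t[idx] - tc)^2) / (2 * sigma^2)) * sin(2 * pi * f0 * (t[idx] - tc))
  d
}

#' Convert displacement to distorted I/Q channel data
#'
#' Forward model of a CW radar channel pair: the target displacement phase
#' modulates the carrier, `phi(t) = 4 pi d(t) / lambda + phi_static`, and the
#' ideal unit circle `(cos phi, sin phi)` is then deformed by the channel
#' distortion: `I = gain_I cos(phi) + offset_I`, `Q = gain_Q sin(phi + skew)
#' + offset_Q`, plus white noise.
#'
#' @param d Displacement series in mm.
#' @param wavelength Carrier wavelength in mm (> 0).
#' @param distortion A [channel_distortion()].
#' @param phi_static Static path phase in radians; drawn uniformly from
#'   `[0, 2 pi)` under `seed` when `NULL`.
#' @param seed Integer seed for static phase and noise.
#' @return A list with `I` and `Q` in mV and the `phi_static` used.
#' @export
displacement_to_iq <- function(d, wavelength, distortion = channel_distortion(),
                               phi_static = NULL, seed = 1L) {
  if (wavelength <= 0) {
    rv_abort("wavelength must be positive", "radarvitals_invalid_argument")
  }
  with_seed(seed, {
    if (is.null(phi_static)) phi_static <- stats::runif(1, 0, 2 * pi)
    phi <- 4 * pi * d / wavelength + phi_static
    skew <- distortion$phase_skew * pi / 180
    n <- length(d)
    I <- distortion$gain_I * cos(phi) + distortion$offset_I
    Q <- distortion$gain_Q * sin(phi + skew) + distortion$offset_Q
    if (distortion$noise_sd > 0) {
      I <- I + stats::rnorm(n, 0, distortion$noise_sd)
      Q <- Q + stats::rnorm(n, 0, distortion$noise_sd)
    }
    list(I = I, Q = Q, phi_static = phi_static)
  })
}

#' Scenario script for the simulator
#'
#' An ordered sequence of segments describing an in-bed measurement:
#' `absent`, `entry`, `rest`, `on_bed_move`, `exit`. Rest segments carry a
#' [vital_profile()]; per-module coupling gains in `[0, 1]` model how
#' strongly the lying position couples chest motion into each module.
#'
#' @param segments A data frame (or list of lists) with columns `label` and
#'   `duration` in seconds; rest segments may carry a `profile` list column.
#' @param profiles Optional list of [vital_profile()]s, one per rest segment
#'   (recycled if length one). Used when `segments` has no profile column.
#' @param couplings Named numeric vector of per-module coupling gains in
#'   `[0, 1]` for modules A--D.
#' @return An object of class `scenario_script`.
#' @export
scenario_script <- function(segments,
                            profiles = list(vital_profile()),
                            couplings = c(A = 0.9, B = 1, C = 1, D = 0.8)) {
  if (is.data.frame(segments)) {
    segs <- lapply(seq_len(nrow(segments)), function(i) {
      as.list(segments[i, c("label", "duration")])
    })
  } else {
    segs <- segments
  }
  labels <- vapply(segs, function(s) s$label, character(1))
  durations <- vapply(segs, function(s) s$duration, numeric(1))
  valid <- c("absent", "entry", "rest", "on_bed_move", "exit")
  if (!all(labels %in% valid)) {
    rv_abort("unknown segment label", "radarvitals_invalid_scenario")
  }
  if (any(durations <= 0)) {
    rv_abort("segment durations must be positive", "radarvitals_invalid_scenario")
  }
  # grammar: entry only after absent; exit only followed by absent
  for (i in seq_along(labels)) {
    if (labels[i] == "entry" &&
        (i == 1L || labels[i - 1] != "absent")) {
      rv_abort("entry must follow an absent segment", "radarvitals_invalid_scenario")
    }
    if (labels[i] == "exit" &&
        (i == length(labels) || labels[i + 1] != "absent")) {
      rv_abort("exit must be followed by an absent segment",
               "radarvitals_invalid_scenario")
    }
    if (labels[i] %in% c("rest", "on_bed_move") &&
        (i == 1L || labels[i - 1] == "absent")) {
      rv_abort("occupied segments must be preceded by entry/rest/move",
               "radarvitals_invalid_scenario")
    }
  }
  n_rest <- sum(labels == "rest")
  if (any(labels %in% c("entry", "rest", "on_bed_move", "exit")) && n_rest == 0L) {
    rv_abort("at least one rest segment per occupied period",
             "radarvitals_invalid_scenario")
  }
  if (length(profiles) == 1L && n_rest > 1L) {
    profiles <- rep(profiles, n_rest)
  }
  if (n_rest > 0L && length(profiles) < n_rest) {
    rv_abort("need one vital profile per rest segment",
             "radarvitals_invalid_scenario")
  }
  if (any(couplings < 0 | couplings > 1)) {
    rv_abort("couplings must lie in [0, 1]", "radarvitals_invalid_scenario")
  }
  structure(list(labels = labels, durations = durations,
                 profiles = profiles, couplings = couplings),
            class = "scenario_script")
}

#' Default test scenario
#'
#' Bed entry after 15 s of absence, four 30 s rest positions separated by
#' three on-bed movements, then exit and 15 s of absence -- the protocol used
#' throughout the package's tests.
#'
#' @param profiles Vital profiles for the four rest segments.
#' @inheritParams scenario_script
#' @return A `scenario_script`.
#' @export
default_scenario <- function(profiles = list(vital_profile()),
                             couplings = c(A = 0.9, B = 1, C = 1, D = 0.8)) {
  labels <- c("absent", "entry",
              "rest", "on_bed_move", "rest", "on_bed_move",
              "rest", "on_bed_move", "rest",
              "exit", "absent")
  durations <- c(15, 4, 30, 4, 30, 4, 30, 4, 30, 4, 15)
  scenario_script(mapply(function(l, d) list(label = l, duration = d),
                         labels, durations, SIMPLIFY = FALSE),
                  profiles = profiles, couplings = couplings)
}

#' Default per-channel distortions for the scenario simulator
#'
#' Channel amplitudes of a few mV with mild I/Q gain imbalance, DC offsets
#' of a few tens of mV (large against the motion signal, as for a real
#' direct-conversion front end), a few degrees of quadrature skew and a
#' microvolt-scale noise floor.
#'
#' @param seed Integer seed.
#' @param noise_sd Noise SD in mV applied to every channel.
#' @return A list of eight [channel_distortion()]s named `A_I, A_Q, ...`.
#' @export
default_distortions <- function(seed = 1L, noise_sd = 0.002) {
  with_seed(seed, {
    out <- list()
    for (m in c("A", "B", "C", "D")) {
      base <- stats::runif(1, 4, 6)
      imb <- stats::runif(1, 0.9, 1.1)
      offs <- stats::runif(2, 25, 40) * sample(c(-1, 1), 2, replace = TRUE)
      skew <- stats::runif(1, -6, 6)
      out[[paste0(m, "_I")]] <- channel_distortion(
        gain_I = base, gain_Q = base * imb,
        offset_I = offs[1], offset_Q = offs[2],
        phase_skew = skew, noise_sd = noise_sd)
    }
    out
  })
}

#' Simulate a full multi-module radar scenario
#'
#' Renders a [scenario_script()] into an 8-channel recording (I and Q for
#' modules A--D) with ground truth. Absent segments contain offset-plus-noise
#' only; entry/exit/movement segments contain broadband displacement
#' transients spanning several wavelengths (guaranteeing phase wrap and
#' movement-threshold exceedance); rest segments embed the vital-sign
#' displacement scaled by the module coupling, preceded by a slow
#' calibration excursion that sweeps enough arc for the downstream ellipse
#' fit.
#'
#' @param script A [scenario_script()].
#' @param distortions A list of eight [channel_distortion()]s (one per I/Q
#'   module pair; the `*_I` entry of each module is used for both channels).
#' @param fs Sampling rate in Hz.
#' @param carriers_ghz Named per-module carrier frequencies in GHz.
#' @param seed Integer seed.
#' @param calibration Logical; prepend a 5 mm / 8 s half-cosine calibration
#'   excursion to every rest segment.
#' @return A list with `recording` (class `radar_recording`: `data` matrix of
#'   8 mV channels, `t`, `fs`, `modules`) and `truth` (class
#'   `radar_ground_truth`: per-module displacement, per-2-s-window states,
#'   breath and beat onset times).
#' @export
simulate_scenario <- function(script,
                              distortions = default_distortions(seed),
                              fs = 2000,
                              carriers_ghz = c(A = 24.000, B = 24.075,
                                               C = 24.150, D = 24.225),
                              seed = 1L,
                              calibration = TRUE) {
  if (!inherits(script, "scenario_script")) {
    rv_abort("script must be a scenario_script", "radarvitals_invalid_scenario")
  }
  with_seed(seed, {
    durations <- script$durations
    labels <- script$labels
    n_seg <- as.integer(floor(durations * fs))
    n <- sum(n_seg)
    t <- (seq_len(n) - 1) / fs
    seg_start <- cumsum(c(0L, n_seg[-length(n_seg)]))

    d_base <- numeric(n)       # subject displacement, mm
    coupling_env <- numeric(n) # 0 when absent, ramps during entry/exit
    sample_state <- integer(n)
    breath_onsets <- numeric(0)
    beat_onsets <- numeric(0)
    rest_idx <- 0L
    state_code <- c(absent = 0L, rest = 1L, entry = 2L, exit = 3L,
                    on_bed_move = 4L)

    for (i in seq_along(labels)) {
      idx <- seg_start[i] + seq_len(n_seg[i])
      lab <- labels[i]
      t0 <- seg_start[i] / fs
      sample_state[idx] <- state_code[[lab]]
      if (lab == "absent") {
        coupling_env[idx] <- 0
      } else if (lab %in% c("entry", "exit", "on_bed_move")) {
        ramp <- if (lab == "entry") {
          (1 - cos(pi * seq_len(n_seg[i]) / n_seg[i])) / 2
        } else if (lab == "exit") {
          (1 + cos(pi * seq_len(n_seg[i]) / n_seg[i])) / 2
        } else rep(1, n_seg[i])
        coupling_env[idx] <- ramp
        d_base[idx] <- movement_transient(n_seg[i], fs)
      } else { # rest
        rest_idx <- rest_idx + 1L
        coupling_env[idx] <- 1
        prof <- script$profiles[[min(rest_idx, length(script$profiles))]]
        sim <- simulate_displacement(prof, n_seg[i] / fs, fs,
                                     seed = sample.int(2^30, 1))
        d <- sim$d
        if (calibration) {
          n_cal <- min(n_seg[i], floor(8 * fs))
          cal <- 5 * (1 - cos(2 * pi * seq_len(n_cal) / n_cal)) / 2
          d[seq_len(n_cal)] <- d[seq_len(n_cal)] + cal
        }
        d_base[idx] <- d
        breath_onsets <- c(breath_onsets, sim$breath_onsets + t0)
        beat_onsets <- c(beat_onsets, sim$beat_onsets + t0)
      }
    }

    modules <- names(carriers_ghz)
    data <- matrix(0, nrow = n, ncol = 2L * length(modules))
    colnames(data) <- as.vector(rbind(paste0(modules, "_I"),
                                      paste0(modules, "_Q")))
    d_module <- matrix(0, nrow = n, ncol = length(modules),
                       dimnames = list(NULL, modules))
    for (m in seq_along(modules)) {
      dist <- distortions[[paste0(modules[m], "_I")]]
      if (is.null(dist)) dist <- distortions[[m]]
      lambda <- carrier_wavelength_mm(carriers_ghz[[m]])
      coup <- script$couplings[[modules[m]]]
      d_m <- coup * d_base
      d_module[, m] <- d_m * coupling_env
      phi_static <- stats::runif(1, 0, 2 * pi)
      iq <- displacement_to_iq(d_m, lambda,
                               channel_distortion(dist$gain_I, dist$gain_Q,
                                                  0, 0, dist$phase_skew, 0),
                               phi_static = phi_static, seed = NULL)
      # amplitude collapses to zero while nobody reflects; offsets remain
      I <- iq$I * coupling_env + dist$offset_I
      Q <- iq$Q * coupling_env + dist$offset_Q
      if (dist$noise_sd > 0) {
        I <- I + stats::rnorm(n, 0, dist$noise_sd)
        Q <- Q + stats::rnorm(n, 0, dist$noise_sd)
      }
      data[, 2L * m - 1L] <- I
      data[, 2L * m] <- Q
    }

    window_n <- floor(2 * fs)
    k <- floor(n / window_n)
    win_states <- vapply(seq_len(k), function(w) {
      majority_label(sample_state[(w - 1L) * window_n + seq_len(window_n)])
    }, integer(1))

    recording <- structure(list(
      data = data, t = t, fs = fs,
      modules = data.frame(name = modules,
                           carrier_ghz = as.numeric(carriers_ghz)),
      units = "mV"), class = "radar_recording")
    truth <- structure(list(
      displacement = d_module,
      t = t, fs = fs,
      states = state_vector(win_states, window_s = 2, t0 = 0),
      breath_onsets = breath_onsets,
      beat_onsets = beat_onsets,
      sample_state = sample_state), class = "radar_ground_truth")
    list(recording = recording, truth = truth)
  })
}

# Band-limited broadband displacement transient of several wavelengths,
# produced by integrating low-passed white-noise velocity (~200 mm/s SD).
movement_transient <- function(n, fs) {
  v <- stats::rnorm(n)
  bf <- signal::butter(2, min(0.99, 1.5 / (fs / 2)), type = "low")
  v <- as.numeric(signal::filtfilt(bf, v))
  v <- v / stats::sd(v) * 200
  cumsum(v) / fs
}

# Majority vote over integer labels; ties resolve to the higher code.
majority_label <- function(x) {
  tab <- table(x)
  cand <- as.integer(names(tab)[tab == max(tab)])
  max(cand)
}

#' @export
print.radar_recording <- function(x, ...) {
  cat(sprintf("<radar_recording> %d channels x %d samples @ %g Sa/s (%.1f s)\n",
              ncol(x$data), nrow(x$data), x$fs, nrow(x$data) / x$fs))
  cat("  modules:", paste(sprintf("%s (%.3f GHz)", x$modules$name,
                                  x$modules$carrier_ghz), collapse = ", "), "\n")
  invisible(x)
}
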