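#' Ellipse parameters of an I/Q point cloud
#'
#' @param center Numeric length-2 centre `(I, Q)` in mV.
#' @param semi_axes Numeric length-2 semi-axes in mV, major first.
#' @param tilt Major-axis orientation in radians, in `(-pi/2, pi/2]`.
#' @return An object of class `ellipse_params`.
#' @export
ellipse_params <- function(center, semi_axes, tilt) {
  if (any(semi_axes <= 0)) {
    rv_abort("semi-axes must be positive", "radarvitals_invalid_argument")
  }
  if (tilt <= -pi / 2 || tilt > pi / 2) {
    rv_abort("tilt must lie in (-pi/2, pi/2]", "radarvitals_invalid_argument")
  }
  structure(list(center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes),
                 tilt = tilt),
            class = "ellipse_params")
}

#' @export
print.ellipse_params <- function(x, ...) {
  cat(sprintf("<ellipse_params> center (%.4g, %.4g), semi-axes (%.4g, %.4g), tilt %.2f deg\n",
              x$center[1], x$center[2], x$semi_axes[1], x$semi_axes[2],
              x$tilt * 180 / pi))
  invisible(x)
}

#' Direct least-squares ellipse fit of raw I/Q data
#'
#' Fits the conic `a x^2 + b x y + c y^2 + d x + e y + f = 0` with the
#' ellipse constraint `4ac - b^2 > 0` enforced through the numerically
#' stable partitioned eigenproblem (Fitzgibbon-style direct fit), after
#' centring and isotropic scaling of the data, and converts the conic to
#' geometric parameters.
#'
#' @param I,Q Raw channel samples in mV.
#' @return An [ellipse_params()].
#' @export
fit_ellipse <- function(I, Q) {
  if (length(I) != length(Q)) {
    rv_abort("I and Q must have equal length", "radarvitals_shape_error")
  }
  if (length(I) < 6L) {
    rv_abort("need at least 6 points for an ellipse fit",
             "radarvitals_degenerate_fit")
  }
  mx <- mean(I); my <- mean(Q)
  s <- mean(sqrt((I - mx)^2 + (Q - my)^2))
  if (!is.finite(s) || s <= 0) {
    rv_abort("degenerate point cluster", "radarvitals_degenerate_fit")
  }
  x <- (I - mx) / s
  y <- (Q - my) / s

  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  if (rcond(S3) < 1e-14) {
    rv_abort("rank-deficient scatter (collinear or clustered points)",
             "radarvitals_degenerate_fit")
  }
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  M2 <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M2)
  disc <- apply(ev$vectors, 2, function(v) {
    v <- Re(v)
    4 * v[1] * v[3] - v[2]^2
  })
  ok <- which(abs(Im(ev$values)) < 1e-8 & disc > 0)
  if (!length(ok)) {
    rv_abort("direct fit returned a non-ellipse conic",
             "radarvitals_degenerate_fit")
  }
  a1 <- Re(ev$vectors[, ok[1]])
  conic <- c(a1, as.numeric(Tm %*% a1))
  geom <- conic_to_ellipse(conic)
  # undo the normalization
  ellipse_params(center = geom$center * s + c(mx, my),
                 semi_axes = geom$semi_axes * s,
                 tilt = geom$tilt)
}

# Convert conic coefficients (a, b, c, d, e, f) to geometric parameters.
conic_to_ellipse <- function(co) {
  a <- co[1]; b <- co[2]; cc <- co[3]; d <- co[4]; e <- co[5]; f <- co[6]
  den <- b^2 - 4 * a * cc
  if (!is.finite(den) || den >= -1e-300) {
    rv_abort("conic discriminant is not elliptical", "radarvitals_degenerate_fit")
  }
  cx <- (2 * cc * d - b * e) / den
  cy <- (2 * a * e - b * d) / den
  f0 <- a * cx^2 + b * cx * cy + cc * cy^2 + d * cx + e * cy + f
  Qm <- matrix(c(a, b / 2, b / 2, cc), 2)
  ee <- eigen(Qm, symmetric = TRUE)
  ax2 <- -f0 / ee$values
  if (any(!is.finite(ax2)) || any(ax2 <= 0)) {
    rv_abort("conic has no real ellipse axes", "radarvitals_degenerate_fit")
  }
  # major axis pairs with the smaller-magnitude eigenvalue
  ord <- order(ax2, decreasing = TRUE)
  axes <- sqrt(ax2[ord])
  v <- ee$vectors[, ord[1]]
  tilt <- atan2(v[2], v[1])
  if (tilt <= -pi / 2) tilt <- tilt + pi
  if (tilt > pi / 2) tilt <- tilt - pi
  if (tilt <= -pi / 2) tilt <- tilt + pi
  list(center = c(cx, cy), semi_axes = axes, tilt = tilt)
}

#' Normalize I/Q data to the unit circle
#'
#' Translates by the fitted centre, rotates into the ellipse frame, scales
#' each axis by its inverse semi-axis and rotates back. Noiseless on-ellipse
#' points map to radius 1; the map is symmetric positive definite, so the
#' recovered phase progression keeps its orientation.
#'
#' @param I,Q Raw samples in mV.
#' @param params An [ellipse_params()].
#' @return A list with unit-circle `I` and `Q`.
#' @export
normalize_to_unit_circle <- function(I, Q, params) {
  ct <- cos(params$tilt); st <- sin(params$tilt)
  u <- I - params$center[1]
  v <- Q - params$center[2]
  # rotate by -tilt
  ur <- ct * u + st * v
  vr <- -st * u + ct * v
  ur <- ur / params$semi_axes[1]
  vr <- vr / params$semi_axes[2]
  # rotate back
  list(I = ct * ur - st * vr,
       Q = st * ur + ct * vr)
}

#' Arctangent demodulation with phase unwrapping
#'
#' Four-quadrant angle of the normalized `(I, Q)` samples, unwrapped so
#' successive differences lie in `(-pi, pi]`. Samples whose radius falls
#' below `radius_floor` are flagged and their phase linearly interpolated
#' from neighbouring samples.
#'
#' @param I,Q Normalized unit-circle samples.
#' @param radius_floor Radius below which a sample is considered unreliable.
#' @return Unwrapped phase series in radians (first sample at its principal
#'   angle).
#' @export
demodulate_phase <- function(I, Q, radius_floor = 0.1) {
  r <- sqrt(I^2 + Q^2)
  good <- r >= radius_floor
  if (!any(good)) {
    rv_abort("all samples below the radius floor", "radarvitals_degenerate_fit")
  }
  idx <- which(good)
  ph_good <- atan2(Q[idx], I[idx])
  d <- diff(ph_good)
  d <- d - 2 * pi * round(d / (2 * pi))  # wrap into [-pi, pi]
  un <- ph_good[1] + cumsum(c(0, d))
  if (all(good)) return(un)
  stats::approx(idx, un, xout = seq_along(I), rule = 2)$y
}

#' Phase to relative displacement
#'
#' `d(t) = phi(t) / (4 pi) * lambda0` with the module-related wavelength
#' `lambda0` in mm.
#'
#' @param phi Unwrapped phase in radians.
#' @param lambda0 Wavelength in mm (> 0).
#' @return Relative displacement in mm.
#' @export
phase_to_displacement <- function(phi, lambda0) {
  if (lambda0 <= 0) {
    rv_abort("lambda0 must be positive", "radarvitals_invalid_argument")
  }
  phi / (4 * pi) * lambda0
}

#' Section-wise displacement reconstruction
#'
#' For every maximal calm (state 1) run of the state vector and every radar
#' module independently: ellipse fit, unit-circle normalization, arctangent
#' demodulation and scaling to relative displacement. Sections whose fit is
#' ill-conditioned (axis ratio above `max_axis_ratio`) fall back to
#' offset-only correction (centre subtraction, unit gains) with a warning;
#' sections whose fit degenerates entirely are skipped with a warning.
#'
#' @param recording A `radar_recording`.
#' @param states A [state_vector()] aligned to the recording.
#' @param skip_initial_s Seconds at the start of the recording excluded from
#'   the returned displacement (the protocol's calibration interval); the
#'   ellipse fit still uses the full section.
#' @param min_section_s Minimum section length in seconds to process.
#' @param max_axis_ratio Conditioning guard for the fitted ellipse.
#' @param fit_max_points Sections longer than this are subsampled evenly for
#'   the fit (demodulation always uses every sample).
#' @return A list of `displacement_signal` objects with fields `d` (mm),
#'   `phi` (radians), `t` (s), `lambda0` (mm), `module`, `section_id` and
#'   the fitted `params`.
#' @export
reconstruct_sections <- function(recording, states, skip_initial_s = 0,
                                 min_section_s = 4, max_axis_ratio = 20,
                                 fit_max_points = 20000L) {
  fs <- recording$fs
  wlen <- floor(states$window_s * fs)
  st <- states$states
  out <- list()
  r <- rle(st == 1L)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sec_id <- 0L
  lambdas <- carrier_wavelength_mm(recording$modules$carrier_ghz)
  for (k in which(r$values)) {
    sec_id <- sec_id + 1L
    i0 <- (starts[k] - 1L) * wlen + 1L
    i1 <- min(nrow(recording$data), ends[k] * wlen)
    if ((i1 - i0 + 1L) / fs < min_section_s) next
    idx <- i0:i1
    for (m in seq_len(nrow(recording$modules))) {
      name <- recording$modules$name[m]
      I <- recording$data[idx, paste0(name, "_I")]
      Q <- recording$data[idx, paste0(name, "_Q")]
      fit_idx <- if (length(idx) > fit_max_points) {
        unique(round(seq(1L, length(idx), length.out = fit_max_points)))
      } else seq_along(idx)
      params <- tryCatch(fit_ellipse(I[fit_idx], Q[fit_idx]),
                         radarvitals_degenerate_fit = function(e) NULL)
      if (!is.null(params) &&
          params$semi_axes[1] / params$semi_axes[2] > max_axis_ratio) {
        params <- NULL
      }
      if (is.null(params)) {
        rv_warn(sprintf("section %d module %s: ill-conditioned ellipse fit; offset-only correction",
                        sec_id, name), "radarvitals_fit_fallback")
        nz <- normalize_to_unit_circle(I, Q,
                                       ellipse_params(c(mean(I), mean(Q)),
                                                      c(1, 1), 0))
      } else {
        nz <- normalize_to_unit_circle(I, Q, params)
      }
      phi <- tryCatch(demodulate_phase(nz$I, nz$Q),
                      radarvitals_degenerate_fit = function(e) NULL)
      if (is.null(phi)) {
        rv_warn(sprintf("section %d module %s skipped: degenerate demodulation",
                        sec_id, name), "radarvitals_section_skipped")
        next
      }
      phi <- phi - phi[1]
      t_sec <- recording$t[idx]
      keep <- t_sec >= skip_initial_s
      if (!any(keep)) next
      out[[length(out) + 1L]] <- structure(list(
        d = phase_to_displacement(phi[keep], lambdas[m]),
        phi = phi[keep],
        t = t_sec[keep],
        fs = fs,
        lambda0 = lambdas[m],
        module = name,
        section_id = sec_id,
        params = params), class = "displacement_signal")
    }
  }
  out
}

#' @export
print.displacement_signal <- function(x, ...) {
  cat(sprintf("<displacement_signal> module %s section %d: %.1f s @ %g Hz, lambda0 %.3f mm, range %.3f mm\n",
              x$module, x$section_id, length(x$d) / x$fs, x$fs, x$lambda0,
              diff(range(x$d))))
  invisible(x)
}
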