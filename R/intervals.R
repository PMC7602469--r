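#' Event-interval series resampled to 1 Hz
#'
#' Container shared by the respiration and heartbeat chains: event times,
#' the raw event-to-event durations, and the conditioned series resampled
#' onto the integer-second grid used for RMSE evaluation.
#'
#' @param event_times Strictly increasing event times in seconds.
#' @param intervals Durations `event_times[k+1] - event_times[k]` in seconds.
#' @param time Resampled grid times in seconds (1 s spacing).
#' @param resampled Conditioned interval values on the grid, in seconds.
#' @return An object of class `interval_series`.
#' @export
interval_series <- function(event_times = numeric(0),
                            intervals = numeric(0),
                            time = numeric(0),
                            resampled = numeric(0)) {
  if (length(event_times) > 1 && any(diff(event_times) <= 0)) {
    rv_abort("event times must be strictly increasing",
             "radarvitals_invalid_argument")
  }
  structure(list(event_times = event_times, intervals = intervals,
                 time = time, resampled = resampled),
            class = "interval_series")
}

#' @export
print.interval_series <- function(x, ...) {
  cat(sprintf("<interval_series> %d events, %d resampled points",
              length(x$event_times), length(x$time)))
  if (length(x$resampled)) {
    cat(sprintf(", mean interval %.3f s", mean(x$resampled)))
  }
  cat("\n")
  invisible(x)
}

#' Condition event intervals for evaluation
#'
#' Turns an event-time list into the 1 Hz interval series used for RMSE
#' comparison: interval sequence, median filter of size 5 (outlier
#' rejection), centred moving-average smoother of size 6, then linear
#' interpolation onto the integer-second grid spanning
#' `[ceiling(first event), floor(last event)]`. Each interval is anchored
#' at its starting event time; the grid edges extend by constant
#' continuation.
#'
#' @param events Strictly increasing event times in seconds.
#' @param median_k Median filter span (1 disables).
#' @param smooth_k Moving-average span (1 disables).
#' @param grid_dt Resampling step in seconds.
#' @return An [interval_series()]; fewer than two events yield an empty one.
#' @export
condition_intervals <- function(events, median_k = 5L, smooth_k = 6L,
                                grid_dt = 1) {
  if (length(events) < 2L) return(interval_series(event_times = events))
  if (any(diff(events) <= 0)) {
    rv_abort("event times must be strictly increasing",
             "radarvitals_invalid_argument")
  }
  intervals <- diff(events)
  sm <- moving_average(median_filter(intervals, median_k), smooth_k)
  anchors <- events[-length(events)]
  lo <- ceiling(events[1] / grid_dt) * grid_dt
  hi <- floor(events[length(events)] / grid_dt) * grid_dt
  if (hi < lo) {
    return(interval_series(events, intervals))
  }
  grid <- seq(lo, hi, by = grid_dt)
  res <- if (length(anchors) == 1L) {
    rep(sm, length(grid))
  } else {
    stats::approx(anchors, sm, xout = grid, rule = 2)$y
  }
  interval_series(events, intervals, grid, res)
}
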