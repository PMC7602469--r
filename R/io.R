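#' Write a multichannel recording to CSV plus JSON sidecar
#'
#' The CSV holds columns `t, A_I, A_Q, B_I, B_Q, C_I, C_Q, D_I, D_Q` (time
#' in seconds, amplitudes in mV); the sidecar holds the sample rate, the
#' per-module carrier frequencies and the units.
#'
#' @param recording A `radar_recording`.
#' @param csv_path Path for the signal table.
#' @param sidecar_path Path for the JSON sidecar; defaults to the CSV path
#'   with a `.json` extension.
#' @return Invisibly, the two paths.
#' @export
write_recording <- function(recording, csv_path,
                            sidecar_path = sub("\\.csv$", ".json", csv_path)) {
  df <- data.frame(t = recording$t, recording$data, check.names = FALSE)
  utils::write.csv(df, csv_path, row.names = FALSE)
  meta <- list(fs_hz = recording$fs,
               modules = recording$modules,
               units = recording$units %||% "mV")
  jsonlite::write_json(meta, sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv_path, sidecar = sidecar_path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a multichannel recording written by [write_recording()]
#'
#' @param csv_path Path to the signal table.
#' @param sidecar_path Path to the JSON sidecar.
#' @return A `radar_recording`.
#' @export
read_recording <- function(csv_path,
                           sidecar_path = sub("\\.csv$", ".json", csv_path)) {
  if (!file.exists(sidecar_path)) {
    rv_abort("missing sidecar metadata", "radarvitals_config_error")
  }
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  df <- utils::read.csv(csv_path, check.names = FALSE)
  data <- as.matrix(df[, setdiff(names(df), "t"), drop = FALSE])
  structure(list(data = data, t = df$t, fs = meta$fs_hz,
                 modules = as.data.frame(meta$modules),
                 units = meta$units %||% "mV"),
            class = "radar_recording")
}

#' Write ground truth as JSON events plus per-window state CSV
#'
#' @param truth A `radar_ground_truth` from [simulate_scenario()].
#' @param events_path Path for the JSON event lists.
#' @param states_path Path for the per-window state CSV (columns
#'   `window_start_s, state`).
#' @return Invisibly, the two paths.
#' @export
write_ground_truth <- function(truth, events_path, states_path) {
  jsonlite::write_json(list(breath_onsets_s = truth$breath_onsets,
                            beat_onsets_s = truth$beat_onsets),
                       events_path, digits = NA)
  sv <- truth$states
  utils::write.csv(data.frame(
    window_start_s = sv$t0 + (seq_along(sv$states) - 1) * sv$window_s,
    state = sv$states), states_path, row.names = FALSE)
  invisible(c(events = events_path, states = states_path))
}

#' Write a state vector as CSV
#'
#' @param states A [state_vector()].
#' @param path Output path; columns `window_start_s, state`.
#' @export
write_states <- function(states, path) {
  utils::write.csv(data.frame(
    window_start_s = states$t0 + (seq_along(states$states) - 1) * states$window_s,
    state = states$states), path, row.names = FALSE)
  invisible(path)
}

#' Read a state vector CSV
#'
#' @param path CSV with columns `window_start_s, state`.
#' @return A [state_vector()].
#' @export
read_states <- function(path) {
  df <- utils::read.csv(path)
  window_s <- if (nrow(df) > 1) df$window_start_s[2] - df$window_start_s[1] else 2
  state_vector(df$state, window_s = window_s, t0 = df$window_start_s[1])
}

#' Write an interval series as CSV
#'
#' @param x An [interval_series()].
#' @param path Output path; columns `t_s, interval_s`.
#' @export
write_intervals <- function(x, path) {
  utils::write.csv(data.frame(t_s = x$time, interval_s = x$resampled),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read an interval series CSV
#'
#' @param path CSV with columns `t_s, interval_s`.
#' @return An [interval_series()] carrying only the resampled grid.
#' @export
read_intervals <- function(path) {
  df <- utils::read.csv(path)
  interval_series(time = df$t_s, resampled = df$interval_s)
}
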