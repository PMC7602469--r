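#' Pipeline configuration
#'
#' Bundles the tunable parameters of the full processing chain: classifier
#' thresholds, per-module carriers, the two vital-sign bands, the HSMM
#' heart-rate prior, the initial calibration skip and the evaluation
#' window.
#'
#' @param classifier A [classifier_config()].
#' @param carriers_ghz Named per-module carrier frequencies in GHz (used
#'   when the recording carries no module metadata).
#' @param resp_band,heart_band Band-pass corner pairs in Hz.
#' @param heart_rate_prior Heart-rate prior in bpm for the default HSMM.
#' @param hsmm An optional pre-fitted [hsmm_params()].
#' @param skip_initial_s Seconds ignored at the start of the recording for
#'   vital-sign evaluation (the calibration-movement interval).
#' @param eval_window_s Majority-vote evaluation window in seconds.
#' @param feature_fs Heart-sound feature frame rate in Hz.
#' @param seed Integer seed for every stochastic component.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(classifier = classifier_config(),
                            carriers_ghz = c(A = 24.000, B = 24.075,
                                             C = 24.150, D = 24.225),
                            resp_band = c(0.07, 0.7),
                            heart_band = c(16, 80),
                            heart_rate_prior = 70,
                            hsmm = NULL,
                            skip_initial_s = 20,
                            eval_window_s = 5,
                            feature_fs = 50,
                            seed = 1L) {
  if (any(resp_band <= 0) || diff(resp_band) <= 0 ||
      any(heart_band <= 0) || diff(heart_band) <= 0) {
    rv_abort("bands must be increasing positive pairs",
             "radarvitals_invalid_argument")
  }
  structure(list(classifier = classifier, carriers_ghz = carriers_ghz,
                 resp_band = resp_band, heart_band = heart_band,
                 heart_rate_prior = heart_rate_prior, hsmm = hsmm,
                 skip_initial_s = skip_initial_s,
                 eval_window_s = eval_window_s,
                 feature_fs = feature_fs, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full monitoring pipeline
#'
#' Raw recording to presence/movement states, section-wise displacement
#' reconstruction, respiration and heartbeat interval extraction, and
#' (when ground truth or references are supplied) evaluation metrics.
#' Degenerate or too-short sections are skipped with a logged reason; the
#' run continues. With `out_dir` set, stage outputs and a machine-readable
#' manifest are written there.
#'
#' @param recording A `radar_recording` or a path to a recording CSV (with
#'   its JSON sidecar next to it).
#' @param config A [pipeline_config()].
#' @param truth Optional `radar_ground_truth` for evaluation.
#' @param out_dir Optional output directory.
#' @return A list with `states`, `sections` (displacement signals),
#'   `respiration` and `heartbeat` (per module/section interval series),
#'   `metrics` (when truth given), `skipped` (reason log) and `manifest`.
#' @export
run_pipeline <- function(recording, config = pipeline_config(),
                         truth = NULL, out_dir = NULL) {
  if (is.character(recording)) recording <- read_recording(recording)
  skipped <- list()
  note_skip <- function(stage, what, reason) {
    skipped[[length(skipped) + 1L]] <<- list(stage = stage, what = what,
                                             reason = reason)
  }

  states <- classify_states(recording, config$classifier)

  sections <- withCallingHandlers(
    reconstruct_sections(recording, states,
                         skip_initial_s = config$skip_initial_s),
    radarvitals_warning = function(w) {
      note_skip("reconstruct", "section", conditionMessage(w))
      invokeRestart("muffleWarning")
    })

  hsmm <- config$hsmm
  if (is.null(hsmm) && length(sections)) {
    hsmm <- default_hsmm_params(config$heart_rate_prior, config$feature_fs,
                                seed = config$seed + 100L)
  }

  respiration <- list()
  heartbeat <- list()
  for (sec in sections) {
    key <- sprintf("%s_section%d", sec$module, sec$section_id)
    respiration[[key]] <- tryCatch(
      suppressWarnings(respiration_intervals(sec, low = config$resp_band[1],
                                             high = config$resp_band[2])),
      error = function(e) {
        note_skip("respiration", key, conditionMessage(e)); NULL
      })
    heartbeat[[key]] <- tryCatch(
      suppressWarnings(heartbeat_intervals(sec, params = hsmm,
                                           low = config$heart_band[1],
                                           high = config$heart_band[2],
                                           feature_fs = config$feature_fs)$intervals),
      error = function(e) {
        note_skip("heartbeat", key, conditionMessage(e)); NULL
      })
  }

  metrics <- NULL
  if (!is.null(truth)) {
    conf <- windowed_confusion(truth$states, states, config$eval_window_s)
    resp_ref <- condition_intervals(truth$breath_onsets)
    beat_ref <- condition_intervals(truth$beat_onsets)
    resp_rmse <- vapply(respiration, function(x) {
      if (is.null(x) || !length(x$time)) return(NA_real_)
      tryCatch(rmse_intervals(x, resp_ref), error = function(e) NA_real_)
    }, numeric(1))
    beat_rmse <- vapply(heartbeat, function(x) {
      if (is.null(x) || !length(x$time)) return(NA_real_)
      tryCatch(rmse_intervals(x, beat_ref), error = function(e) NA_real_)
    }, numeric(1))
    metrics <- list(confusion = conf,
                    state_accuracy = conf$accuracy,
                    respiration_rmse_s = resp_rmse,
                    heartbeat_rmse_s = beat_rmse)
  }

  manifest <- list(
    package = "radarvitals",
    version = as.character(utils::packageVersion("radarvitals")),
    seed = config$seed,
    fs_hz = recording$fs,
    duration_s = nrow(recording$data) / recording$fs,
    stages = list(
      classify = list(status = "complete", windows = length(states$states)),
      reconstruct = list(status = "complete", sections = length(sections)),
      respiration = list(status = "complete",
                         series = sum(!vapply(respiration, is.null, logical(1)))),
      heartbeat = list(status = "complete",
                       series = sum(!vapply(heartbeat, is.null, logical(1)))),
      evaluate = list(status = if (is.null(truth)) "skipped (no reference)"
                      else "complete")),
    skipped = skipped)

  result <- list(states = states, sections = sections,
                 respiration = respiration, heartbeat = heartbeat,
                 metrics = metrics, skipped = skipped, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_states(states, file.path(out_dir, "states.csv"))
    for (key in names(respiration)) {
      if (!is.null(respiration[[key]]) && length(respiration[[key]]$time)) {
        write_intervals(respiration[[key]],
                        file.path(out_dir, paste0("resp_", key, ".csv")))
      }
    }
    for (key in names(heartbeat)) {
      if (!is.null(heartbeat[[key]]) && length(heartbeat[[key]]$time)) {
        write_intervals(heartbeat[[key]],
                        file.path(out_dir, paste0("ibi_", key, ".csv")))
      }
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  result
}
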