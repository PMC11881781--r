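#' Runs of zero pupil diameter
#'
#' Consecutive samples recorded as exactly 0 mm are the eye tracker's
#' signature of a blink or tracking loss.
#'
#' @param x Raw diameter sequence in mm.
#' @return A tibble with one row per zero-run: `start_idx`, `end_idx`,
#'   `length` (in samples, 1-based inclusive indices).
#' @export
zero_runs <- function(x) {
  r <- rle(x == 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble::tibble(start_idx = starts[keep], end_idx = ends[keep],
                 length = r$lengths[keep])
}

trial_abort <- function(reason) {
  structure(list(reason = reason), class = "trial_abort")
}

#' Test for a detector abort
#'
#' @param x Result of [detect_blink()] or [detect_saccade()].
#' @return `TRUE` if the detector aborted the trial.
#' @export
is_abort <- function(x) inherits(x, "trial_abort")

#' Detect the single blink in a blink-condition trial
#'
#' Searches the raw (unsmoothed) diameter sequence for runs of zero that
#' last at least `blink_min_zero_ms` (60 ms = 30 samples at 500 Hz): each
#' such run denotes a blink. Exactly one qualifying run is required;
#' analysis then starts `post_blink_offset_ms` (200 ms) after the last zero
#' sample, the point at which the eyelid no longer obscures the pupil.
#'
#' @param x Raw diameter sequence in mm (zeros encode "pupil lost").
#' @param config A [pipeline_config()].
#' @return A `blink_event` (fields `zero_run_start_idx`, `zero_run_end_idx`,
#'   `analysis_start_idx`) or a `trial_abort` with reason `no_blink`,
#'   `multiple_blinks` or `truncated`.
#' @examples
#' d <- rep(3, 2000); d[966:1000] <- 0
#' detect_blink(d)$analysis_start_idx  # 1100
#' @export
detect_blink <- function(x, config = pipeline_config()) {
  config <- as_pipeline_config(config)
  min_run <- ms_to_samples(config$blink_min_zero_ms, config$rate_hz)
  runs <- zero_runs(x)
  runs <- runs[runs$length >= min_run, , drop = FALSE]
  if (nrow(runs) == 0L) return(trial_abort("no_blink"))
  if (nrow(runs) > 1L) return(trial_abort("multiple_blinks"))
  offset <- ms_to_samples(config$post_blink_offset_ms, config$rate_hz)
  start <- runs$end_idx[1] + offset
  if (start > length(x)) return(trial_abort("truncated"))
  structure(list(zero_run_start_idx = runs$start_idx[1],
                 zero_run_end_idx = runs$end_idx[1],
                 analysis_start_idx = start),
            class = "blink_event")
}

#' Detect the saccade in a saccade-condition trial
#'
#' Scans the smoothed horizontal gaze sequence sample by sample with a fixed
#' lag of `saccade_lag_ms` (40 ms = 20 samples at 500 Hz). Saccade onset is
#' the first index whose lagged gaze difference reaches
#' `saccade_delta_dva` (0.5 dva) in magnitude; the end is the first later
#' index whose lagged difference falls below it again. Leftward and
#' rightward saccades are treated symmetrically. The trial is aborted when
#' no onset is found (`no_saccade`) or when the saccade end is missing or
#' falls in the second half of the recorded samples (`late_saccade`).
#'
#' @param x Smoothed horizontal gaze sequence in dva (see [smooth_gaze()]).
#' @param config A [pipeline_config()].
#' @return A `saccade_event` (fields `onset_idx`, `offset_idx`,
#'   `amplitude_dva`) or a `trial_abort`.
#' @export
detect_saccade <- function(x, config = pipeline_config()) {
  config <- as_pipeline_config(config)
  lag <- ms_to_samples(config$saccade_lag_ms, config$rate_hz)
  n <- length(x)
  if (n <= lag) return(trial_abort("no_saccade"))
  d <- abs(x[(1L + lag):n] - x[1L:(n - lag)])
  above <- d >= config$saccade_delta_dva
  onset <- which(above)[1]
  if (is.na(onset)) return(trial_abort("no_saccade"))
  rest <- which(!above[-seq_len(onset)])
  if (!length(rest)) return(trial_abort("late_saccade"))
  offset <- onset + rest[1]
  if (offset > n %/% 2L) return(trial_abort("late_saccade"))
  structure(list(onset_idx = onset, offset_idx = offset,
                 amplitude_dva = x[offset] - x[onset]),
            class = "saccade_event")
}

#' Locate the analysis start of a trial
#'
#' Onset trials are analysed from the first sample (data collection begins
#' at pattern appearance); blink trials from 200 ms after the last zero of
#' the single detected blink; saccade trials from the detected saccade end.
#' Detector aborts, and stray zero samples in onset trials (extraneous
#' blinks or data loss), mark the trial invalid with a reason.
#'
#' @param trial A [trial_record()].
#' @param config A [pipeline_config()].
#' @return A list with `start_idx` (NA when invalid), `valid`, `reason`
#'   (NA when valid) and `event` (the detector result, when any).
#' @export
analysis_window <- function(trial, config = pipeline_config()) {
  config <- as_pipeline_config(config)
  d <- trial$trace$pupil_mm
  res <- switch(trial$experiment,
    onset = {
      if (any(d == 0)) trial_abort("extraneous_blink") else
        structure(list(analysis_start_idx = 1L), class = "onset_event")
    },
    blink = detect_blink(d, config),
    saccade = {
      ev <- detect_saccade(smooth_gaze(trial$trace$gaze_x_dva, config), config)
      if (!is_abort(ev)) ev$analysis_start_idx <- ev$offset_idx
      ev
    }
  )
  if (is_abort(res)) {
    list(start_idx = NA_integer_, valid = FALSE, reason = res$reason,
         event = res)
  } else {
    list(start_idx = res$analysis_start_idx, valid = TRUE,
         reason = NA_character_, event = res)
  }
}
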