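#' Pipeline configuration
#'
#' Collects every numeric threshold used by the analysis in one place, with
#' defaults matching the published analysis of the peripheral-drift
#' pupillometry experiments: outliers are samples more than three scaled
#' median absolute deviations from the median within a moving 400 ms window;
#' smoothing is a centred 100 ms moving mean; a blink is a run of zero
#' diameter samples lasting at least 60 ms, analysed from 200 ms after the
#' last zero; a saccade is a horizontal gaze difference of at least 0.5 dva
#' across two samples 40 ms apart; the display background was 202 cd/m^2.
#'
#' @param outlier_window_ms Moving window for median/MAD outlier flagging (ms).
#' @param outlier_k Threshold in scaled MADs.
#' @param mad_scale Gaussian consistency constant for the scaled MAD.
#' @param smooth_window_ms Moving-mean window (ms).
#' @param blink_min_zero_ms Minimum zero-run length that counts as a blink (ms).
#' @param post_blink_offset_ms Analysis starts this long after the last zero (ms).
#' @param saccade_delta_dva Gaze-difference threshold for saccade detection (dva).
#' @param saccade_lag_ms Lag between the two compared gaze samples (ms).
#' @param rate_hz Sampling rate (Hz).
#' @param background_luminance_cdm2 Display background luminance (cd/m^2).
#' @param diameter_min_mm,diameter_max_mm Plausibility band for non-zero
#'   pupil diameters after preprocessing (mm).
#' @param min_trials_per_cell Minimum number of valid trials for a
#'   (participant, stimulus, experiment) correlation cell.
#' @param grid_tol_ms Tolerance on the uniform time grid (ms).
#'
#' @return A `pipeline_config` object (a validated named list).
#' @examples
#' cfg <- pipeline_config()
#' cfg$rate_hz
#' @export
pipeline_config <- function(outlier_window_ms = 400,
                            outlier_k = 3,
                            mad_scale = 1.4826,
                            smooth_window_ms = 100,
                            blink_min_zero_ms = 60,
                            post_blink_offset_ms = 200,
                            saccade_delta_dva = 0.5,
                            saccade_lag_ms = 40,
                            rate_hz = 500,
                            background_luminance_cdm2 = 202,
                            diameter_min_mm = 1,
                            diameter_max_mm = 9,
                            min_trials_per_cell = 3,
                            grid_tol_ms = 1e-6) {
  cfg <- list(
    outlier_window_ms = outlier_window_ms,
    outlier_k = outlier_k,
    mad_scale = mad_scale,
    smooth_window_ms = smooth_window_ms,
    blink_min_zero_ms = blink_min_zero_ms,
    post_blink_offset_ms = post_blink_offset_ms,
    saccade_delta_dva = saccade_delta_dva,
    saccade_lag_ms = saccade_lag_ms,
    rate_hz = rate_hz,
    background_luminance_cdm2 = background_luminance_cdm2,
    diameter_min_mm = diameter_min_mm,
    diameter_max_mm = diameter_max_mm,
    min_trials_per_cell = min_trials_per_cell,
    grid_tol_ms = grid_tol_ms
  )
  num <- vapply(cfg, function(v) is.numeric(v) && length(v) == 1L && is.finite(v), logical(1))
  if (!all(num)) {
    stop("pipeline_config: all fields must be finite scalars; offending: ",
         paste(names(cfg)[!num], collapse = ", "))
  }
  pos <- vapply(cfg, function(v) v > 0, logical(1))
  if (!all(pos)) {
    stop("pipeline_config: all fields must be strictly positive; offending: ",
         paste(names(cfg)[!pos], collapse = ", "))
  }
  if (diameter_min_mm >= diameter_max_mm) {
    stop("pipeline_config: diameter_min_mm must be below diameter_max_mm")
  }
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) cat(sprintf("  %-26s %g\n", nm, x[[nm]]))
  invisible(x)
}

# Convert a duration in ms to a whole number of samples at `rate_hz`.
ms_to_samples <- function(ms, rate_hz) {
  k <- as.integer(round(ms * rate_hz / 1000))
  if (k < 1L) stop("window of ", ms, " ms is below one sample at ", rate_hz, " Hz")
  k
}

as_pipeline_config <- function(config) {
  if (inherits(config, "pipeline_config")) return(config)
  if (is.list(config)) return(do.call(pipeline_config, config))
  stop("config must be a pipeline_config or a named list")
}

#' Short provenance hash of a configuration
#'
#' 32-bit FNV-1a hash of the JSON serialisation, used to stamp output tables
#' so results can be traced back to the thresholds that produced them.
#'
#' @param config A [pipeline_config()] (or any jsonlite-serialisable list).
#' @return An 8-character hex string.
#' @export
config_hash <- function(config) {
  txt <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low byte (b < 256); keep h a double to allow 2^32 range
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    # 32-bit FNV prime multiplication in double precision: split to avoid
    # exceeding 2^53 (h < 2^32, prime = 2^24 + 403)
    h <- (h * 403 + (h %% 256) * 16777216) %% 4294967296
  }
  sprintf("%08x", h)
}
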