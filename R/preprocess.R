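#' Centred moving average
#'
#' Moving mean over a window of `k` samples, centred on each element with
#' the convention of the Matlab `movmean` function the analysis mirrors: an
#' even window of length `k` covers `k/2` samples before and `k/2 - 1` after
#' the current one, and the window shrinks at the sequence edges (no
#' padding), so edge means are taken over the available samples only.
#'
#' @param x Numeric sequence.
#' @param k Window length in samples.
#' @return Numeric sequence of the same length.
#' @export
moving_average <- function(x, k) {
  n <- length(x)
  if (n == 0L) return(x)
  k <- as.integer(k)
  if (k < 1L) stop("window must be at least one sample")
  before <- k %/% 2L
  after <- k - before - 1L
  idx <- seq_len(n)
  lo <- pmax(1L, idx - before)
  hi <- pmin(n, idx + after)
  cs <- cumsum(c(0, x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Windowed median/MAD outlier removal
#'
#' Flags samples more than `outlier_k` scaled median absolute deviations
#' from the median within a moving `outlier_window_ms` window (400 ms, i.e.
#' 200 samples at 500 Hz, by default), then replaces each flagged sample by
#' linear interpolation between its nearest unflagged neighbours (flags at
#' the sequence edges take the nearest unflagged value). The scaled MAD uses
#' the Gaussian consistency constant 1.4826; windows with zero MAD flag
#' the strict threshold comparison leaves constant sequences (zero MAD and
#' zero deviation) untouched while still catching isolated spikes in
#' otherwise constant stretches.
#'
#' Blink zero-runs are assumed to have been excluded from the analysed span
#' beforehand (see [analysis_window()]); this stage targets isolated spikes
#' and dropouts from missed tracking.
#'
#' @param x Numeric sequence (pupil diameter in mm, or gaze in dva).
#' @param config A [pipeline_config()].
#' @return A list with `cleaned` (sequence with flagged samples replaced)
#'   and `mask` (logical flags).
#' @examples
#' x <- rep(3, 1000); x[500] <- 6
#' out <- remove_outliers(x)
#' which(out$mask)
#' @export
remove_outliers <- function(x, config = pipeline_config()) {
  config <- as_pipeline_config(config)
  n <- length(x)
  if (n < 2L) stop("sequence too short for outlier removal")
  k <- ms_to_samples(config$outlier_window_ms, config$rate_hz)
  before <- k %/% 2L
  after <- k - before - 1L
  mask <- mad_outlier_flags_cpp(as.numeric(x), before, after,
                                config$outlier_k, config$mad_scale)
  if (all(mask)) stop("degenerate trace: every sample was flagged as an outlier")
  cleaned <- as.numeric(x)
  if (any(mask)) {
    keep <- which(!mask)
    cleaned[mask] <- stats::approx(keep, cleaned[keep], xout = which(mask),
                                   rule = 2)$y
  }
  list(cleaned = cleaned, mask = mask)
}

#' Smooth a pupil-diameter sequence
#'
#' Centred moving mean over `smooth_window_ms` (100 ms = 50 samples at
#' 500 Hz by default). Apply after [remove_outliers()].
#'
#' @inheritParams remove_outliers
#' @return Smoothed numeric sequence.
#' @export
smooth_diameter <- function(x, config = pipeline_config()) {
  config <- as_pipeline_config(config)
  moving_average(x, ms_to_samples(config$smooth_window_ms, config$rate_hz))
}

#' Smooth a horizontal gaze sequence
#'
#' The same outlier-then-moving-mean chain used for the pupil diameter,
#' applied to the horizontal gaze position prior to saccade detection.
#'
#' @inheritParams remove_outliers
#' @return Smoothed numeric sequence.
#' @export
smooth_gaze <- function(x, config = pipeline_config()) {
  config <- as_pipeline_config(config)
  smooth_diameter(remove_outliers(x, config)$cleaned, config)
}

#' Full diameter preprocessing
#'
#' Outlier removal followed by smoothing; returns the intermediate stages.
#'
#' @inheritParams remove_outliers
#' @return A list with `cleaned`, `smoothed` and `mask`.
#' @export
preprocess_diameter <- function(x, config = pipeline_config()) {
  config <- as_pipeline_config(config)
  out <- remove_outliers(x, config)
  list(cleaned = out$cleaned,
       smoothed = smooth_diameter(out$cleaned, config),
       mask = out$mask)
}
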