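#' Parameters of the synthetic experiment generator
#'
#' Defaults emulate the recorded study conditions: a pupil at ~3.1 mm
#' baseline showing a rapid constriction of 0.1-0.7 mm reaching its minimum
#' 0.5-1 s after the triggering event, followed by a slower dilation back to
#' near baseline over 1.5-5 s; blinks as zero-diameter runs of 60-120 ms;
#' saccades as ~20 dva horizontal gaze steps (fixation spots at +/-10 dva);
#' Gaussian measurement noise with sparse spike outliers; and illusion
#' durations spanning roughly 1-7 s, coupled to the dilation duration with
#' target correlation `illusion_corr_rho`.
#'
#' @param baseline_mm Mean baseline pupil diameter (mm).
#' @param baseline_sd_mm Between-trial sd of the baseline (mm).
#' @param constriction_amplitude_range_mm Per-trial uniform range of the
#'   constriction amplitude (mm).
#' @param constriction_latency_ms Gentle pre-constriction drift period (ms).
#' @param time_to_min_range_ms Per-trial range of event-to-minimum time (ms).
#' @param dilation_duration_range_ms Per-trial range of the dilation
#'   duration (minimum to post-minimum maximum, ms).
#' @param overshoot_range_mm Range of the post-minimum maximum relative to
#'   baseline (mm; may be negative).
#' @param pre_drift_mm_per_ms Slope of the gentle pre-constriction decline.
#' @param noise_sd_mm Gaussian measurement noise sd (mm).
#' @param outlier_rate Per-sample probability of a spike outlier.
#' @param blink_zero_ms_range Zero-run length range for blink trials (ms).
#' @param saccade_amplitude_dva Horizontal saccade amplitude (dva).
#' @param gaze_noise_sd_dva Gaze measurement noise sd (dva).
#' @param illusion_corr_rho Target correlation between dilation duration and
#'   illusion duration (0-1).
#' @param illusion_mean_s,illusion_sd_s Mean and sd of illusion durations (s).
#' @param rate_hz Sampling rate (Hz).
#'
#' @return A `synth_params` object (validated named list).
#' @export
synth_params <- function(baseline_mm = 3.1,
                         baseline_sd_mm = 0.12,
                         constriction_amplitude_range_mm = c(0.1, 0.7),
                         constriction_latency_ms = 200,
                         time_to_min_range_ms = c(500, 1000),
                         dilation_duration_range_ms = c(1500, 5000),
                         overshoot_range_mm = c(-0.04, 0.06),
                         pre_drift_mm_per_ms = 5e-5,
                         noise_sd_mm = 0.01,
                         outlier_rate = 0.002,
                         blink_zero_ms_range = c(60, 120),
                         saccade_amplitude_dva = 20,
                         gaze_noise_sd_dva = 0.05,
                         illusion_corr_rho = 0.7,
                         illusion_mean_s = 4,
                         illusion_sd_s = 1.2,
                         rate_hz = 500) {
  p <- as.list(environment())
  if (illusion_corr_rho < 0 || illusion_corr_rho > 1) {
    stop("illusion_corr_rho must lie in [0, 1]")
  }
  ranges <- c("constriction_amplitude_range_mm", "time_to_min_range_ms",
              "dilation_duration_range_ms", "overshoot_range_mm",
              "blink_zero_ms_range")
  for (nm in ranges) {
    if (length(p[[nm]]) != 2L || p[[nm]][1] > p[[nm]][2]) {
      stop(nm, " must be an increasing length-2 range")
    }
  }
  if (min(time_to_min_range_ms) <= constriction_latency_ms + 250) {
    stop("time_to_min_range_ms must exceed constriction_latency_ms + 250 ms")
  }
  if (min(dilation_duration_range_ms) <= 400) {
    stop("dilation_duration_range_ms must exceed 400 ms")
  }
  structure(p, class = "synth_params")
}

# cubic smoothstep: C1 monotone rise from 0 at u=0 to 1 at u=1
smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

#' Deterministic pupil-response waveform
#'
#' The noiseless constriction-dilation curve underlying every synthetic
#' trial: a gentle linear pre-constriction drift, a smooth descent to the
#' minimum, a symmetric parabolic valley around the minimum, a smooth rise,
#' a symmetric parabolic cap around the post-minimum maximum, and an
#' exponential relaxation back toward baseline. The symmetric caps give the
#' curve exact closed-form extrema that survive centred moving-average
#' smoothing without time bias, so the generator's ground truth is
#' recoverable by the pipeline.
#'
#' @param t_ms Time grid in ms from the analysis start (uniform, from 0).
#' @param baseline_mm Baseline diameter (mm); also the value of the
#'   pre-minimum maximum, which sits at `t = 0`.
#' @param constriction_amplitude_mm Depth of the minimum below baseline (mm);
#'   0 yields a constant trace.
#' @param time_to_min_ms Time of the minimum (ms).
#' @param dilation_duration_ms Time from the minimum to the post-minimum
#'   maximum (ms).
#' @param overshoot_mm Post-minimum maximum relative to baseline (mm).
#' @param latency_ms Duration of the gentle pre-constriction drift (ms).
#' @param pre_drift_mm_per_ms Slope of that drift (mm/ms).
#' @param cap_halfwidth_ms Half-width of the parabolic caps (ms).
#' @return Diameter sequence (mm) with an `extrema` attribute: a list with
#'   the analytic `max1`, `min`, `max2` values and times (clipped to the
#'   grid when it ends before the nominal maximum).
#' @examples
#' t <- seq(0, 4000, by = 2)
#' d <- pupil_response(t, 3.1, 0.35, 700, 2500, 0.02)
#' attr(d, "extrema")$min_t_ms
#' @export
pupil_response <- function(t_ms, baseline_mm, constriction_amplitude_mm,
                           time_to_min_ms, dilation_duration_ms,
                           overshoot_mm = 0, latency_ms = 200,
                           pre_drift_mm_per_ms = 5e-5,
                           cap_halfwidth_ms = 150) {
  A <- constriction_amplitude_mm
  if (A < 0) stop("constriction amplitude must be >= 0")
  if (A == 0) {
    d <- rep(baseline_mm, length(t_ms))
    attr(d, "extrema") <- list(degenerate = TRUE)
    return(d)
  }
  v <- cap_halfwidth_ms
  t_min <- time_to_min_ms
  t_max2 <- time_to_min_ms + dilation_duration_ms
  if (t_min - v <= latency_ms || dilation_duration_ms <= 2 * v) {
    stop("parameter error: no interior minimum with these timings")
  }
  if (overshoot_mm <= -A / 2) {
    stop("parameter error: overshoot too negative for an interior maximum")
  }
  d_min <- baseline_mm - A
  d_max2 <- baseline_mm + overshoot_mm
  dv1 <- min(0.08, A / 3)
  dv2 <- min(0.08, (d_max2 - d_min) / 3)
  y_lat <- baseline_mm - pre_drift_mm_per_ms * latency_ms
  y1 <- d_min + dv1
  y2 <- d_max2 - dv2
  if (y1 >= y_lat) stop("parameter error: amplitude too small for the pre-drift")
  k1 <- dv1 / v^2
  k2 <- dv2 / v^2
  y_inf <- max(y2 - 1.5 * dv2, d_min + 0.5 * dv1)
  tau_f <- 800

  d <- numeric(length(t_ms))
  seg_a <- t_ms <= latency_ms
  seg_b <- t_ms > latency_ms & t_ms <= t_min - v
  seg_c <- t_ms > t_min - v & t_ms <= t_min + v
  seg_d <- t_ms > t_min + v & t_ms <= t_max2 - v
  seg_e <- t_ms > t_max2 - v & t_ms <= t_max2 + v
  seg_f <- t_ms > t_max2 + v
  d[seg_a] <- baseline_mm - pre_drift_mm_per_ms * t_ms[seg_a]
  d[seg_b] <- y1 + (y_lat - y1) *
    smoothstep((t_min - v - t_ms[seg_b]) / (t_min - v - latency_ms))
  d[seg_c] <- d_min + k1 * (t_ms[seg_c] - t_min)^2
  d[seg_d] <- y1 + (y2 - y1) *
    smoothstep((t_ms[seg_d] - t_min - v) / (t_max2 - t_min - 2 * v))
  d[seg_e] <- d_max2 - k2 * (t_ms[seg_e] - t_max2)^2
  d[seg_f] <- y_inf + (y2 - y_inf) * exp(-(t_ms[seg_f] - t_max2 - v) / tau_f)

  t_end <- max(t_ms)
  ex <- list(degenerate = FALSE,
             max1_mm = baseline_mm, max1_t_ms = 0,
             min_mm = d_min, min_t_ms = t_min,
             max2_mm = d_max2, max2_t_ms = t_max2,
             constriction_duration_ms = t_min,
             dilation_duration_ms = dilation_duration_ms,
             truncated = t_end < t_max2)
  if (ex$truncated) {
    # recording stops before the nominal maximum: ground truth clips to grid
    i_end <- which.max(t_ms)
    ex$max2_mm <- d[i_end]
    ex$max2_t_ms <- t_ms[i_end]
    ex$dilation_duration_ms <- t_ms[i_end] - t_min
  }
  attr(d, "extrema") <- ex
  d
}

# per-trial random shape draws
draw_shape <- function(params) {
  amp <- runif(1, params$constriction_amplitude_range_mm[1],
               params$constriction_amplitude_range_mm[2])
  over <- runif(1, params$overshoot_range_mm[1], params$overshoot_range_mm[2])
  over <- max(over, -amp / 2 + 0.02)
  list(baseline = min(max(rnorm(1, params$baseline_mm, params$baseline_sd_mm),
                          2), 5),
       amplitude = amp,
       time_to_min = runif(1, params$time_to_min_range_ms[1],
                           params$time_to_min_range_ms[2]),
       dilation = runif(1, params$dilation_duration_range_ms[1],
                        params$dilation_duration_range_ms[2]),
       overshoot = over)
}

# couple the illusion duration to the (nominal) dilation duration at the
# target correlation: linear-plus-Gaussian construction
draw_illusion <- function(dilation_ms, params) {
  rng <- params$dilation_duration_range_ms
  z <- (dilation_ms - mean(rng)) / (diff(rng) / sqrt(12))
  rho <- params$illusion_corr_rho
  ill <- params$illusion_mean_s +
    params$illusion_sd_s * (rho * z + sqrt(1 - rho^2) * rnorm(1))
  # quantised to 1 ms, the resolution of a response-key timestamp; this also
  # keeps the value exact across text serialisation
  round(max(ill, 0.3), 3)
}

add_measurement_noise <- function(x, params, floor_mm = 0.2, ceil_mm = 8.8) {
  n <- length(x)
  y <- x + rnorm(n, 0, params$noise_sd_mm)
  spikes <- runif(n) < params$outlier_rate
  if (any(spikes)) {
    y[spikes] <- y[spikes] +
      sample(c(-1, 1), sum(spikes), replace = TRUE) * runif(sum(spikes), 0.5, 2)
  }
  pmin(pmax(y, floor_mm), ceil_mm)
}

#' Generate one synthetic trial with ground truth
#'
#' Builds a complete trial for the requested experiment type: the
#' [pupil_response()] waveform plus Gaussian noise and spike outliers, with
#' a zero-run prepended for blink trials (analysis then starts exactly
#' 200 ms after its last zero) or a sigmoidal ~40 ms, 20 dva horizontal gaze
#' step for saccade trials. The reported illusion duration is drawn so that,
#' across trials, it correlates with the dilation duration at
#' `illusion_corr_rho`. Recording extends to the later of button press +
#' 250 ms and the post-minimum maximum, so the full profile is observable.
#' All ground-truth quantities (absolute extrema times and values, durations,
#' event indices) are attached.
#'
#' @param experiment `"onset"`, `"blink"` or `"saccade"`.
#' @param params A [synth_params()].
#' @param seed Integer seed; the trial is a pure function of
#'   (experiment, params, seed, labels).
#' @param stimulus,participant,trial_id Labels stored in the record.
#' @return A [trial_record()] with a `ground_truth` list.
#' @export
generate_trial <- function(experiment, params = synth_params(), seed,
                           stimulus = "snakes", participant = "P1",
                           trial_id = NA_character_) {
  experiment <- match.arg(experiment, c("onset", "blink", "saccade"))
  if (missing(seed)) stop("config error: field 'seed' is required")
  set.seed(as.integer(seed))
  rate <- params$rate_hz
  dt <- 1000 / rate
  shape <- draw_shape(params)
  illusion_s <- draw_illusion(shape$dilation, params)
  t_max2 <- shape$time_to_min + shape$dilation
  span_ms <- max(illusion_s * 1000 + 250, t_max2 + 400)
  n_span <- ceiling(span_ms / dt) + 1L
  t_span <- (seq_len(n_span) - 1L) * dt
  wav <- pupil_response(t_span, shape$baseline, shape$amplitude,
                        shape$time_to_min, shape$dilation, shape$overshoot,
                        latency_ms = params$constriction_latency_ms,
                        pre_drift_mm_per_ms = params$pre_drift_mm_per_ms)
  ex <- attr(wav, "extrema")

  gt <- c(list(experiment = experiment, illusion_duration_s = illusion_s,
               baseline_mm = shape$baseline,
               amplitude_mm = shape$amplitude,
               overshoot_mm = shape$overshoot), ex)

  offset_samples <- ms_to_samples(200, rate)  # post-blink analysis offset
  if (experiment == "onset") {
    pupil <- add_measurement_noise(wav, params)
    n <- length(pupil)
    gaze_x <- rnorm(n, 0, params$gaze_noise_sd_dva)
    t_off <- 0
    gt$analysis_start_idx <- 1L
  } else if (experiment == "blink") {
    n_pre <- ms_to_samples(runif(1, 400, 800), rate)
    n_zero <- ms_to_samples(runif(1, params$blink_zero_ms_range[1],
                                  params$blink_zero_ms_range[2]), rate)
    pre <- add_measurement_noise(rep(shape$baseline, n_pre), params)
    # partially occluded pupil while the lid re-opens; the analysis skips it
    n_reopen <- offset_samples - 1L
    reopen <- add_measurement_noise(
      seq(0.75 * shape$baseline, shape$baseline, length.out = n_reopen),
      params)
    pupil <- c(pre, rep(0, n_zero), reopen, add_measurement_noise(wav, params))
    n <- length(pupil)
    gaze_x <- rnorm(n, 0, params$gaze_noise_sd_dva)
    t_off <- (n_pre + n_zero + n_reopen) * dt
    gt$zero_run_start_idx <- n_pre + 1L
    gt$zero_run_end_idx <- n_pre + n_zero
    gt$analysis_start_idx <- n_pre + n_zero + offset_samples
  } else {
    n_pre <- ms_to_samples(runif(1, 400, 800), rate)
    sacc_t <- n_pre * dt
    wav_start_ms <- sacc_t + 250
    n_head <- ms_to_samples(wav_start_ms, rate)
    pupil <- c(add_measurement_noise(rep(shape$baseline, n_head), params),
               add_measurement_noise(wav, params))
    n <- length(pupil)
    t_all <- (seq_len(n) - 1L) * dt
    dir_sign <- sample(c(-1, 1), 1)
    amp <- params$saccade_amplitude_dva
    gaze_x <- dir_sign * amp * (stats::plogis((t_all - sacc_t) / 8) - 0.5) +
      rnorm(n, 0, params$gaze_noise_sd_dva)
    t_off <- n_head * dt
    gt$saccade_t_ms <- sacc_t
    gt$saccade_amplitude_dva <- dir_sign * amp
  }

  if (!isTRUE(ex$degenerate)) {
    for (nm in c("max1_t_ms", "min_t_ms", "max2_t_ms")) gt[[nm]] <- gt[[nm]] + t_off
  }
  gt$analysis_start_t_ms <- t_off

  trace <- pupil_trace((seq_len(n) - 1L) * dt, pupil, gaze_x, 0, rate_hz = rate)
  trial_record(trace, experiment, stimulus, participant, illusion_s,
               trial_id = trial_id, ground_truth = gt)
}

default_stimulus_effects <- function() {
  tibble::tibble(stimulus = c("snakes", "disks", "fraser_wilcox"),
                 amplitude_scale = c(1.15, 1, 0.85),
                 illusion_mean_s = c(4.5, 4, 3))
}

#' Generate a complete synthetic experiment
#'
#' Mirrors the study design: participants x experiments x stimuli with a
#' fixed number of trials per cell. Stimuli differ in effect size through
#' `stimulus_effects` (constriction-amplitude scaling and mean illusion
#' duration; defaults order snakes > disks > fraser_wilcox). All randomness
#' derives from `seed` (one sub-seed per trial, so any single trial is
#' reproducible in isolation).
#'
#' @param n_participants,n_trials_per_cell Design sizes.
#' @param stimuli,experiments Label sets.
#' @param params A [synth_params()].
#' @param seed Integer dataset seed (required).
#' @param dir Optional output directory: writes the native trial layout, a
#'   `ground_truth.csv` manifest and a `params.json` echo.
#' @param stimulus_effects Tibble with columns `stimulus`,
#'   `amplitude_scale`, `illusion_mean_s`.
#' @return Invisibly, a list with `trials` (list of [trial_record()]s),
#'   `ground_truth` (tibble) and `seed`.
#' @export
generate_dataset <- function(n_participants = 4, n_trials_per_cell = 10,
                             stimuli = c("snakes", "disks", "fraser_wilcox"),
                             experiments = c("onset", "blink", "saccade"),
                             params = synth_params(), seed, dir = NULL,
                             stimulus_effects = default_stimulus_effects()) {
  if (missing(seed)) stop("config error: field 'seed' is required")
  design <- expand.grid(trial = seq_len(n_trials_per_cell),
                        stimulus = stimuli,
                        experiment = experiments,
                        participant = paste0("P", seq_len(n_participants)),
                        stringsAsFactors = FALSE)
  set.seed(as.integer(seed))
  trial_seeds <- sample.int(.Machine$integer.max, nrow(design))
  trials <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    row <- design[i, ]
    p_i <- params
    eff <- stimulus_effects[stimulus_effects$stimulus == row$stimulus, ]
    if (nrow(eff) == 1L) {
      p_i$constriction_amplitude_range_mm <-
        pmin(p_i$constriction_amplitude_range_mm * eff$amplitude_scale, 0.9)
      p_i$illusion_mean_s <- eff$illusion_mean_s
    }
    trials[[i]] <- generate_trial(row$experiment, p_i, trial_seeds[i],
                                  stimulus = row$stimulus,
                                  participant = row$participant,
                                  trial_id = sprintf("t%05d", i))
  }
  gt <- dplyr::bind_rows(lapply(trials, function(tr) {
    flat <- tr$ground_truth[!vapply(tr$ground_truth, is.null, logical(1))]
    tibble::as_tibble(c(list(trial_id = tr$trial_id,
                             participant = tr$participant,
                             stimulus = tr$stimulus), flat))
  }))
  out <- list(trials = trials, ground_truth = gt, seed = as.integer(seed))
  if (!is.null(dir)) {
    write_trials(trials, dir)
    utils::write.csv(gt, file.path(dir, "ground_truth.csv"), row.names = FALSE)
    jsonlite::write_json(c(unclass(params), list(seed = as.integer(seed))),
                         file.path(dir, "params.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(out)
}

#' Modulate an image's luminance with a pupil-response profile
#'
#' Demonstration of the retinal effect of a pupil response on a static
#' pattern: each output frame is the input image scaled by the ratio of the
#' pupil area at that sample to the area at the reference diameter, clipped
#' to [0, 1]. The frame-mean luminance trace is therefore proportional to
#' the pupil-area trace (absent clipping).
#'
#' @param image Numeric matrix (grayscale) or h x w x 3 array (RGB), values
#'   in [0, 1] interpreted as linear luminance.
#' @param diameter_mm Pupil-diameter profile (mm), one frame per element.
#' @param reference_mm Diameter whose area maps the image to itself
#'   (default: first element of the profile).
#' @return A list of frames (same shape as `image`), with the applied area
#'   ratios as attribute `scale`.
#' @export
modulate_image_luminance <- function(image, diameter_mm,
                                     reference_mm = diameter_mm[1]) {
  if (any(image < 0 | image > 1)) stop("image values must lie in [0, 1]")
  scale <- pupil_area(diameter_mm) / pupil_area(reference_mm)
  frames <- lapply(scale, function(s) {
    out <- pmin(pmax(image * s, 0), 1)
    dim(out) <- dim(image)
    out
  })
  attr(frames, "scale") <- scale
  frames
}

#' Write modulated frames as numbered PNG files
#'
#' @param frames Output of [modulate_image_luminance()].
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return The file paths, invisibly.
#' @export
write_frames <- function(frames, dir, prefix = "frame") {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required to write frames")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(seq_along(frames), function(k) {
    p <- file.path(dir, sprintf("%s_%04d.png", prefix, k))
    png::writePNG(frames[[k]], p)
    p
  }, character(1))
  invisible(paths)
}
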