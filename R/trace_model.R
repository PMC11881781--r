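#' Construct a pupil trace
#'
#' A uniformly sampled time series of pupil diameter and gaze position for
#' one trial. A diameter of exactly 0 mm is the canonical "pupil not found"
#' sentinel (eyelid closed or tracking loss), matching the eye tracker's
#' blink encoding. Time is in ms from the start of data collection for the
#' trial (pattern appearance for onset trials; fixation-spot colour change
#' for blink and saccade trials).
#'
#' @param t_ms Sample times in ms; strictly increasing uniform grid with
#'   step `1000 / rate_hz`.
#' @param pupil_mm Pupil diameter in mm per sample; `0` means pupil lost.
#' @param gaze_x_dva,gaze_y_dva Gaze position in degrees of visual angle;
#'   scalars are recycled.
#' @param rate_hz Sampling rate in Hz.
#' @param grid_tol_ms Tolerance on the grid step.
#'
#' @return A tibble of class `pupil_trace` with columns `t_ms`, `pupil_mm`,
#'   `gaze_x_dva`, `gaze_y_dva` and a `rate_hz` attribute.
#' @examples
#' tr <- pupil_trace(seq(0, 998, by = 2), rep(3, 500))
#' trace_duration_ms(tr)
#' @export
pupil_trace <- function(t_ms, pupil_mm, gaze_x_dva = 0, gaze_y_dva = 0,
                        rate_hz = 500, grid_tol_ms = 1e-6) {
  n <- length(t_ms)
  if (length(pupil_mm) != n) stop("t_ms and pupil_mm must have equal length")
  if (length(gaze_x_dva) == 1L) gaze_x_dva <- rep(gaze_x_dva, n)
  if (length(gaze_y_dva) == 1L) gaze_y_dva <- rep(gaze_y_dva, n)
  if (length(gaze_x_dva) != n || length(gaze_y_dva) != n) {
    stop("gaze columns must match the trace length")
  }
  step <- 1000 / rate_hz
  if (n > 1L && max(abs(diff(t_ms) - step)) >= grid_tol_ms) {
    stop("time grid error: sample spacing deviates from ", step,
         " ms by more than ", grid_tol_ms, " ms")
  }
  if (any(pupil_mm < 0)) {
    stop("format error in column pupil_mm: negative diameters are not allowed")
  }
  out <- tibble::tibble(t_ms = as.numeric(t_ms), pupil_mm = as.numeric(pupil_mm),
                        gaze_x_dva = as.numeric(gaze_x_dva),
                        gaze_y_dva = as.numeric(gaze_y_dva))
  attr(out, "rate_hz") <- rate_hz
  class(out) <- c("pupil_trace", class(out))
  out
}

#' @rdname pupil_trace
#' @param trace A `pupil_trace`.
#' @export
trace_duration_ms <- function(trace) {
  nrow(trace) * 1000 / attr(trace, "rate_hz")
}

#' Construct a trial record
#'
#' One experimental trial: a [pupil_trace()] plus its metadata, including the
#' triggering event type and the reported illusion duration (time from the
#' event to the button press signalling that apparent motion ceased).
#'
#' @param trace A [pupil_trace()].
#' @param experiment One of `"onset"`, `"blink"`, `"saccade"`; determines
#'   which detector gates feature extraction.
#' @param stimulus Stimulus label (e.g. `"snakes"`, `"disks"`,
#'   `"fraser_wilcox"`; free labels allowed).
#' @param participant Participant identifier.
#' @param illusion_duration_s Reported illusion duration in seconds; must be
#'   positive for valid trials.
#' @param trial_id Identifier used in on-disk layouts.
#' @param valid Logical validity flag.
#' @param invalid_reason Reason string when `valid` is `FALSE`.
#' @param ground_truth Optional list of generator ground-truth values
#'   (synthetic data only).
#'
#' @return A list of class `trial_record`.
#' @export
trial_record <- function(trace, experiment, stimulus, participant,
                         illusion_duration_s, trial_id = NA_character_,
                         valid = TRUE, invalid_reason = NA_character_,
                         ground_truth = NULL) {
  experiment <- match.arg(experiment, c("onset", "blink", "saccade"))
  if (!inherits(trace, "pupil_trace")) stop("trace must be a pupil_trace")
  if (isTRUE(valid) && !(is.numeric(illusion_duration_s) && illusion_duration_s > 0)) {
    stop("illusion_duration_s must be > 0 for valid trials")
  }
  structure(list(
    trial_id = trial_id,
    trace = trace,
    experiment = experiment,
    stimulus = as.character(stimulus),
    participant = as.character(participant),
    illusion_duration_s = as.numeric(illusion_duration_s),
    valid = isTRUE(valid),
    invalid_reason = invalid_reason,
    ground_truth = ground_truth
  ), class = "trial_record")
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("<trial_record %s> %s / %s / %s, %d samples, illusion %.3f s%s\n",
              x$trial_id, x$experiment, x$stimulus, x$participant,
              nrow(x$trace), x$illusion_duration_s,
              if (x$valid) "" else paste0(" [invalid: ", x$invalid_reason, "]")))
  invisible(x)
}

SCHEMA_VERSION <- "1.0"

# Full-precision numeric formatting so CSV round-trips are bit-for-bit.
fmt_num <- function(x) sprintf("%.17g", x)

#' Write trials to the native on-disk layout
#'
#' The native layout is language-neutral and diff-able: one `samples.csv`
#' with a row per sample (`trial_id, t_ms, pupil_mm, gaze_x_dva,
#' gaze_y_dva`) and a `trials.json` sidecar with per-trial metadata and a
#' schema version. Diameters survive a round trip bit-for-bit.
#'
#' @param trials List of [trial_record()]s (may be empty).
#' @param path Directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  if (inherits(trials, "trial_record")) trials <- list(trials)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("I/O error: cannot create directory ", path)

  frames <- lapply(trials, function(tr) {
    data.frame(trial_id = tr$trial_id,
               t_ms = fmt_num(tr$trace$t_ms),
               pupil_mm = fmt_num(tr$trace$pupil_mm),
               gaze_x_dva = fmt_num(tr$trace$gaze_x_dva),
               gaze_y_dva = fmt_num(tr$trace$gaze_y_dva),
               stringsAsFactors = FALSE)
  })
  samples <- if (length(frames)) do.call(rbind, frames) else
    data.frame(trial_id = character(), t_ms = character(),
               pupil_mm = character(), gaze_x_dva = character(),
               gaze_y_dva = character(), stringsAsFactors = FALSE)
  utils::write.csv(samples, file.path(path, "samples.csv"),
                   row.names = FALSE, quote = FALSE)

  meta <- list(
    schema_version = SCHEMA_VERSION,
    package_version = as.character(utils::packageVersion("pupildrift")),
    trials = lapply(trials, function(tr) {
      m <- list(trial_id = tr$trial_id,
                experiment = tr$experiment,
                stimulus = tr$stimulus,
                participant = tr$participant,
                illusion_duration_s = tr$illusion_duration_s,
                rate_hz = attr(tr$trace, "rate_hz"),
                t0_ms = tr$trace$t_ms[1],
                valid = tr$valid,
                invalid_reason = tr$invalid_reason)
      if (!is.null(tr$ground_truth)) m$ground_truth <- tr$ground_truth
      m
    })
  )
  jsonlite::write_json(meta, file.path(path, "trials.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Read trials from the native on-disk layout
#'
#' Counterpart of [write_trials()]. Malformed input is reported, never
#' silently dropped: missing columns raise a format error naming the column,
#' non-uniform time grids raise a grid error, and negative diameters raise a
#' format error.
#'
#' @param path Directory containing `samples.csv` and `trials.json`, or the
#'   path of the `samples.csv` itself.
#' @param grid_tol_ms Tolerance on the uniform time grid, in ms.
#' @return A list of [trial_record()]s, in manifest order.
#' @export
read_trials <- function(path, grid_tol_ms = 1e-6) {
  if (dir.exists(path)) {
    samples_file <- file.path(path, "samples.csv")
    meta_file <- file.path(path, "trials.json")
  } else {
    samples_file <- path
    meta_file <- file.path(dirname(path), "trials.json")
  }
  if (!file.exists(samples_file)) stop("no such file: ", samples_file)
  if (!file.exists(meta_file)) stop("missing metadata sidecar: ", meta_file)

  samples <- utils::read.csv(samples_file, stringsAsFactors = FALSE,
                             comment.char = "#")
  needed <- c("trial_id", "t_ms", "pupil_mm", "gaze_x_dva", "gaze_y_dva")
  missing_cols <- setdiff(needed, names(samples))
  if (length(missing_cols)) {
    stop("format error: samples file is missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  meta <- jsonlite::read_json(meta_file, simplifyVector = FALSE)
  if (is.null(meta$trials)) stop("format error: trials.json has no 'trials' field")

  by_trial <- split(samples, samples$trial_id)
  lapply(meta$trials, function(m) {
    rows <- by_trial[[as.character(m$trial_id)]]
    if (is.null(rows)) stop("format error: trial ", m$trial_id,
                            " is in the manifest but has no samples")
    rows <- rows[order(rows$t_ms), , drop = FALSE]
    trace <- pupil_trace(rows$t_ms, rows$pupil_mm, rows$gaze_x_dva,
                         rows$gaze_y_dva, rate_hz = m$rate_hz,
                         grid_tol_ms = grid_tol_ms)
    trial_record(trace, m$experiment, m$stimulus, m$participant,
                 m$illusion_duration_s, trial_id = m$trial_id,
                 valid = isTRUE(m$valid),
                 invalid_reason = if (is.null(m$invalid_reason)) NA_character_
                                  else m$invalid_reason,
                 ground_truth = m$ground_truth)
  })
}

#' Write tidy result tables
#'
#' Writes one row per trial (`profiles.csv`) and one row per
#' (participant, stimulus, experiment, measure) cell (`correlations.csv`).
#' Rows for degenerate trials are retained with `NaN` measures and their
#' validity flag. Each table carries the configuration hash and package
#' version as a leading comment line.
#'
#' @param profiles Tibble of per-trial profiles (see [extract_profile()]).
#' @param correlations Tibble of correlation cells (see [correlation_grid()]);
#'   may be `NULL`.
#' @param path Output directory.
#' @param config The [pipeline_config()] used (stamped into the tables).
#' @return `path`, invisibly.
#' @export
write_results <- function(profiles, correlations, path,
                          config = pipeline_config()) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  stamp <- sprintf("# pupildrift %s config %s",
                   utils::packageVersion("pupildrift"), config_hash(config))
  write_stamped <- function(df, file) {
    con <- file(file.path(path, file), "w")
    on.exit(close(con))
    writeLines(stamp, con)
    utils::write.csv(df, con, row.names = FALSE)
  }
  write_stamped(profiles, "profiles.csv")
  if (!is.null(correlations)) write_stamped(correlations, "correlations.csv")
  invisible(path)
}
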