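#' Extract the three profile points
#'
#' From the smoothed diameter sequence, analysed from `start_idx` to the end
#' of the trace (recording stops 250 ms after the button press): the global
#' minimum of the analysed span; the maximum before the minimum (`max1`);
#' and the maximum after it (`max2`). Ties are broken by the earliest index.
#' A minimum at the first analysed sample means the constriction phase is
#' absent; at the last sample, the dilation phase is absent — both set
#' degenerate flags.
#'
#' @param diameter Smoothed diameter sequence in mm (full trace).
#' @param t_ms Sample times in ms (same length).
#' @param start_idx First analysed sample (1-based; from [analysis_window()]).
#' @return A list with `max1_mm`, `max1_t_ms`, `min_mm`, `min_t_ms`,
#'   `max2_mm`, `max2_t_ms`, `constriction_absent`, `dilation_absent`.
#' @examples
#' d <- c(seq(3.2, 2.8, length.out = 251), seq(2.8, 3.1, length.out = 1000)[-1])
#' p <- extract_points(d, seq_along(d) * 2 - 2)
#' c(p$max1_mm, p$min_mm, p$max2_mm)
#' @export
extract_points <- function(diameter, t_ms, start_idx = 1L) {
  n <- length(diameter)
  if (length(t_ms) != n) stop("diameter and t_ms must have equal length")
  if (start_idx < 1L || start_idx > n) stop("start_idx outside the trace")
  span <- start_idx:n
  d <- diameter[span]
  tt <- t_ms[span]
  i_min <- which.min(d)
  i_max1 <- which.max(d[1:i_min])
  i_max2 <- i_min - 1L + which.max(d[i_min:length(d)])
  list(max1_mm = d[i_max1], max1_t_ms = tt[i_max1],
       min_mm = d[i_min], min_t_ms = tt[i_min],
       max2_mm = d[i_max2], max2_t_ms = tt[i_max2],
       constriction_absent = i_min == 1L,
       dilation_absent = i_min == length(d))
}

#' Derive the four profile measures from the three points
#'
#' Duration and amplitude of pupil constriction (from `max1` to the
#' minimum), and duration and amplitude of pupil dilation (from the minimum
#' to `max2`). Degenerate points (either phase absent) yield `NaN` measures
#' with the flag carried along, so such trials can be excluded from the
#' correlation layer rather than contributing zero durations.
#'
#' @param points Output of [extract_points()].
#' @return A list with `constriction_duration_ms`,
#'   `constriction_amplitude_mm`, `dilation_duration_ms`,
#'   `dilation_amplitude_mm`, `degenerate`.
#' @export
compute_measures <- function(points) {
  degenerate <- isTRUE(points$constriction_absent) ||
    isTRUE(points$dilation_absent)
  if (degenerate) {
    return(list(constriction_duration_ms = NaN, constriction_amplitude_mm = NaN,
                dilation_duration_ms = NaN, dilation_amplitude_mm = NaN,
                degenerate = TRUE))
  }
  list(constriction_duration_ms = points$min_t_ms - points$max1_t_ms,
       constriction_amplitude_mm = points$max1_mm - points$min_mm,
       dilation_duration_ms = points$max2_t_ms - points$min_t_ms,
       dilation_amplitude_mm = points$max2_mm - points$min_mm,
       degenerate = FALSE)
}

#' Pupil area from diameter
#'
#' `area = pi * (diameter / 2)^2`, the basis of the retinal-luminance
#' quantities: with fixed display luminance, retinal illuminance scales with
#' pupil area.
#'
#' @param diameter_mm Pupil diameter in mm (> 0); vectorised.
#' @return Area in mm^2.
#' @export
pupil_area <- function(diameter_mm) {
  if (any(diameter_mm <= 0)) stop("domain error: diameter must be positive")
  pi * (diameter_mm / 2)^2
}

#' Percentage change in retinal luminance between two pupil diameters
#'
#' Computed from the change in pupil area:
#' `100 * (area(d_to) - area(d_from)) / area(d_from)`. The profile's
#' "decrease" column uses (max1 -> min), the "increase" column (min -> max2).
#'
#' @param d_from_mm,d_to_mm Diameters in mm (> 0); vectorised.
#' @return Percent change (negative for constriction).
#' @examples
#' luminance_change_pct(2.834, 3.044)  # ~ +15.4 %
#' @export
luminance_change_pct <- function(d_from_mm, d_to_mm) {
  100 * (pupil_area(d_to_mm) - pupil_area(d_from_mm)) / pupil_area(d_from_mm)
}

#' Retinal illuminance in Trolands
#'
#' `Td = luminance (cd/m^2) * pupil area (mm^2)`, the standard retinal
#' illuminance measure.
#'
#' @param luminance_cdm2 Luminance in cd/m^2 (>= 0).
#' @param diameter_mm Pupil diameter in mm (> 0).
#' @return Retinal illuminance in Td.
#' @export
trolands <- function(luminance_cdm2, diameter_mm) {
  if (any(luminance_cdm2 < 0)) stop("domain error: luminance must be >= 0")
  luminance_cdm2 * pupil_area(diameter_mm)
}

#' Percentage change in optical blur during dilation
#'
#' Blur is directly proportional to pupil diameter, so the blur increase
#' over the dilation phase is `100 * (max2 - min) / min`; on group-mean
#' diameters this comes to roughly 8%, small enough to be barely detectable
#' and hence an unlikely driver of the illusion compared with the ~15%
#' luminance change.
#'
#' @param d_min_mm,d_max2_mm Minimum and post-minimum maximum diameters (mm).
#' @return Percent change in blur.
#' @export
blur_change_pct <- function(d_min_mm, d_max2_mm) {
  if (any(d_min_mm <= 0) || any(d_max2_mm <= 0)) {
    stop("domain error: diameters must be positive")
  }
  100 * (d_max2_mm - d_min_mm) / d_min_mm
}

# Round half away from zero, the convention of the published summary table.
round_half_away <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Extract the full profile of one trial
#'
#' Runs event detection, preprocessing (outlier removal + smoothing of the
#' analysed span), point extraction and measure derivation for a single
#' trial, returning a one-row tibble. Trials whose detector aborts, or whose
#' smoothed non-zero diameters leave the plausibility band, are returned
#' with `valid = FALSE`, a reason, and `NA`/`NaN` values — quarantined, not
#' dropped.
#'
#' @param trial A [trial_record()].
#' @param config A [pipeline_config()].
#' @return A one-row tibble with trial metadata, the three points, the four
#'   measures and the two luminance-change percentages.
#' @export
extract_profile <- function(trial, config = pipeline_config()) {
  config <- as_pipeline_config(config)
  row <- list(
    trial_id = trial$trial_id, participant = trial$participant,
    experiment = trial$experiment, stimulus = trial$stimulus,
    illusion_duration_s = trial$illusion_duration_s,
    valid = FALSE, invalid_reason = NA_character_,
    analysis_start_idx = NA_integer_,
    max1_mm = NA_real_, max1_t_ms = NA_real_,
    min_mm = NA_real_, min_t_ms = NA_real_,
    max2_mm = NA_real_, max2_t_ms = NA_real_,
    constriction_duration_ms = NA_real_, constriction_amplitude_mm = NA_real_,
    dilation_duration_ms = NA_real_, dilation_amplitude_mm = NA_real_,
    lum_decrease_pct = NA_real_, lum_increase_pct = NA_real_,
    degenerate = NA)
  as_row <- function(x) tibble::new_tibble(x, nrow = 1L)
  if (!isTRUE(trial$valid)) {
    row$invalid_reason <- trial$invalid_reason
    return(as_row(row))
  }
  win <- analysis_window(trial, config)
  if (!win$valid) {
    row$invalid_reason <- win$reason
    return(as_row(row))
  }
  span <- win$start_idx:nrow(trial$trace)
  prep <- preprocess_diameter(trial$trace$pupil_mm[span], config)
  sm <- prep$smoothed
  if (any(sm < config$diameter_min_mm | sm > config$diameter_max_mm)) {
    row$invalid_reason <- "implausible_diameter"
    return(as_row(row))
  }
  pts <- extract_points(sm, trial$trace$t_ms[span], 1L)
  meas <- compute_measures(pts)
  row$valid <- TRUE
  row$analysis_start_idx <- as.integer(win$start_idx)
  row[names(pts)[1:6]] <- pts[1:6]
  row[c("constriction_duration_ms", "constriction_amplitude_mm",
        "dilation_duration_ms", "dilation_amplitude_mm")] <- meas[1:4]
  row$degenerate <- meas$degenerate
  if (!meas$degenerate) {
    row$lum_decrease_pct <- luminance_change_pct(pts$max1_mm, pts$min_mm)
    row$lum_increase_pct <- luminance_change_pct(pts$min_mm, pts$max2_mm)
  }
  as_row(row)
}

#' Summary table of mean diameters and luminance changes
#'
#' Per participant and experiment: mean `max1`, `min`, `max2` diameters (mm)
#' and mean luminance decrease/increase percentages across valid,
#' non-degenerate trials, followed by an experiment-level `Mean` row that is
#' the arithmetic mean of the participant rows in each column. Values are
#' rounded half-away-from-zero to `digits` decimals (`digits = NULL` leaves
#' them unrounded).
#'
#' @param profiles Tibble with columns `participant`, `experiment`,
#'   `max1_mm`, `min_mm`, `max2_mm`, `lum_decrease_pct`, `lum_increase_pct`
#'   (per trial, or already per participant).
#' @param digits Decimals for the report table (default 3).
#' @return A tibble with columns `experiment`, `participant`, `max1_mm`,
#'   `min_mm`, `lum_decrease_pct`, `max2_mm`, `lum_increase_pct`.
#' @export
aggregate_table <- function(profiles, digits = 3) {
  stopifnot(all(c("participant", "experiment", "max1_mm", "min_mm", "max2_mm",
                  "lum_decrease_pct", "lum_increase_pct") %in% names(profiles)))
  if ("valid" %in% names(profiles)) {
    profiles <- profiles[profiles$valid %in% TRUE, , drop = FALSE]
  }
  if ("degenerate" %in% names(profiles)) {
    profiles <- profiles[profiles$degenerate %in% FALSE, , drop = FALSE]
  }
  cols <- c("max1_mm", "min_mm", "lum_decrease_pct", "max2_mm",
            "lum_increase_pct")
  per_part <- profiles %>%
    dplyr::group_by(.data$experiment, .data$participant) %>%
    dplyr::summarise(dplyr::across(dplyr::all_of(cols),
                                   ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop")
  if (any(!is.finite(as.matrix(per_part[cols])))) {
    warning("empty or all-degenerate cell(s): NaN in the summary table")
  }
  mean_rows <- per_part %>%
    dplyr::group_by(.data$experiment) %>%
    dplyr::summarise(dplyr::across(dplyr::all_of(cols), mean),
                     .groups = "drop") %>%
    dplyr::mutate(participant = "Mean")
  out <- dplyr::bind_rows(per_part, mean_rows) %>%
    dplyr::arrange(.data$experiment, .data$participant == "Mean",
                   .data$participant) %>%
    dplyr::select(dplyr::all_of(c("experiment", "participant", cols)))
  if (!is.null(digits)) {
    out[cols] <- lapply(out[cols], round_half_away, digits = digits)
  }
  out
}

#' Published per-participant summary of the source experiments
#'
#' The per-participant mean diameters and area-based luminance-change
#' percentages reported for the four observers of the source pupillometry
#' study, one row per participant and trigger event. Used as reference input
#' for consistency checks of the aggregation and luminance arithmetic.
#'
#' @return A tibble with columns `experiment`, `participant`, `max1_mm`,
#'   `min_mm`, `lum_decrease_pct`, `max2_mm`, `lum_increase_pct`.
#' @export
reference_pupil_summary <- function() {
  path <- system.file("extdata", "reference_pupil_summary.csv",
                      package = "pupildrift", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
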