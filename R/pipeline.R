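#' Run the full analysis pipeline
#'
#' For every trial: event detection ([analysis_window()]), preprocessing of
#' the analysed span ([preprocess_diameter()]), profile extraction
#' ([extract_points()], [compute_measures()]) and luminance conversion; then
#' the summary table ([aggregate_table()]) and the correlation layer
#' ([correlation_grid()], [summarize_grid()]). Per-trial failures quarantine
#' the trial with a reason — they never abort the run — and the discard log
#' reports counts and percentage per reason.
#'
#' @param input Either a directory in the native layout (see
#'   [read_trials()]) or a list of [trial_record()]s.
#' @param output_dir Optional directory for the result tables
#'   (`profiles.csv`, `summary_table.csv`, `correlations.csv`,
#'   `correlation_summary.csv`, `discard_log.json`). Outputs are
#'   deterministic: rerunning with the same inputs and config reproduces
#'   them byte for byte.
#' @param config A [pipeline_config()].
#' @param compute_bf Attach Bayes factors to the correlation grid.
#' @return A list with `profiles`, `summary_table`, `correlations`,
#'   `correlation_summary` and `discard`.
#' @export
run_pipeline <- function(input, output_dir = NULL, config = pipeline_config(),
                         compute_bf = TRUE) {
  config <- as_pipeline_config(config)
  trials <- if (is.character(input)) read_trials(input, config$grid_tol_ms)
            else input
  if (!length(trials)) stop("no trials to analyse")
  profiles <- dplyr::bind_rows(lapply(trials, extract_profile, config = config))

  n_bad <- sum(!profiles$valid)
  reasons <- table(profiles$invalid_reason[!profiles$valid])
  discard <- list(n_trials = nrow(profiles), n_discarded = n_bad,
                  discard_pct = 100 * n_bad / nrow(profiles),
                  reasons = as.list(reasons))

  usable <- profiles$valid %in% TRUE & profiles$degenerate %in% FALSE
  summary_table <- if (any(usable)) aggregate_table(profiles) else NULL
  correlations <- correlation_grid(profiles, config, compute_bf = compute_bf)
  correlation_summary <- if (nrow(correlations)) summarize_grid(correlations)
                         else NULL

  if (!is.null(output_dir)) {
    write_results(profiles, correlations, output_dir, config)
    stamp <- sprintf("# pupildrift %s config %s",
                     utils::packageVersion("pupildrift"), config_hash(config))
    write_stamped <- function(df, file) {
      con <- file(file.path(output_dir, file), "w")
      writeLines(stamp, con)
      utils::write.csv(df, con, row.names = FALSE)
      close(con)
    }
    if (!is.null(summary_table)) write_stamped(summary_table, "summary_table.csv")
    if (!is.null(correlation_summary)) {
      write_stamped(correlation_summary, "correlation_summary.csv")
    }
    jsonlite::write_json(
      c(discard, list(config_hash = config_hash(config),
                      package_version =
                        as.character(utils::packageVersion("pupildrift")))),
      file.path(output_dir, "discard_log.json"),
      auto_unbox = TRUE, digits = NA)
  }
  list(profiles = profiles, summary_table = summary_table,
       correlations = correlations, correlation_summary = correlation_summary,
       discard = discard)
}

#' Generate a synthetic dataset on disk
#'
#' Thin wrapper over [generate_dataset()] for scripted use: validates the
#' configuration, writes the native layout plus the ground-truth manifest,
#' and echoes the generator parameters next to the output for provenance.
#'
#' @param dir Output directory.
#' @param seed Integer seed (required; a missing seed is a config error).
#' @param params A [synth_params()] or a named list of overrides.
#' @param ... Passed to [generate_dataset()] (design sizes, label sets).
#' @return Invisibly, the [generate_dataset()] result.
#' @export
make_synthetic <- function(dir, seed, params = synth_params(), ...) {
  if (missing(seed) || is.null(seed)) {
    stop("config error: field 'seed' is required")
  }
  if (!inherits(params, "synth_params")) {
    params <- do.call(synth_params, as.list(params))
  }
  generate_dataset(params = params, seed = seed, dir = dir, ...)
}
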