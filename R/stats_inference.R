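#' Pearson product-moment correlation
#'
#' Thin, validated wrapper used by the correlation layer: requires at least
#' three paired observations and non-zero variance in both variables.
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @return The correlation coefficient r.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance")
  }
  stats::cor(x, y)
}

# log Gauss hypergeometric 2F1(1/2, 1/2; c; z) by forward series; converges
# for z in [0, 1) and, since c - 1 > 0 here (c = n - 1/2, n >= 3), also at
# z = 1. Scalar z.
log_hyp2f1_half <- function(c_par, z, tol = 1e-13, max_terms = 100000L) {
  if (z < 0 || z > 1) stop("z outside [0, 1]")
  term <- 1
  total <- 1
  k <- 0
  while (k < max_terms) {
    term <- term * (0.5 + k)^2 / ((c_par + k) * (k + 1)) * z
    total <- total + term
    k <- k + 1
    if (term < tol * total) break
  }
  log(total)
}

# log-likelihood of rho given an observed correlation r at sample size n,
# up to rho-free constants: the exact sampling density of the Pearson
# correlation under bivariate normality (Fisher), with its Gauss-series
# factor 2F1(1/2, 1/2; n - 1/2; (1 + rho r)/2).
log_r_likelihood <- function(rho, r, n) {
  0.5 * (n - 1) * log1p(-rho^2) + (1.5 - n) * log1p(-rho * r) +
    vapply(rho, function(p) log_hyp2f1_half(n - 0.5, (1 + p * r) / 2),
           numeric(1))
}

#' Default Bayes factor for a Pearson correlation
#'
#' Evidence ratio BF10 for the two-sided alternative "the population
#' correlation differs from zero" against the point null rho = 0, computed
#' by numerical integration of the exact sampling density of r over a
#' uniform prior on (-1, 1) — the stretched-beta prior with width kappa = 1
#' that is the common default for this test. Values above 1 favour the
#' alternative; below 1, the null.
#'
#' @param r Observed Pearson correlation (|r| < 1; |r| = 1 returns `Inf`).
#' @param n Sample size (>= 3).
#' @return BF10 (> 0; may be `Inf` for |r| = 1).
#' @examples
#' bf_correlation(0.9, 20)
#' bf_correlation(0, 20)   # < 1: data favour the null
#' @export
bf_correlation <- function(r, n) {
  if (!is.finite(r) || abs(r) > 1) stop("r must lie in [-1, 1]")
  if (n < 3) stop("domain error: n must be at least 3")
  if (abs(r) == 1) return(Inf)
  log_lik0 <- log_r_likelihood(0, r, n)
  grid <- seq(-0.9999, 0.9999, length.out = 401)
  log_ratio <- function(rho) log_r_likelihood(rho, r, n) - log_lik0
  m <- max(log_ratio(grid))
  val <- stats::integrate(function(rho) exp(log_ratio(rho) - m), -1, 1,
                          rel.tol = 1e-9, abs.tol = 0,
                          subdivisions = 400L)$value
  exp(m + log(val) + log(0.5))
}

#' Per-cell correlations between pupil measures and illusion duration
#'
#' For each (participant, stimulus, experiment) cell with at least
#' `min_trials_per_cell` valid non-degenerate trials, correlates each of the
#' four profile measures with the reported illusion duration and (optionally)
#' attaches the default Bayes factor. Cells below the trial minimum are
#' skipped with a warning; measure/cell combinations with zero variance
#' yield `NA` with a warning.
#'
#' @param profiles Per-trial profile tibble (see [extract_profile()]).
#' @param config A [pipeline_config()] (supplies `min_trials_per_cell`).
#' @param compute_bf Attach `bf10` per cell (default `TRUE`).
#' @return A tibble with columns `participant`, `stimulus`, `experiment`,
#'   `measure`, `r`, `n`, `bf10`.
#' @export
correlation_grid <- function(profiles, config = pipeline_config(),
                             compute_bf = TRUE) {
  config <- as_pipeline_config(config)
  measures <- c("constriction_duration_ms", "constriction_amplitude_mm",
                "dilation_duration_ms", "dilation_amplitude_mm")
  ok <- profiles$valid %in% TRUE & profiles$degenerate %in% FALSE
  profiles <- profiles[ok, , drop = FALSE]
  cells <- split(profiles,
                 interaction(profiles$participant, profiles$stimulus,
                             profiles$experiment, drop = TRUE))
  rows <- lapply(cells, function(cell) {
    if (nrow(cell) < config$min_trials_per_cell) {
      warning(sprintf("cell %s/%s/%s skipped: only %d valid trial(s)",
                      cell$participant[1], cell$stimulus[1],
                      cell$experiment[1], nrow(cell)), call. = FALSE)
      return(NULL)
    }
    res <- lapply(measures, function(m) {
      r <- tryCatch(pearson_r(cell[[m]], cell$illusion_duration_s),
                    error = function(e) {
                      warning(sprintf("cell %s/%s/%s, %s: %s",
                                      cell$participant[1], cell$stimulus[1],
                                      cell$experiment[1], m, conditionMessage(e)),
                              call. = FALSE)
                      NA_real_
                    })
      bf <- if (compute_bf && is.finite(r)) bf_correlation(r, nrow(cell))
            else NA_real_
      tibble::tibble(participant = cell$participant[1],
                     stimulus = cell$stimulus[1],
                     experiment = cell$experiment[1],
                     measure = m, r = r, n = nrow(cell), bf10 = bf)
    })
    dplyr::bind_rows(res)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out)) out <- dplyr::arrange(out, .data$experiment,
                                       .data$participant, .data$stimulus,
                                       .data$measure)
  out
}

#' Summarise the correlation grid per measure
#'
#' For each experiment and measure: r-values are first averaged across
#' stimuli within each participant, then the participant means are averaged,
#' with the standard error taken across participants (sd / sqrt(P)). The
#' median Bayes factor is taken over all cells of that measure.
#'
#' @param results Output of [correlation_grid()].
#' @return A tibble with columns `experiment`, `measure`, `mean_r`, `se_r`,
#'   `median_bf10`, `n_cells`.
#' @export
summarize_grid <- function(results) {
  results %>%
    dplyr::filter(is.finite(.data$r)) %>%
    dplyr::group_by(.data$experiment, .data$measure, .data$participant) %>%
    dplyr::summarise(r_part = mean(.data$r),
                     bfs = list(.data$bf10), n_cells = dplyr::n(),
                     .groups = "drop_last") %>%
    dplyr::summarise(mean_r = mean(.data$r_part),
                     se_r = stats::sd(.data$r_part) /
                       sqrt(length(.data$r_part)),
                     median_bf10 = stats::median(unlist(.data$bfs)),
                     n_cells = sum(.data$n_cells),
                     .groups = "drop")
}
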