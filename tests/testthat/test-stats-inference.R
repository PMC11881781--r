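test_that("pearson_r matches the textbook formula and its invariances", {
  expect_equal(pearson_r(1:3, c(2, 4, 6)), 1)
  expect_equal(pearson_r(1:5, -(1:5)), -1)
  expect_error(pearson_r(1:5, rep(2, 5)), "zero variance")
  expect_error(pearson_r(1:2, 1:2), "at least 3")

  set.seed(15)
  x <- rnorm(20)
  y <- 0.6 * x + sqrt(1 - 0.36) * rnorm(20)
  # independent recomputation from sums
  n <- 20
  r_ref <- (sum(x * y) - n * mean(x) * mean(y)) /
    sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  expect_equal(pearson_r(x, y), r_ref, tolerance = 1e-12)

  # affine invariance and sign flip
  expect_equal(pearson_r(2 * x + 3, y), pearson_r(x, y), tolerance = 1e-12)
  expect_equal(pearson_r(-x, y), -pearson_r(x, y), tolerance = 1e-12)
})

test_that("correlation Bayes factor behaves like a default two-sided test", {
  # null-consistent data favour the null, increasingly with n
  bfs <- vapply(c(5, 10, 20, 50, 100), function(n) bf_correlation(0, n),
                numeric(1))
  expect_true(all(bfs < 1))
  expect_true(all(diff(bfs) < 0))

  # strictly increasing in |r| at fixed n
  rs <- seq(0, 0.95, by = 0.05)
  bfr <- vapply(rs, bf_correlation, numeric(1), n = 10)
  expect_true(all(diff(bfr) > 0))

  # symmetry in the sign of r (two-sided test)
  expect_equal(bf_correlation(0.5, 15), bf_correlation(-0.5, 15),
               tolerance = 1e-8)

  expect_identical(bf_correlation(1, 10), Inf)
  expect_error(bf_correlation(0.5, 2), "domain")
})

test_that("Bayes factor agrees with the cosh-integral quadrature oracle", {
  for (case in list(c(0.9, 20), c(0.3, 10), c(-0.6, 15))) {
    got <- bf_correlation(case[1], case[2])
    ref <- bf_cosh_oracle(case[1], case[2])
    expect_equal(got, ref, tolerance = 0.01)
  }
})

test_that("correlation_grid computes per-cell results and skips small cells", {
  set.seed(33)
  make_cell <- function(part, stim, n) {
    dd <- runif(n, 1500, 5000)
    tibble::tibble(
      participant = part, stimulus = stim, experiment = "onset",
      illusion_duration_s = 1 + dd / 1000 + rnorm(n, 0, 0.3),
      constriction_duration_ms = runif(n, 400, 900),
      constriction_amplitude_mm = runif(n, 0.1, 0.6),
      dilation_duration_ms = dd,
      dilation_amplitude_mm = runif(n, 0.1, 0.6),
      valid = TRUE, degenerate = FALSE)
  }
  cells <- expand.grid(part = paste0("P", 1:4), stim = c("a", "b", "c"),
                       stringsAsFactors = FALSE)
  profiles <- dplyr::bind_rows(
    Map(make_cell, cells$part, cells$stim, 8))
  grid <- correlation_grid(profiles, compute_bf = FALSE)
  expect_equal(nrow(grid), 48)  # 4 participants x 3 stimuli x 4 measures
  expect_true(all(grid$n == 8))
  expect_true(all(abs(grid$r) <= 1))

  # a 2-trial cell is skipped with a warning
  profiles2 <- dplyr::bind_rows(profiles, make_cell("P5", "a", 2))
  expect_warning(grid2 <- correlation_grid(profiles2, compute_bf = FALSE),
                 "skipped")
  expect_equal(nrow(grid2), 48)
})

test_that("summarize_grid averages stimuli within participant, then observers", {
  base <- expand.grid(participant = paste0("P", 1:4),
                      stimulus = c("a", "b", "c"),
                      stringsAsFactors = FALSE)
  base$experiment <- "onset"
  base$measure <- "dilation_duration_ms"
  base$n <- 10

  all_half <- transform(base, r = 0.5, bf10 = 3)
  s1 <- summarize_grid(tibble::as_tibble(all_half))
  expect_equal(s1$mean_r, 0.5)
  expect_equal(s1$se_r, 0)

  # participant-level means 0.4, 0.5, 0.6, 0.7
  per_part <- setNames(c(0.4, 0.5, 0.6, 0.7), paste0("P", 1:4))
  varied <- transform(base, r = per_part[participant], bf10 = 1)
  s2 <- summarize_grid(tibble::as_tibble(varied))
  expect_equal(s2$mean_r, 0.55)
  expect_equal(s2$se_r, sd(per_part) / 2, tolerance = 1e-12)
  expect_equal(round(s2$se_r, 4), 0.0645)

  # median BF over all cells of the measure
  bf_case <- transform(base[1:4, ], r = 0.2, bf10 = c(1, 2, 10, 1000))
  s3 <- summarize_grid(tibble::as_tibble(bf_case))
  expect_equal(s3$median_bf10, 6)
})

test_that("mean r recovered across replicate datasets brackets the built-in rho", {
  # small-n sanity version of the coupling guarantee: the per-dataset
  # correlation between ground-truth dilation duration and illusion duration
  # concentrates around the target rho
  params <- synth_params(illusion_corr_rho = 0.7)
  rs <- vapply(1:20, function(rep) {
    gt <- t(vapply(1:60, function(i) {
      tr <- generate_trial("onset", params, seed = rep * 1000 + i)
      c(tr$ground_truth$dilation_duration_ms, tr$illusion_duration_s)
    }, numeric(2)))
    cor(gt[, 1], gt[, 2])
  }, numeric(1))
  expect_equal(mean(rs), 0.7, tolerance = 0.05)
})
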