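test_that("point extraction finds the V-shape extrema with earliest-tie rule", {
  t <- seq(0, by = 2, length.out = 1250)
  d <- c(seq(3.2, 2.8, length.out = 251), seq(2.8, 3.1, length.out = 1000)[-1])
  p <- extract_points(d, t)
  expect_equal(p$max1_mm, 3.2)
  expect_equal(p$max1_t_ms, 0)
  expect_equal(p$min_mm, 2.8)
  expect_equal(p$min_t_ms, 500)
  expect_equal(p$max2_mm, 3.1)
  expect_false(p$constriction_absent || p$dilation_absent)

  # constant trace: all three points coincide, both degenerate flags set
  pc <- extract_points(rep(3, 100), seq(0, by = 2, length.out = 100))
  expect_equal(pc$max1_mm, pc$min_mm)
  expect_true(pc$constriction_absent)  # min ties resolve to the first sample
  m <- compute_measures(pc)
  expect_true(m$degenerate)
  expect_true(is.nan(m$dilation_duration_ms))

  # ties break to the earliest index
  dd <- c(3, 2, 2, 2, 3, 3)
  pt <- extract_points(dd, 0:5 * 2)
  expect_equal(pt$min_t_ms, 2)
  expect_equal(pt$max2_t_ms, 8)
})

test_that("the four measures are the stated differences of the three points", {
  p <- list(max1_mm = 3.2, max1_t_ms = 0, min_mm = 2.8, min_t_ms = 500,
            max2_mm = 3.1, max2_t_ms = 2500,
            constriction_absent = FALSE, dilation_absent = FALSE)
  m <- compute_measures(p)
  expect_equal(m$constriction_duration_ms, 500)
  expect_equal(m$constriction_amplitude_mm, 0.4)
  expect_equal(m$dilation_duration_ms, 2000)
  expect_equal(m$dilation_amplitude_mm, 0.3)

  p$max1_mm <- p$min_mm
  expect_equal(compute_measures(p)$constriction_amplitude_mm, 0)

  # randomized profiles: measures equal brute-force recomputation
  set.seed(9)
  for (i in 1:20) {
    ts <- sort(runif(3, 0, 5000))
    ds <- c(runif(1, 3, 4), runif(1, 2, 3), runif(1, 3, 4))
    q <- list(max1_mm = ds[1], max1_t_ms = ts[1], min_mm = ds[2],
              min_t_ms = ts[2], max2_mm = ds[3], max2_t_ms = ts[3],
              constriction_absent = FALSE, dilation_absent = FALSE)
    mq <- compute_measures(q)
    expect_identical(mq$constriction_duration_ms, ts[2] - ts[1])
    expect_identical(mq$dilation_amplitude_mm, ds[3] - ds[2])
  }
})

test_that("area, luminance, Troland and blur arithmetic", {
  expect_equal(pupil_area(2), pi)
  expect_equal(pupil_area(1e-4), pi * 2.5e-9)
  expect_equal(pupil_area(3.232), pi * 1.616^2)
  expect_equal(pupil_area(3.232), 8.2041, tolerance = 1e-4)
  expect_error(pupil_area(0), "domain")

  expect_equal(luminance_change_pct(3, 3), 0)
  expect_equal(luminance_change_pct(2.834, 3.044), 15.37, tolerance = 1e-3)
  expect_equal(luminance_change_pct(3.529, 2.877), -33.54, tolerance = 1e-3)

  expect_equal(trolands(1, 2), pi)
  expect_equal(trolands(202, 3.232), 1657, tolerance = 1e-3)
  expect_equal(trolands(0, 3), 0)

  expect_equal(blur_change_pct(3, 3), 0)
  expect_equal(blur_change_pct(2.895, 3.109), 7.39, tolerance = 1e-2)
  expect_equal(blur_change_pct(2.944, 3.166), 7.54, tolerance = 1e-2)

  # reciprocity: a change and its inverse multiply back to unity
  set.seed(10)
  for (i in 1:25) {
    a <- runif(1, 2, 5); b <- runif(1, 2, 5)
    x <- luminance_change_pct(a, b); y <- luminance_change_pct(b, a)
    expect_equal((1 + x / 100) * (1 + y / 100), 1, tolerance = 1e-12)
  }
})

test_that("profiles recover generator ground truth on low-noise trials", {
  params <- synth_params(noise_sd_mm = 0.005, outlier_rate = 0.002)
  errs <- t(vapply(1:60, function(i) {
    tr <- generate_trial("onset", params, seed = 4000 + i)
    gt <- tr$ground_truth
    p <- extract_profile(tr)
    c(max1 = abs(p$max1_mm - gt$max1_mm),
      min = abs(p$min_mm - gt$min_mm),
      max2 = abs(p$max2_mm - gt$max2_mm),
      cdur = abs(p$constriction_duration_ms - gt$constriction_duration_ms),
      ddur = abs(p$dilation_duration_ms - gt$dilation_duration_ms))
  }, numeric(5)))
  expect_lt(median(errs[, "max1"]), 0.01)
  expect_lt(median(errs[, "min"]), 0.01)
  expect_lt(median(errs[, "max2"]), 0.01)
  expect_lt(median(errs[, "cdur"]), 20)
  expect_lt(median(errs[, "ddur"]), 20)
  # luminance-change signs respect the profile ordering
  tr <- generate_trial("onset", params, seed = 4999)
  p <- extract_profile(tr)
  expect_lte(p$lum_decrease_pct, 0)
  expect_gte(p$lum_increase_pct, 0)
})

test_that("aggregate_table averages participants then experiments", {
  # single participant: the Mean row equals that participant's row
  one <- tibble::tibble(experiment = "blink", participant = "P1",
                        max1_mm = 3, min_mm = 2.8, max2_mm = 3.05,
                        lum_decrease_pct = -12, lum_increase_pct = 18)
  tab <- aggregate_table(one, digits = NULL)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$max1_mm[tab$participant == "Mean"], 3)

  # per-trial rows average within participant before the Mean row
  two <- tibble::tibble(
    experiment = "onset", participant = rep(c("P1", "P2"), each = 2),
    max1_mm = c(3.0, 3.2, 3.4, 3.6), min_mm = 2.8, max2_mm = 3.1,
    lum_decrease_pct = -10, lum_increase_pct = 15)
  tab2 <- aggregate_table(two, digits = NULL)
  expect_equal(tab2$max1_mm[tab2$participant == "Mean"], mean(c(3.1, 3.5)))

  # degenerate/invalid trials are excluded when flagged
  two$valid <- c(TRUE, TRUE, TRUE, FALSE)
  two$degenerate <- FALSE
  tab3 <- aggregate_table(two, digits = NULL)
  expect_equal(tab3$max1_mm[tab3$participant == "P2"], 3.4)
})
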