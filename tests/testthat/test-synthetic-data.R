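test_that("pupil_response has exact, recoverable extrema", {
  t <- seq(0, 6000, by = 2)

  # zero amplitude: constant baseline
  flat <- pupil_response(t, 3.1, 0, 700, 2500)
  expect_equal(as.numeric(flat), rep(3.1, length(t)))

  # deterministic core: identical output on repeat calls
  d1 <- pupil_response(t, 3.1, 0.35, 700, 2500, 0.02)
  d2 <- pupil_response(t, 3.1, 0.35, 700, 2500, 0.02)
  expect_identical(d1, d2)

  # numerical extrema match the analytic ground truth to one sample
  ex <- attr(d1, "extrema")
  expect_equal(t[which.min(d1)], ex$min_t_ms, tolerance = 2)
  expect_equal(min(d1), ex$min_mm, tolerance = 1e-9)
  i_min <- which.min(d1)
  expect_equal(t[i_min - 1 + which.max(d1[i_min:length(d1)])], ex$max2_t_ms,
               tolerance = 2)
  expect_equal(max(d1[i_min:length(d1)]), ex$max2_mm, tolerance = 1e-9)
  expect_equal(d1[1], ex$max1_mm, tolerance = 1e-9)
  # single interior minimum: descending then ascending around it
  expect_true(all(diff(d1[1:i_min]) <= 0))

  # impossible timings are a parameter error
  expect_error(pupil_response(t, 3.1, 0.3, 300, 2500), "parameter error")
  expect_error(pupil_response(t, 3.1, 0.3, 700, 200), "parameter error")
  expect_error(pupil_response(t, 3.1, 0.3, 700, 2500, overshoot_mm = -0.2),
               "parameter error")
})

test_that("generate_trial is a pure function of its seed", {
  a <- generate_trial("blink", synth_params(), seed = 77)
  b <- generate_trial("blink", synth_params(), seed = 77)
  expect_identical(a, b)
  c <- generate_trial("blink", synth_params(), seed = 78)
  expect_false(identical(a$trace$pupil_mm, c$trace$pupil_mm))
})

test_that("injected blink is detected exactly 200 ms after the last zero", {
  for (seed in 301:310) {
    tr <- generate_trial("blink", synth_params(), seed = seed)
    ev <- detect_blink(tr$trace$pupil_mm)
    expect_s3_class(ev, "blink_event")
    expect_equal(ev$zero_run_end_idx, tr$ground_truth$zero_run_end_idx)
    expect_equal(ev$analysis_start_idx, tr$ground_truth$analysis_start_idx)
    expect_equal(ev$analysis_start_idx - ev$zero_run_end_idx, 100)  # 200 ms
  }
})

test_that("illusion durations couple to dilation duration at the target rho", {
  params <- synth_params(illusion_corr_rho = 0.7)
  gt <- t(vapply(1:500, function(i) {
    tr <- generate_trial("onset", params, seed = 20000 + i)
    c(tr$ground_truth$dilation_duration_ms, tr$illusion_duration_s)
  }, numeric(2)))
  r <- cor(gt[, 1], gt[, 2])
  # 95% sampling band of rho = 0.7 at n = 500 (Fisher z) is about +/- 0.045
  expect_gt(r, 0.7 - 0.045)
  expect_lt(r, 0.7 + 0.045)
  # durations span the observed 1-7 s range
  expect_gt(min(gt[, 2]), 0.25)
  expect_lt(mean(gt[, 2]), 5)
})

test_that("generate_dataset mirrors the study design with per-stimulus effects", {
  ds <- generate_dataset(n_participants = 4, n_trials_per_cell = 10,
                         seed = 500)
  expect_length(ds$trials, 360)  # 4 x 3 experiments x 3 stimuli x 10
  expect_equal(nrow(ds$ground_truth), 360)

  # reproducible from the seed alone
  ds2 <- generate_dataset(n_participants = 4, n_trials_per_cell = 10,
                          seed = 500)
  expect_identical(ds$ground_truth, ds2$ground_truth)

  # stimulus effect-size ordering: snakes > disks > fraser_wilcox
  amp <- tapply(ds$ground_truth$amplitude_mm, ds$ground_truth$stimulus, mean)
  expect_gt(amp[["snakes"]], amp[["disks"]])
  expect_gt(amp[["disks"]], amp[["fraser_wilcox"]])

  # on-disk manifest round-trips through the native layout
  dir <- withr::local_tempdir()
  small <- generate_dataset(n_participants = 1, n_trials_per_cell = 2,
                            stimuli = "snakes", experiments = "onset",
                            seed = 501, dir = dir)
  expect_true(file.exists(file.path(dir, "ground_truth.csv")))
  back <- read_trials(dir)
  expect_length(back, 2)
  expect_identical(back[[1]]$trace$pupil_mm, small$trials[[1]]$trace$pupil_mm)
  expect_equal(back[[2]]$ground_truth$min_mm,
               small$trials[[2]]$ground_truth$min_mm)
})

test_that("luminance modulation scales frames by pupil-area ratio", {
  img <- matrix(0.5, 8, 8)

  # constant profile: all frames identical to the input
  frames <- modulate_image_luminance(img, rep(3, 5))
  expect_true(all(vapply(frames, function(f) identical(f, img), logical(1))))

  # area scaled by 0.85: frame mean scales linearly (no clipping)
  d0 <- 3
  d1 <- 2 * sqrt(0.85 * (d0 / 2)^2)
  fr <- modulate_image_luminance(img, c(d0, d1))
  expect_equal(mean(fr[[2]]), 0.85 * mean(img), tolerance = 1e-12)

  # a blink-like profile dips ~9% then recovers ~15% above the dip
  prof <- c(2.971, 2.834, 3.044)
  fr2 <- modulate_image_luminance(img, prof)
  dip <- mean(fr2[[2]]) / mean(fr2[[1]]) - 1
  rec <- mean(fr2[[3]]) / mean(fr2[[2]]) - 1
  expect_equal(100 * dip, -9.0, tolerance = 0.1)
  expect_equal(100 * rec, 15.4, tolerance = 0.1)

  expect_error(modulate_image_luminance(matrix(2, 2, 2), 3), "0, 1")
})
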