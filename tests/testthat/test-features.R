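test_that("track length sums Euclidean steps", {
  sq <- cop_track(c(0, 1, 1, 0, 0), c(0, 0, 1, 1, 0), 10)
  expect_equal(track_length(sq), 4)
  expect_error(track_length(cop_track(1, 1, 10)), "at least 2")

  theta <- seq(0, 2 * pi, length.out = 20001)
  circle <- cop_track(3 * cos(theta), 3 * sin(theta), 100)
  expect_equal(track_length(circle), 2 * pi * 3, tolerance = 1e-6)
})

test_that("track length is rotation invariant", {
  tr <- sine_track(1.3, 2, 1, duration = 5)
  ang <- 0.7
  rot <- cop_track(cos(ang) * tr$x_ml_cm - sin(ang) * tr$y_ap_cm,
                   sin(ang) * tr$x_ml_cm + cos(ang) * tr$y_ap_cm,
                   tr$rate_hz)
  expect_equal(track_length(rot), track_length(tr), tolerance = 1e-9)
})

test_that("the periodogram obeys Parseval against time-domain oracles", {
  cfg <- test_config()
  # sine of amplitude a: band area around f equals a^2/2
  tr <- sine_track(2, a_x = 0.8, a_y = 0, duration = 10)
  tr$y_ap_cm <- tr$y_ap_cm + sin(2 * pi * 0.5 * seq_len(2000) / 200)
  spec <- cop_psd(tr, cfg)
  expect_equal(band_area(spec, 1.5, 2.5, axis = "ML"), 0.8^2 / 2,
               tolerance = 0.01)
  # white noise: total area equals the variance (chi-square spread at n=4000)
  set.seed(4)
  wn <- cop_track(rnorm(4000, 0, 0.5), rnorm(4000, 0, 0.5), 200)
  spw <- cop_psd(wn, cfg)
  pop_var <- function(v) mean((v - mean(v))^2)
  total <- suppressWarnings(band_area(spw, 1e-6, 1e6))  # full support
  expect_equal(total, pop_var(wn$x_ml_cm) + pop_var(wn$y_ap_cm),
               tolerance = 1e-6)
  # degenerate/zero signals
  z <- cop_track(rep(0, 100), rep(0, 100), 100)
  expect_true(all(cop_psd(z, cfg)$density == 0))
  bad <- cop_track(c(rep(0, 99), NA), rep(0, 100), 100)
  expect_error(cop_psd(bad, cfg), "non-finite")
})

test_that("the Welch estimator agrees with the periodogram in the mean", {
  cfg_w <- sway_config(sampling_rate_hz = 200, trial_duration_s = 20,
                       filter_cutoff_hz = 10, psd_method = "welch",
                       welch_segment_s = 5)
  set.seed(6)
  tr <- cop_track(rnorm(4000, 0, 1), rnorm(4000, 0, 1), 200)
  spw <- cop_psd(tr, cfg_w)
  pop_var <- function(v) mean((v - mean(v))^2)
  total <- suppressWarnings(band_area(spw, 1e-6, 1e6))
  expect_equal(total, pop_var(tr$x_ml_cm) + pop_var(tr$y_ap_cm),
               tolerance = 0.1)
})

test_that("band integration is additive and clips to the support", {
  tr <- sine_track(1, 1, 1, duration = 10)
  spec <- cop_psd(tr, test_config())
  a <- band_area(spec, 0.5, 2); b <- band_area(spec, 2, 5)
  expect_equal(a + b, band_area(spec, 0.5, 5), tolerance = 1e-12)
  expect_warning(low <- band_area(spec, 0.001, 1), "below resolution")
  expect_equal(low, band_area(spec, spec$freqs_hz[1], 1))
  expect_equal(spec$freqs_hz[1], 1 / 10)  # 10 s record: first bin 0.1 Hz
  expect_error(band_area(spec, 200, 300), "no overlap")
  expect_error(band_area(spec, 3, 2))
})

test_that("band areas of nested windows are monotone and partition-additive", {
  cfg <- test_config()
  for (seed in 1:5) {
    p <- default_group_params(if (seed %% 2) "Healthy" else "LowBackPain")
    tr <- simulate_cop_track(p, 15, 200, seed = seed)
    spec <- cop_psd(tr, cfg)
    ba <- function(lo, hi) suppressWarnings(band_area(spec, lo, hi))
    nested <- c(ba(0.001, 4), ba(0.001, 6), ba(0.001, 8), ba(0.001, 10))
    expect_true(all(diff(nested) >= 0))
    expect_equal(ba(0.001, 1) + ba(1, 4) + ba(4, 8), ba(0.001, 8),
                 tolerance = 1e-10)
  }
})

test_that("resultant band areas are invariant under axis rotation", {
  tr <- sine_track(1.5, 1.2, 0.5, duration = 10)
  ang <- 1.1
  rot <- cop_track(cos(ang) * tr$x_ml_cm - sin(ang) * tr$y_ap_cm,
                   sin(ang) * tr$x_ml_cm + cos(ang) * tr$y_ap_cm,
                   tr$rate_hz)
  cfg <- test_config()
  s1 <- cop_psd(tr, cfg); s2 <- cop_psd(rot, cfg)
  expect_equal(band_area(s1, 1, 2), band_area(s2, 1, 2), tolerance = 1e-9)
})

test_that("per-cycle peak acceleration matches the analytic sine value", {
  A <- 2; f <- 1; rate <- 200
  t <- seq(0, 10 - 1 / rate, by = 1 / rate)
  tr <- cop_track(0.3 * sin(2 * pi * 0.5 * t), A * sin(2 * pi * f * t), rate)
  got <- mean_max_accel(tr)
  expect_equal(got, A * (2 * pi * f)^2, tolerance = 0.01)
  flat <- cop_track(rep(1, 100), rep(2, 100), 100)
  expect_error(mean_max_accel(flat), "no complete movement cycle")
})

test_that("ellipticity measures the principal-axis ratio and guards edge cases", {
  set.seed(10)
  iso <- cop_track(rnorm(20000), rnorm(20000), 100)
  expect_equal(ellipticity(iso), 1, tolerance = 0.03)

  tr <- sine_track(1, a_x = 1, a_y = 2, duration = 50)
  expect_equal(ellipticity(tr), 2, tolerance = 0.02)

  line <- cop_track(1:100, 2 * (1:100), 100)
  expect_error(ellipticity(line), "degenerate")
  flatx <- cop_track(rep(0, 100), rnorm(100), 100)
  expect_error(ellipticity(flatx), "zero variance")
  expect_error(ellipticity(cop_track(1:5, 1:5, 10)), "at least 10")
})

test_that("feature extraction assembles the configured columns", {
  cfg <- test_config()
  p <- default_group_params("Healthy")
  tr <- simulate_cop_track(p, 10, 200, seed = 5, subject_id = "X1")
  fv <- suppressWarnings(extract_features(tr, cfg))
  expect_equal(fv$subject_id, "X1")
  expect_true(all(c("track_length_cm", "band_0p001_10", "band_4_8",
                    "mean_max_accel", "ellipticity") %in% names(fv)))
  expect_true(all(vapply(fv[-1], is.numeric, logical(1))))
  expect_gte(fv$ellipticity, 1)
})
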