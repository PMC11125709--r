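test_that("the low-pass filter preserves DC and rejects invalid cutoffs", {
  x <- rep(3.7, 500)
  expect_equal(butterworth_lowpass(x, 200, 10, 3), x, tolerance = 1e-9)
  expect_error(butterworth_lowpass(x, 200, 100, 3), "Nyquist")
  expect_error(butterworth_lowpass(c(x, NA), 200, 10, 3), "non-finite")
})

test_that("single-pass design magnitude is -3 dB at the cutoff", {
  h <- butterworth_response(10, 1000, 10, 3)
  expect_equal(h, 1 / sqrt(2), tolerance = 1e-3)
  # monotone low-pass: passband near 1, stopband falling
  expect_gt(butterworth_response(1, 1000, 10, 3), 0.999)
  expect_lt(butterworth_response(50, 1000, 10, 3), 0.01)
})

test_that("a decade above cutoff a tone mixture is attenuated > 60 dB", {
  rate <- 1000
  t <- seq(0, 4 - 1 / rate, by = 1 / rate)
  x <- sin(2 * pi * 0.5 * t) + sin(2 * pi * 100 * t)
  y <- butterworth_lowpass(x, rate, 10, 3)
  amp_at <- function(v, f) {
    X <- fft(v); n <- length(v)
    2 * Mod(X[round(f * n / rate) + 1]) / n
  }
  atten_db <- 20 * log10(amp_at(x, 100) / amp_at(y, 100))
  expect_gt(atten_db, 60)
  # low-frequency content passes essentially unchanged
  expect_equal(amp_at(y, 0.5), 1, tolerance = 0.01)
})

test_that("filtering is zero-phase (no lag on a passband tone)", {
  rate <- 200
  t <- seq(0, 10 - 1 / rate, by = 1 / rate)
  x <- sin(2 * pi * 1 * t)
  y <- butterworth_lowpass(x, rate, 10, 3)
  core <- 200:1800  # away from the ends
  lags <- -5:5
  cc <- vapply(lags, function(L) cor(x[core], y[core + L]), numeric(1))
  expect_equal(lags[which.max(cc)], 0)
  expect_gt(max(cc), 0.999)
})

test_that("the residual-analysis cutoff lands above the signal band", {
  cfg <- sway_config(sampling_rate_hz = 200, trial_duration_s = 10,
                     filter_cutoff_hz = "auto", max_auto_cutoff_hz = 20)
  p <- sway_params(component_bands = list(c(1, 0.3, 0.1), c(2.5, 0.2, 0.1)),
                   noise_sd_cm = 0.05)
  recs <- lapply(1:3, function(i) {
    tr <- simulate_cop_track(p, 10, 200, seed = 40 + i)
    inverse_cop_to_forces(tr, 75)
  })
  fc <- select_cutoff(recs, cfg)
  expect_gte(fc, 3)
  expect_lte(fc, 15)
})

test_that("cutoff selection honors overrides and degenerate inputs", {
  cfg_fixed <- sway_config(sampling_rate_hz = 200, filter_cutoff_hz = 10)
  rec_any <- inverse_cop_to_forces(sine_track(1, 1, 1, duration = 5), 75)
  expect_equal(select_cutoff(list(rec_any), cfg_fixed), 10)

  cfg_auto <- sway_config(sampling_rate_hz = 200, filter_cutoff_hz = "auto",
                          max_auto_cutoff_hz = 20)
  flat <- force_recording(rep(100, 1000), rep(100, 1000), rep(100, 1000),
                          rep(100, 1000), 200)
  expect_warning(fc <- select_cutoff(list(flat), cfg_auto), "degenerate")
  expect_equal(fc, 20)

  set.seed(8)
  wn <- force_recording(rnorm(2000, 100), rnorm(2000, 100),
                        rnorm(2000, 100), rnorm(2000, 100), 200)
  expect_warning(fcw <- select_cutoff(list(wn), cfg_auto), "no residual knee")
  expect_equal(fcw, 20)
  expect_error(select_cutoff(list(), cfg_auto), "at least one")
})

test_that("CoP follows the four-sensor board formula", {
  eq <- force_recording(rep(10, 5), rep(10, 5), rep(10, 5), rep(10, 5),
                        100, 25.5, 15.5)
  tr <- compute_cop(eq)
  expect_true(all(tr$x_ml_cm == 0) && all(tr$y_ap_cm == 0))

  corner <- force_recording(rep(0, 5), rep(50, 5), rep(0, 5), rep(0, 5),
                            100, 25.5, 15.5)
  trc <- compute_cop(corner)
  expect_equal(trc$x_ml_cm, rep(15.5, 5))
  expect_equal(trc$y_ap_cm, rep(25.5, 5))

  unloaded <- force_recording(c(1, 0), c(1, 0), c(1, 0), c(1, 0), 100)
  expect_error(compute_cop(unloaded), "sample 2")
})

test_that("CoP is invariant to uniform channel scaling", {
  set.seed(2)
  base <- matrix(runif(400, 50, 150), ncol = 4)
  r1 <- force_recording(base[, 1], base[, 2], base[, 3], base[, 4], 100)
  r2 <- force_recording(3 * base[, 1], 3 * base[, 2], 3 * base[, 3],
                        3 * base[, 4], 100)
  t1 <- compute_cop(r1); t2 <- compute_cop(r2)
  expect_equal(t1$x_ml_cm, t2$x_ml_cm, tolerance = 1e-12)
  expect_equal(t1$y_ap_cm, t2$y_ap_cm, tolerance = 1e-12)
})

test_that("filter-then-CoP commutes with CoP-then-filter for small sway", {
  cfg <- test_config()
  p <- sway_params(component_bands = list(c(1, 0.2, 0.1), c(3, 0.1, 0.2)),
                   noise_sd_cm = 0.02)
  tr <- simulate_cop_track(p, 10, 200, seed = 77)
  rec <- inverse_cop_to_forces(tr, 75)
  a <- preprocess_recording(rec, 10, cfg)              # filter forces first
  b_raw <- compute_cop(rec)                            # CoP on raw forces
  b <- cop_track(butterworth_lowpass(b_raw$x_ml_cm, 200, 10, 3),
                 butterworth_lowpass(b_raw$y_ap_cm, 200, 10, 3), 200)
  # linearization about the board center: sway is < 2% of the half-width
  expect_lt(max(abs(a$x_ml_cm - b$x_ml_cm)), 0.005)
  expect_lt(max(abs(a$y_ap_cm - b$y_ap_cm)), 0.005)
})
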