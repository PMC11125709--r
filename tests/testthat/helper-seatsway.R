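# Shared fixture builders. Everything is generated in code; tests that
# need files write them to tempdir().

# A light config for unit tests: full band set still fits under the
# reduced Nyquist (rate 200 Hz).
test_config <- function(...) {
  sway_config(sampling_rate_hz = 200, trial_duration_s = 10,
              filter_cutoff_hz = 10, rng_seed = 42L, ...)
}

# Deterministic sinusoidal track: x = a_x sin(2 pi f t), y = a_y sin(.. + phase)
sine_track <- function(f = 1, a_x = 1, a_y = 1, phase = pi / 2,
                       duration = 10, rate = 200, id = "sine") {
  t <- seq(0, duration - 1 / rate, by = 1 / rate)
  cop_track(a_x * sin(2 * pi * f * t),
            a_y * sin(2 * pi * f * t + phase), rate, subject_id = id)
}

# Small labeled feature table with a clean group separation.
toy_features <- function(n_per_group = 10, sep = 3, seed = 7) {
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); expr
  }
  withr_seed({
    data.frame(
      subject_id = sprintf("T%02d", seq_len(2 * n_per_group)),
      pain = rep(c("Healthy", "LowBackPain"), each = n_per_group),
      f1 = c(rnorm(n_per_group, 0), rnorm(n_per_group, sep)),
      f2 = c(rnorm(n_per_group, 0), rnorm(n_per_group, -sep)),
      stringsAsFactors = FALSE)
  })
}

# Explicit sums-of-squares oracle for a balanced two-way factorial with
# interaction, from cell/marginal means only.
anova_oracle_2way <- function(y, a, b) {
  grand <- mean(y)
  cell <- tapply(y, list(a, b), mean)
  ma <- tapply(y, a, mean); mb <- tapply(y, b, mean)
  n_cell <- length(y) / (nlevels(a) * nlevels(b))
  ss_a <- nlevels(b) * n_cell * sum((ma - grand)^2)
  ss_b <- nlevels(a) * n_cell * sum((mb - grand)^2)
  ss_ab <- n_cell * sum((sweep(sweep(cell, 1, ma), 2, mb) + grand)^2)
  ss_e <- sum((y - cell[cbind(as.integer(a), as.integer(b))])^2)
  df <- c(a = nlevels(a) - 1, b = nlevels(b) - 1,
          ab = (nlevels(a) - 1) * (nlevels(b) - 1),
          e = length(y) - nlevels(a) * nlevels(b))
  ss <- c(a = ss_a, b = ss_b, ab = ss_ab, e = ss_e)
  ms_e <- ss_e / df[["e"]]
  ss_tot <- sum(ss)
  list(F = (ss[1:3] / df[1:3]) / ms_e,
       etasq = ss[1:3] / ss_tot,
       omegasq = (ss[1:3] - df[1:3] * ms_e) / (ss_tot + ms_e))
}

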