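#' Sway-model parameters
#'
#' Parameters of the generative model for one subject's seated sway. The
#' CoP is modelled, per axis, as a sum of narrowband stochastic
#' oscillators — each a sinusoid whose phase performs a slow random walk,
#' giving a Lorentzian line of the requested bandwidth around its center
#' frequency — plus a low-frequency random-walk drift and white
#' measurement noise. The anteroposterior (AP) axis carries the same
#' component structure as the mediolateral (ML) axis with all amplitudes
#' scaled by `ellipticity`, so `ellipticity = 1` yields statistically
#' circular tracks and larger values yield AP-elongated ellipses.
#'
#' Component center frequencies follow the pendular anatomy of seated
#' sway: hip-axis motion a few cm above the plate maps to roughly
#' 1.5–3 Hz, sacroiliac-level motion (~20 cm) to about 1 Hz, and thoracic
#' motion (~30–45 cm) to 0.7–0.9 Hz, with faster corrective activity from
#' the musculature in contact with the seat.
#'
#' @param component_bands Matrix-like list of components; each a numeric
#'   `c(center_freq_hz, amplitude_cm, bandwidth_hz)`. `amplitude_cm` is
#'   the ML sinusoid amplitude, so each component contributes
#'   `amplitude_cm^2 / 2` to the ML variance.
#' @param ellipticity AP/ML amplitude ratio, >= 1 for AP-dominant sway.
#' @param drift_amplitude_cm Standard deviation of the low-frequency
#'   random-walk drift over the trial (cm); 0 disables drift.
#' @param noise_sd_cm SD of white broadband jitter (cm): sensor noise
#'   plus unresolved high-frequency neuromuscular activity. Referenced
#'   to a 1 kHz sampling rate: the per-sample SD used in simulation is
#'   scaled by `sqrt(rate_hz/1000)` so the jitter's spectral density
#'   (cm^2/Hz) — the physically meaningful quantity — is identical
#'   whatever rate the track is sampled at.
#' @param subject_mass_kg Subject mass (kg), used when converting tracks
#'   to corner forces.
#' @param board_half_length_cm,board_half_width_cm Board half-dimensions.
#' @return An object of class `sway_params`.
#' @export
sway_params <- function(component_bands = list(c(1, 0.1, 0.1)),
                        ellipticity = 1,
                        drift_amplitude_cm = 0,
                        noise_sd_cm = 0,
                        subject_mass_kg = 75.8,
                        board_half_length_cm = 25.5,
                        board_half_width_cm = 15.5) {
  comps <- lapply(component_bands, function(b) as.numeric(unlist(b)))
  for (b in comps) {
    if (length(b) != 3 || !all(is.finite(b))) {
      stop("each component must be finite c(center_hz, amplitude_cm, bandwidth_hz)")
    }
    if (b[1] <= 0) stop("component center frequency must be positive")
    if (b[2] < 0 || b[3] < 0) stop("amplitude and bandwidth must be >= 0")
  }
  if (!is.finite(ellipticity) || ellipticity < 1) {
    stop("ellipticity must be finite and >= 1")
  }
  stopifnot(is.finite(drift_amplitude_cm), drift_amplitude_cm >= 0,
            is.finite(noise_sd_cm), noise_sd_cm >= 0,
            is.finite(subject_mass_kg), subject_mass_kg > 0)
  structure(list(component_bands = comps,
                 ellipticity = ellipticity,
                 drift_amplitude_cm = drift_amplitude_cm,
                 noise_sd_cm = noise_sd_cm,
                 subject_mass_kg = subject_mass_kg,
                 board_half_length_cm = board_half_length_cm,
                 board_half_width_cm = board_half_width_cm),
            class = "sway_params")
}

# Evaluate expr with a local, restored RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# One narrowband oscillator: amplitude a at f0, phase random walk whose
# diffusion gives a Lorentzian line of FWHM = bw Hz.
narrowband_component <- function(t, f0, a, bw, dt) {
  phi0 <- stats::runif(1, 0, 2 * pi)
  if (bw > 0) {
    dphi <- stats::rnorm(length(t), 0, sqrt(2 * pi * bw * dt))
    phi <- cumsum(dphi)
  } else {
    phi <- 0
  }
  a * sin(2 * pi * f0 * t + phi0 + phi)
}

sway_axis <- function(t, comps, amp_scale, drift_sd, noise_sd, dt) {
  x <- numeric(length(t))
  for (b in comps) {
    x <- x + narrowband_component(t, b[1], b[2] * amp_scale, b[3], dt)
  }
  if (drift_sd > 0) {
    w <- cumsum(stats::rnorm(length(t)))
    w <- w - mean(w)
    x <- x + w * (drift_sd * amp_scale / stats::sd(w))
  }
  if (noise_sd > 0) x <- x + stats::rnorm(length(t), 0, noise_sd)
  x
}

#' Simulate a CoP track from sway-model parameters
#'
#' @param params A [sway_params()].
#' @param duration_s Trial duration (s).
#' @param rate_hz Sampling rate (Hz).
#' @param seed Integer seed; identical seeds give bit-identical tracks.
#' @param subject_id Identifier for the track.
#' @return A [cop_track()].
#' @export
simulate_cop_track <- function(params, duration_s = 60, rate_hz = 1000,
                               seed = 1L, subject_id = "sim") {
  stopifnot(inherits(params, "sway_params"))
  n <- round(duration_s * rate_hz)
  if (n < 2) stop("duration_s * rate_hz must give at least 2 samples")
  nyq <- rate_hz / 2
  for (b in params$component_bands) {
    if (b[1] >= nyq) {
      stop(sprintf("component frequency %g Hz at or above Nyquist", b[1]))
    }
  }
  dt <- 1 / rate_hz
  t <- (seq_len(n) - 1) * dt
  # constant-density jitter: per-sample SD referenced to 1 kHz
  noise_sd <- params$noise_sd_cm * sqrt(rate_hz / 1000)
  with_seed(seed, {
    x <- sway_axis(t, params$component_bands, 1,
                   params$drift_amplitude_cm, noise_sd, dt)
    y <- sway_axis(t, params$component_bands, params$ellipticity,
                   params$drift_amplitude_cm * params$ellipticity,
                   noise_sd, dt)
    cop_track(x, y, rate_hz, subject_id = subject_id)
  })
}

#' Corner forces from a CoP track (exact inverse of [compute_cop()])
#'
#' Distributes the subject's weight force over the four load cells so
#' that the forward CoP computation recovers the input track to machine
#' precision and the channel sum equals `mass_kg * g` at every sample:
#' with reduced coordinates `a = x/half_width`, `b = y/half_length`,
#' \deqn{TL = F(1-a)(1+b)/4,\; TR = F(1+a)(1+b)/4,\;
#'       BL = F(1-a)(1-b)/4,\; BR = F(1+a)(1-b)/4.}
#'
#' @param track A [cop_track()].
#' @param mass_kg Subject mass (kg).
#' @param board_half_length_cm,board_half_width_cm Board half-dimensions.
#' @param g Gravitational acceleration (m/s^2).
#' @return A [force_recording()].
#' @export
inverse_cop_to_forces <- function(track, mass_kg,
                                  board_half_length_cm = 25.5,
                                  board_half_width_cm = 15.5,
                                  g = 9.80665) {
  stopifnot(inherits(track, "cop_track"), mass_kg > 0)
  a <- track$x_ml_cm / board_half_width_cm
  b <- track$y_ap_cm / board_half_length_cm
  if (any(abs(a) > 1) || any(abs(b) > 1)) {
    stop("track exceeds board half-dimensions; cannot realize as corner forces")
  }
  f <- mass_kg * g
  rec <- force_recording(
    f_tl = f * (1 - a) * (1 + b) / 4,
    f_tr = f * (1 + a) * (1 + b) / 4,
    f_bl = f * (1 - a) * (1 - b) / 4,
    f_br = f * (1 + a) * (1 - b) / 4,
    rate_hz = track$rate_hz,
    board_half_length_cm = board_half_length_cm,
    board_half_width_cm = board_half_width_cm,
    subject_id = track$subject_id
  )
  rec
}

#' Default sway parameters for the two study groups
#'
#' Calibrated once so a default cohort reproduces the direction and rough
#' magnitude of the published group contrasts: healthy sway is faster,
#' near-circular and lower-power (longer CoP track, total 0.001–10 Hz
#' band area around 0.026 cm^2); low-back-pain sway is slower, AP-
#' elongated and higher-power (shorter track, band area around 0.115
#' cm^2, roughly 4x healthy), with extra high-frequency corrective jitter
#' raising its per-cycle peak acceleration.
#'
#' @param group `"Healthy"` or `"LowBackPain"`.
#' @return A [sway_params()].
#' @export
default_group_params <- function(group = c("Healthy", "LowBackPain")) {
  group <- match.arg(group)
  if (group == "Healthy") {
    sway_params(
      component_bands = list(
        c(0.75, 0.0825, 0.05),  # thoracic pendulum
        c(0.95, 0.0831, 0.05),  # sacroiliac pendulum
        c(2.20, 0.0729, 0.15),  # hip-axis pendulum
        c(5.00, 0.0317, 0.40)   # fast corrective activity
      ),
      ellipticity = 1.1,
      drift_amplitude_cm = 0.05,
      noise_sd_cm = 0.04
    )
  } else {
    sway_params(
      component_bands = list(
        c(0.30, 0.1334, 0.03),  # slowed postural corrections
        c(0.50, 0.1334, 0.03),
        c(2.20, 0.0359, 0.15),
        c(5.00, 0.0135, 0.40)
      ),
      ellipticity = 2.0,
      drift_amplitude_cm = 0.05,
      noise_sd_cm = 0.10
    )
  }
}

#' Cohort specification for the synthetic generator
#'
#' @param n_per_group Subjects per group (>= 1).
#' @param healthy_params,pain_params Group-level [sway_params()] around
#'   which individual subjects are drawn.
#' @param amp_sdlog Log-SD of the per-subject multiplicative amplitude
#'   factor (applied to all components at once), so band power spreads
#'   log-normally with a coefficient of variation near 1 at the default.
#' @param ellipticity_sd SD of per-subject additive ellipticity jitter
#'   (floored at 1).
#' @param noise_sdlog Log-SD of the per-subject noise-level factor.
#' @param rng_seed Master seed; per-subject seeds are derived from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 50,
                        healthy_params = default_group_params("Healthy"),
                        pain_params = default_group_params("LowBackPain"),
                        amp_sdlog = 0.4,
                        ellipticity_sd = 0.15,
                        noise_sdlog = 0.2,
                        rng_seed = 1L) {
  if (!is.numeric(n_per_group) || n_per_group < 1 ||
        n_per_group != round(n_per_group)) {
    stop("n_per_group must be a positive integer")
  }
  stopifnot(inherits(healthy_params, "sway_params"),
            inherits(pain_params, "sway_params"))
  structure(list(n_per_group = as.integer(n_per_group),
                 healthy_params = healthy_params,
                 pain_params = pain_params,
                 amp_sdlog = amp_sdlog,
                 ellipticity_sd = ellipticity_sd,
                 noise_sdlog = noise_sdlog,
                 rng_seed = as.integer(rng_seed)),
            class = "cohort_spec")
}

#' Draw one subject's sway parameters from a cohort specification
#'
#' @param spec A [cohort_spec()].
#' @param group `"Healthy"` or `"LowBackPain"`.
#' @param seed Integer seed for the subject's parameter draw.
#' @return A [sway_params()].
#' @export
draw_sway_params <- function(spec, group, seed) {
  base <- if (group == "Healthy") spec$healthy_params else spec$pain_params
  with_seed(seed, {
    amp_f <- stats::rlnorm(1, 0, spec$amp_sdlog)
    ell <- max(1, base$ellipticity + stats::rnorm(1, 0, spec$ellipticity_sd))
    noise_f <- stats::rlnorm(1, 0, spec$noise_sdlog)
    comps <- lapply(base$component_bands,
                    function(b) c(b[1], b[2] * amp_f, b[3]))
    sway_params(component_bands = comps, ellipticity = ell,
                drift_amplitude_cm = base$drift_amplitude_cm * amp_f,
                noise_sd_cm = base$noise_sd_cm * noise_f,
                subject_mass_kg = base$subject_mass_kg,
                board_half_length_cm = base$board_half_length_cm,
                board_half_width_cm = base$board_half_width_cm)
  })
}

# Anthropometry draws follow the published cohort description: ~52% male;
# male height 180.9 +/- 7.7 cm, weight 83.9 +/- 13.7 kg, shoe 42.5 EU;
# female 160.3 +/- 8 cm (the printed female height SD of 34 cm is a table
# artifact; 8 cm is the physiological value), 66.1 +/- 11.9 kg, shoe 38.9.
# The pain group is older than the healthy group, as in the study.
draw_anthropometry <- function(group, seed) {
  with_seed(seed, {
    sex <- if (stats::runif(1) < 0.52) "M" else "F"
    if (sex == "M") {
      height <- stats::rnorm(1, 180.9, 7.7)
      weight <- max(45, stats::rnorm(1, 83.9, 13.7))
      shoe <- stats::rnorm(1, 42.5, 2.7)
    } else {
      height <- stats::rnorm(1, 160.3, 8)
      weight <- max(40, stats::rnorm(1, 66.1, 11.9))
      shoe <- stats::rnorm(1, 38.9, 1.5)
    }
    age <- if (group == "LowBackPain") stats::rnorm(1, 45, 10)
           else stats::rnorm(1, 28, 8)
    age <- min(60, max(18, age))
    korff <- if (group == "LowBackPain") sample(1:4, 1) else 0L
    list(sex = sex, age = age, height = height, weight = weight,
         shoe = shoe, korff = korff)
  })
}

#' Generate a labeled synthetic cohort
#'
#' Draws `n_per_group` subjects per group, simulates each subject's CoP
#' track from individually jittered group parameters, and (by default)
#' converts each track to a raw four-channel force recording via
#' [inverse_cop_to_forces()] so the data enter the pipeline at the raw
#' stage. Fully deterministic given `spec$rng_seed`.
#'
#' @param spec A [cohort_spec()].
#' @param duration_s,rate_hz Trial duration and sampling rate.
#' @param output `"forces"` (default) for raw recordings, `"tracks"` to
#'   stop at the noiseless-inverse CoP stage.
#' @return A list with elements `subjects` (a cohort data.frame) and
#'   `recordings` (or `tracks`), in subject order.
#' @export
generate_cohort <- function(spec, duration_s = 60, rate_hz = 1000,
                            output = c("forces", "tracks")) {
  stopifnot(inherits(spec, "cohort_spec"))
  output <- match.arg(output)
  groups <- rep(c("Healthy", "LowBackPain"), each = spec$n_per_group)
  subjects <- vector("list", length(groups))
  data <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    grp <- groups[i]
    id <- sprintf("S%03d", i)
    p <- draw_sway_params(spec, grp, derive_seed(spec$rng_seed, "params", i))
    anth <- draw_anthropometry(grp, derive_seed(spec$rng_seed, "anthro", i))
    track <- simulate_cop_track(p, duration_s, rate_hz,
                                seed = derive_seed(spec$rng_seed, "track", i),
                                subject_id = id)
    subjects[[i]] <- subject_record(
      id, anth$sex, anth$age, anth$height, anth$weight, anth$shoe,
      pain = grp, korff_grade = anth$korff)
    data[[i]] <- if (output == "forces") {
      inverse_cop_to_forces(track, anth$weight,
                            p$board_half_length_cm, p$board_half_width_cm)
    } else track
  }
  cohort <- do.call(rbind.data.frame, subjects)
  class(cohort) <- c("cohort", "data.frame")
  out <- list(subjects = cohort)
  out[[if (output == "forces") "recordings" else "tracks"]] <- data
  out
}

#' Write a generated cohort to a directory
#'
#' Emits `cohort.csv` plus one `rec_<subject_id>.csv` per subject.
#'
#' @param cohort Output of [generate_cohort()] (forces mode).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_dir <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort(cohort$subjects, file.path(dir, "cohort.csv"))
  for (rec in cohort$recordings) {
    write_recording(rec, file.path(dir, paste0("rec_", rec$subject_id, ".csv")))
  }
  invisible(dir)
}
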