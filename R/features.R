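#' CoP track length
#'
#' Total path length of the planar CoP trajectory: the sum over samples
#' of the Euclidean step \eqn{\sqrt{\Delta x^2 + \Delta y^2}}, in cm.
#' Rotation-invariant.
#'
#' @param track A [cop_track()].
#' @return Path length (cm).
#' @export
track_length <- function(track) {
  stopifnot(inherits(track, "cop_track"))
  if (length(track$x_ml_cm) < 2) stop("need at least 2 samples")
  sum(sqrt(diff(track$x_ml_cm)^2 + diff(track$y_ap_cm)^2))
}

# One-sided periodogram of a mean-detrended series: density in unit^2/Hz,
# rectangular window, so sum(density) * df equals the (population)
# variance exactly apart from the Nyquist-bin convention.
periodogram_density <- function(x, rate_hz) {
  n <- length(x)
  x <- x - mean(x)
  X <- stats::fft(x)
  df <- rate_hz / n
  two_sided <- (Mod(X)^2) / (n * rate_hz)   # unit^2/Hz
  half <- floor(n / 2)
  k <- seq_len(half)                        # positive-frequency bins
  dens <- 2 * two_sided[k + 1]
  if (n %% 2 == 0) dens[half] <- two_sided[half + 1]  # Nyquist not doubled
  list(freqs = k * df, density = dens)
}

# Welch estimate: averaged periodograms of Hann-windowed overlapping
# segments, normalized by the window power so densities stay in unit^2/Hz.
welch_density <- function(x, rate_hz, segment_s, overlap) {
  n <- length(x)
  seg <- min(n, max(8, round(segment_s * rate_hz)))
  step <- max(1, round(seg * (1 - overlap)))
  starts <- seq(1, n - seg + 1, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(seg) / (seg + 1)))   # Hann
  u <- mean(w^2)
  df <- rate_hz / seg
  half <- floor(seg / 2)
  acc <- numeric(half)
  for (s in starts) {
    xs <- x[s:(s + seg - 1)]
    xs <- (xs - mean(xs)) * w
    X <- stats::fft(xs)
    two_sided <- (Mod(X)^2) / (seg * rate_hz * u)
    dens <- 2 * two_sided[seq_len(half) + 1]
    if (seg %% 2 == 0) dens[half] <- two_sided[half + 1]
    acc <- acc + dens
  }
  list(freqs = seq_len(half) * df, density = acc / length(starts))
}

#' Power spectral density of a CoP track
#'
#' Computes one-sided PSDs of the mean-detrended ML and AP coordinate
#' series (cm^2/Hz) and their sum, the resultant density, whose band
#' integrals are invariant under rotation of the coordinate axes. The
#' default periodogram (rectangular window) satisfies Parseval exactly:
#' the integral over the full support equals the time-domain variance
#' var(x) + var(y). The Welch option trades that exactness for reduced
#' estimator variance.
#'
#' @param track A [cop_track()].
#' @param config A [sway_config()]; supplies `psd_method` and the Welch
#'   segment parameters.
#' @return An object of class `sway_spectrum` with elements `freqs_hz`,
#'   `density_ml`, `density_ap`, `density` (resultant), `method`.
#' @export
cop_psd <- function(track, config = sway_config()) {
  stopifnot(inherits(track, "cop_track"))
  if (!all(is.finite(track$x_ml_cm)) || !all(is.finite(track$y_ap_cm))) {
    stop("track contains non-finite samples")
  }
  est <- switch(config$psd_method,
    periodogram = function(v) periodogram_density(v, track$rate_hz),
    welch = function(v) welch_density(v, track$rate_hz,
                                      config$welch_segment_s,
                                      config$welch_overlap))
  ml <- est(track$x_ml_cm)
  ap <- est(track$y_ap_cm)
  structure(list(freqs_hz = ml$freqs,
                 density_ml = ml$density,
                 density_ap = ap$density,
                 density = ml$density + ap$density,
                 rate_hz = track$rate_hz,
                 method = config$psd_method,
                 subject_id = track$subject_id),
            class = "sway_spectrum")
}

#' @export
print.sway_spectrum <- function(x, ...) {
  cat(sprintf(
    "CoP spectrum '%s' (%s): %d bins, %.4g to %.4g Hz, total area %.4g cm^2\n",
    x$subject_id, x$method, length(x$freqs_hz), x$freqs_hz[1],
    max(x$freqs_hz), sum(x$density) * diff(x$freqs_hz[1:2])))
  invisible(x)
}

#' @export
plot.sway_spectrum <- function(x, xlim = c(0, 10), ...) {
  graphics::plot(x$freqs_hz, x$density, type = "l", log = "y", xlim = xlim,
                 xlab = "Frequency [Hz]", ylab = "PSD [cm^2/Hz]",
                 main = paste("CoP PSD", x$subject_id), ...)
  invisible(x)
}

#' Integrated band power ("area below the envelope")
#'
#' Integral of a spectral density over `[low_hz, high_hz]` under the
#' bin-measure convention: each spectral bin at frequency f_k owns the
#' interval [f_k - df/2, f_k + df/2] and contributes its density times
#' the overlap of that interval with the band. This makes the full-
#' support integral satisfy Parseval exactly for the periodogram (even
#' when power concentrates in the lowest bin, as drift does) and makes
#' disjoint band areas exactly additive. Edges outside the support are
#' clipped to it with a warning — in particular a nominal 0.001 Hz lower
#' edge on a 60 s trial starts at the first resolvable bin (1/60 Hz).
#'
#' @param spec A `sway_spectrum` from [cop_psd()].
#' @param low_hz,high_hz Band edges, `low_hz < high_hz`.
#' @param axis `"resultant"` (ML + AP densities, default), `"ML"` or `"AP"`.
#' @return Band area (cm^2).
#' @export
band_area <- function(spec, low_hz, high_hz,
                      axis = c("resultant", "ML", "AP")) {
  stopifnot(inherits(spec, "sway_spectrum"), low_hz < high_hz)
  axis <- match.arg(axis)
  dens <- switch(axis, resultant = spec$density, ML = spec$density_ml,
                 AP = spec$density_ap)
  f <- spec$freqs_hz
  df <- f[2] - f[1]
  sup_lo <- f[1] - df / 2
  sup_hi <- f[length(f)] + df / 2
  if (high_hz <= sup_lo || low_hz >= sup_hi) {
    stop(sprintf("band (%g, %g) Hz has no overlap with support [%g, %g] Hz",
                 low_hz, high_hz, sup_lo, sup_hi))
  }
  lo <- low_hz; hi <- high_hz
  if (lo < sup_lo) {
    warning(sprintf("band edge %g Hz below resolution; clipped to %g Hz",
                    lo, sup_lo))
    lo <- sup_lo
  }
  if (hi > sup_hi) {
    warning(sprintf("band edge %g Hz above support; clipped to %g Hz",
                    hi, sup_hi))
    hi <- sup_hi
  }
  overlap <- pmax(0, pmin(hi, f + df / 2) - pmax(lo, f - df / 2))
  sum(dens * overlap)
}

#' Mean of the per-cycle maximum CoP acceleration
#'
#' Acceleration is the resultant magnitude of second-order central
#' differences of the track (cm/s^2). Movement cycles are delimited by
#' successive upward zero crossings of the AP velocity (one full sway
#' oscillation); the statistic is the mean over cycles of each cycle's
#' maximum acceleration.
#'
#' @param track A [cop_track()].
#' @return Mean per-cycle maximum acceleration (cm/s^2).
#' @export
mean_max_accel <- function(track) {
  stopifnot(inherits(track, "cop_track"))
  x <- track$x_ml_cm; y <- track$y_ap_cm
  n <- length(x)
  if (n < 3) stop("need at least 3 samples")
  dt <- 1 / track$rate_hz
  mid <- 2:(n - 1)
  vy <- (y[mid + 1] - y[mid - 1]) / (2 * dt)
  ax <- (x[mid + 1] - 2 * x[mid] + x[mid - 1]) / dt^2
  ay <- (y[mid + 1] - 2 * y[mid] + y[mid - 1]) / dt^2
  acc <- sqrt(ax^2 + ay^2)
  up <- which(vy[-length(vy)] < 0 & vy[-1] >= 0)
  if (length(up) < 2) stop("no complete movement cycle in track")
  mean(vapply(seq_len(length(up) - 1), function(i) {
    max(acc[up[i]:(up[i + 1])])
  }, numeric(1)))
}

#' Sway-track ellipticity
#'
#' Ratio \eqn{\sqrt{\lambda_1/\lambda_2}} of the principal-axis standard
#' deviations of the centered (ML, AP) point cloud; 1 for a circular
#' cloud, larger for elongated (elliptical) tracks. Always >= 1.
#'
#' @param track A [cop_track()].
#' @param max_ratio Cap on the returned ratio; degenerate near-collinear
#'   clouds beyond the cap are an error (`Inf` disables the check).
#' @return Ellipticity (dimensionless, >= 1).
#' @export
ellipticity <- function(track, max_ratio = 1e6) {
  stopifnot(inherits(track, "cop_track"))
  n <- length(track$x_ml_cm)
  if (n < 10) stop("need at least 10 samples")
  if (stats::var(track$x_ml_cm) == 0 || stats::var(track$y_ap_cm) == 0) {
    stop("zero variance on an axis; ellipticity undefined")
  }
  ev <- eigen(stats::cov(cbind(track$x_ml_cm, track$y_ap_cm)),
              symmetric = TRUE, only.values = TRUE)$values
  if (ev[2] <= 0 || sqrt(ev[1] / ev[2]) > max_ratio) {
    stop("degenerate (near-collinear) track; ellipticity diverges")
  }
  sqrt(ev[1] / ev[2])
}

band_col_name <- function(band) {
  paste0("band_", gsub("\\.", "p", band[1]), "_", gsub("\\.", "p", band[2]))
}

#' Extract the per-trial feature vector
#'
#' @param track A filtered [cop_track()].
#' @param config A [sway_config()]; supplies the PSD method and band set.
#' @return A one-row data.frame: `subject_id`, `track_length_cm`, one
#'   `band_<low>_<high>` column per configured band (cm^2),
#'   `mean_max_accel`, `ellipticity`.
#' @export
extract_features <- function(track, config = sway_config()) {
  spec <- cop_psd(track, config)
  areas <- suppressWarnings(
    vapply(config$band_set, function(b) band_area(spec, b[1], b[2]),
           numeric(1)))
  out <- data.frame(subject_id = track$subject_id,
                    track_length_cm = track_length(track),
                    stringsAsFactors = FALSE)
  for (i in seq_along(config$band_set)) {
    out[[band_col_name(config$band_set[[i]])]] <- areas[i]
  }
  out$mean_max_accel <- mean_max_accel(track)
  out$ellipticity <- ellipticity(track)
  out
}

#' Feature table for a list of tracks
#'
#' @param tracks List of [cop_track()] objects.
#' @param config A [sway_config()].
#' @return A data.frame of class `feature_table`, one row per track.
#' @export
feature_table <- function(tracks, config = sway_config()) {
  out <- do.call(rbind, lapply(tracks, extract_features, config = config))
  class(out) <- c("feature_table", "data.frame")
  out
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("Feature table: %d trials x %d features\n",
              nrow(x), ncol(x) - 1))
  NextMethod()
}

#' Names of the numeric feature columns of a feature table
#' @param features A [feature_table()] (or compatible data.frame).
#' @return Character vector of feature column names.
#' @export
feature_columns <- function(features) {
  setdiff(names(features)[vapply(features, is.numeric, logical(1))],
          c("age_years", "height_cm", "weight_kg", "shoe_size_eu",
            "korff_grade"))
}
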