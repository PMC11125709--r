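#' Construct a CoP track
#'
#' A planar center-of-pressure trajectory. `x_ml_cm` is mediolateral
#' (right positive), `y_ap_cm` anteroposterior (anterior positive), origin
#' at the board center.
#'
#' @param x_ml_cm,y_ap_cm Equal-length coordinate series (cm).
#' @param rate_hz Sampling rate (Hz).
#' @param subject_id Subject identifier.
#' @return An object of class `cop_track`.
#' @export
cop_track <- function(x_ml_cm, y_ap_cm, rate_hz, subject_id = "anon") {
  if (length(x_ml_cm) != length(y_ap_cm)) {
    stop("x and y series must have equal length")
  }
  stopifnot(rate_hz > 0)
  structure(list(x_ml_cm = as.numeric(x_ml_cm),
                 y_ap_cm = as.numeric(y_ap_cm),
                 rate_hz = rate_hz, subject_id = subject_id),
            class = "cop_track")
}

#' @export
print.cop_track <- function(x, ...) {
  n <- length(x$x_ml_cm)
  cat(sprintf("CoP track '%s': %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, n, x$rate_hz, n / x$rate_hz))
  cat(sprintf("  ML range [%.3f, %.3f] cm, AP range [%.3f, %.3f] cm\n",
              min(x$x_ml_cm), max(x$x_ml_cm),
              min(x$y_ap_cm), max(x$y_ap_cm)))
  invisible(x)
}

#' @export
plot.cop_track <- function(x, ...) {
  graphics::plot(x$x_ml_cm, x$y_ap_cm, type = "l", asp = 1,
                 xlab = "ML [cm]", ylab = "AP [cm]",
                 main = paste("CoP track", x$subject_id), ...)
  invisible(x)
}

#' Serialize a CoP track to CSV (t, x_cm, y_cm)
#' @param track A [cop_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cop_track <- function(track, path) {
  n <- length(track$x_ml_cm)
  df <- data.frame(t = (seq_len(n) - 1) / track$rate_hz,
                   x_cm = track$x_ml_cm, y_cm = track$y_ap_cm)
  utils::write.csv(format(df, digits = 12, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Zero-phase Butterworth low-pass filter
#'
#' Designs an `order`-th order Butterworth low-pass at `cutoff_hz` and
#' applies it forward-backward (zero phase, no lag), so path-length
#' features are not distorted by filter delay. The quoted -3 dB point at
#' the cutoff refers to the single-pass design response; the two-pass
#' application gives -6 dB there and twice the stopband attenuation.
#'
#' @param series Numeric series.
#' @param rate_hz Sampling rate (Hz).
#' @param cutoff_hz Cutoff frequency, strictly below Nyquist.
#' @param order Filter order (>= 1).
#' @return Filtered series, same length as the input.
#' @export
butterworth_lowpass <- function(series, rate_hz, cutoff_hz, order = 3) {
  stopifnot(order >= 1, rate_hz > 0)
  if (!(cutoff_hz > 0 && cutoff_hz < rate_hz / 2)) {
    stop(sprintf("cutoff %g Hz must lie in (0, Nyquist = %g Hz)",
                 cutoff_hz, rate_hz / 2))
  }
  if (!all(is.finite(series))) stop("series contains non-finite values")
  # filtfilt startup transients are suppressed by filtering about the mean
  mu <- mean(series)
  bf <- signal::butter(order, cutoff_hz / (rate_hz / 2), type = "low")
  as.numeric(signal::filtfilt(bf, series - mu)) + mu
}

#' Single-pass Butterworth magnitude response
#'
#' Analytic magnitude of the digital design used by
#' [butterworth_lowpass()], evaluated via its transfer function.
#'
#' @param freq_hz Frequencies at which to evaluate (Hz).
#' @param rate_hz,cutoff_hz,order As in [butterworth_lowpass()].
#' @return Magnitude response (linear units) at `freq_hz`.
#' @export
butterworth_response <- function(freq_hz, rate_hz, cutoff_hz, order = 3) {
  bf <- signal::butter(order, cutoff_hz / (rate_hz / 2), type = "low")
  w <- 2 * pi * freq_hz / rate_hz
  z <- exp(1i * w)
  num <- vapply(z, function(zi) sum(bf$b * zi^-(seq_along(bf$b) - 1)),
                complex(1))
  den <- vapply(z, function(zi) sum(bf$a * zi^-(seq_along(bf$a) - 1)),
                complex(1))
  Mod(num / den)
}

#' Cohort-wide low-pass cutoff by residual analysis
#'
#' For each recording, the root-mean-square residual between each raw
#' force channel and its filtered version is computed over a grid of
#' candidate cutoffs. Above the signal bandwidth the residual falls on a
#' straight line in the cutoff (pure noise removal); that line is
#' extrapolated back to 0 Hz to estimate the noise floor, and the selected
#' cutoff is the smallest one whose residual drops to the floor. The
#' cohort cutoff is the median over recordings. A fixed
#' `config$filter_cutoff_hz` overrides the analysis entirely.
#'
#' @param recordings List of [force_recording()] objects.
#' @param config A [sway_config()].
#' @param grid Optional cutoff grid (Hz); default 30 points from 0.5 Hz to
#'   `config$max_auto_cutoff_hz`.
#' @return Selected cutoff (Hz).
#' @export
select_cutoff <- function(recordings, config, grid = NULL) {
  if (!length(recordings)) stop("need at least one recording")
  if (!identical(config$filter_cutoff_hz, "auto")) {
    return(config$filter_cutoff_hz)
  }
  if (is.null(grid)) {
    grid <- seq(0.5, config$max_auto_cutoff_hz, length.out = 30)
  }
  per_rec <- vapply(recordings, function(rec) {
    residual_cutoff(rec, grid, config)
  }, numeric(1))
  stats::median(per_rec)
}

residual_cutoff <- function(rec, grid, config) {
  rms <- function(v) sqrt(mean(v^2))
  # residual curve averaged over the four channels
  res <- vapply(grid, function(fc) {
    mean(apply(rec$channels, 2, function(ch) {
      if (stats::sd(ch) == 0) return(0)
      rms(ch - butterworth_lowpass(ch, rec$rate_hz, fc, config$filter_order))
    }))
  }, numeric(1))
  if (all(res == 0)) {
    warning("degenerate (constant) recording; using maximum grid cutoff")
    return(max(grid))
  }
  # linear noise line fitted on the upper half of the grid, extrapolated to 0
  hi <- grid >= stats::median(grid)
  fit <- stats::lm(res[hi] ~ grid[hi])
  floor_rms <- stats::coef(fit)[1]
  # a knee exists only if low cutoffs leave residuals well above the
  # extrapolated noise line; a flat curve is broadband noise end to end
  if (res[1] < 1.2 * floor_rms) {
    warning("no residual knee found (broadband signal); using maximum cutoff")
    return(max(grid))
  }
  ok <- which(res <= floor_rms)
  if (!length(ok)) {
    warning("residual never reaches the noise floor; using maximum cutoff")
    return(max(grid))
  }
  grid[min(ok)]
}

#' Apply the configured low-pass filter to all four force channels
#'
#' @param rec A [force_recording()].
#' @param cutoff_hz Cutoff (Hz).
#' @param config A [sway_config()] (supplies the filter order).
#' @return A filtered [force_recording()].
#' @export
filter_recording <- function(rec, cutoff_hz, config) {
  out <- rec
  out$channels <- apply(rec$channels, 2, butterworth_lowpass,
                        rate_hz = rec$rate_hz, cutoff_hz = cutoff_hz,
                        order = config$filter_order)
  colnames(out$channels) <- colnames(rec$channels)
  out
}

#' Center of pressure from four corner forces
#'
#' For channel order top-left, top-right, bottom-left, bottom-right with
#' total load S = TL+TR+BL+BR:
#' \deqn{x = w \cdot ((TR+BR) - (TL+BL))/S, \quad
#'       y = l \cdot ((TL+TR) - (BL+BR))/S}
#' with `w`, `l` the board half-width and half-length in cm. The top edge
#' is anterior and the right edge is the subject's right.
#'
#' @param rec A [force_recording()] (normally already filtered).
#' @return A [cop_track()].
#' @export
compute_cop <- function(rec) {
  ch <- rec$channels
  s <- ch[, "f_tl"] + ch[, "f_tr"] + ch[, "f_bl"] + ch[, "f_br"]
  bad <- which(s <= 0)
  if (length(bad)) {
    stop(sprintf("non-positive total load at sample %d (unloaded board?)",
                 bad[1]))
  }
  x <- rec$board_half_width_cm *
    ((ch[, "f_tr"] + ch[, "f_br"]) - (ch[, "f_tl"] + ch[, "f_bl"])) / s
  y <- rec$board_half_length_cm *
    ((ch[, "f_tl"] + ch[, "f_tr"]) - (ch[, "f_bl"] + ch[, "f_br"])) / s
  cop_track(x, y, rec$rate_hz, subject_id = rec$subject_id)
}

#' Preprocess one recording: filter forces, then compute the CoP track
#'
#' @param rec A [force_recording()].
#' @param cutoff_hz Low-pass cutoff (Hz); e.g. the output of
#'   [select_cutoff()].
#' @param config A [sway_config()].
#' @return A [cop_track()].
#' @export
preprocess_recording <- function(rec, cutoff_hz, config) {
  compute_cop(filter_recording(rec, cutoff_hz, config))
}
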