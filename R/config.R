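#' Default frequency bands for seated posturography
#'
#' The eight analysis windows over which the CoP power spectral density is
#' integrated: five nested low-frequency windows starting at the lowest
#' resolvable frequency and three windows at and above 1 Hz. Edges in Hz.
#'
#' @return A list of length-2 numeric vectors `c(low_hz, high_hz)`.
#' @export
default_band_set <- function() {
  list(
    c(0.001, 10), c(0.001, 8), c(0.001, 6), c(0.001, 4), c(0.001, 1),
    c(1, 8), c(1, 4), c(4, 8)
  )
}

#' Pipeline configuration
#'
#' Collects every tunable of the analysis pipeline in one validated object.
#'
#' @param sampling_rate_hz Sampling rate of the force channels (Hz).
#' @param trial_duration_s Trial length (s).
#' @param filter_order Butterworth low-pass order.
#' @param filter_cutoff_hz Low-pass cutoff (Hz), or `"auto"` to select a
#'   cohort-wide cutoff by residual analysis (see [select_cutoff()]).
#' @param psd_method `"periodogram"` (rectangular window, Parseval-exact) or
#'   `"welch"` (averaged Hann-windowed segments).
#' @param welch_segment_s,welch_overlap Welch segment length (s) and
#'   fractional overlap; ignored for the periodogram.
#' @param band_set List of `c(low_hz, high_hz)` integration windows.
#' @param split_fraction Training fraction for the classifier benchmark.
#' @param n_repeats Number of repeated train/test splits.
#' @param rng_seed Master seed; per-stage seeds are derived from it.
#' @param board_half_length_cm,board_half_width_cm Board half-dimensions
#'   (cm), anterior-posterior and mediolateral. Defaults are the nominal
#'   Wii-board footprint (51 x 31 cm plate).
#' @param korff_threshold Minimum Korff chronic-pain grade classified as
#'   `LowBackPain` when deriving the binary label.
#' @param max_auto_cutoff_hz Upper bound of the cutoff search grid (Hz).
#'
#' @return An object of class `sway_config` (a named list).
#' @export
sway_config <- function(sampling_rate_hz = 1000,
                        trial_duration_s = 60,
                        filter_order = 3,
                        filter_cutoff_hz = "auto",
                        psd_method = c("periodogram", "welch"),
                        welch_segment_s = 20,
                        welch_overlap = 0.5,
                        band_set = default_band_set(),
                        split_fraction = 0.7,
                        n_repeats = 10,
                        rng_seed = 1L,
                        board_half_length_cm = 25.5,
                        board_half_width_cm = 15.5,
                        korff_threshold = 1L,
                        max_auto_cutoff_hz = 20) {
  psd_method <- match.arg(psd_method)
  stopifnot(
    is.numeric(sampling_rate_hz), sampling_rate_hz > 0,
    is.numeric(trial_duration_s), trial_duration_s > 0,
    filter_order >= 1, filter_order == round(filter_order),
    split_fraction > 0, split_fraction < 1,
    n_repeats >= 1, n_repeats == round(n_repeats),
    board_half_length_cm > 0, board_half_width_cm > 0
  )
  if (!identical(filter_cutoff_hz, "auto")) {
    stopifnot(is.numeric(filter_cutoff_hz), filter_cutoff_hz > 0,
              filter_cutoff_hz < sampling_rate_hz / 2)
  }
  if (!length(band_set)) stop("band_set must contain at least one band")
  for (b in band_set) {
    if (length(b) != 2 || !is.numeric(b)) {
      stop("each band must be a numeric c(low_hz, high_hz) pair")
    }
    if (!(b[1] > 0 && b[1] < b[2] && b[2] <= sampling_rate_hz / 2)) {
      stop(sprintf("invalid band (%g, %g): need 0 < low < high <= Nyquist",
                   b[1], b[2]))
    }
  }
  structure(list(
    sampling_rate_hz = sampling_rate_hz,
    trial_duration_s = trial_duration_s,
    filter_order = as.integer(filter_order),
    filter_cutoff_hz = filter_cutoff_hz,
    psd_method = psd_method,
    welch_segment_s = welch_segment_s,
    welch_overlap = welch_overlap,
    band_set = band_set,
    split_fraction = split_fraction,
    n_repeats = as.integer(n_repeats),
    rng_seed = as.integer(rng_seed),
    board_half_length_cm = board_half_length_cm,
    board_half_width_cm = board_half_width_cm,
    korff_threshold = as.integer(korff_threshold),
    max_auto_cutoff_hz = max_auto_cutoff_hz
  ), class = "sway_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys take [sway_config()] defaults.
#' Bands may be given as a list of two-element lists.
#'
#' @param path Path to a YAML file.
#' @return A `sway_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(sway_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(raw$band_set)) {
    raw$band_set <- lapply(raw$band_set, function(b) as.numeric(unlist(b)))
  }
  do.call(sway_config, raw)
}

#' @export
print.sway_config <- function(x, ...) {
  cat("Seated-posturography pipeline configuration\n")
  cat(sprintf("  sampling: %g Hz x %g s; Butterworth order %d, cutoff %s\n",
              x$sampling_rate_hz, x$trial_duration_s, x$filter_order,
              if (identical(x$filter_cutoff_hz, "auto")) "auto"
              else sprintf("%g Hz", x$filter_cutoff_hz)))
  cat(sprintf("  PSD: %s; %d bands; benchmark: %d x %g/%g split, seed %d\n",
              x$psd_method, length(x$band_set), x$n_repeats,
              x$split_fraction, 1 - x$split_fraction, x$rng_seed))
  invisible(x)
}

# Deterministic per-stage seed derivation from the master seed, so stages
# (and subjects) draw from independent streams and adding subjects does not
# perturb earlier signals. Kept strictly below 2^31.
derive_seed <- function(master, stage, index = 0L) {
  stage_code <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(master) * 7919 + stage_code * 104729 +
                as.double(index) * 15485863) %% 2147483587)
}
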