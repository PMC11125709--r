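#' Construct a raw force recording
#'
#' One trial's four load-cell force channels, in newtons, channel order
#' top-left, top-right, bottom-left, bottom-right as seen from above with
#' the anterior edge at the top.
#'
#' @param f_tl,f_tr,f_bl,f_br Numeric force series (N), equal length.
#' @param rate_hz Sampling rate (Hz).
#' @param board_half_length_cm,board_half_width_cm Board half-dimensions (cm).
#' @param subject_id Subject identifier.
#' @return An object of class `force_recording`.
#' @export
force_recording <- function(f_tl, f_tr, f_bl, f_br, rate_hz,
                            board_half_length_cm = 25.5,
                            board_half_width_cm = 15.5,
                            subject_id = "anon") {
  n <- length(f_tl)
  if (!all(lengths(list(f_tr, f_bl, f_br)) == n)) {
    stop("all four force channels must have equal length")
  }
  stopifnot(rate_hz > 0, n >= 1)
  structure(list(
    channels = cbind(f_tl = as.numeric(f_tl), f_tr = as.numeric(f_tr),
                     f_bl = as.numeric(f_bl), f_br = as.numeric(f_br)),
    rate_hz = rate_hz,
    board_half_length_cm = board_half_length_cm,
    board_half_width_cm = board_half_width_cm,
    subject_id = subject_id
  ), class = "force_recording")
}

#' @export
print.force_recording <- function(x, ...) {
  n <- nrow(x$channels)
  cat(sprintf(
    "Force recording '%s': %d samples @ %g Hz (%.1f s), board %g x %g cm\n",
    x$subject_id, n, x$rate_hz, n / x$rate_hz,
    2 * x$board_half_width_cm, 2 * x$board_half_length_cm))
  invisible(x)
}

#' Read a raw recording from CSV
#'
#' Expects a header row and columns `f_tl, f_tr, f_bl, f_br` (newtons); an
#' optional leading `time_s` column is ignored for reconstruction (the rate
#' comes from `config`). If the file holds more samples than
#' `trial_duration_s` implies, it is truncated with a warning; a shortfall
#' beyond 1% is an error.
#'
#' @param path CSV file path.
#' @param config A [sway_config()].
#' @param subject_id Identifier to attach; defaults to the file stem.
#' @param max_na_gap Longest tolerated run of NA samples per channel
#'   (linearly interpolated); longer gaps are a data error.
#' @return A [force_recording()].
#' @export
read_recording <- function(path, config, subject_id = NULL, max_na_gap = 10) {
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("f_tl", "f_tr", "f_bl", "f_br")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("recording format error: missing columns ",
         paste(missing_cols, collapse = ", "))
  }
  n_expect <- round(config$sampling_rate_hz * config$trial_duration_s)
  if (nrow(df) > n_expect) {
    warning(sprintf(
      "recording has %d rows but config implies %d; truncating",
      nrow(df), n_expect))
    df <- df[seq_len(n_expect), , drop = FALSE]
  } else if (nrow(df) < 0.99 * n_expect) {
    stop(sprintf("recording too short: %d rows, expected %d",
                 nrow(df), n_expect))
  }
  ch <- lapply(df[need], function(v) fill_na_runs(as.numeric(v), max_na_gap))
  force_recording(ch$f_tl, ch$f_tr, ch$f_bl, ch$f_br,
                  rate_hz = config$sampling_rate_hz,
                  board_half_length_cm = config$board_half_length_cm,
                  board_half_width_cm = config$board_half_width_cm,
                  subject_id = subject_id)
}

# Linear interpolation over NA runs no longer than max_gap; longer runs or
# NAs at the series ends are a data error.
fill_na_runs <- function(v, max_gap) {
  if (!anyNA(v)) return(v)
  r <- rle(is.na(v))
  if (any(r$values & r$lengths > max_gap)) {
    stop(sprintf("data error: NA gap longer than %d samples", max_gap))
  }
  if (is.na(v[1]) || is.na(v[length(v)])) {
    stop("data error: NA at series boundary")
  }
  idx <- seq_along(v)
  v[is.na(v)] <- stats::approx(idx[!is.na(v)], v[!is.na(v)],
                               xout = idx[is.na(v)])$y
  v
}

#' Write a recording to CSV
#'
#' Emits `time_s, f_tl, f_tr, f_bl, f_br` with enough digits that a
#' read-back reproduces the forces to formatting precision.
#'
#' @param rec A [force_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  n <- nrow(rec$channels)
  df <- data.frame(time_s = (seq_len(n) - 1) / rec$rate_hz, rec$channels)
  utils::write.csv(format(df, digits = 12, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a subject record
#'
#' @param subject_id Unique identifier.
#' @param sex `"M"` or `"F"`.
#' @param age_years,height_cm,weight_kg,shoe_size_eu Anthropometry.
#' @param pain `"LowBackPain"` or `"Healthy"`; derived from `korff_grade`
#'   when omitted.
#' @param korff_grade Optional Korff chronic-pain grade, integer 0..4.
#' @param korff_threshold Grade at or above which the subject is labelled
#'   `LowBackPain`.
#' @param protocol_ok `FALSE` marks a stage-1 protocol exclusion (could not
#'   hold the seated position for the full trial, excessive movement).
#' @return An object of class `subject_record` (a one-row data.frame).
#' @export
subject_record <- function(subject_id, sex, age_years, height_cm, weight_kg,
                           shoe_size_eu, pain = NULL, korff_grade = NA,
                           korff_threshold = 1L, protocol_ok = TRUE) {
  sex <- as.character(sex)
  if (!sex %in% c("M", "F")) stop("sex must be 'M' or 'F', got: ", sex)
  if (!is.na(korff_grade) && !(korff_grade %in% 0:4)) {
    stop("korff_grade must be an integer in 0..4")
  }
  if (is.null(pain) || is.na(pain)) {
    if (is.na(korff_grade)) stop("need either pain label or korff_grade")
    pain <- if (korff_grade >= korff_threshold) "LowBackPain" else "Healthy"
  }
  pain <- as.character(pain)
  if (!pain %in% c("LowBackPain", "Healthy")) {
    stop("pain must be 'LowBackPain' or 'Healthy', got: ", pain)
  }
  out <- data.frame(
    subject_id = as.character(subject_id), sex = sex,
    age_years = as.numeric(age_years), height_cm = as.numeric(height_cm),
    weight_kg = as.numeric(weight_kg),
    shoe_size_eu = as.numeric(shoe_size_eu),
    pain = pain, korff_grade = as.integer(korff_grade),
    protocol_ok = isTRUE(protocol_ok),
    stringsAsFactors = FALSE
  )
  class(out) <- c("subject_record", class(out))
  out
}

#' Read a cohort table from CSV
#'
#' One row per subject; required columns `subject_id, sex, age_years,
#' height_cm, weight_kg, shoe_size_eu` plus at least one of `pain`,
#' `korff_grade`. Duplicate subject ids and unknown sex/pain tokens are
#' rejected.
#'
#' @param path CSV file path.
#' @param korff_threshold Korff grade dichotomization threshold.
#' @return A data.frame of validated subject records (class `cohort`).
#' @export
read_cohort <- function(path, korff_threshold = 1L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "sex", "age_years", "height_cm", "weight_kg",
            "shoe_size_eu")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("cohort format error: missing columns ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(df$subject_id)) {
    stop("duplicate subject_id: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]),
               collapse = ", "))
  }
  if (is.null(df$pain)) df$pain <- NA_character_
  if (is.null(df$korff_grade)) df$korff_grade <- NA_integer_
  if (is.null(df$protocol_ok)) df$protocol_ok <- TRUE
  recs <- lapply(seq_len(nrow(df)), function(i) {
    subject_record(df$subject_id[i], df$sex[i], df$age_years[i],
                   df$height_cm[i], df$weight_kg[i], df$shoe_size_eu[i],
                   pain = df$pain[i], korff_grade = df$korff_grade[i],
                   korff_threshold = korff_threshold,
                   protocol_ok = df$protocol_ok[i])
  })
  out <- do.call(rbind.data.frame, recs)
  class(out) <- c("cohort", "data.frame")
  out
}

#' Write a cohort table to CSV
#' @param cohort A cohort data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
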