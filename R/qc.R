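#' Exclusion report
#'
#' Record of one staged quality-control pass.
#'
#' @param stage `"protocol"`, `"implausible"` or `"iqr_distance"`.
#' @param excluded_ids Identifiers (or indices) removed at this stage.
#' @param rule_params Named list of the rule's parameters.
#' @param n_before,n_after Counts before and after the stage.
#' @return An object of class `exclusion_report`.
#' @export
exclusion_report <- function(stage, excluded_ids, rule_params,
                             n_before, n_after) {
  stage <- match.arg(stage, c("protocol", "implausible", "iqr_distance"))
  stopifnot(n_after == n_before - length(excluded_ids))
  structure(list(stage = stage, excluded_ids = excluded_ids,
                 rule_params = rule_params,
                 n_before = n_before, n_after = n_after),
            class = "exclusion_report")
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf("QC stage '%s': %d -> %d (excluded %d)\n",
              x$stage, x$n_before, x$n_after, length(x$excluded_ids)))
  if (length(x$excluded_ids)) {
    cat("  excluded:", paste(x$excluded_ids, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Remove trials with implausible feature values
#'
#' Any trial with any feature value strictly greater than `threshold`
#' (default 10^6) is declared implausible and removed; a value exactly at
#' the threshold is kept.
#'
#' @param features A feature table (data.frame with `subject_id`).
#' @param threshold Implausibility threshold.
#' @param cols Columns checked; default all numeric feature columns.
#' @return `list(kept = <feature table>, report = <exclusion_report>)`.
#' @export
filter_implausible <- function(features, threshold = 1e6, cols = NULL) {
  if (is.null(cols)) cols <- feature_columns(features)
  bad <- rep(FALSE, nrow(features))
  for (cl in cols) bad <- bad | features[[cl]] > threshold
  report <- exclusion_report(
    "implausible", features$subject_id[bad],
    list(threshold = threshold), nrow(features), sum(!bad))
  list(kept = features[!bad, , drop = FALSE], report = report)
}

#' Interquartile-distance outlier fence
#'
#' With Q1 and Q3 the sample quartiles (type-7, R's default linear
#' interpolation) and IQR = Q3 - Q1, a value is kept iff it lies within
#' `k * IQR` of the central interval:
#' \deqn{Q_1 - k\,IQR \le x \le Q_3 + k\,IQR.}
#' The default `k = 0.9` keeps everything within 90% of the IQR of the
#' middle-50% interval. When IQR = 0 the fence collapses to the common
#' central value and only values away from it are excluded.
#'
#' @param values Numeric vector (>= 4 values).
#' @param k Fence width as a multiple of the IQR.
#' @param ids Optional identifiers reported for excluded entries;
#'   defaults to indices.
#' @param fence Optional previously fitted fence (`c(lo, hi)`), applied
#'   as-is instead of re-estimating the quartiles — reapplying a fitted
#'   fence is idempotent, whereas re-estimation on the kept subset
#'   shrinks the quartiles and can exclude further values.
#' @return `list(kept = <indices kept>, fence = c(lo, hi),
#'   report = <exclusion_report>)`.
#' @export
filter_iqr_distance <- function(values, k = 0.9, ids = NULL, fence = NULL) {
  if (length(values) < 4) stop("need at least 4 values for quartile fences")
  if (is.null(ids)) ids <- seq_along(values)
  if (is.null(fence)) {
    q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    fence <- c(q[1] - k * iqr, q[2] + k * iqr)
    params <- list(k = k, q1 = q[1], q3 = q[2], iqr = iqr,
                   quantile_type = 7, fence = fence)
  } else {
    params <- list(k = k, fence = fence, refit = FALSE)
  }
  keep <- values >= fence[1] & values <= fence[2]
  report <- exclusion_report(
    "iqr_distance", ids[!keep], params, length(values), sum(keep))
  list(kept = which(keep), fence = fence, report = report)
}

#' Staged quality control on a cohort's feature table
#'
#' Applies, in fixed order: (1) protocol exclusions (subjects flagged
#' `protocol_ok = FALSE`, e.g. unable to hold the seated position for the
#' full trial); (2) the implausible-value rule (> 10^6); (3) the
#' IQR-distance fence per feature column — a trial is dropped if any of
#' its analysis-relevant features falls outside the fence.
#'
#' @param features A feature table.
#' @param subjects Optional cohort data.frame carrying `protocol_ok`.
#' @param threshold Implausibility threshold.
#' @param k IQR fence multiple.
#' @param iqr_cols Columns the IQR rule screens; default all feature
#'   columns.
#' @return `list(kept, reports)` where `reports` is a list of
#'   [exclusion_report()] objects in stage order.
#' @export
apply_qc <- function(features, subjects = NULL, threshold = 1e6, k = 0.9,
                     iqr_cols = NULL) {
  reports <- list()
  # stage 1: protocol
  if (!is.null(subjects) && "protocol_ok" %in% names(subjects)) {
    bad_ids <- subjects$subject_id[!subjects$protocol_ok]
    drop <- features$subject_id %in% bad_ids
    reports$protocol <- exclusion_report(
      "protocol", features$subject_id[drop], list(),
      nrow(features), sum(!drop))
    features <- features[!drop, , drop = FALSE]
  }
  # stage 2: implausible values
  st2 <- filter_implausible(features, threshold)
  reports$implausible <- st2$report
  features <- st2$kept
  # stage 3: IQR fence, per feature column; drop trial on any exclusion
  if (is.null(iqr_cols)) iqr_cols <- feature_columns(features)
  if (nrow(features) >= 4) {
    drop <- rep(FALSE, nrow(features))
    for (cl in iqr_cols) {
      res <- filter_iqr_distance(features[[cl]], k,
                                 ids = features$subject_id)
      drop[!seq_len(nrow(features)) %in% res$kept] <- TRUE
    }
    reports$iqr_distance <- exclusion_report(
      "iqr_distance", features$subject_id[drop], list(k = k),
      nrow(features), sum(!drop))
    features <- features[!drop, , drop = FALSE]
  }
  list(kept = features, reports = reports)
}

#' Write exclusion reports to JSON
#' @param reports List of [exclusion_report()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_exclusion_reports <- function(reports, path) {
  jsonlite::write_json(
    lapply(reports, function(r) {
      list(stage = r$stage, excluded_ids = as.character(r$excluded_ids),
           rule_params = r$rule_params,
           n_before = r$n_before, n_after = r$n_after)
    }), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
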