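#' Two-group comparison of one feature
#'
#' Group means, their difference (No-Pain minus Pain, matching the sign
#' convention of the published summary tables) and a two-sided t-test
#' p-value. Welch's unequal-variance test is the default; the pooled
#' Student variant is available.
#'
#' @param features Data.frame with the feature column and a `pain` column
#'   (values `"Healthy"` / `"LowBackPain"`), or any binary label passed
#'   via `label`.
#' @param feature_name Name of the feature column.
#' @param label Optional explicit label vector; `"Healthy"` is the
#'   no-pain level.
#' @param test `"welch"` (default) or `"student"`.
#' @return An object of class `group_comparison`.
#' @export
compare_groups <- function(features, feature_name, label = NULL,
                           test = c("welch", "student")) {
  test <- match.arg(test)
  if (is.null(label)) label <- features$pain
  if (!feature_name %in% names(features)) {
    stop("no such feature column: ", feature_name)
  }
  v <- features[[feature_name]]
  no_pain <- v[label == "Healthy"]
  pain <- v[label == "LowBackPain"]
  if (length(no_pain) < 2 || length(pain) < 2) {
    stop("each group needs at least 2 observations")
  }
  if (stats::sd(no_pain) == 0 && stats::sd(pain) == 0 &&
        mean(no_pain) == mean(pain)) {
    p <- 1  # identical degenerate groups: no evidence of difference
  } else {
    p <- stats::t.test(no_pain, pain, var.equal = (test == "student"))$p.value
  }
  structure(list(feature_name = feature_name,
                 mean_no_pain = mean(no_pain), mean_pain = mean(pain),
                 difference = mean(no_pain) - mean(pain),
                 p_value = p,
                 test = if (test == "welch") "welch_t" else "student_t",
                 n_no_pain = length(no_pain), n_pain = length(pain)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: no-pain %.6g vs pain %.6g, difference %.6g, p = %.4g (%s)\n",
              x$feature_name, x$mean_no_pain, x$mean_pain, x$difference,
              x$p_value, x$test))
  invisible(x)
}

#' Per-feature group comparison table
#'
#' Runs [compare_groups()] over a set of feature columns and assembles a
#' summary table (columns No Pain / Pain / Difference / p-value).
#'
#' @param features Feature table with a `pain` column.
#' @param cols Feature columns; default all numeric feature columns.
#' @param test t-test variant, see [compare_groups()].
#' @return A data.frame, one row per feature.
#' @export
compare_all_features <- function(features, cols = NULL,
                                 test = c("welch", "student")) {
  test <- match.arg(test)
  if (is.null(cols)) cols <- feature_columns(features)
  rows <- lapply(cols, function(cl) {
    g <- compare_groups(features, cl, test = test)
    data.frame(feature = cl, mean_no_pain = g$mean_no_pain,
               mean_pain = g$mean_pain, difference = g$difference,
               p_value = g$p_value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Factorial ANOVA with effect sizes and post-hoc power
#'
#' Fits a linear model for `response` against the supplied term list
#' (main effects and interactions up to fourth order), decomposes the
#' sums of squares (Type II by default, which is order-invariant for
#' unbalanced data; Type I available), and augments each term with
#' \deqn{\eta^2 = SS_{term}/SS_{total}, \quad
#'   \omega^2 = (SS_{term} - df_{term} MS_{err})/(SS_{total} + MS_{err})}
#' and the post-hoc power at level `alpha`: the probability that a
#' noncentral F with noncentrality \eqn{\lambda = F \cdot df_{term}}
#' exceeds the central critical value.
#'
#' Age is deliberately not part of the default term set: the pain group
#' of the study cohort is older than the healthy group, and including age
#' would let group status be proxied by it.
#'
#' @param features Data.frame holding the response and term columns.
#' @param response Response column name.
#' @param terms Character vector of model terms (interactions as
#'   `"a:b"`); defaults to sex, weight, height, pain and their
#'   interactions up to fourth order.
#' @param ss_type 2 (default) or 1.
#' @param alpha Significance level for the power computation.
#' @return A data.frame of class `anova_effects`: term, df, statistic
#'   (F), p_value, etasq, omegasq, power; the residual row carries only
#'   df and SS-derived columns.
#' @export
anova_effects <- function(features, response, terms = NULL, ss_type = 2,
                          alpha = 0.05) {
  if (is.null(terms)) {
    base <- c("sex", "weight_kg", "height_cm", "pain")
    terms <- c(base, utils::combn(base, 2, paste, collapse = ":"),
               utils::combn(base, 3, paste, collapse = ":"),
               paste(base, collapse = ":"))
  }
  fml <- stats::as.formula(paste(response, "~", paste(terms, collapse = " + ")))
  fit <- stats::lm(fml, data = features)
  if (any(is.na(stats::coef(fit)))) {
    stop("rank-deficient design; aliased coefficients: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  }
  tab <- if (ss_type == 2) {
    as.data.frame(car::Anova(fit, type = 2))
  } else {
    as.data.frame(stats::anova(fit))
  }
  names(tab)[names(tab) == "Sum Sq"] <- "ss"
  names(tab)[names(tab) == "Df"] <- "df"
  names(tab)[names(tab) == "F value"] <- "statistic"
  names(tab)[names(tab) == "Pr(>F)"] <- "p_value"
  res_row <- rownames(tab) == "Residuals"
  ms_err <- tab$ss[res_row] / tab$df[res_row]
  df_err <- tab$df[res_row]
  ss_total <- sum(tab$ss)
  out <- data.frame(term = rownames(tab), df = tab$df,
                    statistic = tab$statistic, p_value = tab$p_value,
                    etasq = tab$ss / ss_total,
                    omegasq = (tab$ss - tab$df * ms_err) / (ss_total + ms_err),
                    stringsAsFactors = FALSE)
  out$power <- ifelse(
    res_row, NA_real_,
    stats::pf(stats::qf(1 - alpha, out$df, df_err), out$df, df_err,
              ncp = out$statistic * out$df, lower.tail = FALSE))
  out$etasq[res_row] <- NA_real_
  out$omegasq[res_row] <- NA_real_
  rownames(out) <- NULL
  class(out) <- c("anova_effects", "data.frame")
  attr(out, "ss_type") <- ss_type
  attr(out, "df_error") <- df_err
  out
}

#' @export
print.anova_effects <- function(x, digits = 3, ...) {
  cat(sprintf("Factorial ANOVA (Type %s SS)\n", attr(x, "ss_type")))
  print.data.frame(format(as.data.frame(x), digits = digits), row.names = FALSE)
  invisible(x)
}

#' Stratified mean (SD) summary
#'
#' Per-cell mean, sample SD (n-1 denominator) and n of one value column
#' over the cross-classification of the given strata. Empty cells are
#' reported with n = 0 and missing mean; singleton cells have missing SD.
#'
#' @param features Data.frame.
#' @param value Value column name.
#' @param strata Character vector of stratifying column names.
#' @return A data.frame with the strata columns plus `mean`, `sd`, `n`.
#' @export
stratified_summary <- function(features, value, strata) {
  missing_cols <- setdiff(c(value, strata), names(features))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  fac <- lapply(features[strata], factor)
  cells <- expand.grid(lapply(fac, levels), stringsAsFactors = FALSE)
  names(cells) <- strata
  key <- interaction(fac, drop = FALSE)
  cell_key <- interaction(lapply(cells, factor), drop = FALSE)
  stats_by <- function(f) {
    vapply(levels(key), function(lv) {
      f(features[[value]][key == lv])
    }, numeric(1))
  }
  m <- stats_by(function(v) if (length(v)) mean(v) else NA_real_)
  s <- stats_by(function(v) if (length(v) >= 2) stats::sd(v) else NA_real_)
  n <- stats_by(length)
  idx <- match(as.character(cell_key), levels(key))
  out <- cbind(cells, mean = m[idx], sd = s[idx], n = as.integer(n[idx]))
  rownames(out) <- NULL
  out
}

#' Age-band factor used in the stratified summaries
#' @param age_years Numeric ages.
#' @return Factor with levels `20-29`, `30-39`, `40-49`, `>50` (ages
#'   below 20 fold into the first band).
#' @export
age_band <- function(age_years) {
  cut(age_years, breaks = c(-Inf, 29, 39, 49, Inf),
      labels = c("20-29", "30-39", "40-49", ">50"))
}
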