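#' Min-max feature normalization fitted on the training set
#'
#' Scales every column of `train` to [0, 1] by its own min and max, and
#' applies the same affine map to `test` (values outside the training
#' range are preserved outside [0, 1]; no clipping). Constant training
#' columns are mapped to 0 with a warning.
#'
#' @param train,test Numeric data.frames with identical columns.
#' @param params Optional previously fitted parameters (list with `min`,
#'   `range`), overriding the fit.
#' @return `list(train, test, params)`.
#' @export
normalize_features <- function(train, test = NULL, params = NULL) {
  if (is.null(params)) {
    mins <- vapply(train, min, numeric(1))
    rngs <- vapply(train, function(v) max(v) - min(v), numeric(1))
    if (any(rngs == 0)) {
      warning("constant training column(s) mapped to 0: ",
              paste(names(train)[rngs == 0], collapse = ", "))
    }
    params <- list(min = mins, range = rngs)
  }
  scale_df <- function(df) {
    for (j in seq_along(df)) {
      df[[j]] <- if (params$range[j] == 0) rep(0, nrow(df))
                 else (df[[j]] - params$min[j]) / params$range[j]
    }
    df
  }
  list(train = scale_df(train),
       test = if (!is.null(test)) scale_df(test),
       params = params)
}

#' Train one of the four benchmark classifiers
#'
#' Hyperparameters follow the corresponding R packages' defaults: SVM
#' with RBF kernel and cost 1 (e1071), CART with default cost-complexity
#' pruning (rpart), random forest with 500 trees and sqrt(p) candidate
#' features per split (randomForest), and a single-hidden-layer network
#' with logistic activation (nnet).
#'
#' @param kind `"svm"`, `"tree"`, `"random_forest"` or `"nn"`.
#' @param train Numeric data.frame of predictors (normalized).
#' @param labels Factor (or coercible) of binary class labels.
#' @param params Named list of overrides: `cost`, `ntree`, `nn_size`,
#'   `nn_decay`, `nn_maxit`, `rf_ntree`.
#' @return An object of class `sway_classifier` wrapping the fit.
#' @export
train_model <- function(kind, train, labels, params = list()) {
  if (!kind %in% c("svm", "tree", "random_forest", "nn")) {
    stop("unknown classifier kind: ", kind)
  }
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("need exactly two classes")
  df <- cbind(train, .label = labels)
  fit <- switch(kind,
    svm = e1071::svm(.label ~ ., data = df, kernel = "radial",
                     cost = params$cost %||% 1),
    tree = rpart::rpart(.label ~ ., data = df, method = "class"),
    random_forest = randomForest::randomForest(
      .label ~ ., data = df, ntree = params$rf_ntree %||% 500),
    nn = nnet::nnet(.label ~ ., data = df,
                    size = params$nn_size %||% 3,
                    decay = params$nn_decay %||% 1e-4,
                    maxit = params$nn_maxit %||% 500, trace = FALSE))
  structure(list(kind = kind, fit = fit, levels = levels(labels)),
            class = "sway_classifier")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
predict.sway_classifier <- function(object, newdata, ...) {
  out <- switch(object$kind,
    svm = as.character(stats::predict(object$fit, newdata)),
    tree = as.character(stats::predict(object$fit, newdata, type = "class")),
    random_forest = as.character(stats::predict(object$fit, newdata)),
    nn = {
      p <- as.numeric(stats::predict(object$fit, newdata))
      object$levels[1 + (p > 0.5)]
    })
  factor(out, levels = object$levels)
}

#' Repeated-split benchmark of the four classifiers
#'
#' For each of `config$n_repeats` runs the data are split at random into
#' training and evaluation sets (`config$split_fraction` training); the
#' same partition is used for all four models within a run, min-max
#' normalization is fitted on the training part only, and accuracy is the
#' percentage of correct class assignments on the evaluation set. Splits
#' missing a class on either side are redrawn with a warning. Results are
#' summarized as mean and SD over runs, per model.
#'
#' @param features Numeric data.frame of predictors (one row per trial).
#' @param labels Binary labels (`"Healthy"` / `"LowBackPain"` or any two
#'   levels).
#' @param config A [sway_config()] (split fraction, repeats, seed).
#' @param models Classifier kinds to run.
#' @param stratified Stratify splits by class (off by default; the study
#'   protocol splits purely at random).
#' @param params Hyperparameter overrides for [train_model()].
#' @return An object of class `benchmark_report`.
#' @export
run_benchmark <- function(features, labels, config = sway_config(),
                          models = c("svm", "tree", "random_forest", "nn"),
                          stratified = FALSE, params = list()) {
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("need exactly two classes")
  if (min(table(labels)) < 2) stop("need at least 2 samples per class")
  n <- nrow(features)
  n_train <- round(config$split_fraction * n)
  if (n_train < 2 || n_train > n - 2) stop("split leaves too few samples")
  runs <- lapply(seq_len(config$n_repeats), function(r) {
    seed_r <- derive_seed(config$rng_seed, "split", r)
    idx <- with_seed(seed_r, draw_split(labels, n_train, stratified))
    tr_x <- features[idx, , drop = FALSE]
    te_x <- features[-idx, , drop = FALSE]
    nm <- suppressWarnings(normalize_features(tr_x, te_x))
    acc <- vapply(models, function(kind) {
      m <- with_seed(derive_seed(seed_r, kind),
                     train_model(kind, nm$train, labels[idx], params))
      100 * mean(predict(m, nm$test) == labels[-idx])
    }, numeric(1))
    list(train_idx = idx, accuracy = acc,
         split_hash = paste(sort(idx), collapse = ","))
  })
  acc_mat <- t(vapply(runs, `[[`, numeric(length(models)), "accuracy"))
  colnames(acc_mat) <- models
  per_model <- lapply(models, function(m) {
    list(mean_accuracy_pct = mean(acc_mat[, m]),
         sd_pct = stats::sd(acc_mat[, m]),
         runs = as.numeric(acc_mat[, m]))
  })
  names(per_model) <- models
  structure(list(per_model = per_model, accuracy = acc_mat,
                 n_repeats = config$n_repeats,
                 split_fraction = config$split_fraction,
                 seed = config$rng_seed,
                 split_hashes = vapply(runs, `[[`, character(1),
                                       "split_hash")),
            class = "benchmark_report")
}

# Random (optionally class-stratified) training index draw; redraws until
# both classes appear on both sides of the split.
draw_split <- function(labels, n_train, stratified, max_tries = 100) {
  n <- length(labels)
  for (i in seq_len(max_tries)) {
    idx <- if (stratified) {
      unlist(lapply(levels(labels), function(lv) {
        pool <- which(labels == lv)
        sample(pool, round(length(pool) * n_train / n))
      }))
    } else {
      sample.int(n, n_train)
    }
    if (nlevels(droplevels(labels[idx])) == 2 &&
          nlevels(droplevels(labels[-idx])) == 2) {
      if (i > 1) warning("redrew split missing a class")
      return(sort(idx))
    }
  }
  stop("could not draw a split containing both classes on both sides")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("Classifier benchmark: %d repeats, %g/%g split, seed %d\n",
              x$n_repeats, x$split_fraction, 1 - x$split_fraction, x$seed))
  cat(sprintf("  %-14s %-10s %s\n", "Type", "Result [%]", "SD"))
  for (m in names(x$per_model)) {
    cat(sprintf("  %-14s %-10.2f +/-%.2f\n", m,
                x$per_model[[m]]$mean_accuracy_pct, x$per_model[[m]]$sd_pct))
  }
  invisible(x)
}

#' Write a benchmark report to JSON
#' @param report A [run_benchmark()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_benchmark_report <- function(report, path) {
  jsonlite::write_json(
    list(n_repeats = report$n_repeats,
         split_fraction = report$split_fraction,
         seed = report$seed, per_model = report$per_model),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
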