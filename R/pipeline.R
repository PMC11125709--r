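#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> preprocess -> features -> quality
#' control -> group statistics -> classifier benchmark under a single
#' configuration and master seed, writing every report to `out_dir`:
#' `features.csv`, `exclusions.json`, `group_comparisons.csv`,
#' `stratified_age.csv`, `stratified_height_sex.csv`, `anova_track.csv`,
#' `anova_band.csv`, `benchmark.json`, `benchmark.csv` and
#' `manifest.json`. Identical config + seed give identical outputs.
#'
#' @param config A [sway_config()].
#' @param out_dir Output directory (created if needed); `NULL` writes
#'   nothing and just returns the results.
#' @param cohort_dir Directory of an existing cohort
#'   (see [write_cohort_dir()]); `NULL` simulates one.
#' @param n_per_group Group size when simulating.
#' @param spec Optional [cohort_spec()] overriding the default generator
#'   settings (its seed is replaced by the config seed).
#' @param benchmark_features Feature columns fed to the classifiers;
#'   default the track length and the two most group-discriminating
#'   low-frequency band areas.
#' @return A list of class `sway_run`: subjects, cutoff_hz, features
#'   (post-QC), qc reports, comparisons, stratified summaries, ANOVA
#'   tables, benchmark report and the run manifest.
#' @export
run_pipeline <- function(config = sway_config(), out_dir = NULL,
                         cohort_dir = NULL, n_per_group = 30, spec = NULL,
                         benchmark_features = c("track_length_cm",
                                                "band_0p001_10",
                                                "band_0p001_4")) {
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    t0 <<- proc.time()[["elapsed"]]
  }

  if (is.null(cohort_dir)) {
    if (is.null(spec)) spec <- cohort_spec(n_per_group = n_per_group)
    spec$rng_seed <- config$rng_seed
    sim <- generate_cohort(spec, duration_s = config$trial_duration_s,
                           rate_hz = config$sampling_rate_hz)
    subjects <- sim$subjects
    recordings <- sim$recordings
  } else {
    subjects <- read_cohort(file.path(cohort_dir, "cohort.csv"),
                            korff_threshold = config$korff_threshold)
    recordings <- lapply(subjects$subject_id, function(id) {
      read_recording(file.path(cohort_dir, paste0("rec_", id, ".csv")),
                     config, subject_id = id)
    })
  }
  tick("simulate_or_load")

  cutoff <- select_cutoff(recordings, config)
  tracks <- lapply(recordings, preprocess_recording, cutoff_hz = cutoff,
                   config = config)
  tick("preprocess")

  feats <- feature_table(tracks, config)
  feats <- merge(feats, subjects, by = "subject_id", sort = FALSE)
  class(feats) <- c("feature_table", "data.frame")
  tick("features")

  qc <- apply_qc(feats, subjects)
  kept <- qc$kept
  tick("qc")

  comparisons <- compare_all_features(kept)
  kept$age_group <- age_band(kept$age_years)
  strat_age <- stratified_summary(kept, "band_0p001_10",
                                  c("age_group", "pain"))
  kept$height_band <- 10 * floor(kept$height_cm / 10)
  strat_height <- stratified_summary(kept, "track_length_cm",
                                     c("height_band", "sex"))
  anova_track <- anova_with_fallback(kept, "track_length_cm")
  anova_band <- anova_with_fallback(kept, "band_0p001_10")
  tick("stats")

  bench <- run_benchmark(kept[, benchmark_features, drop = FALSE],
                         kept$pain, config)
  tick("benchmark")

  manifest <- list(
    package_version = as.character(utils::packageVersion("seatsway")),
    seed = config$rng_seed,
    config = unclass(config),
    cutoff_hz = cutoff,
    n_subjects = nrow(subjects),
    n_retained = nrow(kept),
    stage_timings_s = as.list(timings)
  )

  out <- structure(list(subjects = subjects, cutoff_hz = cutoff,
                        features = kept, qc = qc$reports,
                        comparisons = comparisons,
                        stratified_age = strat_age,
                        stratified_height_sex = strat_height,
                        anova_track = anova_track,
                        anova_band = anova_band,
                        benchmark = bench, manifest = manifest),
                   class = "sway_run")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    w <- function(df, f) utils::write.csv(df, file.path(out_dir, f),
                                          row.names = FALSE)
    w(as.data.frame(kept), "features.csv")
    write_exclusion_reports(qc$reports, file.path(out_dir, "exclusions.json"))
    w(comparisons, "group_comparisons.csv")
    w(strat_age, "stratified_age.csv")
    w(strat_height, "stratified_height_sex.csv")
    w(as.data.frame(anova_track), "anova_track.csv")
    w(as.data.frame(anova_band), "anova_band.csv")
    write_benchmark_report(bench, file.path(out_dir, "benchmark.json"))
    bench_df <- data.frame(
      type = names(bench$per_model),
      result_pct = vapply(bench$per_model, `[[`, numeric(1),
                          "mean_accuracy_pct"),
      sd = vapply(bench$per_model, `[[`, numeric(1), "sd_pct"))
    w(bench_df, "benchmark.csv")
    manifest$outputs <- list.files(out_dir)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out$manifest <- manifest
  }
  out
}

# The four-way factorial needs enough retained subjects to estimate all
# interaction cells; small demonstration runs fall back to lower-order
# term sets rather than aborting.
anova_with_fallback <- function(df, response) {
  base <- c("sex", "weight_kg", "height_cm", "pain")
  sets <- list(
    c(base, utils::combn(base, 2, paste, collapse = ":"),
      utils::combn(base, 3, paste, collapse = ":"),
      paste(base, collapse = ":")),
    c(base, utils::combn(base, 2, paste, collapse = ":")),
    base,
    "pain")  # tiny cohorts can confound pain with anthropometry
  for (terms in sets) {
    out <- tryCatch(anova_effects(df, response, terms = terms),
                    error = function(e) NULL)
    if (!is.null(out)) return(out)
  }
  stop("ANOVA rank-deficient even for main effects; cohort too small")
}

#' @export
print.sway_run <- function(x, ...) {
  cat("Seated-posturography pipeline run\n")
  cat(sprintf("  %d subjects, %d retained after QC; cutoff %.2f Hz\n",
              nrow(x$subjects), nrow(x$features), x$cutoff_hz))
  cat("\nGroup comparisons (no-pain vs pain):\n")
  print(format(x$comparisons, digits = 4), row.names = FALSE)
  cat("\n")
  print(x$benchmark)
  invisible(x)
}

#' @export
summary.sway_run <- function(object, ...) {
  print(object)
  cat("\nANOVA, 0.001-10 Hz band area:\n")
  print(object$anova_band)
  invisible(object)
}
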