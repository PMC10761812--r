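#' Analysis configuration
#'
#' All tunable thresholds of the pipeline in one list. Defaults encode the
#' protocol constants (strict 12-h wear rule, at most 2 missed task
#' sessions and 1 missed query, 30-min report delay, 75% diary fill within
#' 2 h) and the package's own numerical guards (non-wear gap thresholds of
#' three windows, 1 h of worn windows for a defined daily score, 50%
#' minimum slot coverage, 10% minimum phase-cell coverage, 6-h cap on the
#' post-last-dose interval).
#'
#' @param alpha two-sided significance level (0.05; no multiple-testing
#'   correction by default — set `bonferroni_m > 1` to divide alpha).
#' @param gap_threshold_s non-wear gap threshold for the 30-s channels.
#' @param gap_threshold_activity_s same for the 5-s activity channel.
#' @param wear_threshold_h daily wear rule, strict `>` (hours).
#' @param required_sessions,max_missed_tasks motor-task completion rule.
#' @param max_missed_queries allowed unanswered queries.
#' @param max_report_delay_min allowed median reporting delay.
#' @param max_skip_fraction allowed fraction of skipped doses.
#' @param diary_max_delay_h,diary_min_fill diary completeness rule.
#' @param min_bins_per_day worn 30-s windows needed for a daily score.
#' @param min_slot_coverage worn fraction needed to use a diary slot.
#' @param max_final_h cap on the final inter-dose interval (hours).
#' @param n_phase_bins bins per inter-dose interval.
#' @param min_cell_coverage worn fraction needed for a phase cell.
#' @param var_equal use pooled-variance t-tests instead of Welch.
#' @param paired_cohort paired group-level diary test (default) vs
#'   unpaired.
#' @param bonferroni_m Bonferroni divisor applied to alpha (1 = none).
#' @param thresholds a [profile_thresholds()] object.
#' @return list of class `hbm_config`.
#' @export
hbm_config <- function(alpha = 0.05, gap_threshold_s = 90L,
                       gap_threshold_activity_s = 15L, wear_threshold_h = 12,
                       required_sessions = 28L, max_missed_tasks = 2L,
                       max_missed_queries = 1L, max_report_delay_min = 30,
                       max_skip_fraction = 0.1, diary_max_delay_h = 2,
                       diary_min_fill = 0.75, min_bins_per_day = 120L,
                       min_slot_coverage = 0.5, max_final_h = 6,
                       n_phase_bins = 10L, min_cell_coverage = 0.1,
                       var_equal = FALSE, paired_cohort = TRUE,
                       bonferroni_m = 1L,
                       thresholds = profile_thresholds()) {
  cfg <- as.list(environment())
  assert_that(cfg$alpha > 0 && cfg$alpha < 1, "alpha must be in (0,1)")
  assert_that(cfg$bonferroni_m >= 1, "bonferroni_m must be >= 1")
  cfg$alpha <- cfg$alpha / cfg$bonferroni_m
  class(cfg) <- "hbm_config"
  cfg
}

#' Load an analysis configuration from YAML
#'
#' Top-level keys map to [hbm_config()] arguments; a `thresholds` block
#' maps to [profile_thresholds()]. Unknown keys are an error.
#'
#' @param path YAML file.
#' @return an `hbm_config`.
#' @export
hbm_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path) %||% list()
  th <- y$thresholds
  y$thresholds <- NULL
  known <- names(formals(hbm_config))
  bad <- setdiff(names(y), known)
  assert_that(length(bad) == 0, "config: unknown key(s): %s",
              paste(bad, collapse = ", "))
  if (!is.null(th)) {
    badt <- setdiff(names(th), names(formals(profile_thresholds)))
    assert_that(length(badt) == 0, "config: unknown threshold key(s): %s",
                paste(badt, collapse = ", "))
    y$thresholds <- do.call(profile_thresholds, th)
  }
  do.call(hbm_config, y)
}

#' Run the full analysis pipeline for one patient
#'
#' Chains every stage on one dataset: compliance report, daily and overall
#' free-living scores, diary-slot alignment and per-patient ON/OFF tests,
#' motor-task summaries and ON/OFF tests, the medication-cycle phase
#' signature, the classifier features and the fluctuation-profile label.
#'
#' @param dataset a [patient_dataset()].
#' @param config an [hbm_config()].
#' @return object of class `hbm_analysis`.
#' @export
hbm_analyze <- function(dataset, config = hbm_config()) {
  assert_that(inherits(dataset, "patient_dataset"),
              "dataset must be a patient_dataset")
  daily <- daily_scores(dataset, config)
  slots <- slot_measures(dataset, config)
  diary_tests <- lapply(c(tremor = "tremor", dyskinesia = "dyskinesia",
                          activity = "activity"), function(ch)
    per_patient_on_off(slots, ch, alpha = config$alpha,
                       var_equal = config$var_equal))
  combos <- list(c("FINGER_TAPPING", "valid_taps"),
                 c("FINGER_TAPPING", "mean_intertap_s"),
                 c("TUG", "tug_time_s"),
                 c("REST", "tremor_score"),
                 c("POSTURAL", "tremor_score"),
                 c("PRONATION_SUPINATION", "bradykinesia_score"))
  task_summ <- do.call(rbind, lapply(combos, function(cm) {
    s <- tryCatch(overall_state_scores(dataset$tasks, cm[1], cm[2]),
                  error = function(e) NULL)
    if (!is.null(s)) s$metric <- cm[2]
    s
  }))
  task_tests <- lapply(combos, function(cm)
    on_off_task_test(dataset$tasks, cm[1], cm[2], alpha = config$alpha))
  names(task_tests) <- vapply(combos, function(cm)
    paste(cm[1], cm[2], sep = "."), character(1))
  features <- fluctuation_features(dataset, config)
  out <- list(
    patient_id = dataset$patient_id,
    config = config,
    compliance = compliance_report(dataset, config),
    daily = daily,
    overall = overall_scores(daily),
    slots = slots,
    diary_tests = diary_tests,
    task_summaries = task_summ,
    task_tests = task_tests,
    signature = phase_signature(dataset, config),
    features = features,
    profile = classify_profile(features, config$thresholds),
    dataset = dataset)
  class(out) <- "hbm_analysis"
  out
}

#' @export
print.hbm_analysis <- function(x, ...) {
  cat(sprintf("<hbm_analysis %s>\n", x$patient_id))
  cat(sprintf("  profile        : %s\n", x$profile$label))
  f <- x$features
  cat(sprintf("  features       : P = %.2f  PMI = %.2f  TDI = %.2f  C = %.2f\n",
              f$P, f$PMI, f$TDI, f$C))
  cat(sprintf("  overall tremor : %.3f   dyskinesia: %.3f   activity: %.3f\n",
              x$overall$overall_tremor, x$overall$overall_dyskinesia,
              x$overall$overall_activity))
  tt <- x$diary_tests$tremor
  if (!tt$undefined)
    cat(sprintf("  diary tremor   : higher in %s (p = %.3g)\n",
                tt$direction, tt$p_value))
  cat(sprintf("  wear > 12 h    : %.0f%% of days\n",
              100 * x$compliance$pct_days_wear_over_12h))
  invisible(x)
}

#' @export
summary.hbm_analysis <- function(object, ...) {
  x <- object
  print(x)
  cat("\nDaily scores (first days):\n")
  print(utils::head(x$daily, 5))
  cat("\nMotor-task summaries:\n")
  print(x$task_summaries)
  cat("\nDiary ON/OFF tests:\n")
  for (ch in names(x$diary_tests)) {
    cat(sprintf("  %-10s ", ch)); print(x$diary_tests[[ch]])
  }
  invisible(x)
}

#' @export
plot.hbm_analysis <- function(x, which = c("raster", "phase"), ...) {
  which <- match.arg(which)
  if (which == "raster") plot_raster(x$dataset, config = x$config, ...)
  else plot_phase_bars(x$signature, ...)
}

#' Run the pipeline over a cohort
#'
#' @param datasets named list of [patient_dataset()] objects.
#' @param config an [hbm_config()].
#' @return object of class `hbm_cohort_analysis`: per-patient
#'   `hbm_analysis` objects plus the cohort diary ON/OFF table, the
#'   cohort motor-task table and the classification table.
#' @export
hbm_analyze_cohort <- function(datasets, config = hbm_config()) {
  analyses <- lapply(datasets, hbm_analyze, config = config)
  slot_list <- lapply(analyses, `[[`, "slots")
  task_list <- lapply(datasets, `[[`, "tasks")
  profiles <- do.call(rbind, lapply(analyses, function(a) {
    f <- a$features
    data.frame(patient_id = a$patient_id, label = a$profile$label,
               P = f$P, PMI = f$PMI, TDI = f$TDI, C = f$C,
               archetype = a$dataset$meta$archetype %||% NA_character_)
  }))
  rownames(profiles) <- NULL
  out <- list(analyses = analyses,
              diary_summary = cohort_on_off_summary(
                slot_list, alpha = config$alpha,
                paired = config$paired_cohort),
              task_summary = cohort_task_summary(task_list,
                                                 alpha = config$alpha),
              profiles = profiles,
              config = config)
  class(out) <- "hbm_cohort_analysis"
  out
}

#' @export
print.hbm_cohort_analysis <- function(x, ...) {
  cat(sprintf("<hbm_cohort_analysis> %d patient(s)\n", length(x$analyses)))
  cat("\nProfile labels:\n")
  print(table(x$profiles$label))
  cat("\nDiary ON/OFF summary:\n")
  print(x$diary_summary)
  cat("\nMotor-task summary:\n")
  print(x$task_summary[, c("task_type", "metric", "mean_on", "mean_off",
                           "pct_better_in_on")])
  invisible(x)
}

#' Write the analysis output files
#'
#' Emits the tabular interfaces of the pipeline into a directory:
#' `daily_scores.csv`, `overall_scores.csv`, `slot_measures.csv`,
#' `diary_onoff.json`, `task_summaries.csv`, `task_onoff.json`,
#' `signature.csv` (long format), `profiles.csv` and per-patient
#' `compliance_<id>.json`.
#'
#' @param cohort an [hbm_analyze_cohort()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_analysis <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) utils::write.csv(df, file.path(dir, name),
                                            row.names = FALSE)
  daily <- do.call(rbind, lapply(cohort$analyses, function(a)
    cbind(patient_id = a$patient_id, a$daily)))
  wr(daily, "daily_scores.csv")
  overall <- do.call(rbind, lapply(cohort$analyses, function(a)
    data.frame(patient_id = a$patient_id,
               overall_tremor = a$overall$overall_tremor,
               overall_dyskinesia = a$overall$overall_dyskinesia,
               overall_activity = a$overall$overall_activity)))
  wr(overall, "overall_scores.csv")
  slots <- do.call(rbind, lapply(cohort$analyses, function(a) {
    s <- a$slots
    if (nrow(s) == 0) return(NULL)
    cbind(patient_id = a$patient_id,
          data.frame(slot_start = hbm_time_format(s$slot_start),
                     s[, setdiff(names(s), "slot_start")]))
  }))
  if (!is.null(slots)) wr(slots, "slot_measures.csv")
  jsonlite::write_json(cohort$diary_summary,
                       file.path(dir, "diary_onoff.json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  ts <- do.call(rbind, lapply(cohort$analyses, function(a)
    if (!is.null(a$task_summaries))
      cbind(patient_id = a$patient_id, a$task_summaries)))
  if (!is.null(ts)) wr(ts, "task_summaries.csv")
  jsonlite::write_json(cohort$task_summary, file.path(dir, "task_onoff.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  sig_long <- do.call(rbind, lapply(cohort$analyses, function(a) {
    s <- a$signature
    if (is.null(s$tremor)) return(NULL)
    K <- nrow(s$tremor); nb <- ncol(s$tremor)
    data.frame(patient_id = a$patient_id,
               interval = rep(seq_len(K), nb),
               bin = rep(seq_len(nb), each = K),
               tremor = as.vector(s$tremor),
               activity = as.vector(s$activity),
               coverage = as.vector(s$coverage),
               days_used = s$days_used)
  }))
  if (!is.null(sig_long)) wr(sig_long, "signature.csv")
  wr(cohort$profiles, "profiles.csv")
  for (a in cohort$analyses) {
    cr <- a$compliance
    jsonlite::write_json(
      list(patient_id = cr$patient_id,
           pct_days_wear_over_12h = cr$pct_days_wear_over_12h,
           median_report_delay_min = cr$median_report_delay_min,
           missed_motor_tasks = cr$missed_motor_tasks,
           missed_daily_queries = cr$missed_daily_queries,
           doses_scheduled = cr$doses_scheduled,
           doses_skipped = cr$doses_skipped,
           diary_complete = cr$diary_complete,
           flags = cr$flags),
      file.path(dir, sprintf("compliance_%s.json", cr$patient_id)),
      auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
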