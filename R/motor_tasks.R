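# direction of improvement per metric: TRUE = higher is better
.METRIC_BETTER_HIGH <- c(valid_taps = TRUE, mean_intertap_s = FALSE,
                         tug_time_s = FALSE, tremor_score = FALSE,
                         bradykinesia_score = FALSE)

.check_task_metric <- function(task_type, metric) {
  assert_that(task_type %in% .TASK_TYPES, "unknown task_type %s", task_type)
  assert_that(metric %in% .TASK_METRICS[[task_type]],
              "metric %s is not defined for task %s", metric, task_type)
}

.task_values <- function(tasks, task_type, metric, state) {
  v <- tasks[[metric]][tasks$task_type == task_type &
                         tasks$reported_state == state]
  v[!is.na(v)]
}

#' Overall ON and OFF scores for a motor task
#'
#' The overall state score is the mean (with SD) of the metric over all
#' sessions the patient performed in that self-reported state.
#'
#' @param tasks a [motor_tasks()] table.
#' @param task_type one of the five task types.
#' @param metric the metric field to summarise (must belong to the task
#'   type, e.g. `valid_taps` for `FINGER_TAPPING`).
#' @return data.frame with one row per state present: `task_type`,
#'   `state`, `mean`, `sd` (0 for a single session), `n`.
#' @export
overall_state_scores <- function(tasks, task_type, metric) {
  .check_task_metric(task_type, metric)
  rows <- lapply(c("OFF", "ON"), function(st) {
    v <- .task_values(tasks, task_type, metric, st)
    if (length(v) == 0) return(NULL)
    data.frame(task_type = task_type, state = st, mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else 0,
               n = length(v))
  })
  out <- do.call(rbind, rows)
  assert_that(!is.null(out), "no records for task %s", task_type)
  rownames(out) <- NULL
  out
}

#' ON vs OFF test for a motor-task metric
#'
#' Welch t-test of the metric in ON vs OFF sessions, with a
#' `better_in_on` flag using the metric's direction of improvement
#' (more valid taps is better; shorter inter-tap time, TUG time and lower
#' tremor/bradykinesia scores are better).
#'
#' @inheritParams overall_state_scores
#' @param alpha significance level.
#' @return a [swa_stats] result with fields `better_in_on`, `mean_on`,
#'   `mean_off`, `metric`, `task_type`.
#' @export
on_off_task_test <- function(tasks, task_type, metric, alpha = 0.05) {
  .check_task_metric(task_type, metric)
  on <- .task_values(tasks, task_type, metric, "ON")
  off <- .task_values(tasks, task_type, metric, "OFF")
  res <- welch_test(on, off, alpha = alpha)
  res$mean_on <- if (length(on)) mean(on) else NA_real_
  res$mean_off <- if (length(off)) mean(off) else NA_real_
  res$metric <- metric; res$task_type <- task_type
  res$better_in_on <- if (is.na(res$mean_on) || is.na(res$mean_off))
    NA else if (.METRIC_BETTER_HIGH[[metric]])
      res$mean_on > res$mean_off else res$mean_on < res$mean_off
  res
}

#' Session-level variability flags
#'
#' A session is flagged as part of the patient's variability signature
#' when its score differs from the patient's task mean by strictly more
#' than one within-patient SD. A zero SD yields no flags.
#'
#' @inheritParams overall_state_scores
#' @return logical vector, one flag per session with a defined metric
#'   value (ordered as in `tasks`).
#' @export
variability_flags <- function(tasks, task_type, metric) {
  .check_task_metric(task_type, metric)
  v <- tasks[[metric]][tasks$task_type == task_type]
  v <- v[!is.na(v)]
  assert_that(length(v) >= 3, "need >= 3 sessions, got %d", length(v))
  s <- stats::sd(v)
  if (s == 0) return(rep(FALSE, length(v)))
  abs(v - mean(v)) > s
}

#' Combined tremor-task score per session
#'
#' Sum of the rest and postural tremor scores of each (day, state)
#' session, computed when both tasks were performed; each component is
#' also analysable separately.
#'
#' @param tasks a [motor_tasks()] table.
#' @return data.frame with `date`, `state`, `combined_score`.
#' @export
combined_tremor_scores <- function(tasks) {
  sel <- tasks$task_type %in% c("POSTURAL", "REST")
  t2 <- tasks[sel, , drop = FALSE]
  if (nrow(t2) == 0)
    return(data.frame(date = as.Date(character(0)), state = character(0),
                      combined_score = numeric(0)))
  key <- paste(hbm_date(t2$session_time), t2$reported_state)
  rows <- lapply(split(t2, key), function(g) {
    rest <- g$tremor_score[g$task_type == "REST"]
    post <- g$tremor_score[g$task_type == "POSTURAL"]
    if (length(rest) == 0 || length(post) == 0) return(NULL)
    data.frame(date = hbm_date(g$session_time[1]),
               state = g$reported_state[1],
               combined_score = mean(rest) + mean(post))
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  out <- out[order(out$date, out$state), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map a 0-4 clinician rating onto the 0-2 smartwatch scale
#'
#' Ratings of 2 and above collapse to 2 so clinician and smartwatch
#' scores are comparable: 0 -> 0, 1 -> 1, 2,3,4 -> 2. Idempotent and
#' monotone.
#'
#' @param raw integer vector in \[0,4\].
#' @return integer vector in \[0,2\].
#' @export
clamp_clinician <- function(raw) {
  raw <- as.integer(raw)
  assert_that(all(raw >= 0L & raw <= 4L, na.rm = TRUE),
              "clinician score outside [0,4]")
  pmin(raw, 2L)
}

#' Correlate smartwatch scores with (clamped) clinician ratings
#'
#' Spearman correlation of paired in-clinic task scores, after mapping
#' the clinician's 0-4 ratings to the 0-2 scale.
#'
#' @param swa_scores numeric smartwatch scores in \[0,2\].
#' @param clinician_raw integer clinician ratings in \[0,4\].
#' @param alpha significance level.
#' @return a [swa_stats] result (UNDEFINED for n < 3 or constant input).
#' @export
validate_against_clinician <- function(swa_scores, clinician_raw,
                                       alpha = 0.05) {
  spearman_rho(swa_scores, as.numeric(clamp_clinician(clinician_raw)),
               alpha = alpha)
}

#' Whether a patient "shows tremor" in a task
#'
#' Default rule: any session with a positive score; `"mean_positive"`
#' requires the patient's mean score to be positive.
#'
#' @param tasks a [motor_tasks()] table.
#' @param task_type `"REST"` or `"POSTURAL"`.
#' @param rule `"any_positive"` (default) or `"mean_positive"`.
#' @return logical.
#' @export
shows_tremor <- function(tasks, task_type = c("REST", "POSTURAL"),
                         rule = c("any_positive", "mean_positive")) {
  task_type <- match.arg(task_type); rule <- match.arg(rule)
  v <- tasks$tremor_score[tasks$task_type == task_type]
  v <- v[!is.na(v)]
  if (length(v) == 0) return(NA)
  if (rule == "any_positive") any(v > 0) else mean(v) > 0
}

#' Cohort-level motor-task summary
#'
#' For each (task, metric): pooled ON and OFF session means and SDs across
#' all patients, the percent of patients whose own ON/OFF comparison was
#' in the "better in ON" direction, and the percent with a significant
#' per-patient test. Percentages are over patients with defined tests.
#'
#' @param task_list named list of [motor_tasks()] tables (one per
#'   patient).
#' @param alpha significance level.
#' @return data.frame, one row per (task_type, metric).
#' @export
cohort_task_summary <- function(task_list, alpha = 0.05) {
  combos <- list(c("FINGER_TAPPING", "valid_taps"),
                 c("FINGER_TAPPING", "mean_intertap_s"),
                 c("TUG", "tug_time_s"),
                 c("REST", "tremor_score"),
                 c("POSTURAL", "tremor_score"),
                 c("PRONATION_SUPINATION", "bradykinesia_score"))
  out <- lapply(combos, function(cm) {
    tk <- cm[1]; m <- cm[2]
    on_all <- unlist(lapply(task_list, .task_values, tk, m, "ON"))
    off_all <- unlist(lapply(task_list, .task_values, tk, m, "OFF"))
    per <- lapply(task_list, function(t)
      tryCatch(on_off_task_test(t, tk, m, alpha), error = function(e) NULL))
    per <- Filter(function(r) !is.null(r) && !r$undefined, per)
    data.frame(
      task_type = tk, metric = m,
      mean_on = mean(on_all), sd_on = stats::sd(on_all),
      mean_off = mean(off_all), sd_off = stats::sd(off_all),
      pct_better_in_on = if (length(per))
        100 * mean(vapply(per, `[[`, logical(1), "better_in_on")) else NA_real_,
      pct_significant = if (length(per))
        100 * mean(vapply(per, `[[`, logical(1), "significant")) else NA_real_,
      n_defined = length(per))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
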