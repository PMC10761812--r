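#' Per-day wear compliance
#'
#' Protocol target: wear the watch for more than 12 hours per day (strict
#' inequality — a 12.0-hour day does not comply).
#'
#' @param mask a [infer_wear_mask()] result.
#' @param threshold_h daily threshold in hours (default 12).
#' @return data.frame with `date`, `hours`, `compliant`.
#' @export
wear_compliance <- function(mask, threshold_h = 12) {
  by_day <- worn_seconds_by_day(mask)
  data.frame(date = by_day$date, hours = by_day$seconds / 3600,
             compliant = by_day$seconds / 3600 > threshold_h)
}

#' Motor-task completion
#'
#' A session is one (calendar day, reported state) pair: the protocol asks
#' for 14 daily ON sessions and 14 OFF sessions (28 in total); duplicate
#' same-state sessions on a day count once. Compliance allows at most
#' `max_missed` missed sessions. With `per_task_type = TRUE` a session is
#' counted per (day, state, task type) instead and `required_sessions`
#' should be scaled accordingly.
#'
#' @param tasks a [motor_tasks()] table.
#' @param required_sessions required session count (default 28).
#' @param max_missed allowed misses (default 2, inclusive).
#' @param per_task_type count each task type separately.
#' @return list with `completed`, `missed`, `compliant`.
#' @export
task_completion <- function(tasks, required_sessions = 28L, max_missed = 2L,
                            per_task_type = FALSE) {
  key <- if (per_task_type)
    paste(hbm_date(tasks$session_time), tasks$reported_state, tasks$task_type)
  else paste(hbm_date(tasks$session_time), tasks$reported_state)
  completed <- length(unique(key))
  missed <- required_sessions - completed
  if (missed < 0) {
    warning(sprintf("more sessions completed (%d) than required (%d); clamping",
                    completed, required_sessions), call. = FALSE)
    missed <- 0L
  }
  list(completed = completed, missed = as.integer(missed),
       compliant = missed <= max_missed)
}

#' Medication-intake adherence
#'
#' Skipped doses are scheduled slots with no reported intake; for reported
#' doses the delay is reported minus scheduled time in minutes (negative
#' for early intakes).
#'
#' @param log a [medication_log()].
#' @return list with `scheduled`, `reported`, `skipped`, `delays_min`
#'   (one entry per reported dose).
#' @export
medication_adherence <- function(log) {
  skipped <- sum(is.na(log$reported_time))
  rep_ok <- !is.na(log$reported_time)
  delays <- mins_between(log$scheduled_time[rep_ok], log$reported_time[rep_ok])
  list(scheduled = nrow(log), reported = sum(rep_ok),
       skipped = as.integer(skipped), delays_min = delays)
}

#' Diary-day completeness
#'
#' A diary day is complete when at least `min_fill` of its 24 half-hour
#' slots were filled within `max_delay_h` hours of the slot start (a
#' report at exactly the deadline still counts).
#'
#' @param entries [diary_entries()] for a single day.
#' @param max_delay_h maximum reporting delay in hours (default 2).
#' @param min_fill required filled fraction (default 0.75, inclusive).
#' @return list with `filled_on_time`, `required` (24), `fraction`,
#'   `complete`.
#' @export
diary_completeness <- function(entries, max_delay_h = 2, min_fill = 0.75) {
  assert_that(length(unique(hbm_date(entries$slot_start))) <= 1,
              "diary_completeness expects entries from a single day")
  required <- 24L
  ok <- entries$state != "MISSING" & !is.na(entries$reported_at) &
    mins_between(entries$slot_start, entries$reported_at) <= max_delay_h * 60
  filled <- sum(ok)
  list(filled_on_time = as.integer(filled), required = required,
       fraction = filled / required,
       complete = filled / required >= min_fill)
}

#' Report delay for prompted queries
#'
#' @param query_time,answered_at POSIXct vectors; answering before the
#'   prompt is a validation error.
#' @return delays in minutes.
#' @export
report_delay <- function(query_time, answered_at) {
  query_time <- hbm_time(query_time); answered_at <- hbm_time(answered_at)
  d <- mins_between(query_time, answered_at)
  assert_that(all(d >= 0, na.rm = TRUE), "answered_at precedes query_time")
  d
}

#' Full protocol-compliance report for one patient
#'
#' Bundles the four adherence measures: (1) daily wear hours against the
#' strict >12 h rule, (2) reporting delay (median of the diary-slot
#' reporting delays, against the 30-min rule; unanswered slots count as
#' missed queries, at most 1 allowed), (3) motor-task completion (at most
#' 2 missed of 28 sessions), and (4) medication intake (skipped doses and
#' the intake-delay distribution; the flag allows up to 10% skipped).
#'
#' @param dataset a [patient_dataset()].
#' @param config an [hbm_config()] list (thresholds).
#' @return list of class `compliance_report`.
#' @export
compliance_report <- function(dataset, config = hbm_config()) {
  mask <- infer_wear_mask(dataset$tremor, config$gap_threshold_s)
  wear <- wear_compliance(mask, config$wear_threshold_h)
  tasks <- task_completion(dataset$tasks,
                           required_sessions = config$required_sessions,
                           max_missed = config$max_missed_tasks)
  med <- medication_adherence(dataset$medications)
  answered <- dataset$diary$state != "MISSING" & !is.na(dataset$diary$reported_at)
  delays <- if (any(answered))
    report_delay(dataset$diary$slot_start[answered],
                 dataset$diary$reported_at[answered]) else numeric(0)
  missed_queries <- sum(!answered)
  diary_by_day <- split(dataset$diary,
                        as.character(hbm_date(dataset$diary$slot_start)))
  diary_complete <- vapply(diary_by_day, function(e)
    diary_completeness(e, config$diary_max_delay_h,
                       config$diary_min_fill)$complete, logical(1))
  med_delay <- if (length(delays)) stats::median(delays) else NA_real_
  out <- list(
    patient_id = dataset$patient_id,
    wear = wear,
    pct_days_wear_over_12h = mean(wear$compliant),
    median_report_delay_min = med_delay,
    missed_motor_tasks = tasks$missed,
    missed_daily_queries = as.integer(missed_queries),
    doses_scheduled = med$scheduled,
    doses_skipped = med$skipped,
    intake_delays_min = med$delays_min,
    diary_complete = diary_complete,
    flags = list(
      wear = stats::median(wear$hours) > config$wear_threshold_h,
      report_delay = !is.na(med_delay) &&
        med_delay <= config$max_report_delay_min,
      tasks = tasks$compliant,
      queries = missed_queries <= config$max_missed_queries,
      medication = med$skipped <= config$max_skip_fraction * med$scheduled
    )
  )
  class(out) <- "compliance_report"
  out
}

#' @export
print.compliance_report <- function(x, ...) {
  cat(sprintf("<compliance_report %s>\n", x$patient_id))
  cat(sprintf("  days > 12 h wear : %.0f%% (median %.1f h)\n",
              100 * x$pct_days_wear_over_12h, stats::median(x$wear$hours)))
  cat(sprintf("  missed tasks     : %d\n", x$missed_motor_tasks))
  cat(sprintf("  missed queries   : %d\n", x$missed_daily_queries))
  cat(sprintf("  doses skipped    : %d of %d (median delay %.0f min)\n",
              x$doses_skipped, x$doses_scheduled,
              stats::median(x$intake_delays_min)))
  cat(sprintf("  diary complete   : %s\n",
              paste(x$diary_complete, collapse = ", ")))
  flg <- unlist(x$flags)
  cat(sprintf("  flags            : %s\n",
              paste(names(flg)[flg], collapse = " ")))
  invisible(x)
}
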