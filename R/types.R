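#' @title Domain containers for home-based-monitoring data
#' @description
#' A `patient_dataset` bundles everything the smartwatch platform exports
#' for one participant over the two-week home-monitoring period:
#' free-living symptom streams (binary tremor / dyskinesia detections, one
#' per 30-s window), the activity stream (one score in \[0,1\] per 5-s
#' window), the medication log (scheduled slots and reported intakes), the
#' two-day 30-min symptom diary, the daily ON/OFF motor-task records and
#' optional in-clinic clinician ratings. All tables are plain data frames;
#' the constructor validates the schema invariants and orders rows by time.
#' @name patient_dataset
NULL

.CHANNELS    <- c("TREMOR", "DYSKINESIA")
.DIARY_STATES <- c("ON", "ON_DYSK", "OFF", "ASLEEP", "MISSING")
.TASK_TYPES  <- c("POSTURAL", "REST", "PRONATION_SUPINATION", "FINGER_TAPPING", "TUG")
.TASK_STATES <- c("ON", "OFF")

# metric fields that must be non-NA for each task type (all others NA)
.TASK_METRICS <- list(
  POSTURAL             = "tremor_score",
  REST                 = "tremor_score",
  PRONATION_SUPINATION = "bradykinesia_score",
  FINGER_TAPPING       = c("valid_taps", "mean_intertap_s"),
  TUG                  = "tug_time_s"
)
.ALL_METRICS <- c("tremor_score", "bradykinesia_score", "valid_taps",
                  "mean_intertap_s", "tug_time_s")

#' Build a free-living symptom stream
#'
#' One binary detection per 30-s window: 1 means the symptom was detected
#' during the past window, 0 means it was not.
#'
#' @param timestamp POSIXct (or ISO-8601 character) window start times,
#'   strictly increasing.
#' @param value integer 0/1 detections.
#' @param channel `"TREMOR"` or `"DYSKINESIA"`.
#' @param window_seconds window length, 30 by default.
#' @return data.frame of class `symptom_stream` with attributes `channel`
#'   and `window_seconds`.
#' @export
symptom_stream <- function(timestamp, value, channel = "TREMOR",
                           window_seconds = 30L) {
  channel <- match.arg(channel, .CHANNELS)
  timestamp <- hbm_time(timestamp)
  value <- as.integer(value)
  assert_that(length(timestamp) == length(value),
              "timestamp and value lengths differ")
  assert_that(!anyNA(timestamp), "symptom stream timestamps contain NA")
  assert_that(all(value %in% c(0L, 1L)),
              "%s stream values must be 0 or 1", channel)
  if (length(timestamp) > 1) {
    d <- diff(as.numeric(timestamp))
    assert_that(all(d > 0), "%s stream timestamps not strictly increasing", channel)
    assert_that(all(d >= window_seconds),
                "%s stream samples closer than the %d-s window", channel,
                window_seconds)
  }
  out <- data.frame(timestamp = timestamp, value = value)
  attr(out, "channel") <- channel
  attr(out, "window_seconds") <- as.integer(window_seconds)
  class(out) <- c("symptom_stream", "data.frame")
  out
}

#' Build an activity stream
#'
#' One score in \[0,1\] per 5-s window quantifying the participant's level
#' of activity; treated throughout as an opaque intensity.
#'
#' @inheritParams symptom_stream
#' @param value numeric in \[0,1\].
#' @return data.frame of class `activity_stream`.
#' @export
activity_stream <- function(timestamp, value, window_seconds = 5L) {
  timestamp <- hbm_time(timestamp)
  value <- as.numeric(value)
  assert_that(length(timestamp) == length(value),
              "timestamp and value lengths differ")
  assert_that(!anyNA(timestamp), "activity timestamps contain NA")
  assert_that(all(value >= 0 & value <= 1), "activity values outside [0,1]")
  if (length(timestamp) > 1)
    assert_that(all(diff(as.numeric(timestamp)) > 0),
                "activity timestamps not strictly increasing")
  out <- data.frame(timestamp = timestamp, value = value)
  attr(out, "window_seconds") <- as.integer(window_seconds)
  class(out) <- c("activity_stream", "data.frame")
  out
}

#' Build a medication log
#'
#' Scheduled dose slots with the participant's reported intake times; a
#' missing `reported_time` marks a skipped (unreported) dose.
#'
#' @param date Date (or character) of each slot.
#' @param slot_index 1-based dose slot within the day, increasing.
#' @param scheduled_time,reported_time POSIXct (reported may be NA).
#' @param dose_mg levodopa dose in mg, `>= 0`.
#' @return data.frame of class `medication_log`.
#' @export
medication_log <- function(date, slot_index, scheduled_time, reported_time,
                           dose_mg) {
  out <- data.frame(
    date = as.Date(date),
    slot_index = as.integer(slot_index),
    scheduled_time = hbm_time(scheduled_time),
    reported_time = hbm_time(reported_time),
    dose_mg = as.numeric(dose_mg)
  )
  assert_that(!anyNA(out$date) && !anyNA(out$scheduled_time),
              "medication log: date/scheduled_time contain NA")
  assert_that(all(out$dose_mg >= 0, na.rm = TRUE), "negative dose_mg")
  out <- out[order(out$date, out$slot_index), , drop = FALSE]
  for (d in unique(out$date)) {
    day <- out[out$date == d, ]
    assert_that(!anyDuplicated(day$slot_index),
                "duplicate slot_index on %s", as.character(as.Date(d)))
    assert_that(all(diff(as.numeric(day$scheduled_time)) > 0),
                "scheduled times not increasing on %s", as.character(as.Date(d)))
  }
  rownames(out) <- NULL
  class(out) <- c("medication_log", "data.frame")
  out
}

#' Build diary entries
#'
#' 30-min self-reported motor-state slots covering 08:00-20:00 (24 slots a
#' day): `ON`, `ON_DYSK` (ON with dyskinesia), `OFF`, `ASLEEP`, or
#' `MISSING` when the slot was never filled.
#'
#' @param slot_start POSIXct on the 30-min grid.
#' @param state character, one of the diary states.
#' @param reported_at POSIXct when the slot was filled (NA if MISSING).
#' @return data.frame of class `diary_entries`.
#' @export
diary_entries <- function(slot_start, state, reported_at) {
  slot_start <- hbm_time(slot_start)
  state <- as.character(state)
  assert_that(all(state %in% .DIARY_STATES),
              "invalid diary state(s): %s",
              paste(setdiff(state, .DIARY_STATES), collapse = ", "))
  sod <- secs_of_day(slot_start)
  assert_that(all(sod %% 1800 == 0), "diary slot_start not on the 30-min grid")
  assert_that(all(sod >= 8 * 3600 & sod < 20 * 3600),
              "diary slot_start outside the 08:00-20:00 window")
  out <- data.frame(slot_start = slot_start, state = state,
                    reported_at = hbm_time(reported_at))
  out <- out[order(out$slot_start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("diary_entries", "data.frame")
  out
}

#' Build daily motor-task records
#'
#' One row per task execution during an ON or OFF session. Scores from the
#' motor-task algorithm range 0-2; only the metric fields defined for each
#' task type may be non-missing (tremor score for postural/rest,
#' bradykinesia score for pronation-supination, valid taps and mean
#' inter-tap time for finger tapping, completion time for TUG).
#'
#' @param session_time POSIXct of the task execution.
#' @param reported_state `"ON"` or `"OFF"` (self-reported).
#' @param task_type one of the five task types.
#' @param tremor_score,bradykinesia_score numeric in \[0,2\] or NA.
#' @param valid_taps integer `>= 0` or NA.
#' @param mean_intertap_s,tug_time_s positive numeric or NA.
#' @return data.frame of class `motor_tasks`.
#' @export
motor_tasks <- function(session_time, reported_state, task_type,
                        tremor_score = NA_real_, bradykinesia_score = NA_real_,
                        valid_taps = NA_integer_, mean_intertap_s = NA_real_,
                        tug_time_s = NA_real_) {
  session_time <- hbm_time(session_time)
  n <- length(session_time)
  rec <- function(v) rep_len(v, n)    # recycle defaults, incl. zero rows
  out <- data.frame(
    session_time = session_time,
    reported_state = rec(as.character(reported_state)),
    task_type = rec(as.character(task_type)),
    tremor_score = rec(as.numeric(tremor_score)),
    bradykinesia_score = rec(as.numeric(bradykinesia_score)),
    valid_taps = rec(as.integer(valid_taps)),
    mean_intertap_s = rec(as.numeric(mean_intertap_s)),
    tug_time_s = rec(as.numeric(tug_time_s))
  )
  assert_that(all(out$reported_state %in% .TASK_STATES),
              "reported_state must be ON or OFF")
  assert_that(all(out$task_type %in% .TASK_TYPES),
              "invalid task_type(s): %s",
              paste(setdiff(out$task_type, .TASK_TYPES), collapse = ", "))
  for (i in seq_len(nrow(out))) {
    need <- .TASK_METRICS[[out$task_type[i]]]
    other <- setdiff(.ALL_METRICS, need)
    assert_that(!anyNA(out[i, need]),
                "row %d (%s): required metric missing", i, out$task_type[i])
    assert_that(all(is.na(out[i, other])),
                "row %d (%s): metric set for wrong task type", i, out$task_type[i])
  }
  sc <- c(out$tremor_score, out$bradykinesia_score)
  assert_that(all(sc >= 0 & sc <= 2, na.rm = TRUE), "scores outside [0,2]")
  assert_that(all(out$valid_taps >= 0, na.rm = TRUE), "negative valid_taps")
  assert_that(all(out$mean_intertap_s > 0, na.rm = TRUE),
              "non-positive mean_intertap_s")
  assert_that(all(out$tug_time_s > 0, na.rm = TRUE), "non-positive tug_time_s")
  out <- out[order(out$session_time), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("motor_tasks", "data.frame")
  out
}

#' Build clinician ratings
#'
#' In-clinic 0-4 ratings of the motor tasks, paired with the smartwatch
#' scores for validation. See [clamp_clinician()] for the 0-2 mapping.
#'
#' @param task_type,state task reference (type and ON/OFF condition).
#' @param raw_score integer 0-4.
#' @param swa_score matched smartwatch score in \[0,2\] (optional, NA ok).
#' @return data.frame of class `clinician_ratings`.
#' @export
clinician_ratings <- function(task_type, state, raw_score,
                              swa_score = NA_real_) {
  out <- data.frame(task_type = as.character(task_type),
                    state = as.character(state),
                    raw_score = as.integer(raw_score),
                    swa_score = as.numeric(swa_score))
  assert_that(all(out$task_type %in% .TASK_TYPES), "invalid task_type")
  assert_that(all(out$state %in% .TASK_STATES), "state must be ON or OFF")
  assert_that(all(out$raw_score >= 0L & out$raw_score <= 4L),
              "clinician raw_score outside [0,4]")
  class(out) <- c("clinician_ratings", "data.frame")
  out
}

#' Assemble a patient dataset
#'
#' @param patient_id character id, e.g. `"P001"`.
#' @param tremor,dyskinesia [symptom_stream()] objects (may have 0 rows).
#' @param activity an [activity_stream()].
#' @param medications a [medication_log()].
#' @param diary a [diary_entries()] table.
#' @param tasks a [motor_tasks()] table.
#' @param clinician optional [clinician_ratings()].
#' @param meta free-form list (the simulator stores its latent truth here;
#'   not part of the on-disk schema).
#' @return list of class `patient_dataset`.
#' @export
patient_dataset <- function(patient_id, tremor, dyskinesia, activity,
                            medications, diary, tasks, clinician = NULL,
                            meta = list()) {
  assert_that(is.character(patient_id) && length(patient_id) == 1 &&
                nzchar(patient_id), "patient_id must be a non-empty string")
  assert_that(inherits(tremor, "symptom_stream") &&
                attr(tremor, "channel") == "TREMOR", "tremor stream invalid")
  assert_that(inherits(dyskinesia, "symptom_stream") &&
                attr(dyskinesia, "channel") == "DYSKINESIA",
              "dyskinesia stream invalid")
  assert_that(inherits(activity, "activity_stream"), "activity stream invalid")
  assert_that(inherits(medications, "medication_log"), "medication log invalid")
  assert_that(inherits(diary, "diary_entries"), "diary invalid")
  assert_that(inherits(tasks, "motor_tasks"), "tasks invalid")
  if (!is.null(clinician))
    assert_that(inherits(clinician, "clinician_ratings"), "clinician invalid")
  structure(list(patient_id = patient_id, tremor = tremor,
                 dyskinesia = dyskinesia, activity = activity,
                 medications = medications, diary = diary, tasks = tasks,
                 clinician = clinician, meta = meta),
            class = "patient_dataset")
}

#' @export
print.patient_dataset <- function(x, ...) {
  cat(sprintf("<patient_dataset %s>\n", x$patient_id))
  days <- unique(hbm_date(x$tremor$timestamp))
  cat(sprintf("  monitoring days : %d\n", length(days)))
  cat(sprintf("  tremor windows  : %d (30 s)\n", nrow(x$tremor)))
  cat(sprintf("  dyskinesia wins : %d (30 s)\n", nrow(x$dyskinesia)))
  cat(sprintf("  activity windows: %d (5 s)\n", nrow(x$activity)))
  cat(sprintf("  dose slots      : %d (%d reported)\n", nrow(x$medications),
              sum(!is.na(x$medications$reported_time))))
  cat(sprintf("  diary slots     : %d on %d day(s)\n", nrow(x$diary),
              length(unique(hbm_date(x$diary$slot_start)))))
  cat(sprintf("  motor-task rows : %d\n", nrow(x$tasks)))
  if (!is.null(x$clinician))
    cat(sprintf("  clinician rows  : %d\n", nrow(x$clinician)))
  invisible(x)
}

# Fetch one symptom stream by channel name.
get_stream <- function(dataset, channel = c("TREMOR", "DYSKINESIA")) {
  channel <- match.arg(channel)
  if (channel == "TREMOR") dataset$tremor else dataset$dyskinesia
}
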