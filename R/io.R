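#' Read and write the monitoring CSV bundle
#'
#' A dataset directory holds six UTF-8 CSV files with a header row; an
#' empty cell encodes MISSING:
#' \describe{
#'   \item{streams.csv}{`patient_id,timestamp,channel,value` — 30-s binary
#'     tremor/dyskinesia detections.}
#'   \item{activity.csv}{`patient_id,timestamp,value` — 5-s activity in
#'     \[0,1\].}
#'   \item{medications.csv}{`patient_id,date,slot_index,scheduled_time,reported_time,dose_mg`.}
#'   \item{diary.csv}{`patient_id,slot_start,state,reported_at`.}
#'   \item{tasks.csv}{`patient_id,session_time,reported_state,task_type,tremor_score,bradykinesia_score,valid_taps,mean_intertap_s,tug_time_s`.}
#'   \item{clinician.csv}{`patient_id,task_type,state,raw_score[,swa_score]`
#'     — optional file; `swa_score` carries the matched smartwatch score
#'     when available.}
#' }
#' `write_dataset()` accepts a single [patient_dataset()] or a list of
#' them; `read_dataset()` returns a named list of `patient_dataset`
#' objects (one per `patient_id` found). Writing then reading reproduces
#' the same tables.
#'
#' @param x a `patient_dataset` or list of them.
#' @param dir directory for the CSV bundle (created if needed).
#' @return `read_dataset()`: named list of `patient_dataset` objects;
#'   `write_dataset()`: `dir`, invisibly.
#' @export
write_dataset <- function(x, dir) {
  if (inherits(x, "patient_dataset")) x <- list(x)
  assert_that(length(x) > 0 && all(vapply(x, inherits, logical(1),
                                          "patient_dataset")),
              "x must be a patient_dataset or a list of them")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fmt_num <- function(v) ifelse(is.na(v), "", as.character(v))
  streams <- do.call(rbind, lapply(x, function(d) {
    rbind(
      data.frame(patient_id = d$patient_id,
                 timestamp = hbm_time_format(d$tremor$timestamp),
                 channel = "TREMOR", value = d$tremor$value),
      data.frame(patient_id = d$patient_id,
                 timestamp = hbm_time_format(d$dyskinesia$timestamp),
                 channel = "DYSKINESIA", value = d$dyskinesia$value)
    )
  }))
  act <- do.call(rbind, lapply(x, function(d)
    data.frame(patient_id = d$patient_id,
               timestamp = hbm_time_format(d$activity$timestamp),
               value = fmt_num(d$activity$value))))
  meds <- do.call(rbind, lapply(x, function(d)
    data.frame(patient_id = d$patient_id,
               date = as.character(d$medications$date),
               slot_index = d$medications$slot_index,
               scheduled_time = hbm_time_format(d$medications$scheduled_time),
               reported_time = hbm_time_format(d$medications$reported_time),
               dose_mg = fmt_num(d$medications$dose_mg))))
  diary <- do.call(rbind, lapply(x, function(d)
    data.frame(patient_id = d$patient_id,
               slot_start = hbm_time_format(d$diary$slot_start),
               state = d$diary$state,
               reported_at = hbm_time_format(d$diary$reported_at))))
  tasks <- do.call(rbind, lapply(x, function(d)
    data.frame(patient_id = d$patient_id,
               session_time = hbm_time_format(d$tasks$session_time),
               reported_state = d$tasks$reported_state,
               task_type = d$tasks$task_type,
               tremor_score = fmt_num(d$tasks$tremor_score),
               bradykinesia_score = fmt_num(d$tasks$bradykinesia_score),
               valid_taps = fmt_num(d$tasks$valid_taps),
               mean_intertap_s = fmt_num(d$tasks$mean_intertap_s),
               tug_time_s = fmt_num(d$tasks$tug_time_s))))
  wr <- function(df, name) utils::write.csv(
    df, file.path(dir, name), row.names = FALSE, quote = FALSE,
    fileEncoding = "UTF-8")
  wr(streams, "streams.csv"); wr(act, "activity.csv")
  wr(meds, "medications.csv"); wr(diary, "diary.csv"); wr(tasks, "tasks.csv")
  clin <- Filter(Negate(is.null), lapply(x, function(d) {
    if (is.null(d$clinician)) return(NULL)
    data.frame(patient_id = d$patient_id,
               task_type = d$clinician$task_type, state = d$clinician$state,
               raw_score = d$clinician$raw_score,
               swa_score = fmt_num(d$clinician$swa_score))
  }))
  if (length(clin) > 0) wr(do.call(rbind, clin), "clinician.csv")
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  rd <- function(name, required = TRUE) {
    path <- file.path(dir, name)
    if (!file.exists(path)) {
      if (required) stop_hbm("%s: file not found", path)
      return(NULL)
    }
    utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                    fileEncoding = "UTF-8")
  }
  check_cols <- function(df, name, cols) {
    miss <- setdiff(cols, names(df))
    assert_that(length(miss) == 0, "%s: missing column(s) %s", name,
                paste(miss, collapse = ", "))
  }
  streams <- rd("streams.csv"); act <- rd("activity.csv")
  meds <- rd("medications.csv"); diary <- rd("diary.csv")
  tasks <- rd("tasks.csv"); clin <- rd("clinician.csv", required = FALSE)
  check_cols(streams, "streams.csv",
             c("patient_id", "timestamp", "channel", "value"))
  check_cols(act, "activity.csv", c("patient_id", "timestamp", "value"))
  check_cols(meds, "medications.csv",
             c("patient_id", "date", "slot_index", "scheduled_time",
               "reported_time", "dose_mg"))
  check_cols(diary, "diary.csv",
             c("patient_id", "slot_start", "state", "reported_at"))
  check_cols(tasks, "tasks.csv",
             c("patient_id", "session_time", "reported_state", "task_type",
               "tremor_score", "bradykinesia_score", "valid_taps",
               "mean_intertap_s", "tug_time_s"))
  bad <- which(!streams$value %in% c(0L, 1L))
  assert_that(length(bad) == 0,
              "streams.csv row %d: field value = %s not in {0,1}",
              bad[1], as.character(streams$value[bad[1]]))
  bad <- which(!streams$channel %in% .CHANNELS)
  assert_that(length(bad) == 0, "streams.csv row %d: field channel invalid",
              bad[1])
  ids <- unique(c(streams$patient_id, act$patient_id, meds$patient_id,
                  diary$patient_id, tasks$patient_id))
  out <- lapply(ids, function(id) {
    pick <- function(df) df[df$patient_id == id, , drop = FALSE]
    s <- pick(streams); a <- pick(act); m <- pick(meds)
    dy <- pick(diary); tk <- pick(tasks)
    mk_stream <- function(ch) {
      ss <- s[s$channel == ch, , drop = FALSE]
      ss <- ss[order(hbm_time(ss$timestamp)), , drop = FALSE]
      symptom_stream(ss$timestamp, ss$value, channel = ch)
    }
    a <- a[order(hbm_time(a$timestamp)), , drop = FALSE]
    cl <- NULL
    if (!is.null(clin)) {
      cc <- clin[clin$patient_id == id, , drop = FALSE]
      if (nrow(cc) > 0)
        cl <- clinician_ratings(cc$task_type, cc$state, cc$raw_score,
                                if ("swa_score" %in% names(cc))
                                  cc$swa_score else NA_real_)
    }
    patient_dataset(
      patient_id = id,
      tremor = mk_stream("TREMOR"),
      dyskinesia = mk_stream("DYSKINESIA"),
      activity = activity_stream(a$timestamp, a$value),
      medications = medication_log(m$date, m$slot_index, m$scheduled_time,
                                   m$reported_time, m$dose_mg),
      diary = diary_entries(dy$slot_start, dy$state, dy$reported_at),
      tasks = motor_tasks(tk$session_time, tk$reported_state, tk$task_type,
                          tk$tremor_score, tk$bradykinesia_score,
                          tk$valid_taps, tk$mean_intertap_s, tk$tug_time_s),
      clinician = cl
    )
  })
  names(out) <- ids
  out
}
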