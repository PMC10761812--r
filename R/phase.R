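#' Inter-dose intervals for one day
#'
#' Builds the dosing intervals used for phase normalization, anchored at
#' the *reported* intake times. Interval `k` runs from reported dose `k`
#' to reported dose `k+1`; the final interval runs from the last scheduled
#' dose's report to the end of the day's last worn interval, capped at
#' `max_final_h` hours. Intervals adjacent to a skipped (unreported)
#' scheduled slot are invalid for that day, and a day with fewer than two
#' reported doses is excluded entirely (zero rows).
#'
#' @param meds_day [medication_log()] rows of a single day.
#' @param mask wear mask (bounds the final interval).
#' @param max_final_h cap on the post-last-dose interval, hours.
#' @return data.frame with `slot_index`, `start`, `end`, `valid`; one row
#'   per scheduled slot (the row for slot `k` is the interval that starts
#'   at dose `k`).
#' @export
interdose_intervals <- function(meds_day, mask, max_final_h = 6) {
  assert_that(length(unique(meds_day$date)) <= 1,
              "interdose_intervals expects a single day")
  meds_day <- meds_day[order(meds_day$slot_index), , drop = FALSE]
  K <- nrow(meds_day)
  rep_s <- as.numeric(meds_day$reported_time)
  if (sum(!is.na(rep_s)) < 2) {
    message(sprintf("day %s: fewer than 2 reported doses; excluded",
                    as.character(meds_day$date[1])))
    return(data.frame(slot_index = integer(0), start = hbm_time(character(0)),
                      end = hbm_time(character(0)), valid = logical(0)))
  }
  d_end <- as.numeric(day_start(meds_day$date[1])) + 86400
  wear_end <- if (nrow(mask) > 0) {
    ends <- as.numeric(mask$end)
    ends <- ends[ends <= d_end & ends > as.numeric(day_start(meds_day$date[1]))]
    if (length(ends)) max(ends) else NA_real_
  } else NA_real_
  start <- rep_s
  end <- c(rep_s[-1], NA)
  valid <- !is.na(start) & !is.na(end)
  # final interval after the last scheduled dose
  if (!is.na(rep_s[K])) {
    cap <- rep_s[K] + max_final_h * 3600
    end[K] <- if (!is.na(wear_end)) min(wear_end, cap) else cap
    valid[K] <- end[K] > start[K]
  }
  num2t <- function(v) as.POSIXct(v, origin = "1970-01-01", tz = .HBM_TZ)
  data.frame(slot_index = meds_day$slot_index, start = num2t(start),
             end = num2t(end), valid = valid)
}

#' Phase-bin one day's streams
#'
#' Splits every valid inter-dose interval into `n_bins` equal-duration
#' bins and scores each bin: tremor fraction = detected / worn 30-s
#' samples, activity = mean of worn 5-s values. A sample belongs to the
#' bin containing its start timestamp (half-open bins). Cells whose worn
#' coverage is below `min_coverage_frac` of the bin duration are `NA`.
#'
#' @param tremor a tremor [symptom_stream()] (worn samples only).
#' @param activity an [activity_stream()].
#' @param intervals an [interdose_intervals()] table.
#' @param n_bins bins per interval (default 10).
#' @param min_coverage_frac minimum worn fraction per cell (default 0.1).
#' @return list with `tremor`, `activity` (K x n_bins matrices, rows
#'   named by dose-slot index) and `coverage` (worn seconds of the tremor
#'   channel per cell).
#' @export
phase_bin_day <- function(tremor, activity, intervals, n_bins = 10L,
                          min_coverage_frac = 0.1) {
  K <- nrow(intervals)
  trem <- act <- cov <- matrix(NA_real_, K, n_bins,
                               dimnames = list(intervals$slot_index, NULL))
  w_t <- attr(tremor, "window_seconds") %||% 30L
  w_a <- attr(activity, "window_seconds") %||% 5L
  for (k in seq_len(K)) {
    if (!intervals$valid[k]) next
    s0 <- as.numeric(intervals$start[k]); s1 <- as.numeric(intervals$end[k])
    bw <- (s1 - s0) / n_bins
    tt <- as.numeric(tremor$timestamp)
    at <- as.numeric(activity$timestamp)
    t_in <- tt >= s0 & tt < s1
    a_in <- at >= s0 & at < s1
    t_bin <- pmin(floor((tt[t_in] - s0) / bw) + 1, n_bins)
    a_bin <- pmin(floor((at[a_in] - s0) / bw) + 1, n_bins)
    for (b in seq_len(n_bins)) {
      tv <- tremor$value[t_in][t_bin == b]
      av <- activity$value[a_in][a_bin == b]
      cov[k, b] <- length(tv) * w_t
      if (length(tv) * w_t >= min_coverage_frac * bw)
        trem[k, b] <- mean(tv)
      if (length(av) * w_a >= min_coverage_frac * bw)
        act[k, b] <- mean(av)
    }
  }
  list(tremor = trem, activity = act, coverage = cov)
}

#' Average daily phase matrices into a signature
#'
#' Cellwise mean over the days in which a cell is defined, aligned by
#' scheduled dose-slot index, so days with different reported dose counts
#' still contribute their valid cells. Cells defined on no day stay `NA`
#' (e.g. when the watch is systematically removed after an early dose,
#' the later intervals drop out of the average).
#'
#' @param day_matrices list of [phase_bin_day()] results.
#' @param patient_id id stored in the signature.
#' @return object of class `phase_signature`: `tremor`, `activity`
#'   (K x 10 mean matrices), `coverage` (summed worn seconds),
#'   `cell_days` (days contributing per cell), `days_used`. `NULL`
#'   matrices signal an undefined signature (no usable day).
#' @export
average_signature <- function(day_matrices, patient_id = NA_character_) {
  day_matrices <- Filter(function(m) !is.null(m) && nrow(m$tremor) > 0,
                         day_matrices)
  if (length(day_matrices) == 0) {
    out <- list(patient_id = patient_id, tremor = NULL, activity = NULL,
                coverage = NULL, cell_days = NULL, days_used = 0L)
    class(out) <- "phase_signature"
    return(out)
  }
  K <- max(vapply(day_matrices, function(m) max(as.integer(rownames(m$tremor))),
                  numeric(1)))
  nb <- ncol(day_matrices[[1]]$tremor)
  sum_t <- sum_a <- n_t <- n_a <- cov <- matrix(0, K, nb)
  used <- 0L
  for (m in day_matrices) {
    idx <- as.integer(rownames(m$tremor))
    def_t <- !is.na(m$tremor); def_a <- !is.na(m$activity)
    if (any(def_t) || any(def_a)) used <- used + 1L
    sum_t[idx, ] <- sum_t[idx, ] + ifelse(def_t, m$tremor, 0)
    n_t[idx, ] <- n_t[idx, ] + def_t
    sum_a[idx, ] <- sum_a[idx, ] + ifelse(def_a, m$activity, 0)
    n_a[idx, ] <- n_a[idx, ] + def_a
    cov[idx, ] <- cov[idx, ] + ifelse(is.na(m$coverage), 0, m$coverage)
  }
  trem <- ifelse(n_t > 0, sum_t / pmax(n_t, 1), NA_real_)
  act <- ifelse(n_a > 0, sum_a / pmax(n_a, 1), NA_real_)
  rownames(trem) <- rownames(act) <- rownames(cov) <- seq_len(K)
  out <- list(patient_id = patient_id, tremor = trem, activity = act,
              coverage = cov, cell_days = n_t, days_used = used)
  class(out) <- "phase_signature"
  out
}

#' @export
print.phase_signature <- function(x, ...) {
  if (is.null(x$tremor)) {
    cat(sprintf("<phase_signature %s> UNDEFINED (no usable day)\n",
                x$patient_id))
    return(invisible(x))
  }
  cat(sprintf("<phase_signature %s> %d interval(s) x %d bins, %d day(s)\n",
              x$patient_id, nrow(x$tremor), ncol(x$tremor), x$days_used))
  cat(sprintf("  tremor range   : [%.2f, %.2f]\n",
              min(x$tremor, na.rm = TRUE), max(x$tremor, na.rm = TRUE)))
  cat(sprintf("  missing cells  : %d of %d\n", sum(is.na(x$tremor)),
              length(x$tremor)))
  invisible(x)
}

#' Compute the phase signature of a patient
#'
#' Runs [interdose_intervals()] and [phase_bin_day()] for every monitored
#' day and averages the results with [average_signature()].
#'
#' @param dataset a [patient_dataset()].
#' @param config an [hbm_config()].
#' @return a `phase_signature`.
#' @export
phase_signature <- function(dataset, config = hbm_config()) {
  mask <- infer_wear_mask(dataset$tremor, config$gap_threshold_s)
  dates <- unique(dataset$medications$date)
  mats <- lapply(dates, function(d) {
    meds <- dataset$medications[dataset$medications$date == d, , drop = FALSE]
    ivl <- suppressMessages(
      interdose_intervals(meds, mask, config$max_final_h))
    if (nrow(ivl) == 0) return(NULL)
    d0 <- day_start(d); d1 <- d0 + 86400
    phase_bin_day(slice_window(dataset$tremor, d0, d1),
                  slice_window(dataset$activity, d0, d1), ivl,
                  n_bins = config$n_phase_bins,
                  min_coverage_frac = config$min_cell_coverage)
  })
  average_signature(mats, patient_id = dataset$patient_id)
}

#' Hourly tremor-prevalence profile for one day
#'
#' Per clock-hour fraction of worn 30-s windows with the symptom
#' detected; `NA` for hours with no worn sample.
#'
#' @param stream a [symptom_stream()].
#' @param mask wear mask (samples outside it are ignored).
#' @param date calendar day.
#' @return numeric vector of length 24 (hour 0-23).
#' @export
hourly_profile <- function(stream, mask, date) {
  date <- as.Date(date)
  sub <- slice_window(stream, day_start(date), day_start(date) + 86400)
  if (nrow(mask) > 0 && nrow(sub) > 0) {
    idx <- findInterval(as.numeric(sub$timestamp), as.numeric(mask$start))
    worn <- idx >= 1 & as.numeric(sub$timestamp) <
      as.numeric(mask$end)[pmax(idx, 1)]
    sub <- sub[worn, , drop = FALSE]
  }
  out <- rep(NA_real_, 24)
  if (nrow(sub) == 0) return(out)
  hr <- floor(secs_of_day(sub$timestamp) / 3600)
  agg <- tapply(sub$value, factor(hr, levels = 0:23), mean)
  out[] <- as.numeric(agg)
  out
}

# days x 24 matrix of hourly profiles across the monitoring period
hourly_profiles <- function(dataset, config = hbm_config()) {
  mask <- infer_wear_mask(dataset$tremor, config$gap_threshold_s)
  if (nrow(mask) == 0) return(matrix(NA_real_, 0, 24))
  days <- seq(hbm_date(min(mask$start)), hbm_date(max(mask$end) - 1), by = "day")
  t(vapply(days, function(d) hourly_profile(dataset$tremor, mask, d),
           numeric(24)))
}
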