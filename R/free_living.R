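#' Daily symptom prevalence
#'
#' Fraction of worn 30-s windows on a calendar day in which the symptom
#' was detected. Days with fewer than `min_bins` worn windows (default
#' 120, i.e. one hour) are returned as `NA` and excluded from overall
#' averages.
#'
#' @param stream a [symptom_stream()].
#' @param mask the wear mask (only worn samples enter the denominator).
#' @param date calendar day (Date).
#' @param min_bins minimum worn windows for a defined score.
#' @return prevalence in \[0,1\], or `NA` when undefined.
#' @export
daily_prevalence <- function(stream, mask, date, min_bins = 120L) {
  date <- as.Date(date)
  sub <- slice_window(stream, day_start(date), day_start(date) + 86400)
  if (nrow(mask) > 0 && nrow(sub) > 0) {
    idx <- findInterval(as.numeric(sub$timestamp), as.numeric(mask$start))
    worn <- idx >= 1 & as.numeric(sub$timestamp) <
      as.numeric(mask$end)[pmax(idx, 1)]
    sub <- sub[worn, , drop = FALSE]
  }
  if (nrow(sub) < min_bins) return(NA_real_)
  mean(sub$value)
}

#' Daily mean activity
#'
#' Mean of the worn 5-s activity scores on a day; `NA` when fewer than
#' `min_bins` worn windows exist (default 720, one hour of 5-s windows).
#'
#' @param activity an [activity_stream()].
#' @inheritParams daily_prevalence
#' @return mean activity in \[0,1\] or `NA`.
#' @export
daily_activity_mean <- function(activity, mask, date, min_bins = 720L) {
  date <- as.Date(date)
  sub <- slice_window(activity, day_start(date), day_start(date) + 86400)
  if (nrow(mask) > 0 && nrow(sub) > 0) {
    idx <- findInterval(as.numeric(sub$timestamp), as.numeric(mask$start))
    worn <- idx >= 1 & as.numeric(sub$timestamp) <
      as.numeric(mask$end)[pmax(idx, 1)]
    sub <- sub[worn, , drop = FALSE]
  }
  if (nrow(sub) < min_bins) return(NA_real_)
  mean(sub$value)
}

#' Daily score table for one patient
#'
#' @param dataset a [patient_dataset()].
#' @param config an [hbm_config()].
#' @return data.frame with `date`, `tremor_prevalence`,
#'   `dyskinesia_prevalence`, `activity_mean`, `worn_bins`.
#' @export
daily_scores <- function(dataset, config = hbm_config()) {
  mask <- infer_wear_mask(dataset$tremor, config$gap_threshold_s)
  amask <- infer_wear_mask(dataset$activity, config$gap_threshold_activity_s)
  if (nrow(mask) == 0)
    return(data.frame(date = as.Date(character(0)),
                      tremor_prevalence = numeric(0),
                      dyskinesia_prevalence = numeric(0),
                      activity_mean = numeric(0), worn_bins = integer(0)))
  days <- seq(hbm_date(min(mask$start)), hbm_date(max(mask$end) - 1), by = "day")
  out <- do.call(rbind, lapply(days, function(d) {
    sub <- slice_window(dataset$tremor, day_start(d), day_start(d) + 86400)
    data.frame(
      date = d,
      tremor_prevalence = daily_prevalence(dataset$tremor, mask, d,
                                           config$min_bins_per_day),
      dyskinesia_prevalence = daily_prevalence(dataset$dyskinesia, mask, d,
                                               config$min_bins_per_day),
      activity_mean = daily_activity_mean(dataset$activity, amask, d,
                                          config$min_bins_per_day * 6L),
      worn_bins = nrow(sub))
  }))
  rownames(out) <- NULL
  out
}

#' Overall (per-patient) symptom and activity scores
#'
#' The overall score is the unweighted mean of the defined daily scores —
#' each monitored day carries equal weight regardless of how long the
#' watch was worn that day.
#'
#' @param daily a [daily_scores()] table.
#' @return list with `overall_tremor`, `overall_dyskinesia`,
#'   `overall_activity`, `days_used` (per measure); `NA` when no day is
#'   defined.
#' @export
overall_scores <- function(daily) {
  avg <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  list(overall_tremor = avg(daily$tremor_prevalence),
       overall_dyskinesia = avg(daily$dyskinesia_prevalence),
       overall_activity = avg(daily$activity_mean),
       days_used = c(tremor = sum(!is.na(daily$tremor_prevalence)),
                     dyskinesia = sum(!is.na(daily$dyskinesia_prevalence)),
                     activity = sum(!is.na(daily$activity_mean))))
}

#' Rank-correlate overall sensor scores with clinical item scores
#'
#' Spearman correlation between per-patient overall sensor scores and a
#' clinical rating (e.g. an MDS-UPDRS item), over the intersection of
#' patient ids; dropped ids are reported.
#'
#' @param overall named numeric vector of per-patient overall scores.
#' @param clinical named numeric vector of per-patient clinical scores.
#' @param alpha significance level.
#' @return a [swa_stats] result with attribute `dropped` (ids present in
#'   only one vector).
#' @export
correlate_with_clinical <- function(overall, clinical, alpha = 0.05) {
  assert_that(!is.null(names(overall)) && !is.null(names(clinical)),
              "both vectors must be named by patient id")
  common <- intersect(names(overall), names(clinical))
  dropped <- setdiff(union(names(overall), names(clinical)), common)
  if (length(dropped) > 0)
    message("correlate_with_clinical: dropped unmatched id(s): ",
            paste(dropped, collapse = ", "))
  res <- spearman_rho(overall[common], clinical[common], alpha = alpha)
  attr(res, "dropped") <- dropped
  res
}
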