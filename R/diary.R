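#' Sensor measures aligned to the 30-min diary slots
#'
#' For every filled diary slot, computes the percent of worn 30-s windows
#' with tremor and with dyskinesia, the mean worn 5-s activity score, and
#' the wear coverage of the slot. Slots worn for less than
#' `min_slot_coverage` of their 30 minutes are flagged `excluded` and are
#' dropped from the ON/OFF tests.
#'
#' @param dataset a [patient_dataset()].
#' @param config an [hbm_config()].
#' @return data.frame of class `slot_measures`: `slot_start`, `state`,
#'   `tremor_pct`, `dysk_pct`, `activity_mean`, `coverage`, `excluded`.
#' @export
slot_measures <- function(dataset, config = hbm_config()) {
  mask <- infer_wear_mask(dataset$tremor, config$gap_threshold_s)
  diary <- dataset$diary[dataset$diary$state != "MISSING", , drop = FALSE]
  rows <- lapply(seq_len(nrow(diary)), function(i) {
    s0 <- diary$slot_start[i]; s1 <- s0 + 1800
    cov <- worn_seconds(mask, s0, s1) / 1800
    tr <- slice_window(dataset$tremor, s0, s1)
    dy <- slice_window(dataset$dyskinesia, s0, s1)
    ac <- slice_window(dataset$activity, s0, s1)
    data.frame(
      slot_start = s0, state = diary$state[i],
      tremor_pct = if (nrow(tr)) mean(tr$value) else NA_real_,
      dysk_pct = if (nrow(dy)) mean(dy$value) else NA_real_,
      activity_mean = if (nrow(ac)) mean(ac$value) else NA_real_,
      coverage = cov,
      excluded = cov < config$min_slot_coverage)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(slot_start = hbm_time(character(0)), state = character(0),
               tremor_pct = numeric(0), dysk_pct = numeric(0),
               activity_mean = numeric(0), coverage = numeric(0),
               excluded = logical(0))
  class(out) <- c("slot_measures", "data.frame")
  out
}

#' Per-patient ON vs OFF comparison of a slot measure
#'
#' Welch t-test of the slot values in self-reported ON slots (ON and
#' ON-with-dyskinesia pooled) against OFF slots. ASLEEP slots and
#' low-coverage (excluded) slots are dropped. With
#' `pool_dysk = FALSE`, ON_DYSK slots form their own stratum and are left
#' out of the ON group.
#'
#' @param slots a [slot_measures()] table.
#' @param channel `"tremor"`, `"dyskinesia"` or `"activity"`.
#' @param alpha significance level.
#' @param pool_dysk pool ON_DYSK into ON (default TRUE).
#' @param var_equal use the pooled-variance t-test variant.
#' @return a [swa_stats] result with extra fields `direction`
#'   (`"OFF"`/`"ON"`/`NA`: state with the higher mean), `mean_on`,
#'   `mean_off`.
#' @export
per_patient_on_off <- function(slots, channel = c("tremor", "dyskinesia",
                                                  "activity"),
                               alpha = 0.05, pool_dysk = TRUE,
                               var_equal = FALSE) {
  channel <- match.arg(channel)
  col <- switch(channel, tremor = "tremor_pct", dyskinesia = "dysk_pct",
                activity = "activity_mean")
  use <- slots[!slots$excluded & slots$state != "ASLEEP" &
                 !is.na(slots[[col]]), , drop = FALSE]
  on_states <- if (pool_dysk) c("ON", "ON_DYSK") else "ON"
  on <- use[[col]][use$state %in% on_states]
  off <- use[[col]][use$state == "OFF"]
  res <- if (length(on) < 2 || length(off) < 2)
    undefined_test(sprintf("need >= 2 usable slots per state (ON %d, OFF %d)",
                           length(on), length(off)),
                   if (var_equal) "student" else "welch",
                   length(on), length(off), alpha)
  else welch_test(on, off, alpha = alpha, var_equal = var_equal)
  res$mean_on <- if (length(on)) mean(on) else NA_real_
  res$mean_off <- if (length(off)) mean(off) else NA_real_
  res$direction <- if (is.na(res$mean_on) || is.na(res$mean_off)) NA_character_
    else if (res$mean_off > res$mean_on) "OFF" else "ON"
  res$channel <- channel
  res
}

#' Cohort-level diary ON/OFF summary
#'
#' For each channel: a group-level test on the per-patient (ON mean,
#' OFF mean) pairs — paired t by default, since every participant
#' contributes both states — plus the percent of patients with the higher
#' mean in OFF (tremor) or ON (dyskinesia, activity), and the percent of
#' patients whose own Welch test was significant. Percentages are over
#' patients with a defined comparison.
#'
#' @param slot_list named list of [slot_measures()] tables (one per
#'   patient).
#' @param alpha significance level.
#' @param paired use the paired group-level test (default) or an unpaired
#'   Welch test pooling patients.
#' @return data.frame with one row per channel: `channel`, `group_p`,
#'   `pct_higher_off`, `pct_higher_on`, `pct_significant`, `n_defined`.
#' @export
cohort_on_off_summary <- function(slot_list, alpha = 0.05, paired = TRUE) {
  channels <- c("tremor", "dyskinesia", "activity")
  out <- lapply(channels, function(ch) {
    per <- lapply(slot_list, per_patient_on_off, channel = ch, alpha = alpha)
    ok <- vapply(per, function(r) !r$undefined, logical(1))
    def <- per[ok]
    mon <- vapply(def, `[[`, numeric(1), "mean_on")
    moff <- vapply(def, `[[`, numeric(1), "mean_off")
    gp <- if (length(def) >= 2) {
      if (paired) paired_test(mon, moff, alpha = alpha)
      else welch_test(mon, moff, alpha = alpha)
    } else undefined_test("fewer than 2 patients with defined comparisons",
                          "paired", length(def), length(def), alpha)
    data.frame(
      channel = ch,
      group_p = gp$p_value,
      pct_higher_off = if (length(def)) 100 * mean(moff > mon) else NA_real_,
      pct_higher_on = if (length(def)) 100 * mean(mon > moff) else NA_real_,
      pct_significant = if (length(def))
        100 * mean(vapply(def, `[[`, logical(1), "significant")) else NA_real_,
      n_defined = length(def))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
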