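#' Archetype parameters for the synthetic cohort generator
#'
#' The generator emulates the smartwatch platform's outputs for one of four
#' motor-fluctuation archetypes observed in advanced Parkinson's disease:
#' \describe{
#'   \item{DOSE_RESPONSIVE}{tremor concentrated around medication intakes
#'     (wearing-off), suppressed during the levodopa plateau.}
#'   \item{TIME_OF_DAY}{dose-coupled tremor in the morning, persistent
#'     tremor after `switch_hour` regardless of the medication cycle.}
#'   \item{CONSTANT}{tremor throughout the day, interrupted by random
#'     dose-independent quiet blocks.}
#'   \item{IRREGULAR}{a per-day two-state Markov chain whose stationary
#'     tremor probability is resampled every day, so no pattern repeats
#'     across days.}
#' }
#' A latent medication-effect level `E(t)` in \[0,1\] drives everything:
#' the tremor detection probability is
#' `p(t) = p_tremor_off * (1 - E) + p_tremor_on * E`, dyskinesia
#' analogously (dyskinesia accompanies the ON state), and the 5-s activity
#' score is a declining daily baseline minus `activity_coupling` times the
#' concurrent tremor detection, plus Gaussian noise. A bin is labelled
#' latent-ON when `E >= 0.5`.
#'
#' Defaults mirror the home-monitoring protocol: 14 days, 5 daily doses
#' between 08:00 and 20:00, roughly 14 h of daily wear, two non-consecutive
#' diary days, and one OFF plus one ON motor-task session per day. The
#' motor-task score distributions default to the published cohort-level
#' means/SDs (valid taps ON 34.4 +/- 6.6 vs OFF 24.6 +/- 8.2; inter-tap time
#' ON 0.29 +/- 0.06 s vs OFF 0.4 +/- 0.13 s; TUG ON 17 +/- 3.6 s vs OFF
#' 21.68 +/- 4.42 s).
#'
#' @param archetype one of `"DOSE_RESPONSIVE"`, `"TIME_OF_DAY"`,
#'   `"CONSTANT"`, `"IRREGULAR"`.
#' @param ... overrides for any default listed below.
#' @return list of class `archetype_params`.
#' @export
archetype_params <- function(archetype = c("DOSE_RESPONSIVE", "TIME_OF_DAY",
                                           "CONSTANT", "IRREGULAR"), ...) {
  archetype <- match.arg(archetype)
  p <- list(
    archetype = archetype,
    days = 14L,
    doses_per_day = 5L,
    scheduled_times = NULL,        # auto: evenly spaced 08:00-20:00
    start_date = as.Date("2024-03-04"),
    # tremor emission probabilities
    p_tremor_off = 0.8,
    p_tremor_on = 0.05,
    # trapezoidal medication-effect curve (minutes)
    onset_lag_min = 30,
    rise_min = 15,
    fall_min = 15,
    effect_fraction = 0.75,
    # TIME_OF_DAY: persistent tremor after this clock hour
    switch_hour = 12,
    # CONSTANT quiet blocks / IRREGULAR dwell
    markov_dwell_min = 45,
    quiet_blocks_per_day = 2L,
    irregular_stationary = c(0.2, 0.7),
    # dyskinesia (appears during ON)
    p_dysk_on = 0.3,
    p_dysk_off = 0.05,
    # activity model
    activity_base_start = 0.6,
    activity_base_end = 0.3,
    activity_coupling = 0.2,
    activity_noise_sd = 0.05,
    # medication reporting
    intake_delay_mean_min = 10,
    intake_delay_sd_min = 10,
    p_skip_dose = 0.03,
    # wear behaviour
    wear_start = "08:00",
    wear_end = "22:00",
    wear_jitter_sd_min = 20,
    p_midday_gap = 0.15,
    midday_gap_min = 45,
    # diary behaviour
    diary_error_p = 0.1,
    diary_missing_p = 0.05,
    dysk_slot_threshold = 0.3,
    # motor-task score distributions: list(on = c(mean, sd), off = ...)
    task_effects = list(
      valid_taps      = list(on = c(34.4, 6.6),  off = c(24.6, 8.2)),
      mean_intertap_s = list(on = c(0.29, 0.06), off = c(0.4, 0.13)),
      tug_time_s      = list(on = c(17, 3.6),    off = c(21.68, 4.42)),
      tremor_score    = list(on = c(0.4, 0.5),   off = c(1.6, 0.5)),
      brady_score     = list(on = c(0.5, 0.4),   off = c(1.3, 0.5))
    )
  )
  # archetype-specific defaults
  if (archetype == "TIME_OF_DAY") p$p_tremor_off <- 0.6
  if (archetype == "CONSTANT") { p$p_dysk_on <- 0.05 }
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  assert_that(length(bad) == 0, "unknown parameter(s): %s",
              paste(bad, collapse = ", "))
  p[names(dots)] <- dots
  p$days <- as.integer(p$days)
  p$doses_per_day <- as.integer(p$doses_per_day)
  assert_that(p$days >= 1, "days must be >= 1")
  assert_that(p$doses_per_day >= 3 && p$doses_per_day <= 9,
              "doses_per_day must be in [3, 9]")
  if (is.null(p$scheduled_times)) {
    hrs <- seq(8, 20, length.out = p$doses_per_day)
    p$scheduled_times <- sprintf("%02d:%02d", floor(hrs),
                                 round((hrs - floor(hrs)) * 60))
  }
  assert_that(length(p$scheduled_times) == p$doses_per_day,
              "scheduled_times length must equal doses_per_day")
  probs <- c(p$p_tremor_off, p$p_tremor_on, p$p_dysk_on, p$p_dysk_off,
             p$p_skip_dose, p$p_midday_gap, p$diary_error_p,
             p$diary_missing_p)
  assert_that(all(probs >= 0 & probs <= 1), "probabilities must be in [0,1]")
  assert_that(p$effect_fraction > 0 && p$effect_fraction <= 1,
              "effect_fraction must be in (0,1]")
  class(p) <- "archetype_params"
  p
}

#' Trapezoidal medication-effect curve
#'
#' Models the levodopa cycle within one inter-dose interval: no effect
#' during the absorption lag, a linear onset over `rise_min` minutes, full
#' effect until `effect_fraction` of the interval has elapsed, then a
#' linear wearing-off over `fall_min` minutes back to zero. Degenerate
#' intervals no longer than the lag yield an all-zero effect.
#'
#' @param t_since_dose_min minutes since the (reported) dose, vectorised.
#' @param interval_min length of the inter-dose interval in minutes.
#' @param params an [archetype_params()] object (only the curve fields are
#'   used).
#' @return effect level(s) in \[0,1\].
#' @export
effect_curve <- function(t_since_dose_min, interval_min, params) {
  lag <- params$onset_lag_min
  if (interval_min <= lag) return(rep(0, length(t_since_dose_min)))
  plateau_end <- params$effect_fraction * interval_min
  r <- pmin(pmax((t_since_dose_min - lag) / params$rise_min, 0), 1)
  f <- pmin(pmax((plateau_end + params$fall_min - t_since_dose_min) /
                   params$fall_min, 0), 1)
  out <- pmin(r, f)
  out[t_since_dose_min < 0 | t_since_dose_min >= interval_min] <- 0
  out
}

# --- internal per-day machinery ---------------------------------------------

# Latent effect E on a 30-s grid (seconds since midnight) for one day.
.latent_effect <- function(grid_s, reported_s, params) {
  E <- numeric(length(grid_s))
  arch <- params$archetype
  if (arch %in% c("DOSE_RESPONSIVE", "TIME_OF_DAY")) {
    rep_s <- sort(reported_s[!is.na(reported_s)])
    if (length(rep_s) >= 1) {
      spacing <- if (length(rep_s) >= 2) stats::median(diff(rep_s)) else
        12 * 3600 / params$doses_per_day
      bounds <- c(rep_s, rep_s[length(rep_s)] + spacing)
      idx <- findInterval(grid_s, rep_s)
      tsd <- (grid_s - rep_s[pmax(idx, 1)]) / 60
      # effect_curve takes a scalar interval length; evaluate per interval
      for (k in seq_along(rep_s)) {
        sel <- idx == k
        if (!any(sel)) next
        E[sel] <- effect_curve(tsd[sel], (bounds[k + 1] - rep_s[k]) / 60,
                               params)
      }
    }
    if (arch == "TIME_OF_DAY") E[grid_s >= params$switch_hour * 3600] <- 0
  } else if (arch == "CONSTANT") {
    # E = 0 (tremor present) except random dose-independent quiet blocks
    n <- params$quiet_blocks_per_day
    if (n > 0 && length(grid_s) > 0) {
      span <- range(grid_s)
      starts <- stats::runif(n, span[1], span[2])
      lens <- params$markov_dwell_min * 60 * stats::runif(n, 0.7, 1.3)
      for (k in seq_len(n))
        E[grid_s >= starts[k] & grid_s < starts[k] + lens[k]] <- 1
    }
  } else { # IRREGULAR: two-state Markov chain at 30-s steps
    pi_t <- stats::runif(1, params$irregular_stationary[1],
                         params$irregular_stationary[2])
    p_leave <- min(1, 0.5 / params$markov_dwell_min)   # dwell ~45 min
    p_enter <- min(1, p_leave * pi_t / (1 - pi_t))
    n <- length(grid_s)
    if (n > 0) {
      state <- integer(n)                      # 1 = tremor-present state
      state[1] <- stats::rbinom(1, 1, pi_t)
      u <- stats::runif(n)
      for (i in seq_len(n - 1)) {
        state[i + 1] <- if (state[i] == 1) {
          if (u[i] < p_leave) 0L else 1L
        } else {
          if (u[i] < p_enter) 1L else 0L
        }
      }
      E <- 1 - state
    }
  }
  E
}

.draw_task_metric <- function(effects, metric, state, n = 1) {
  ms <- effects[[metric]][[tolower(state)]]
  stats::rnorm(n, ms[1], ms[2])
}

#' Simulate one patient's complete monitoring dataset
#'
#' Deterministic given `(params, seed)`. Produces the free-living tremor,
#' dyskinesia and activity streams inside a jittered daily wear window
#' (with occasional midday non-wear gaps), the medication log (reported
#' intakes are scheduled times plus a truncated-normal delay, skipped with
#' `p_skip_dose`), two non-consecutive diary days derived from the latent
#' ON/OFF labels with reporting errors, one OFF and one ON motor-task
#' session per day (all five task types), and a small in-clinic clinician
#' rating table. The latent effect grid and labels are kept in
#' `$meta$latent` for validation against ground truth.
#'
#' @param params an [archetype_params()] object.
#' @param seed integer seed.
#' @param patient_id id string, default `"P001"`.
#' @return a [patient_dataset()].
#' @export
simulate_patient <- function(params, seed, patient_id = "P001") {
  assert_that(inherits(params, "archetype_params"),
              "params must come from archetype_params()")
  with_seed(seed, .simulate_patient_impl(params, patient_id, seed))
}

.simulate_patient_impl <- function(params, patient_id, seed) {
  days <- params$start_date + seq_len(params$days) - 1
  clock_s <- vapply(strsplit(params$scheduled_times, ":"), function(h)
    as.numeric(h[1]) * 3600 + as.numeric(h[2]) * 60, numeric(1))

  trem_ts <- trem_v <- dysk_v <- act_ts <- act_v <- list()
  med_rows <- list(); latent <- list()
  diary_days <- sort(sample(seq_len(params$days), 2))
  while (params$days > 2 && diff(diary_days) < 2)
    diary_days <- sort(sample(seq_len(params$days), 2))
  diary_rows <- list(); task_rows <- list()

  for (d in seq_len(params$days)) {
    d0 <- as.numeric(day_start(days[d]))
    # --- wear window (rounded to the 30-s grid) ---
    ws <- at_clock(days[d], params$wear_start)
    we <- at_clock(days[d], params$wear_end)
    ws_s <- round((as.numeric(ws) - d0 +
                     stats::rnorm(1, 0, params$wear_jitter_sd_min * 60)) / 30) * 30
    we_s <- round((as.numeric(we) - d0 +
                     stats::rnorm(1, 0, params$wear_jitter_sd_min * 60)) / 30) * 30
    ws_s <- max(ws_s, 5.5 * 3600); we_s <- min(we_s, 23.75 * 3600)
    if (we_s - ws_s < 8 * 3600) we_s <- ws_s + 8 * 3600
    worn <- matrix(c(ws_s, we_s), ncol = 2)
    if (stats::runif(1) < params$p_midday_gap) {
      g0 <- round(stats::runif(1, 12 * 3600, 16 * 3600) / 30) * 30
      g1 <- g0 + round(params$midday_gap_min * 60 *
                         stats::runif(1, 0.7, 1.3) / 30) * 30
      if (g0 > ws_s && g1 < we_s)
        worn <- matrix(c(ws_s, g0, g1, we_s), ncol = 2, byrow = TRUE)
    }
    # --- medication log ---
    delay <- pmin(pmax(stats::rnorm(params$doses_per_day,
                                    params$intake_delay_mean_min,
                                    params$intake_delay_sd_min), -15), 60)
    skipped <- stats::runif(params$doses_per_day) < params$p_skip_dose
    rep_s <- clock_s + delay * 60
    rep_s[skipped] <- NA
    med_rows[[d]] <- data.frame(
      date = days[d], slot_index = seq_len(params$doses_per_day),
      scheduled_s = clock_s, reported_s = rep_s,
      dose_mg = rep(150, params$doses_per_day))
    # --- latent effect on the worn 30-s grid ---
    grid_s <- unlist(lapply(seq_len(nrow(worn)), function(k)
      seq(worn[k, 1], worn[k, 2] - 30, by = 30)), use.names = FALSE)
    E <- .latent_effect(grid_s, rep_s, params)
    p_trem <- params$p_tremor_off * (1 - E) + params$p_tremor_on * E
    p_dysk <- params$p_dysk_off * (1 - E) + params$p_dysk_on * E
    tv <- stats::rbinom(length(grid_s), 1, p_trem)
    dv <- stats::rbinom(length(grid_s), 1, p_dysk)
    trem_ts[[d]] <- d0 + grid_s; trem_v[[d]] <- tv; dysk_v[[d]] <- dv
    latent[[d]] <- data.frame(timestamp = d0 + grid_s, effect = E,
                              on_label = E >= 0.5)
    # --- activity stream, 5-s windows nested in the 30-s bins ---
    a_s <- rep(grid_s, each = 6) + rep(seq(0, 25, by = 5), length(grid_s))
    frac <- (a_s - ws_s) / max(we_s - ws_s, 1)
    base <- params$activity_base_start +
      (params$activity_base_end - params$activity_base_start) * frac
    a_v <- base - params$activity_coupling * rep(tv, each = 6) +
      stats::rnorm(length(a_s), 0, params$activity_noise_sd)
    act_ts[[d]] <- d0 + a_s
    act_v[[d]] <- pmin(pmax(a_v, 0), 1)
    # --- diary (two non-consecutive days) ---
    if (d %in% diary_days) {
      slot_s <- seq(8 * 3600, 20 * 3600 - 1800, by = 1800)
      st <- character(length(slot_s)); rep_at <- rep(NA_real_, length(slot_s))
      for (j in seq_along(slot_s)) {
        in_slot <- grid_s >= slot_s[j] & grid_s < slot_s[j] + 1800
        mE <- if (any(in_slot)) mean(E[in_slot]) else 0
        lab <- if (mE >= 0.5) "ON" else "OFF"
        if (stats::runif(1) < params$diary_error_p)
          lab <- if (lab == "ON") "OFF" else "ON"
        if (lab == "ON" && any(in_slot) &&
            mean(dv[in_slot]) > params$dysk_slot_threshold)
          lab <- "ON_DYSK"
        if (stats::runif(1) < params$diary_missing_p) {
          st[j] <- "MISSING"
        } else {
          st[j] <- lab
          rep_at[j] <- d0 + slot_s[j] + 1800 +
            abs(stats::rnorm(1, 10, 10)) * 60
        }
      }
      diary_rows[[length(diary_rows) + 1]] <- data.frame(
        slot_start = d0 + slot_s, state = st, reported_at = rep_at)
    }
    # --- motor-task sessions: OFF before first dose, ON mid-plateau ---
    sess <- c(OFF = d0 + 7.5 * 3600, ON = d0 + clock_s[1] + 75 * 60)
    for (state in names(sess)) {
      eff <- params$task_effects
      tt <- sess[[state]]
      clip02 <- function(v) pmin(pmax(round(v, 1), 0), 2)
      task_rows[[length(task_rows) + 1]] <- data.frame(
        session_time = tt + (0:4) * 120,
        reported_state = state,
        task_type = .TASK_TYPES,
        tremor_score = c(clip02(.draw_task_metric(eff, "tremor_score", state, 2)),
                         NA, NA, NA),
        bradykinesia_score = c(NA, NA,
                               clip02(.draw_task_metric(eff, "brady_score", state)),
                               NA, NA),
        valid_taps = c(NA, NA, NA,
                       max(0, round(.draw_task_metric(eff, "valid_taps", state))),
                       NA),
        mean_intertap_s = c(NA, NA, NA,
                            max(0.05, round(.draw_task_metric(
                              eff, "mean_intertap_s", state), 3)), NA),
        tug_time_s = c(NA, NA, NA, NA,
                       max(5, round(.draw_task_metric(eff, "tug_time_s", state), 2))))
    }
  }

  med <- do.call(rbind, med_rows)
  num2t <- function(v) as.POSIXct(v, origin = "1970-01-01", tz = .HBM_TZ)
  d0v <- as.numeric(day_start(med$date))
  diary <- do.call(rbind, diary_rows)
  tasks <- do.call(rbind, task_rows)
  # in-clinic validation session: postural + rest in both states
  clin_swa <- clin_raw <- numeric(0); clin_task <- clin_state <- character(0)
  for (state in c("OFF", "ON")) for (tk in c("POSTURAL", "REST")) {
    swa <- pmin(pmax(round(.draw_task_metric(params$task_effects,
                                             "tremor_score", state), 1), 0), 2)
    raw <- min(max(round(swa * 2 + stats::rnorm(1, 0, 0.5)), 0), 4)
    clin_swa <- c(clin_swa, swa); clin_raw <- c(clin_raw, raw)
    clin_task <- c(clin_task, tk); clin_state <- c(clin_state, state)
  }

  patient_dataset(
    patient_id = patient_id,
    tremor = symptom_stream(num2t(unlist(trem_ts)), unlist(trem_v), "TREMOR"),
    dyskinesia = symptom_stream(num2t(unlist(trem_ts)), unlist(dysk_v),
                                "DYSKINESIA"),
    activity = activity_stream(num2t(unlist(act_ts)), unlist(act_v)),
    medications = medication_log(med$date, med$slot_index,
                                 num2t(d0v + med$scheduled_s),
                                 num2t(d0v + med$reported_s), med$dose_mg),
    diary = diary_entries(num2t(diary$slot_start), diary$state,
                          num2t(diary$reported_at)),
    tasks = motor_tasks(num2t(tasks$session_time), tasks$reported_state,
                        tasks$task_type, tasks$tremor_score,
                        tasks$bradykinesia_score, tasks$valid_taps,
                        tasks$mean_intertap_s, tasks$tug_time_s),
    clinician = clinician_ratings(clin_task, clin_state, clin_raw, clin_swa),
    meta = list(archetype = params$archetype, seed = seed, params = params,
                latent = do.call(rbind, latent), diary_days = diary_days)
  )
}

#' Simulate a cohort across archetypes
#'
#' @param spec named integer vector or named list, e.g.
#'   `c(DOSE_RESPONSIVE = 10, TIME_OF_DAY = 10, CONSTANT = 10,
#'   IRREGULAR = 10)`. All counts must be `>= 1`.
#' @param seed master seed; each patient's seed is derived from it
#'   deterministically.
#' @param overrides named list (by archetype) of parameter overrides passed
#'   to [archetype_params()].
#' @return named list of [patient_dataset()] objects with ids
#'   `P001, P002, ...` in spec order.
#' @export
simulate_cohort <- function(spec, seed, overrides = list()) {
  spec <- unlist(spec)
  assert_that(!is.null(names(spec)) && all(nzchar(names(spec))),
              "spec must be named by archetype")
  assert_that(all(names(spec) %in% c("DOSE_RESPONSIVE", "TIME_OF_DAY",
                                     "CONSTANT", "IRREGULAR")),
              "unknown archetype in spec")
  assert_that(all(spec >= 1), "all archetype counts must be >= 1")
  out <- list(); i <- 0L
  for (arch in names(spec)) {
    pars <- do.call(archetype_params,
                    c(list(archetype = arch), overrides[[arch]] %||% list()))
    for (k in seq_len(spec[[arch]])) {
      i <- i + 1L
      id <- sprintf("P%03d", i)
      pseed <- (as.numeric(seed) * 1009 + i * 9973) %% 2147483647
      out[[id]] <- simulate_patient(pars, pseed, patient_id = id)
    }
  }
  out
}

#' Read a cohort simulation spec from YAML
#'
#' The file lists the master seed and one entry per archetype:
#' ```yaml
#' seed: 42
#' cohort:
#'   - archetype: DOSE_RESPONSIVE
#'     count: 10
#'     params: {days: 14, doses_per_day: 5}
#' ```
#'
#' @param path YAML file path.
#' @return list with `seed`, `spec` (named counts) and `overrides`,
#'   ready for [simulate_cohort()].
#' @export
read_simspec <- function(path) {
  y <- yaml::read_yaml(path)
  assert_that(!is.null(y$cohort), "simspec: missing 'cohort' key")
  spec <- integer(0); overrides <- list()
  for (entry in y$cohort) {
    assert_that(!is.null(entry$archetype) && !is.null(entry$count),
                "simspec: cohort entries need archetype and count")
    spec[entry$archetype] <- as.integer(entry$count)
    if (!is.null(entry$params)) overrides[[entry$archetype]] <- entry$params
  }
  list(seed = y$seed %||% 1L, spec = spec, overrides = overrides)
}
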