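mask_from <- function(...) {
  iv <- list(...)
  pdhbm:::new_wear_mask(vapply(iv, function(x) as.numeric(hbm_time(x[1])),
                               numeric(1)),
                        vapply(iv, function(x) as.numeric(hbm_time(x[2])),
                               numeric(1)))
}

test_that("daily wear hours follow the strict >12 h rule", {
  m <- mask_from(c("2024-03-04T08:00:00", "2024-03-04T20:30:00"))
  w <- wear_compliance(m)
  expect_equal(w$hours, 12.5)
  expect_true(w$compliant)

  m <- mask_from(c("2024-03-04T07:00:00", "2024-03-04T19:00:00"))
  w <- wear_compliance(m)
  expect_equal(w$hours, 12)
  expect_false(w$compliant)       # exactly 12 h does not comply

  m <- mask_from(c("2024-03-04T08:00:00", "2024-03-04T12:00:00"),
                 c("2024-03-04T13:00:00", "2024-03-04T20:00:00"))
  expect_equal(wear_compliance(m)$hours, 11)
})

session_fixture <- function(n_days, states = c("OFF", "ON")) {
  days <- as.Date("2024-03-04") + seq_len(n_days) - 1
  grid <- expand.grid(day = days, state = states,
                      stringsAsFactors = FALSE)
  motor_tasks(hbm_time(paste0(grid$day, "T10:00:00")) +
                ifelse(grid$state == "ON", 3600, 0),
              grid$state, rep("TUG", nrow(grid)),
              tug_time_s = rep(20, nrow(grid)))
}

test_that("task completion counts sessions against the 28-session rule", {
  full <- session_fixture(14)                       # 28 sessions
  expect_equal(task_completion(full)$missed, 0)
  expect_true(task_completion(full)$compliant)

  t26 <- session_fixture(13)                        # 26 sessions
  expect_equal(task_completion(t26)$missed, 2)
  expect_true(task_completion(t26)$compliant)       # boundary: 2 allowed

  # 25 sessions: 12 full days + an OFF-only day
  t25 <- motor_tasks(c(session_fixture(12)$session_time,
                       hbm_time("2024-03-17T10:00:00")),
                     c(session_fixture(12)$reported_state, "OFF"),
                     rep("TUG", 25), tug_time_s = rep(20, 25))
  expect_equal(task_completion(t25)$missed, 3)
  expect_false(task_completion(t25)$compliant)

  # duplicate same-state sessions on a day count once
  dup <- motor_tasks(hbm_time(c("2024-03-04T10:00:00", "2024-03-04T15:00:00")),
                     c("ON", "ON"), c("TUG", "TUG"),
                     tug_time_s = c(20, 21))
  expect_equal(task_completion(dup, required_sessions = 2)$missed, 1)
  expect_warning(task_completion(full, required_sessions = 10), "clamping")
})

test_that("medication adherence separates skips from delays", {
  log <- medication_log(rep(as.Date("2024-03-04"), 3), 1:3,
                        hbm_time(c("2024-03-04T08:00:00",
                                   "2024-03-04T12:00:00",
                                   "2024-03-04T16:00:00")),
                        hbm_time(c("2024-03-04T08:25:00", NA,
                                   "2024-03-04T15:50:00")),
                        c(100, 100, 100))
  a <- medication_adherence(log)
  expect_equal(a$skipped, 1)
  expect_equal(a$delays_min, c(25, -10))
  expect_equal(a$skipped + a$reported, a$scheduled)   # conservation
})

diary_fixture <- function(n_filled, delay_min = 10) {
  slots <- hbm_time("2024-03-05T08:00:00") + seq(0, 23) * 1800
  state <- c(rep("ON", n_filled), rep("MISSING", 24 - n_filled))
  rep_at <- c(slots[seq_len(n_filled)] + delay_min * 60,
              rep(hbm_time(NA), 24 - n_filled))
  diary_entries(slots, state, rep_at)
}

test_that("diary completeness applies the 75% / 2 h rule inclusively", {
  expect_true(diary_completeness(diary_fixture(18))$complete)   # 18/24 = 75%
  expect_false(diary_completeness(diary_fixture(17))$complete)  # 70.8%

  # exactly +2 h counts; +2 h 01 min does not
  at_boundary <- diary_fixture(18, delay_min = 120)
  expect_true(diary_completeness(at_boundary)$complete)
  over <- diary_fixture(18, delay_min = 121)
  expect_equal(diary_completeness(over)$filled_on_time, 0)
  expect_false(diary_completeness(over)$complete)
})

test_that("report delays are non-negative minutes with a median rule", {
  expect_equal(report_delay(hbm_time("2024-03-04T10:00:00"),
                            hbm_time("2024-03-04T10:12:00")), 12)
  expect_equal(median(c(5, 40, 10)), 10)   # median rule: compliant at 30
  expect_error(report_delay(hbm_time("2024-03-04T10:00:00"),
                            hbm_time("2024-03-04T09:59:00")), "precedes")
})

test_that("adding completed items never worsens compliance flags", {
  d <- simulate_patient(tiny_params(days = 14L, p_skip_dose = 0.2,
                                    diary_missing_p = 0.3), 6)
  base <- compliance_report(d)
  # answer one previously-missed diary slot
  miss <- which(d$diary$state == "MISSING")[1]
  expect_false(is.na(miss))
  d2 <- d
  d2$diary$state[miss] <- "ON"
  d2$diary$reported_at[miss] <- d2$diary$slot_start[miss] + 600
  # report one previously-skipped dose
  skip <- which(is.na(d$medications$reported_time))[1]
  expect_false(is.na(skip))
  d2$medications$reported_time[skip] <-
    d2$medications$scheduled_time[skip] + 300
  better <- compliance_report(d2)
  for (f in names(base$flags)) {
    expect_true(better$flags[[f]] >= base$flags[[f]],
                label = sprintf("flag %s must not degrade", f))
  }
  expect_lte(better$missed_daily_queries, base$missed_daily_queries)
  expect_lt(better$doses_skipped, base$doses_skipped)
})
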