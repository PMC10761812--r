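tug_fixture <- function(times, states) {
  motor_tasks(hbm_time("2024-03-04T10:00:00") + seq_along(times) * 3600,
              states, rep("TUG", length(times)), tug_time_s = times)
}

test_that("overall state scores are per-state means with SD", {
  t <- tug_fixture(c(20, 22, 15), c("OFF", "OFF", "ON"))
  s <- overall_state_scores(t, "TUG", "tug_time_s")
  off <- s[s$state == "OFF", ]
  expect_equal(off$mean, 21)
  expect_equal(off$sd, sqrt(2))
  expect_equal(off$n, 2)
  expect_equal(s$sd[s$state == "ON"], 0)    # single record
  expect_error(overall_state_scores(t, "TUG", "valid_taps"), "not defined")
})

test_that("ON/OFF task tests apply the metric's improvement direction", {
  taps <- motor_tasks(hbm_time("2024-03-04T10:00:00") + 1:4 * 3600,
                      c("ON", "ON", "OFF", "OFF"), rep("FINGER_TAPPING", 4),
                      valid_taps = c(30, 31, 20, 21),
                      mean_intertap_s = c(0.3, 0.31, 0.41, 0.42))
  expect_true(on_off_task_test(taps, "FINGER_TAPPING", "valid_taps")$better_in_on)
  expect_true(on_off_task_test(taps, "FINGER_TAPPING",
                               "mean_intertap_s")$better_in_on)
  tug <- tug_fixture(c(15, 16, 20, 21), c("ON", "ON", "OFF", "OFF"))
  r <- on_off_task_test(tug, "TUG", "tug_time_s")
  expect_true(r$better_in_on)              # lower TUG time is better
  expect_equal(r$mean_on, 15.5)
})

test_that("variability flags use the strict 1-SD rule", {
  t <- tug_fixture(c(10, 10, 10, 20), rep("OFF", 4))
  expect_equal(variability_flags(t, "TUG", "tug_time_s"),
               c(FALSE, FALSE, FALSE, TRUE))   # mean 12.5, sd 5
  expect_equal(variability_flags(tug_fixture(c(7, 7, 7), rep("ON", 3)),
                                 "TUG", "tug_time_s"), rep(FALSE, 3))
  # score exactly at mean + 1 SD is not flagged
  t2 <- tug_fixture(c(10, 20, 30), rep("OFF", 3))   # mean 20, sd 10
  expect_equal(variability_flags(t2, "TUG", "tug_time_s"), rep(FALSE, 3))
  expect_error(variability_flags(tug_fixture(c(10, 20), c("ON", "OFF")),
                                 "TUG", "tug_time_s"), ">= 3")
})

test_that("variability flag count is invariant to affine rescaling", {
  set.seed(21)
  v <- rnorm(12, 20, 4)
  t1 <- tug_fixture(v, rep("OFF", 12))
  t2 <- tug_fixture(v * 3 + 7, rep("OFF", 12))
  expect_equal(variability_flags(t1, "TUG", "tug_time_s"),
               variability_flags(t2, "TUG", "tug_time_s"))
})

test_that("combined tremor score sums rest and postural per session", {
  t <- motor_tasks(hbm_time("2024-03-04T10:00:00") + 0:3 * 600,
                   c("OFF", "OFF", "ON", "ON"),
                   c("REST", "POSTURAL", "REST", "POSTURAL"),
                   tremor_score = c(1.5, 0.5, 0.3, 0.1))
  cs <- combined_tremor_scores(t)
  expect_equal(cs$combined_score[cs$state == "OFF"], 2)
  expect_equal(cs$combined_score[cs$state == "ON"], 0.4)
})

test_that("clinician scores clamp onto the 0-2 smartwatch scale", {
  expect_equal(clamp_clinician(0:4), c(0L, 1L, 2L, 2L, 2L))
  expect_identical(clamp_clinician(clamp_clinician(0:4)), clamp_clinician(0:4))
  expect_true(all(diff(clamp_clinician(0:4)) >= 0))   # monotone
  expect_error(clamp_clinician(5), "outside")
  expect_error(clamp_clinician(-1), "outside")
})

test_that("clinician validation correlates clamped pairs", {
  expect_equal(validate_against_clinician(c(0, 1, 2, 2, 2),
                                          0:4)$statistic, 1)
  set.seed(21)
  swa <- pmin(pmax(runif(40, 0, 2), 0), 2)
  clin <- round(pmin(pmax(swa + rnorm(40, 0, 0.3), 0), 2) * 2)
  expect_gte(validate_against_clinician(swa, pmin(clin, 4))$statistic, 0.7)
  expect_true(validate_against_clinician(c(1, 1.2, 1.4),
                                         c(2, 2, 2))$undefined)
})

test_that("shows_tremor rules distinguish any-positive from mean-positive", {
  t <- motor_tasks(hbm_time("2024-03-04T10:00:00") + 0:2 * 600,
                   rep("OFF", 3), rep("REST", 3),
                   tremor_score = c(0, 0, 0.5))
  expect_true(shows_tremor(t, "REST"))
  expect_true(shows_tremor(t, "REST", rule = "mean_positive"))
  none <- motor_tasks(hbm_time("2024-03-04T10:00:00"), "OFF", "REST",
                      tremor_score = 0)
  expect_false(shows_tremor(none, "REST"))
  expect_true(is.na(shows_tremor(none, "POSTURAL")))
})

test_that("simulated ON/OFF task effects are recovered within 2 SE", {
  cohort <- simulate_cohort(c(DOSE_RESPONSIVE = 6), 13,
                            overrides = list(DOSE_RESPONSIVE = list(days = 7L)))
  tab <- cohort_task_summary(lapply(cohort, `[[`, "tasks"))
  taps <- tab[tab$metric == "valid_taps", ]
  n_on <- 6 * 7
  expect_lt(abs(taps$mean_on - 34.4), 2 * 6.6 / sqrt(n_on) + 0.5)
  expect_lt(abs(taps$mean_off - 24.6), 2 * 8.2 / sqrt(n_on) + 0.5)
  tug <- tab[tab$metric == "tug_time_s", ]
  expect_lt(abs(tug$mean_off - 21.68), 2 * 4.42 / sqrt(n_on) + 0.5)
  expect_equal(taps$pct_better_in_on, 100)
})
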