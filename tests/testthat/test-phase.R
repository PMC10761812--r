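meds_at <- function(date, clocks, reported = clocks) {
  medication_log(rep(date, length(clocks)), seq_along(clocks),
                 hbm_time(paste0(date, "T", clocks, ":00")),
                 hbm_time(ifelse(is.na(reported), NA,
                                 paste0(date, "T", reported, ":00"))),
                 rep(100, length(clocks)))
}

test_that("inter-dose intervals follow reported doses and the final cap", {
  date <- as.Date("2024-03-04")
  m <- meds_at(date, c("08:00", "12:00", "16:00"))
  mask <- pdhbm:::new_wear_mask(as.numeric(hbm_time("2024-03-04T07:30:00")),
                                as.numeric(hbm_time("2024-03-04T21:00:00")))
  iv <- interdose_intervals(m, mask, max_final_h = 6)
  expect_equal(nrow(iv), 3)
  expect_true(all(iv$valid))
  expect_equal(iv$start, hbm_time(paste0("2024-03-04T",
                                         c("08:00", "12:00", "16:00"), ":00")))
  expect_equal(iv$end[1:2], iv$start[2:3])
  expect_equal(iv$end[3], hbm_time("2024-03-04T21:00:00"))  # wear-end bound
})

test_that("skipped doses invalidate adjacent intervals", {
  date <- as.Date("2024-03-04")
  m <- meds_at(date, c("08:00", "12:00", "16:00"),
               reported = c("08:05", NA, "16:10"))
  mask <- pdhbm:::new_wear_mask(as.numeric(hbm_time("2024-03-04T07:30:00")),
                                as.numeric(hbm_time("2024-03-04T21:00:00")))
  iv <- interdose_intervals(m, mask, 6)
  expect_equal(iv$valid, c(FALSE, FALSE, TRUE))
  expect_equal(iv$start[3], hbm_time("2024-03-04T16:10:00"))
})

test_that("a day with fewer than two reported doses is excluded", {
  date <- as.Date("2024-03-04")
  m <- meds_at(date, c("08:00", "12:00"), reported = c("08:00", NA))
  mask <- pdhbm:::new_wear_mask(as.numeric(hbm_time("2024-03-04T07:30:00")),
                                as.numeric(hbm_time("2024-03-04T21:00:00")))
  expect_message(iv <- interdose_intervals(m, mask, 6), "excluded")
  expect_equal(nrow(iv), 0)
})

phase_stream <- function(start, end, value_fun) {
  secs <- seq(as.numeric(start), as.numeric(end) - 30, by = 30)
  ts <- as.POSIXct(secs, origin = "1970-01-01", tz = "UTC")
  symptom_stream(ts, value_fun(secs - as.numeric(start)), "TREMOR")
}

test_that("phase bins score segments of an interval correctly", {
  date <- as.Date("2024-03-04")
  iv <- data.frame(slot_index = 1L, start = hbm_time("2024-03-04T08:00:00"),
                   end = hbm_time("2024-03-04T09:40:00"), valid = TRUE)
  # 100-min interval, tremor only in the final 20 min
  s <- phase_stream(iv$start, iv$end, function(off) as.integer(off >= 80 * 60))
  empty_act <- activity_stream(hbm_time(character(0)), numeric(0))
  pb <- phase_bin_day(s, empty_act, iv)
  expect_equal(as.numeric(pb$tremor[1, ]), c(rep(0, 8), 1, 1))
  # constant detection fills the whole row
  s1 <- phase_stream(iv$start, iv$end, function(off) rep(1L, length(off)))
  expect_equal(as.numeric(phase_bin_day(s1, empty_act, iv)$tremor[1, ]),
               rep(1, 10))
  # an unworn interval yields an all-missing row
  s0 <- symptom_stream(hbm_time(character(0)), integer(0))
  expect_true(all(is.na(phase_bin_day(s0, empty_act, iv)$tremor)))
})

test_that("bin fractions are invariant to stretching the interval", {
  mk <- function(len_min) {
    iv <- data.frame(slot_index = 1L, start = hbm_time("2024-03-04T08:00:00"),
                     end = hbm_time("2024-03-04T08:00:00") + len_min * 60,
                     valid = TRUE)
    s <- phase_stream(iv$start, iv$end, function(off)
      as.integer(off / (len_min * 60) >= 0.8))
    phase_bin_day(s, activity_stream(hbm_time(character(0)), numeric(0)), iv)
  }
  expect_equal(mk(100)$tremor[1, ], mk(200)$tremor[1, ])
})

test_that("signature averaging is cellwise over defined days", {
  iv <- data.frame(slot_index = 1L, start = hbm_time("2024-03-04T08:00:00"),
                   end = hbm_time("2024-03-04T09:40:00"), valid = TRUE)
  empty_act <- activity_stream(hbm_time(character(0)), numeric(0))
  d1 <- phase_bin_day(phase_stream(iv$start, iv$end, function(off)
    rbinom(length(off), 1, 0.2) * 0 + as.integer(off < 50 * 60)), empty_act, iv)
  d1$tremor[1, ] <- 0.2
  d2 <- d1; d2$tremor[1, ] <- 0.4
  sig <- average_signature(list(d1, d2), "PX")
  expect_equal(as.numeric(sig$tremor[1, ]), rep(0.3, 10))
  expect_equal(sig$days_used, 2)
  # a cell missing on one day falls back to the other day's value
  d2$tremor[1, 3] <- NA
  sig2 <- average_signature(list(d1, d2), "PX")
  expect_equal(unname(sig2$tremor[1, 3]), 0.2)
  # cells missing on all days stay missing (watch removed after dose k)
  d1$tremor[1, 9:10] <- NA; d2$tremor[1, 9:10] <- NA
  sig3 <- average_signature(list(d1, d2), "PX")
  expect_true(all(is.na(sig3$tremor[1, 9:10])))
  und <- average_signature(list(), "PX")
  expect_null(und$tremor)
  expect_equal(und$days_used, 0)
})

test_that("dose-responsive simulant reproduces the effect-curve shape", {
  d <- simulate_patient(archetype_params("DOSE_RESPONSIVE"), 17)
  sig <- phase_signature(d)
  peri <- sig$tremor[, c(1, 10)]
  mid <- sig$tremor[, 5:6]
  expect_gte(mean(peri, na.rm = TRUE), 0.6)
  expect_lte(mean(mid, na.rm = TRUE), 0.2)
})

test_that("phase binning conserves every worn sample in the dosing span", {
  d <- simulate_patient(tiny_params(p_skip_dose = 0, p_midday_gap = 0), 29)
  mask <- infer_wear_mask(d$tremor, 90)
  for (date in unique(d$medications$date)) {
    meds <- d$medications[d$medications$date == date, ]
    iv <- interdose_intervals(meds, mask, 6)
    d0 <- hbm_time(paste0(as.Date(date, origin = "1970-01-01"), "T00:00:00"))
    trem <- slice_window(d$tremor, d0, d0 + 86400)
    pb <- phase_bin_day(trem, d$activity, iv, min_coverage_frac = 0)
    assigned <- sum(pb$coverage, na.rm = TRUE) / 30
    span_n <- sum(trem$timestamp >= min(iv$start) &
                    trem$timestamp < max(iv$end))
    expect_equal(assigned, span_n)
  }
})

test_that("hourly profiles match per-hour counting", {
  d0 <- hbm_time("2024-05-06T00:00:00")
  all1 <- symptom_stream(d0 + seq(8 * 3600, 20 * 3600 - 30, by = 30),
                         rep(1L, 1440))
  m <- infer_wear_mask(all1, 90)
  hp <- hourly_profile(all1, m, as.Date("2024-05-06"))
  expect_equal(hp[9:20], rep(1, 12))
  expect_true(all(is.na(hp[1:8])))
  noon <- symptom_stream(d0 + seq(8 * 3600, 20 * 3600 - 30, by = 30),
                         as.integer(seq(8 * 3600, 20 * 3600 - 30, by = 30) >=
                                      12 * 3600))
  hp2 <- hourly_profile(noon, infer_wear_mask(noon, 90), as.Date("2024-05-06"))
  expect_equal(hp2[9:12], rep(0, 4))
  expect_equal(hp2[13:20], rep(1, 8))
})

test_that("phase and hourly computations agree with brute-force oracles", {
  for (seed in 1:5) {
    day <- random_day(200 + seed)
    mask <- infer_wear_mask(day$tremor, 90)
    iv <- suppressMessages(interdose_intervals(day$meds, mask, 6))
    if (nrow(iv) > 0) {
      pb <- phase_bin_day(day$tremor, day$activity, iv)
      expect_equal(unname(pb$tremor), oracle_phase_bins(day$tremor, iv))
    }
    expect_equal(hourly_profile(day$tremor, mask, day$date),
                 oracle_hourly(day$tremor, mask, day$date))
  }
})
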