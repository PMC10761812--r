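# one diary day with two slots: 09:00 fully worn, 11:00 unworn
slot_fixture <- function() {
  d0 <- hbm_time("2024-03-05T08:30:00")
  secs <- seq(0, 2.5 * 3600 - 30, by = 30)      # worn 08:30-11:00
  vals <- integer(length(secs))
  ts <- d0 + secs
  in_slot <- ts >= hbm_time("2024-03-05T09:00:00") &
    ts < hbm_time("2024-03-05T09:30:00")
  vals[which(in_slot)[1:30]] <- 1               # 30 of 60 slot bins set
  asecs <- seq(0, 2.5 * 3600 - 5, by = 5)
  diary <- diary_entries(hbm_time(c("2024-03-05T09:00:00",
                                    "2024-03-05T11:00:00")),
                         c("ON", "OFF"),
                         hbm_time(c("2024-03-05T09:35:00",
                                    "2024-03-05T11:40:00")))
  patient_dataset("PX", symptom_stream(ts, vals, "TREMOR"),
                  symptom_stream(ts, integer(length(ts)), "DYSKINESIA"),
                  activity_stream(d0 + asecs, rep(0.7, length(asecs))),
                  empty_meds(), diary, empty_tasks())
}

test_that("slot measures count worn bins inside each 30-min slot", {
  s <- slot_measures(slot_fixture())
  expect_equal(nrow(s), 2)
  expect_equal(s$tremor_pct[1], 0.5)
  expect_equal(s$activity_mean[1], 0.7)
  expect_equal(s$coverage[1], 1)
  expect_false(s$excluded[1])
  expect_true(s$excluded[2])          # unworn slot
  expect_equal(s$coverage[2], 0)
})

test_that("per-patient ON/OFF comparison reports direction and pools ON_DYSK", {
  r <- per_patient_on_off(mk_slots(on = c(0, 0, 0), off = c(1, 1, 1)), "tremor")
  expect_equal(r$direction, "OFF")
  pooled <- per_patient_on_off(mk_slots(c(0.1, 0.2, 0.3), c(0.5, 0.6, 0.7),
                                        state_on = "ON_DYSK"), "tremor")
  plain <- per_patient_on_off(mk_slots(c(0.1, 0.2, 0.3), c(0.5, 0.6, 0.7)),
                              "tremor")
  expect_equal(pooled$statistic, plain$statistic)
  unpooled <- per_patient_on_off(mk_slots(c(0.1, 0.2, 0.3), c(0.5, 0.6, 0.7),
                                          state_on = "ON_DYSK"), "tremor",
                                 pool_dysk = FALSE)
  expect_true(unpooled$undefined)     # no plain-ON slots left
})

test_that("asleep and excluded slots are dropped", {
  s <- mk_slots(c(0.1, 0.2, 0.3), c(0.5, 0.6, 0.7))
  s$state[1] <- "ASLEEP"
  s2 <- mk_slots(c(0.2, 0.3), c(0.5, 0.6, 0.7))
  expect_equal(per_patient_on_off(s, "tremor")$statistic,
               per_patient_on_off(s2, "tremor")$statistic)
  s$excluded[4] <- TRUE
  s3 <- mk_slots(c(0.2, 0.3), c(0.6, 0.7))
  expect_equal(per_patient_on_off(s, "tremor")$statistic,
               per_patient_on_off(s3, "tremor")$statistic)
})

test_that("dose-responsive simulant shows OFF-dominant diary tremor", {
  d <- simulate_patient(archetype_params("DOSE_RESPONSIVE"), 5)
  s <- slot_measures(d)
  r <- per_patient_on_off(s, "tremor")
  expect_equal(r$direction, "OFF")
  expect_lt(r$p_value, 0.05)
})

test_that("identical slot distributions rarely reach significance", {
  set.seed(77)
  sig <- 0L
  for (i in 1:100) {
    s <- mk_slots(runif(10, 0.3, 0.5), runif(10, 0.3, 0.5))
    if (per_patient_on_off(s, "tremor")$significant) sig <- sig + 1L
  }
  expect_lte(sig, 10)
})

test_that("cohort summary counts directions and significance", {
  slots <- list(P1 = mk_slots(c(0.1, 0.1, 0.2), c(0.7, 0.8, 0.9)),
                P2 = mk_slots(c(0.2, 0.2, 0.3), c(0.6, 0.7, 0.8)),
                P3 = mk_slots(c(0.0, 0.1, 0.1), c(0.5, 0.6, 0.7)))
  tab <- cohort_on_off_summary(slots)
  trem <- tab[tab$channel == "tremor", ]
  expect_equal(trem$pct_higher_off, 100)
  expect_equal(trem$n_defined, 3)
  act <- tab[tab$channel == "activity", ]
  expect_equal(act$pct_higher_on, 100)     # activity = 1 - tremor here
})

test_that("dose-responsive cohort has ON-dominant activity", {
  cohort <- simulate_cohort(c(DOSE_RESPONSIVE = 10), 9)
  slots <- lapply(cohort, slot_measures)
  tab <- cohort_on_off_summary(slots)
  expect_gte(tab$pct_higher_on[tab$channel == "activity"], 80)
  expect_gte(tab$pct_higher_off[tab$channel == "tremor"], 80)
})

test_that("null cohort keeps the significance rate near alpha", {
  # a full null: no tremor, dyskinesia or activity coupling to the
  # medication cycle, and a flat activity baseline (the default baseline
  # declines over the day, which is a real ON/OFF confound, not noise)
  cohort <- simulate_cohort(c(DOSE_RESPONSIVE = 10), 31,
                            overrides = list(DOSE_RESPONSIVE = list(
                              p_tremor_off = 0.3, p_tremor_on = 0.3,
                              p_dysk_on = 0.05, p_dysk_off = 0.05,
                              activity_coupling = 0,
                              activity_base_start = 0.45,
                              activity_base_end = 0.45)))
  slots <- lapply(cohort, slot_measures)
  tab <- cohort_on_off_summary(slots)
  # 10 patients: at alpha = 0.05, >3 significant would be very surprising
  expect_lte(max(tab$pct_significant), 30)
})
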