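# Independent brute-force oracles. These deliberately use per-sample loops
# and first-principles formulas so they share no code with the package
# implementations they check.

ts_at <- function(date, secs) {
  as.POSIXct(paste(date, "00:00:00"), tz = "UTC") + secs
}

# worn test for a single timestamp against a mask, by explicit scan
oracle_worn <- function(t, mask) {
  for (i in seq_len(nrow(mask)))
    if (t >= mask$start[i] && t < mask$end[i]) return(TRUE)
  FALSE
}

oracle_daily_prevalence <- function(stream, mask, date, min_bins = 120L) {
  n <- 0L; hits <- 0L
  d0 <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  for (i in seq_len(nrow(stream))) {
    t <- stream$timestamp[i]
    if (t >= d0 && t < d0 + 86400 && oracle_worn(t, mask)) {
      n <- n + 1L
      if (stream$value[i] == 1) hits <- hits + 1L
    }
  }
  if (n < min_bins) return(NA_real_)
  hits / n
}

oracle_slot_tremor <- function(stream, slot_start) {
  n <- 0L; hits <- 0L
  for (i in seq_len(nrow(stream))) {
    t <- stream$timestamp[i]
    if (t >= slot_start && t < slot_start + 1800) {
      n <- n + 1L
      if (stream$value[i] == 1) hits <- hits + 1L
    }
  }
  if (n == 0) return(NA_real_)
  hits / n
}

oracle_hourly <- function(stream, mask, date) {
  d0 <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  n <- integer(24); hits <- integer(24)
  for (i in seq_len(nrow(stream))) {
    t <- stream$timestamp[i]
    if (t < d0 || t >= d0 + 86400 || !oracle_worn(t, mask)) next
    h <- floor(as.numeric(t - d0, units = "secs") / 3600) + 1
    n[h] <- n[h] + 1L
    if (stream$value[i] == 1) hits[h] <- hits[h] + 1L
  }
  ifelse(n > 0, hits / n, NA_real_)
}

# per-sample assignment of stream samples to (interval, bin) cells
oracle_phase_bins <- function(stream, intervals, n_bins = 10L,
                              min_coverage_frac = 0.1) {
  K <- nrow(intervals)
  n <- hits <- matrix(0L, K, n_bins)
  for (i in seq_len(nrow(stream))) {
    t <- as.numeric(stream$timestamp[i])
    for (k in seq_len(K)) {
      if (!intervals$valid[k]) next
      s0 <- as.numeric(intervals$start[k]); s1 <- as.numeric(intervals$end[k])
      if (t < s0 || t >= s1) next
      bw <- (s1 - s0) / n_bins
      b <- min(floor((t - s0) / bw) + 1, n_bins)
      n[k, b] <- n[k, b] + 1L
      if (stream$value[i] == 1) hits[k, b] <- hits[k, b] + 1L
    }
  }
  mat <- matrix(NA_real_, K, n_bins)
  for (k in seq_len(K)) {
    if (!intervals$valid[k]) next
    bw <- (as.numeric(intervals$end[k]) - as.numeric(intervals$start[k])) /
      n_bins
    for (b in seq_len(n_bins))
      if (n[k, b] * 30 >= min_coverage_frac * bw)
        mat[k, b] <- hits[k, b] / n[k, b]
  }
  mat
}

# Welch two-sample t from the textbook formula
oracle_welch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(statistic = t, p = 2 * pt(-abs(t), df))
}

# Spearman rho as Pearson correlation of midranks, from first principles
oracle_spearman <- function(x, y) {
  midrank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) r[i] <- (sum(v < v[i]) + 1 + sum(v <= v[i])) / 2
    r
  }
  rx <- midrank(x); ry <- midrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# A random synthetic day with wear gaps, for oracle-equivalence checks:
# 30-s tremor samples, 5-s activity samples, a plausible dose schedule.
random_day <- function(seed, date = as.Date("2024-05-06")) {
  set.seed(seed)
  d0 <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  # 1-3 worn blocks between 07:00 and 22:00
  nblk <- sample(1:3, 1)
  edges <- sort(round(runif(2 * nblk, 7 * 3600, 22 * 3600) / 30) * 30)
  blocks <- matrix(edges, ncol = 2, byrow = TRUE)
  blocks <- blocks[blocks[, 2] - blocks[, 1] >= 1800, , drop = FALSE]
  if (nrow(blocks) == 0) blocks <- matrix(c(8, 20) * 3600, ncol = 2)
  secs <- unlist(apply(blocks, 1, function(b) seq(b[1], b[2] - 30, by = 30),
                       simplify = FALSE))
  trem <- pdhbm::symptom_stream(d0 + secs, rbinom(length(secs), 1, runif(1)),
                                "TREMOR")
  asec <- unlist(apply(blocks, 1, function(b) seq(b[1], b[2] - 5, by = 5),
                       simplify = FALSE))
  act <- pdhbm::activity_stream(d0 + asec, runif(length(asec)))
  doses <- sort(runif(sample(3:5, 1), 8 * 3600, 19 * 3600))
  meds <- pdhbm::medication_log(rep(date, length(doses)),
                                seq_along(doses), d0 + doses, d0 + doses,
                                rep(100, length(doses)))
  list(date = date, tremor = trem, activity = act, meds = meds)
}

# small deterministic simulants for pipeline tests (3 days to stay fast)
tiny_params <- function(arch = "DOSE_RESPONSIVE", ...) {
  pdhbm::archetype_params(arch, days = 3L, ...)
}

empty_meds <- function() {
  pdhbm::medication_log(as.Date(character(0)), integer(0),
                        pdhbm::hbm_time(character(0)),
                        pdhbm::hbm_time(character(0)), numeric(0))
}

empty_tasks <- function() {
  pdhbm::motor_tasks(pdhbm::hbm_time(character(0)), character(0),
                     character(0))
}

# hand-built slot-measure table for ON/OFF testing
mk_slots <- function(on, off, state_on = "ON") {
  n <- length(on) + length(off)
  out <- data.frame(
    slot_start = pdhbm::hbm_time("2024-03-05T08:00:00") +
      seq_len(n) * 1800 - 1800,
    state = c(rep(state_on, length(on)), rep("OFF", length(off))),
    tremor_pct = c(on, off), dysk_pct = c(on, off) / 2,
    activity_mean = 1 - c(on, off), coverage = 1, excluded = FALSE)
  class(out) <- c("slot_measures", "data.frame")
  out
}
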