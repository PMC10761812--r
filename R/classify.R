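#' Classifier feature: phase-modulation index
#'
#' Quantifies how strongly tremor concentrates around medication intakes:
#' for each usable interval row of the signature (at least
#' `min_cells` defined cells), the mean tremor fraction in the peri-dose
#' bins (bins 9, 10 and 1 — just before and just after an intake) minus
#' the mean in the mid-interval bins (4-7, the levodopa plateau); the
#' index is the average over usable rows. Positive values mean
#' wearing-off tremor.
#'
#' @param sig a [phase_signature()].
#' @param min_cells minimum defined cells for a usable row (default 8).
#' @return index in \[-1,1\], or `NA` when no row is usable.
#' @export
phase_modulation_index <- function(sig, min_cells = 8L) {
  if (is.null(sig$tremor)) return(NA_real_)
  peri <- c(9, 10, 1); mid <- 4:7
  vals <- apply(sig$tremor, 1, function(row) {
    if (sum(!is.na(row)) < min_cells) return(NA_real_)
    p <- mean(row[peri], na.rm = TRUE); m <- mean(row[mid], na.rm = TRUE)
    if (is.nan(p) || is.nan(m)) return(NA_real_)
    p - m
  })
  if (all(is.na(vals))) return(NA_real_)
  mean(vals, na.rm = TRUE)
}

#' Classifier feature: time-of-day index
#'
#' Afternoon (12:00-20:00) minus morning (08:00-12:00) mean tremor
#' prevalence, averaged over days where both halves have worn data.
#' Positive values mean afternoon-dominant tremor.
#'
#' @param profiles days x 24 matrix of [hourly_profile()] vectors.
#' @param min_days minimum usable days (default 5).
#' @return index in \[-1,1\], or `NA` when fewer than `min_days` days are
#'   usable.
#' @export
time_of_day_index <- function(profiles, min_days = 5L) {
  if (nrow(profiles) == 0) return(NA_real_)
  per_day <- apply(profiles, 1, function(h) {
    morning <- h[9:12]          # hours 8-11
    afternoon <- h[13:20]       # hours 12-19
    if (all(is.na(morning)) || all(is.na(afternoon))) return(NA_real_)
    mean(afternoon, na.rm = TRUE) - mean(morning, na.rm = TRUE)
  })
  if (sum(!is.na(per_day)) < min_days) return(NA_real_)
  mean(per_day, na.rm = TRUE)
}

#' Classifier feature: day-to-day consistency
#'
#' Mean pairwise Pearson correlation between the days' hourly tremor
#' profiles, over the hours defined in both days of a pair. Pairs where
#' both vectors have zero variance count as correlation 1 (identically
#' flat days are perfectly consistent); pairs where exactly one vector is
#' constant are skipped.
#'
#' @inheritParams time_of_day_index
#' @param min_hours minimum common defined hours per pair (default 3).
#' @return mean correlation in \[-1,1\], `NA` when fewer than `min_days`
#'   usable days or fewer than 2 scorable pairs.
#' @export
day_consistency <- function(profiles, min_days = 5L, min_hours = 3L) {
  usable <- which(rowSums(!is.na(profiles)) >= 2)
  if (length(usable) < min_days) return(NA_real_)
  cors <- c()
  for (i in seq_along(usable)) for (j in seq_len(i - 1)) {
    a <- profiles[usable[i], ]; b <- profiles[usable[j], ]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < min_hours) next
    va <- stats::var(a[ok]); vb <- stats::var(b[ok])
    if (va == 0 && vb == 0) { cors <- c(cors, 1); next }
    if (va == 0 || vb == 0) next
    cors <- c(cors, stats::cor(a[ok], b[ok]))
  }
  if (length(cors) < 2) return(NA_real_)
  mean(cors)
}

#' Extract the four classifier features for a patient
#'
#' @param dataset a [patient_dataset()].
#' @param config an [hbm_config()].
#' @return list of class `fluctuation_features` with `P` (overall tremor
#'   prevalence), `PMI`, `TDI`, `C`, and `reasons` for any `NA` feature.
#' @export
fluctuation_features <- function(dataset, config = hbm_config()) {
  ds <- daily_scores(dataset, config)
  P <- overall_scores(ds)$overall_tremor
  sig <- phase_signature(dataset, config)
  profiles <- hourly_profiles(dataset, config)
  PMI <- phase_modulation_index(sig)
  TDI <- time_of_day_index(profiles)
  C <- day_consistency(profiles)
  reasons <- character(0)
  if (is.na(P)) reasons <- c(reasons, "no defined daily prevalence")
  if (is.na(PMI)) reasons <- c(reasons, "no usable signature row")
  if (is.na(TDI)) reasons <- c(reasons, "too few days with both halves worn")
  if (is.na(C)) reasons <- c(reasons, "too few comparable day pairs")
  structure(list(P = P, PMI = PMI, TDI = TDI, C = C, reasons = reasons),
            class = "fluctuation_features")
}

#' Classification thresholds
#'
#' @param theta_const minimum overall prevalence for CONSTANT (0.60).
#' @param theta_pmi minimum phase-modulation index for DOSE_RESPONSIVE
#'   (0.15).
#' @param theta_tdi minimum |time-of-day index| for TIME_OF_DAY (0.20).
#' @param theta_c minimum day-consistency for TIME_OF_DAY (0.30).
#' @return named list of class `profile_thresholds`.
#' @export
profile_thresholds <- function(theta_const = 0.60, theta_pmi = 0.15,
                               theta_tdi = 0.20, theta_c = 0.30) {
  th <- list(theta_const = theta_const, theta_pmi = theta_pmi,
             theta_tdi = theta_tdi, theta_c = theta_c)
  assert_that(all(vapply(th, function(v) is.numeric(v) && length(v) == 1 &&
                           is.finite(v), logical(1))),
              "thresholds must be single finite numbers")
  class(th) <- "profile_thresholds"
  th
}

#' Assign one of the four motor-fluctuation profiles
#'
#' Ordered rules over the feature vector:
#' 1. `P >= theta_const` and `PMI < theta_pmi` -> `CONSTANT`
#'    (tremor most of the day, not dose-modulated);
#' 2. `PMI >= theta_pmi` -> `DOSE_RESPONSIVE`;
#' 3. `|TDI| >= theta_tdi` and `C >= theta_c` -> `TIME_OF_DAY`
#'    (a reproducible part-of-day pattern);
#' 4. otherwise `IRREGULAR`.
#' Any `NA` feature yields `UNCLASSIFIABLE` with the reason.
#'
#' @param features a [fluctuation_features()] object.
#' @param thresholds a [profile_thresholds()] object.
#' @return list of class `profile_label` with `label`, `features`,
#'   `thresholds`.
#' @export
classify_profile <- function(features, thresholds = profile_thresholds()) {
  assert_that(inherits(thresholds, "profile_thresholds"),
              "thresholds must come from profile_thresholds()")
  f <- features
  label <- if (anyNA(c(f$P, f$PMI, f$TDI, f$C))) {
    "UNCLASSIFIABLE"
  } else if (f$P >= thresholds$theta_const && f$PMI < thresholds$theta_pmi) {
    "CONSTANT"
  } else if (f$PMI >= thresholds$theta_pmi) {
    "DOSE_RESPONSIVE"
  } else if (abs(f$TDI) >= thresholds$theta_tdi && f$C >= thresholds$theta_c) {
    "TIME_OF_DAY"
  } else "IRREGULAR"
  structure(list(label = label, features = features, thresholds = thresholds),
            class = "profile_label")
}

#' @export
print.profile_label <- function(x, ...) {
  f <- x$features
  cat(sprintf("<profile_label> %s  (P = %.2f, PMI = %.2f, TDI = %.2f, C = %.2f)\n",
              x$label, f$P, f$PMI, f$TDI, f$C))
  if (x$label == "UNCLASSIFIABLE")
    cat("  reasons:", paste(f$reasons, collapse = "; "), "\n")
  invisible(x)
}

#' Threshold-sensitivity report for the profile classifier
#'
#' Re-labels a classified cohort while perturbing each threshold by
#' `+/- factor` (one at a time) and reports the archetype-recovery rate
#' under every perturbation. Documents how robust the rule set is to the
#' exact cut-offs; it is a report, not a gate.
#'
#' @param profiles a [classify_cohort()] table (needs columns `P`, `PMI`,
#'   `TDI`, `C` and `archetype`).
#' @param thresholds baseline [profile_thresholds()].
#' @param factor relative perturbation (default 0.25).
#' @return data.frame with `threshold`, `direction`, `value`, `recovery`.
#' @export
threshold_sensitivity <- function(profiles, thresholds = profile_thresholds(),
                                  factor = 0.25) {
  assert_that(all(c("P", "PMI", "TDI", "C", "archetype") %in%
                    names(profiles)), "profiles table lacks feature columns")
  relabel <- function(th) {
    labs <- vapply(seq_len(nrow(profiles)), function(i) {
      f <- structure(list(P = profiles$P[i], PMI = profiles$PMI[i],
                          TDI = profiles$TDI[i], C = profiles$C[i],
                          reasons = character(0)),
                     class = "fluctuation_features")
      classify_profile(f, th)$label
    }, character(1))
    mean(labs == profiles$archetype)
  }
  rows <- list()
  for (nm in names(unclass(thresholds))) {
    for (dir in c(-1, 1)) {
      th <- thresholds
      th[[nm]] <- thresholds[[nm]] * (1 + dir * factor)
      rows[[length(rows) + 1]] <- data.frame(
        threshold = nm, direction = if (dir < 0) "down" else "up",
        value = th[[nm]], recovery = relabel(th))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify a whole cohort
#'
#' @param datasets named list of [patient_dataset()] objects.
#' @param config an [hbm_config()].
#' @param thresholds a [profile_thresholds()].
#' @return data.frame with `patient_id`, `label`, `P`, `PMI`, `TDI`, `C`
#'   (and `archetype` when the datasets carry simulator ground truth).
#' @export
classify_cohort <- function(datasets, config = hbm_config(),
                            thresholds = profile_thresholds()) {
  rows <- lapply(datasets, function(d) {
    f <- fluctuation_features(d, config)
    lab <- classify_profile(f, thresholds)
    data.frame(patient_id = d$patient_id, label = lab$label,
               P = f$P, PMI = f$PMI, TDI = f$TDI, C = f$C,
               archetype = d$meta$archetype %||% NA_character_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
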