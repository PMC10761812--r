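#' Longitudinal raster plot of a patient's monitoring period
#'
#' One row per study day (first day on top), x from midnight to midnight.
#' Dark blue ticks mark 30-s tremor detections, the light blue trace shows
#' the activity level, bold green verticals the reported medication
#' intakes, gray shading the non-worn periods, and the two diary days get
#' a green (ON) / red (OFF) slot background.
#'
#' Every rendered element is also returned (and optionally written) as a
#' machine-readable sidecar list so figures can be tested without pixel
#' comparison.
#'
#' @param dataset a [patient_dataset()].
#' @param file optional PNG path; when given, the sidecar JSON is written
#'   next to it as `<file>.json`.
#' @param config an [hbm_config()].
#' @return the sidecar list, invisibly.
#' @export
plot_raster <- function(dataset, file = NULL, config = hbm_config()) {
  assert_that(nrow(dataset$tremor) > 0, "empty dataset: no tremor samples")
  mask <- infer_wear_mask(dataset$tremor, config$gap_threshold_s)
  days <- seq(hbm_date(min(mask$start)), hbm_date(max(mask$end) - 1), by = "day")
  n <- length(days)
  sidecar <- list(patient_id = dataset$patient_id, n_days = n,
                  tremor_marks = list(), medication_lines = list(),
                  nonwear = list(), diary_background = list(),
                  activity_points = 0)
  if (!is.null(file)) {
    grDevices::png(file, width = 1000, height = 80 * n + 120, res = 110)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  op <- graphics::par(mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  graphics::plot(NULL, xlim = c(0, 24), ylim = c(n + 0.5, 0.5),
                 xlab = "time of day [h]", ylab = "study day",
                 main = dataset$patient_id, xaxs = "i", yaxs = "i", axes = FALSE)
  graphics::axis(1, at = seq(0, 24, 4)); graphics::axis(2, at = seq_len(n))
  graphics::box()
  for (d in seq_len(n)) {
    d0 <- day_start(days[d]); d1 <- d0 + 86400
    y0 <- d + 0.45; y1 <- d - 0.45
    # diary background
    di <- dataset$diary[hbm_date(dataset$diary$slot_start) == days[d] &
                          dataset$diary$state %in% c("ON", "ON_DYSK", "OFF"), ,
                        drop = FALSE]
    for (j in seq_len(nrow(di))) {
      h0 <- secs_of_day(di$slot_start[j]) / 3600
      col <- if (di$state[j] == "OFF") grDevices::adjustcolor("red", 0.25)
        else grDevices::adjustcolor("green3", 0.25)
      graphics::rect(h0, y0, h0 + 0.5, y1, col = col, border = NA)
      sidecar$diary_background[[length(sidecar$diary_background) + 1]] <-
        list(day = d, hour = h0, state = di$state[j])
    }
    # non-wear shading: complement of the mask within the day
    worn <- mask[mask$end > d0 & mask$start < d1, , drop = FALSE]
    cuts <- c(0, as.vector(t(cbind(pmax(secs_of_day(worn$start), 0),
                                   pmin(as.numeric(worn$end) - as.numeric(d0),
                                        86400)))), 86400) / 3600
    for (j in seq(1, length(cuts) - 1, by = 2)) {
      if (cuts[j + 1] > cuts[j]) {
        graphics::rect(cuts[j], y0, cuts[j + 1], y1,
                       col = grDevices::adjustcolor("gray", 0.5), border = NA)
        sidecar$nonwear[[length(sidecar$nonwear) + 1]] <-
          list(day = d, from = cuts[j], to = cuts[j + 1])
      }
    }
    # tremor ticks
    tr <- slice_window(dataset$tremor, d0, d1)
    tk <- secs_of_day(tr$timestamp[tr$value == 1]) / 3600
    if (length(tk))
      graphics::segments(tk, d + 0.35, tk, d - 0.05, col = "navy", lwd = 0.4)
    sidecar$tremor_marks[[d]] <- length(tk)
    # activity trace within the lower half of the row
    ac <- slice_window(dataset$activity, d0, d1)
    if (nrow(ac) > 0) {
      step <- max(1, floor(nrow(ac) / 600))  # thin for drawing only
      ai <- seq(1, nrow(ac), by = step)
      graphics::lines(secs_of_day(ac$timestamp[ai]) / 3600,
                      d + 0.45 - 0.4 * ac$value[ai], col = "skyblue3",
                      lwd = 0.6)
      sidecar$activity_points <- sidecar$activity_points + nrow(ac)
    }
    # medication lines
    md <- dataset$medications[dataset$medications$date == days[d] &
                                !is.na(dataset$medications$reported_time), ,
                              drop = FALSE]
    mh <- secs_of_day(md$reported_time) / 3600
    if (length(mh))
      graphics::segments(mh, y0, mh, y1, col = "green4", lwd = 2)
    sidecar$medication_lines[[d]] <- mh
  }
  if (!is.null(file))
    jsonlite::write_json(sidecar, paste0(file, ".json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(sidecar)
}

#' Phase-signature bar plot
#'
#' Dark blue bars show the average tremor fraction for each of the 10
#' bins of every inter-dose interval; the light blue line overlays the
#' average activity level; green verticals separate the dose intervals.
#' All-missing intervals are omitted. Bar heights are returned as a
#' sidecar list identical to the signature cells.
#'
#' @param sig a [phase_signature()]; an undefined signature is an error.
#' @param file optional PNG path (sidecar JSON written as `<file>.json`).
#' @return sidecar list, invisibly.
#' @export
plot_phase_bars <- function(sig, file = NULL) {
  assert_that(!is.null(sig$tremor), "undefined phase signature")
  keep <- which(rowSums(!is.na(sig$tremor)) > 0)
  assert_that(length(keep) > 0, "all intervals missing")
  nb <- ncol(sig$tremor)
  heights <- as.vector(t(sig$tremor[keep, , drop = FALSE]))
  act <- as.vector(t(sig$activity[keep, , drop = FALSE]))
  sidecar <- list(patient_id = sig$patient_id, n_bins = nb,
                  intervals = as.integer(rownames(sig$tremor)[keep]),
                  tremor = heights, activity = act,
                  days_used = sig$days_used)
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 420, res = 110)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  op <- graphics::par(mar = c(4, 4, 2, 4))
  on.exit(graphics::par(op), add = TRUE)
  bx <- graphics::barplot(ifelse(is.na(heights), 0, heights),
                          col = "navy", border = NA, ylim = c(0, 1),
                          ylab = "avg tremor fraction",
                          xlab = sprintf("inter-dose interval phase (%d bins each)", nb),
                          main = sig$patient_id %||% "")
  for (k in seq_along(keep)[-1])
    graphics::abline(v = (bx[(k - 1) * nb] + bx[(k - 1) * nb + 1]) / 2,
                     col = "green4", lwd = 2)
  ok <- !is.na(act)
  graphics::lines(bx[ok], act[ok], col = "skyblue3", lwd = 2)
  graphics::axis(4, at = seq(0, 1, 0.25))
  graphics::mtext("avg activity level", side = 4, line = 2.5, cex = 0.9)
  if (!is.null(file))
    jsonlite::write_json(sidecar, paste0(file, ".json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(sidecar)
}
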