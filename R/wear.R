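#' Infer the wear mask from sampling continuity
#'
#' The watch emits a sample for every window while worn, so non-wear shows
#' up as gaps in the stream. Any inter-sample gap larger than
#' `gap_threshold_s` splits the worn time; each worn interval spans its
#' samples plus one trailing window (a sample summarises the window that
#' starts at its timestamp).
#'
#' @param stream a [symptom_stream()] or [activity_stream()].
#' @param gap_threshold_s split threshold in seconds; defaults to three
#'   windows (90 s for the 30-s channels, 15 s for the 5-s channel). Must
#'   exceed the window length.
#' @return data.frame of class `wear_mask` with POSIXct columns
#'   `start`, `end` (half-open intervals, disjoint, sorted). An empty
#'   stream yields an empty mask.
#' @export
infer_wear_mask <- function(stream, gap_threshold_s = NULL) {
  w <- attr(stream, "window_seconds")
  assert_that(!is.null(w), "stream has no window_seconds attribute")
  gap_threshold_s <- gap_threshold_s %||% (3 * w)
  assert_that(gap_threshold_s > w,
              "gap_threshold_s (%s) must exceed the window length (%s)",
              gap_threshold_s, w)
  ts <- as.numeric(stream$timestamp)
  if (length(ts) == 0) return(new_wear_mask(numeric(0), numeric(0)))
  assert_that(all(diff(ts) > 0), "stream timestamps not strictly increasing")
  brk <- which(diff(ts) > gap_threshold_s)
  first <- c(1L, brk + 1L)
  last <- c(brk, length(ts))
  new_wear_mask(ts[first], ts[last] + w)
}

new_wear_mask <- function(start, end) {
  out <- data.frame(
    start = as.POSIXct(as.numeric(start), origin = "1970-01-01", tz = .HBM_TZ),
    end = as.POSIXct(as.numeric(end), origin = "1970-01-01", tz = .HBM_TZ)
  )
  if (nrow(out) > 1) {
    assert_that(all(diff(as.numeric(out$start)) > 0), "mask not sorted")
    assert_that(all(out$start[-1] >= out$end[-nrow(out)]),
                "mask intervals overlap")
  }
  assert_that(all(as.numeric(out$end) > as.numeric(out$start)),
              "mask interval with non-positive length")
  class(out) <- c("wear_mask", "data.frame")
  out
}

#' Slice a stream to a half-open time window
#'
#' Returns exactly the samples with `start <= timestamp < end`.
#'
#' @param stream a symptom or activity stream.
#' @param start,end POSIXct bounds, `start < end`.
#' @return stream of the same class (attributes preserved).
#' @export
slice_window <- function(stream, start, end) {
  start <- hbm_time(start); end <- hbm_time(end)
  assert_that(as.numeric(start) < as.numeric(end),
              "slice_window: start must precede end")
  keep <- stream$timestamp >= start & stream$timestamp < end
  out <- stream[keep, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)[c("channel", "window_seconds")] <-
    attributes(stream)[c("channel", "window_seconds")]
  class(out) <- class(stream)
  out
}

# Seconds of worn time inside [start, end).
worn_seconds <- function(mask, start, end) {
  if (nrow(mask) == 0) return(0)
  s <- pmax(as.numeric(mask$start), as.numeric(start))
  e <- pmin(as.numeric(mask$end), as.numeric(end))
  sum(pmax(e - s, 0))
}

# Worn seconds per calendar day, over the mask's full span.
worn_seconds_by_day <- function(mask) {
  if (nrow(mask) == 0)
    return(data.frame(date = as.Date(character(0)), seconds = numeric(0)))
  days <- seq(hbm_date(min(mask$start)), hbm_date(max(mask$end) - 1), by = "day")
  secs <- vapply(days, function(d) {
    worn_seconds(mask, day_start(d), day_start(d) + 86400)
  }, numeric(1))
  data.frame(date = days, seconds = secs)
}
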