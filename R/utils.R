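# Time handling: all timestamps are naive local datetimes. They are stored
# as POSIXct in the UTC ruler so that arithmetic is purely calendrical
# (no DST jumps), matching the platform's local-clock export format.

.HBM_TZ <- "UTC"

#' Parse ISO-8601 local datetimes
#'
#' Accepts `"2024-03-01T08:00:00"` or `"2024-03-01 08:00:00"`; empty strings
#' and `NA` become `NA` (the MISSING convention of the CSV schemas).
#'
#' @param x character vector (or POSIXct, returned as-is after tz
#'   normalisation).
#' @return POSIXct vector.
#' @export
hbm_time <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- .HBM_TZ
    return(x)
  }
  x <- as.character(x)
  x[!is.na(x) & !nzchar(trimws(x))] <- NA_character_
  x <- sub("T", " ", x, fixed = TRUE)
  out <- as.POSIXct(x, tz = .HBM_TZ, format = "%Y-%m-%d %H:%M:%S")
  # tolerate date-hour-minute without seconds
  miss <- is.na(out) & !is.na(x)
  if (any(miss)) {
    out[miss] <- as.POSIXct(x[miss], tz = .HBM_TZ, format = "%Y-%m-%d %H:%M")
  }
  out
}

#' Format datetimes back to the ISO-8601 schema form
#' @param x POSIXct vector.
#' @return character vector; `NA` becomes the empty string (MISSING).
#' @export
hbm_time_format <- function(x) {
  out <- format(x, "%Y-%m-%dT%H:%M:%S", tz = .HBM_TZ)
  out[is.na(x)] <- ""
  out
}

# Calendar day (local midnight boundary) of a timestamp.
hbm_date <- function(x) as.Date(x, tz = .HBM_TZ)

# Midnight starting a given Date, as POSIXct (length-0 safe).
day_start <- function(d)
  as.POSIXct(as.numeric(as.Date(d)) * 86400, origin = "1970-01-01",
             tz = .HBM_TZ)

# Seconds since local midnight.
secs_of_day <- function(x) as.numeric(x) - as.numeric(day_start(hbm_date(x)))

# Combine a Date and "HH:MM[:SS]" clock string.
at_clock <- function(d, clock) {
  clock <- ifelse(nchar(clock) == 5, paste0(clock, ":00"), clock)
  as.POSIXct(paste(as.character(d), clock), tz = .HBM_TZ)
}

# Minutes between two POSIXct (b - a).
mins_between <- function(a, b) as.numeric(b) / 60 - as.numeric(a) / 60

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_hbm <- function(...) stop(sprintf(...), call. = FALSE)

assert_that <- function(cond, ...) if (!isTRUE(cond)) stop_hbm(...)

# Preserve the caller's RNG state while running seeded simulation code.
with_seed <- function(seed, code) {
  assert_that(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
              "seed must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
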