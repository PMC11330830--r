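#' Define an LD/DD light schedule
#'
#' Describes the lighting protocol of a DAM experiment: `ld_days` of
#' entrained light-dark cycles followed by `dd_days` of constant darkness.
#' Zeitgeber time 0 (ZT0) is lights-on; recordings handled by this package
#' start at ZT0 of the first LD day.
#'
#' @param lights_on,lights_off Clock times as `"hh:mm"` strings. `lights_on`
#'   must precede `lights_off` within the day; any photoperiod is accepted
#'   (the canonical protocol is 12:12).
#' @param ld_days,dd_days Whole days spent in light-dark cycles and in
#'   constant darkness.
#'
#' @return A `light_schedule` object (a named list with `lights_on_min`,
#'   `lights_off_min`, `photoperiod_min`, `ld_days`, `dd_days`).
#' @examples
#' light_schedule("08:00", "20:00", ld_days = 3, dd_days = 7)
#' @export
light_schedule <- function(lights_on = "08:00", lights_off = "20:00",
                           ld_days = 3, dd_days = 7) {
  on_min <- parse_clock(lights_on)
  off_min <- parse_clock(lights_off)
  if (off_min <= on_min) {
    stop("`lights_on` must precede `lights_off` within the day", call. = FALSE)
  }
  if (ld_days < 0 || dd_days < 0) {
    stop("`ld_days` and `dd_days` must be non-negative", call. = FALSE)
  }
  structure(
    list(
      lights_on_min = on_min,
      lights_off_min = off_min,
      photoperiod_min = off_min - on_min,
      ld_days = as.integer(ld_days),
      dd_days = as.integer(dd_days)
    ),
    class = "light_schedule"
  )
}

parse_clock <- function(x) {
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})$", x))[[1]]
  if (length(m) != 3) stop("clock time must be 'hh:mm', got '", x, "'", call. = FALSE)
  h <- as.integer(m[2]); mi <- as.integer(m[3])
  if (h > 23 || mi > 59) stop("invalid clock time '", x, "'", call. = FALSE)
  h * 60L + mi
}

#' @export
print.light_schedule <- function(x, ...) {
  cat(sprintf(
    "<light_schedule> lights on %s, off %s (photoperiod %.1f h); %d LD day(s) + %d DD day(s)\n",
    fmt_clock(x$lights_on_min), fmt_clock(x$lights_off_min),
    x$photoperiod_min / 60, x$ld_days, x$dd_days
  ))
  invisible(x)
}

fmt_clock <- function(min) sprintf("%02d:%02d", min %/% 60L, min %% 60L)

n_days <- function(schedule) schedule$ld_days + schedule$dd_days

#' Experimental phase of each time bin
#'
#' Labels bins `L` (lights on) or `D` (lights off) during the LD days and
#' `DD` throughout constant darkness. Bin 0 starts at ZT0 of LD day 1; bins
#' are half-open `[t, t + bin)` and a bin takes the label of its first
#' minute.
#'
#' @param schedule A [light_schedule()].
#' @param n_bins Number of bins to label.
#' @param bin_minutes Bin width in minutes.
#' @return Character vector of length `n_bins` over `{"L", "D", "DD"}`.
#' @export
phase_of_bins <- function(schedule, n_bins, bin_minutes = 1L) {
  start_min <- (seq_len(n_bins) - 1L) * bin_minutes
  day <- start_min %/% 1440L
  zt <- start_min %% 1440L
  dplyr::case_when(
    day >= schedule$ld_days ~ "DD",
    zt < schedule$photoperiod_min ~ "L",
    .default = "D"
  )
}
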