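#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

# Activity tables are plain tibbles in long format -- one row per fly per
# time bin -- with columns fly_id, genotype, minute (bin start, minutes from
# ZT0 of LD day 1, 0-based), phase (L/D/DD) and count. The bin width and the
# light schedule ride along as attributes; every accessor falls back to
# re-deriving the bin width from the data so dplyr verbs that strip
# attributes do not break downstream calls.
new_dam_activity <- function(tbl, bin_minutes, schedule) {
  out <- as_tibble(tbl)
  attr(out, "bin_minutes") <- as.integer(bin_minutes)
  attr(out, "schedule") <- schedule
  class(out) <- unique(c("dam_activity", class(out)))
  out
}

#' Bin width of an activity table
#'
#' @param activity An activity tibble as returned by [read_dam()] or
#'   [simulate_group()].
#' @return Bin width in minutes (inferred from the `minute` column when the
#'   attribute has been stripped by data-frame operations).
#' @export
bin_minutes <- function(activity) {
  bw <- attr(activity, "bin_minutes")
  if (!is.null(bw)) return(as.integer(bw))
  mins <- sort(unique(activity$minute))
  if (length(mins) < 2) return(1L)
  as.integer(min(diff(mins)))
}

#' Light schedule attached to an activity table
#'
#' @inheritParams bin_minutes
#' @return The [light_schedule()] the table was built with.
#' @export
activity_schedule <- function(activity) {
  sch <- attr(activity, "schedule")
  if (is.null(sch)) {
    stop("activity table has lost its schedule attribute; ",
         "rebuild it with `as_dam_activity()`", call. = FALSE)
  }
  sch
}

#' Rebuild an activity table from a plain data frame
#'
#' Reattaches the bin width and schedule metadata after data-frame
#' operations that drop attributes.
#'
#' @param x Data frame with columns `fly_id`, `genotype`, `minute`, `count`
#'   (and optionally `phase`, which is recomputed if absent).
#' @param schedule A [light_schedule()].
#' @param bin_minutes Bin width in minutes.
#' @return An activity tibble.
#' @export
as_dam_activity <- function(x, schedule, bin_minutes = 1L) {
  need <- c("fly_id", "genotype", "minute", "count")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- as_tibble(x)
  if (!"phase" %in% names(x)) {
    x$phase <- dplyr::case_when(
      x$minute %/% 1440L >= schedule$ld_days ~ "DD",
      x$minute %% 1440L < schedule$photoperiod_min ~ "L",
      .default = "D"
    )
  }
  new_dam_activity(x[, c("fly_id", "genotype", "minute", "phase", "count")],
                   bin_minutes, schedule)
}

# One fly's counts ordered by time, as a named list of vectors.
split_by_fly <- function(activity) {
  ord <- order(activity$fly_id, activity$minute)
  split(activity$count[ord], activity$fly_id[ord])
}

fly_table <- function(activity) {
  dplyr::distinct(as_tibble(activity)[, c("fly_id", "genotype")])
}

# ---------------------------------------------------------------------------
# TriKinetics monitor dialect
#
# Tab-delimited text, one row per minute. Columns consumed:
#   1  reading index (integer)
#   2  date, "dd Mon yy" with English month abbreviations
#   3  time, "hh:mm:ss"
#   4  monitor status code (written as 1, ignored on read)
#   5  light sensor value (written as 0/1 from the schedule, ignored on read)
#   6..37  beam-cross counts for channels 1..32
# Any further columns are ignored.

.dam_months <- c("Jan", "Feb", "Mar", "Apr", "May", "Jun",
                 "Jul", "Aug", "Sep", "Oct", "Nov", "Dec")

#' Read a TriKinetics-style DAM monitor file
#'
#' Parses a tab-delimited monitor file recorded at 1-minute resolution and
#' returns a long activity tibble with one row per mapped channel per
#' minute. The recording must start at lights-on (ZT0) of LD day 1 of
#' `schedule`; phases are assigned from the schedule. Channels absent from
#' `channel_map` are dropped.
#'
#' @param path Path to the monitor file.
#' @param schedule A [light_schedule()].
#' @param channel_map Named character vector mapping channel numbers to
#'   genotype labels, e.g. `c("1" = "wild_type", "2" = "pink1_b9")`.
#' @return An activity tibble (`fly_id`, `genotype`, `minute`, `phase`,
#'   `count`) at 1-minute bins.
#' @seealso [write_dam()] for the inverse operation.
#' @export
read_dam <- function(path, schedule, channel_map) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty DAM file: ", path, call. = FALSE)

  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  bad <- which(ncol < 37L)
  if (length(bad)) {
    stop(sprintf("malformed DAM row at line %d: expected >= 37 tab-separated columns, found %d",
                 bad[1], ncol[bad[1]]), call. = FALSE)
  }

  n <- length(fields)
  mat <- matrix(unlist(lapply(fields, `[`, 1:37)), nrow = n, byrow = TRUE)
  tmins <- dam_time_minutes(mat[, 2], mat[, 3])
  if (n > 1) {
    d <- diff(tmins)
    if (any(d != 1L)) {
      i <- which(d != 1L)[1]
      stop(sprintf("timestamp gap or disorder between lines %d and %d (step of %d min); no interpolation is performed",
                   i, i + 1L, d[i]), call. = FALSE)
    }
  }
  start_clock <- tmins[1] %% 1440L
  if (start_clock != schedule$lights_on_min) {
    stop(sprintf("recording starts at %s but the schedule's lights-on is %s; recordings must start at ZT0",
                 fmt_clock(start_clock), fmt_clock(schedule$lights_on_min)),
         call. = FALSE)
  }

  counts <- matrix(suppressWarnings(as.integer(mat[, 6:37])), nrow = n)
  if (anyNA(counts) || any(counts < 0)) {
    stop("non-integer or negative count encountered", call. = FALSE)
  }

  channels <- as.integer(names(channel_map))
  if (anyNA(channels) || any(channels < 1L | channels > 32L)) {
    stop("`channel_map` names must be channel numbers 1..32", call. = FALSE)
  }
  phase <- phase_of_bins(schedule, n, 1L)
  long <- purrr::map_dfr(seq_along(channels), function(j) {
    ch <- channels[j]
    tibble(
      fly_id = sprintf("ch%02d", ch),
      genotype = unname(channel_map[j]),
      minute = seq_len(n) - 1L,
      phase = phase,
      count = counts[, ch]
    )
  })
  new_dam_activity(long, 1L, schedule)
}

dam_time_minutes <- function(date_str, time_str) {
  dp <- strsplit(date_str, " ", fixed = TRUE)
  day <- suppressWarnings(as.integer(vapply(dp, `[`, "", 1)))
  mon <- match(vapply(dp, `[`, "", 2), .dam_months)
  yr <- suppressWarnings(as.integer(vapply(dp, `[`, "", 3)))
  tp <- strsplit(time_str, ":", fixed = TRUE)
  hh <- suppressWarnings(as.integer(vapply(tp, `[`, "", 1)))
  mm <- suppressWarnings(as.integer(vapply(tp, `[`, "", 2)))
  if (anyNA(day) || anyNA(mon) || anyNA(yr) || anyNA(hh) || anyNA(mm)) {
    stop("unparseable date/time field in DAM file", call. = FALSE)
  }
  # days since an arbitrary epoch; month lengths via Date arithmetic
  d <- as.integer(as.Date(sprintf("20%02d-%02d-%02d", yr, mon, day)))
  d * 1440L + hh * 60L + mm
}

#' Write an activity table as a TriKinetics-style monitor file
#'
#' The inverse of [read_dam()]: emits the 37-column monitor dialect with
#' one row per minute. Flies are assigned to channels 1..n in `fly_id`
#' order; unused channels are written as zero counts.
#'
#' @inheritParams bin_minutes
#' @param path Output file path.
#' @param start_date First-day date as `"yyyy-mm-dd"`.
#' @return `path`, invisibly.
#' @export
write_dam <- function(activity, path, start_date = "2024-01-01") {
  if (bin_minutes(activity) != 1L) {
    stop("DAM files are written at 1-minute resolution", call. = FALSE)
  }
  schedule <- activity_schedule(activity)
  series <- split_by_fly(activity)
  if (length(series) > 32L) stop("a monitor file holds at most 32 channels", call. = FALSE)
  n <- length(series[[1]])
  counts <- matrix(0L, nrow = n, ncol = 32L)
  for (j in seq_along(series)) counts[, j] <- series[[j]]

  t0 <- as.integer(as.Date(start_date)) * 1440L + schedule$lights_on_min
  tmins <- t0 + seq_len(n) - 1L
  dpart <- as.Date(tmins %/% 1440L, origin = "1970-01-01")
  dl <- as.POSIXlt(dpart)
  date_str <- sprintf("%02d %s %02d", dl$mday, .dam_months[dl$mon + 1L], dl$year %% 100L)
  clock <- tmins %% 1440L
  time_str <- sprintf("%02d:%02d:00", clock %/% 60L, clock %% 60L)
  light <- as.integer(phase_of_bins(schedule, n, 1L) == "L")

  rows <- paste(seq_len(n), date_str, time_str, 1L, light,
                apply(counts, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(rows, path)
  invisible(path)
}

#' Rebin an activity table to coarser time bins
#'
#' Sums counts into bins of `target_bin_minutes` (an integer multiple of
#' the current bin width). A trailing partial bin is dropped with a
#' warning, never padded. The phase label of an output bin is that of its
#' first constituent bin.
#'
#' @inheritParams bin_minutes
#' @param target_bin_minutes New bin width in minutes.
#' @return An activity tibble at the requested bin width; per-fly totals
#'   are conserved up to any dropped partial bin.
#' @export
rebin_activity <- function(activity, target_bin_minutes) {
  bw <- bin_minutes(activity)
  target_bin_minutes <- as.integer(target_bin_minutes)
  if (target_bin_minutes == bw) return(activity)
  if (target_bin_minutes %% bw != 0L) {
    stop(sprintf("target bin (%d min) is not a multiple of the current bin (%d min)",
                 target_bin_minutes, bw), call. = FALSE)
  }
  schedule <- activity_schedule(activity)
  out <- as_tibble(activity) |>
    dplyr::mutate(.bin = (.data$minute %/% target_bin_minutes) * target_bin_minutes) |>
    dplyr::group_by(.data$fly_id, .data$genotype, .data$.bin) |>
    dplyr::summarise(
      count = sum(.data$count),
      phase = .data$phase[which.min(.data$minute)],
      .n_in = dplyr::n(),
      .groups = "drop"
    )
  full <- target_bin_minutes %/% bw
  if (any(out$.n_in < full)) {
    warning(sprintf("dropped a trailing partial bin (%d of %d sub-bins)",
                    max(out$.n_in[out$.n_in < full]), full), call. = FALSE)
    out <- dplyr::filter(out, .data$.n_in == full)
  }
  out <- out |>
    dplyr::transmute(.data$fly_id, .data$genotype, minute = .data$.bin,
                     .data$phase, .data$count) |>
    dplyr::arrange(.data$fly_id, .data$minute)
  new_dam_activity(out, target_bin_minutes, schedule)
}

#' Flag flies that died during the recording
#'
#' A fly is flagged dead when its counts are all zero over the final
#' `window_hours` of the recording -- the standard DAM exclusion heuristic.
#' Flagged flies should be excluded from group statistics.
#'
#' @inheritParams bin_minutes
#' @param window_hours Length of the terminal all-zero window that defines
#'   death (default 24 h).
#' @return A tibble with `fly_id`, `genotype`, `dead`.
#' @export
flag_dead_flies <- function(activity, window_hours = 24) {
  bw <- bin_minutes(activity)
  window_bins <- as.integer(round(window_hours * 60 / bw))
  end_min <- max(activity$minute)
  total_bins <- length(unique(activity$minute))
  if (total_bins < window_bins) {
    stop("recording shorter than the dead-fly window", call. = FALSE)
  }
  cut <- end_min - (window_bins - 1L) * bw
  as_tibble(activity) |>
    dplyr::group_by(.data$fly_id, .data$genotype) |>
    dplyr::summarise(dead = sum(.data$count[.data$minute >= cut]) == 0L,
                     .groups = "drop")
}

#' Write an activity table to long-format CSV
#'
#' @inheritParams bin_minutes
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_activity_csv <- function(activity, path) {
  readr::write_csv(as_tibble(activity), path)
  invisible(path)
}
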