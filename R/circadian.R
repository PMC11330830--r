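#' Total activity on one recording day
#'
#' Per-fly sum of beam crosses over the 24 h of the given day. Day 1 starts
#' at ZT0 of the first LD day; the conventional comparison day is LD day 2.
#'
#' @inheritParams bin_minutes
#' @param day 1-based day index (default 2).
#' @return Tibble with `fly_id`, `genotype`, `total_activity`.
#' @export
total_activity <- function(activity, day = 2) {
  win <- day_window(activity, day)
  as_tibble(activity) |>
    dplyr::filter(.data$minute >= win[1], .data$minute < win[2]) |>
    dplyr::group_by(.data$fly_id, .data$genotype) |>
    dplyr::summarise(total_activity = sum(.data$count), .groups = "drop")
}

day_window <- function(activity, day) {
  from <- (day - 1L) * 1440L
  to <- day * 1440L
  bw <- bin_minutes(activity)
  if (from < min(activity$minute) || to > max(activity$minute) + bw) {
    stop(sprintf("day %d is not fully covered by the recording", day),
         call. = FALSE)
  }
  c(from, to)
}

# Sum of counts over [from, to) minutes for each fly; bins must align with
# the window edges.
window_sums <- function(activity, from, to) {
  bw <- bin_minutes(activity)
  if (from %% bw != 0 || to %% bw != 0) {
    stop(sprintf("a %d-min window does not align with %d-min bins",
                 to - from, bw), call. = FALSE)
  }
  as_tibble(activity) |>
    dplyr::filter(.data$minute >= from, .data$minute < to) |>
    dplyr::group_by(.data$fly_id) |>
    dplyr::summarise(s = sum(.data$count), .groups = "drop")
}

#' Morning and evening anticipation indices
#'
#' The morning index is the fraction of the activity in the 6 h before
#' lights-on that falls in the final 3 h, minus 0.5:
#' `MI = sum(activity, 3 h before lights-on) / sum(activity, 6 h before
#' lights-on) - 0.5`, so it ranges over \[-0.5, +0.5\] and a positive value
#' means activity escalates toward the transition. The evening index is the
#' mirrored construction around lights-off. An index is undefined (`NA`)
#' when its 6-h sum is zero; such flies are excluded from the anticipation
#' percentages. A fly "has" morning/evening anticipation when its index is
#' strictly positive (the simplest defensible cut-off; override by
#' thresholding the returned indices yourself).
#'
#' @inheritParams bin_minutes
#' @param day 1-based LD day whose transitions are scored (default 2; day 1
#'   has no recorded pre-lights-on window).
#' @return Tibble with `fly_id`, `genotype`, `morning_index`,
#'   `evening_index`, `has_ma`, `has_ea`.
#' @export
anticipation <- function(activity, day = 2) {
  dplyr::left_join(
    dplyr::left_join(fly_table(activity),
                     morning_index(activity, day), by = "fly_id"),
    evening_index(activity, day), by = "fly_id"
  ) |>
    dplyr::mutate(has_ma = .data$morning_index > 0,
                  has_ea = .data$evening_index > 0)
}

#' @rdname anticipation
#' @export
morning_index <- function(activity, day = 2) {
  anchor <- (day - 1L) * 1440L # lights-on of the given day
  anticipation_index(activity, anchor, "morning_index")
}

#' @rdname anticipation
#' @export
evening_index <- function(activity, day = 2) {
  schedule <- activity_schedule(activity)
  anchor <- (day - 1L) * 1440L + schedule$photoperiod_min
  anticipation_index(activity, anchor, "evening_index")
}

anticipation_index <- function(activity, anchor, name) {
  if (anchor - 360L < 0L) {
    stop("the 6-h pre-transition window extends before the recording start",
         call. = FALSE)
  }
  s6 <- window_sums(activity, anchor - 360L, anchor)
  s3 <- window_sums(activity, anchor - 180L, anchor)
  out <- dplyr::left_join(s6, s3, by = "fly_id", suffix = c("6", "3")) |>
    dplyr::mutate(idx = ifelse(.data$s6 > 0, .data$s3 / .data$s6 - 0.5, NA_real_))
  if (anyNA(out$idx)) {
    message(sum(is.na(out$idx)), " fly/flies with no activity in the 6-h window: ",
            name, " undefined")
  }
  stats::setNames(out[, c("fly_id", "idx")], c("fly_id", name))
}

#' Average-day activity profile (eduction chart)
#'
#' Mean across flies, per genotype, of the counts in each 30-min bin of the
#' given day -- the classic eduction chart of one average day.
#'
#' @inheritParams bin_minutes
#' @param day 1-based day index (default 2).
#' @param profile_bin_minutes Width of the profile bins (default 30).
#' @return Tibble with `genotype`, `bin`, `zt_h`, `mean_counts` (one row
#'   per genotype per bin; 48 bins for 30-min profiles).
#' @export
eduction_profile <- function(activity, day = 2, profile_bin_minutes = 30) {
  bw <- bin_minutes(activity)
  if (profile_bin_minutes %% bw != 0) {
    stop("profile bins must be a multiple of the data bin width", call. = FALSE)
  }
  win <- day_window(activity, day)
  as_tibble(activity) |>
    dplyr::filter(.data$minute >= win[1], .data$minute < win[2]) |>
    dplyr::mutate(bin = (.data$minute - win[1]) %/% profile_bin_minutes) |>
    dplyr::group_by(.data$fly_id, .data$genotype, .data$bin) |>
    dplyr::summarise(fly_counts = sum(.data$count), .groups = "drop") |>
    dplyr::group_by(.data$genotype, .data$bin) |>
    dplyr::summarise(mean_counts = mean(.data$fly_counts), .groups = "drop") |>
    dplyr::mutate(zt_h = .data$bin * profile_bin_minutes / 60, .after = "bin")
}
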