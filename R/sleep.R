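#' Score sleep by the 5-minute immobility rule
#'
#' A fly is asleep in minute `m` when `m` belongs to a maximal run of at
#' least 5 consecutive minutes with zero beam crosses; shorter zero runs
#' are quiet wake. "Does not change position" is operationalised as a zero
#' count, since a single-beam monitor registers nothing else; any count
#' greater than zero makes the minute a wake minute regardless of
#' magnitude.
#'
#' @param counts Integer vector of per-minute counts for one fly.
#' @param min_bout_min Immobility threshold in minutes (default 5).
#' @return Logical vector: `TRUE` for each sleeping minute.
#' @examples
#' score_sleep(c(2, 0, 0, 0, 0, 0, 1, 0, 0, 0, 0, 3))
#' @export
score_sleep <- function(counts, min_bout_min = 5L) {
  r <- rle(counts == 0)
  rep(r$values & r$lengths >= min_bout_min, r$lengths)
}

#' Extract sleep bouts from a scored sleep vector
#'
#' Maximal runs of sleeping minutes. A bout spanning the light-to-dark
#' boundary counts as one episode attributed to the phase in which it
#' starts; for per-phase sleep totals its minutes are split at the
#' boundary (see [sleep_summary()]).
#'
#' @param asleep Logical per-minute sleep vector (from [score_sleep()]).
#' @param phase Character vector of phase labels aligned to `asleep`.
#' @param offset Minute index of the first element (0-based), so bout
#'   positions can be reported in recording coordinates.
#' @return Tibble with `start`, `end` (half-open minutes), `duration_min`,
#'   `phase_at_start`.
#' @export
sleep_bouts <- function(asleep, phase, offset = 0L) {
  r <- rle(asleep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble(
    start = offset + starts[keep] - 1L,
    end = offset + ends[keep],
    duration_min = r$lengths[keep],
    phase_at_start = phase[starts[keep]]
  )
}

#' Per-fly sleep summary for one analysis day
#'
#' Computes, for each fly, the daily sleep metrics on the given day:
#' total sleep minutes, sleep minutes in the light and dark phases,
#' number of sleep episodes per phase, and mean episode length per phase.
#' Sleep is scored on the uncut 1-minute series first, then clipped to the
#' day, so zero runs straddling the day edges are resolved before
#' truncation. Episodes straddling the light/dark boundary are counted
#' once, in their starting phase; their minutes are split between the
#' phase totals. Mean episode length per phase is the mean in-day duration
#' of the episodes attributed to that phase, so
#' `n_episodes * mean_length` summed over phases equals total sleep.
#'
#' When `rhythmic` flags are supplied (e.g. from [periodogram_summary()]),
#' non-rhythmic flies are excluded, following the convention of analysing
#' sleep in rhythmic flies only.
#'
#' @inheritParams bin_minutes
#' @param day 1-based day index (default 2, the conventional analysis day).
#' @param rhythmic Optional tibble with `fly_id` and logical `rhythmic`.
#' @param min_bout_min Immobility threshold in minutes (default 5).
#' @return Tibble with one row per (included) fly: `fly_id`, `genotype`,
#'   `total_sleep_min`, `sleep_min_light`, `sleep_min_dark`,
#'   `n_episodes_light`, `n_episodes_dark`, `mean_episode_len_light`,
#'   `mean_episode_len_dark`.
#' @export
sleep_summary <- function(activity, day = 2, rhythmic = NULL,
                          min_bout_min = 5L) {
  check_one_minute(activity)
  win <- day_window(activity, day)
  tbl <- as_tibble(activity)
  if (!is.null(rhythmic)) {
    keep <- rhythmic$fly_id[rhythmic$rhythmic %in% TRUE]
    dropped <- setdiff(unique(tbl$fly_id), keep)
    if (length(dropped)) {
      message("excluding ", length(dropped),
              " non-rhythmic fly/flies from the sleep summary")
    }
    tbl <- dplyr::filter(tbl, .data$fly_id %in% keep)
  }
  ord <- order(tbl$fly_id, tbl$minute)
  tbl <- tbl[ord, ]
  per_fly <- split(tbl, tbl$fly_id)
  purrr::map_dfr(per_fly, function(d) {
    asleep <- score_sleep(d$count, min_bout_min)
    in_day <- d$minute >= win[1] & d$minute < win[2]
    a <- asleep[in_day]
    ph <- d$phase[in_day]
    bouts <- sleep_bouts(a, ph, offset = win[1])
    by_phase <- function(p) {
      b <- bouts[bouts$phase_at_start == p, ]
      c(n = nrow(b),
        len = if (nrow(b)) mean(b$duration_min) else NA_real_)
    }
    l <- by_phase("L"); dk <- by_phase("D")
    tibble(
      fly_id = d$fly_id[1],
      genotype = d$genotype[1],
      total_sleep_min = sum(a),
      sleep_min_light = sum(a & ph == "L"),
      sleep_min_dark = sum(a & ph == "D"),
      n_episodes_light = as.integer(l[["n"]]),
      n_episodes_dark = as.integer(dk[["n"]]),
      mean_episode_len_light = l[["len"]],
      mean_episode_len_dark = dk[["len"]]
    )
  })
}

check_one_minute <- function(activity) {
  if (bin_minutes(activity) != 1L) {
    stop("sleep is scored on 1-minute data; pass the raw matrix, not a ",
         "rebinned one (30-min bins are for circadian analysis)", call. = FALSE)
  }
}

#' Average daily sleep profile
#'
#' Minutes asleep per 30-min bin of the given day, averaged across flies
#' within each genotype -- each value lies in \[0, 30\].
#'
#' @inheritParams sleep_summary
#' @param profile_bin_minutes Width of the profile bins (default 30).
#' @return Tibble with `genotype`, `bin`, `zt_h`, `mean_sleep_min`.
#' @export
sleep_profile <- function(activity, day = 2, rhythmic = NULL,
                          min_bout_min = 5L, profile_bin_minutes = 30) {
  check_one_minute(activity)
  win <- day_window(activity, day)
  tbl <- as_tibble(activity)
  if (!is.null(rhythmic)) {
    keep <- rhythmic$fly_id[rhythmic$rhythmic %in% TRUE]
    tbl <- dplyr::filter(tbl, .data$fly_id %in% keep)
  }
  ord <- order(tbl$fly_id, tbl$minute)
  tbl <- tbl[ord, ]
  per_fly <- split(tbl, tbl$fly_id)
  purrr::map_dfr(per_fly, function(d) {
    asleep <- score_sleep(d$count, min_bout_min)
    in_day <- d$minute >= win[1] & d$minute < win[2]
    tibble(
      genotype = d$genotype[1],
      fly_id = d$fly_id[1],
      bin = (d$minute[in_day] - win[1]) %/% profile_bin_minutes,
      asleep = asleep[in_day]
    )
  }) |>
    dplyr::group_by(.data$fly_id, .data$genotype, .data$bin) |>
    dplyr::summarise(fly_sleep = sum(.data$asleep), .groups = "drop") |>
    dplyr::group_by(.data$genotype, .data$bin) |>
    dplyr::summarise(mean_sleep_min = mean(.data$fly_sleep), .groups = "drop") |>
    dplyr::mutate(zt_h = .data$bin * profile_bin_minutes / 60, .after = "bin")
}
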