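#' Define a phenotype preset for the synthetic DAM generator
#'
#' A preset bundles the behavioural parameters of one genotype: how much the
#' fly moves, its free-running period, how strongly it anticipates the light
#' transitions, how likely it is to be arrhythmic in constant darkness, and
#' the sleep/wake bout structure in each phase.
#'
#' The generative model (see the methods vignette) is a two-state
#' wake/sleep alternating-renewal process at 1-minute resolution with
#' geometrically distributed bout lengths -- realised as per-minute exit
#' hazards equal to the reciprocal phase bout means, so a bout spanning a
#' phase transition continues under the new phase's hazard -- gating a
#' Poisson count process whose rate carries linear anticipation ramps over
#' the 3 h preceding each (subjective) light transition. Once DD begins,
#' subjective time advances at `24 / free_running_period_h` circadian hours
#' per clock hour, so the whole waveform free-runs with period tau.
#'
#' @param name Genotype label attached to simulated flies.
#' @param mean_daily_activity Expected beam crosses per 24 h on an LD day.
#' @param free_running_period_h Free-running period tau in hours (16-32).
#' @param morning_ramp_strength,evening_ramp_strength Dimensionless peak of
#'   the linear activity ramp over the 3 h before (subjective) lights-on /
#'   lights-off; 0 disables anticipation.
#' @param arrhythmic_fraction Probability that a fly is arrhythmic: its
#'   rate modulation is flattened to the time-average and its bout means are
#'   phase-averaged, removing all circadian structure while preserving the
#'   expected daily activity.
#' @param sleep_bout_mean_min,wake_bout_mean_min Named numeric vectors
#'   `c(light = , dark = )`: mean bout length in minutes per phase.
#' @param siesta_factor Multiplier (>= 1) applied to the light-phase sleep
#'   bout mean, peaking at mid-light and tapering linearly to 1 at the
#'   phase edges; values > 1 produce the wild-type midday "siesta".
#' @return A `phenotype_preset` object.
#' @seealso [builtin_presets()], [simulate_fly()], [simulate_group()]
#' @export
phenotype_preset <- function(name, mean_daily_activity, free_running_period_h,
                             morning_ramp_strength, evening_ramp_strength,
                             arrhythmic_fraction,
                             sleep_bout_mean_min, wake_bout_mean_min,
                             siesta_factor = 1) {
  stopifnot(
    mean_daily_activity > 0,
    free_running_period_h >= 16, free_running_period_h <= 32,
    morning_ramp_strength >= 0, evening_ramp_strength >= 0,
    arrhythmic_fraction >= 0, arrhythmic_fraction <= 1,
    all(c("light", "dark") %in% names(sleep_bout_mean_min)),
    all(c("light", "dark") %in% names(wake_bout_mean_min)),
    all(sleep_bout_mean_min > 0), all(wake_bout_mean_min > 0),
    siesta_factor >= 1
  )
  structure(
    list(
      name = name,
      mean_daily_activity = mean_daily_activity,
      free_running_period_h = free_running_period_h,
      morning_ramp_strength = morning_ramp_strength,
      evening_ramp_strength = evening_ramp_strength,
      arrhythmic_fraction = arrhythmic_fraction,
      sleep_bout_mean_min = sleep_bout_mean_min[c("light", "dark")],
      wake_bout_mean_min = wake_bout_mean_min[c("light", "dark")],
      siesta_factor = siesta_factor
    ),
    class = "phenotype_preset"
  )
}

#' @export
print.phenotype_preset <- function(x, ...) {
  cat(sprintf(
    "<phenotype_preset> %s: %.0f crosses/day, tau %.1f h, ramps M %.1f / E %.1f, arrhythmic %.0f%%\n",
    x$name, x$mean_daily_activity, x$free_running_period_h,
    x$morning_ramp_strength, x$evening_ramp_strength, 100 * x$arrhythmic_fraction
  ))
  invisible(x)
}

# Calibration constants for the built-in genotype presets.
#
# Values reported by the study they emulate:
#   wild_type           ~500 beam crosses/day; tau 23.6 h; clear MA/EA;
#                       mostly rhythmic in DD
#   pink1_b9            reduced activity; tau 26.2 h; blunted MA/EA; a
#                       higher fraction arrhythmic; more total sleep in
#                       fewer, longer bouts in both phases
#   tim_usp14_kd        tau 24.5 h, otherwise wild-type-like
#   pdf_usp14_kd        tau 24.2 h, otherwise wild-type-like
#   pink1_usp14_rescue  wild-type-like activity/anticipation/sleep but the
#                       long tau is retained
# Magnitudes the study does not report (Pink1 activity mean, ramp
# strengths, bout means, arrhythmic fractions) are calibration choices of
# this package, fixed here once; see the methods vignette.
.preset_table <- function() {
  wt_sleep <- c(light = 20, dark = 40)
  wt_wake <- c(light = 80, dark = 20)
  wt_ramp <- 2 # "most" flies show MA/EA on the analysis day
  list(
    wild_type = phenotype_preset(
      "wild_type",
      mean_daily_activity = 500, free_running_period_h = 23.6,
      morning_ramp_strength = wt_ramp, evening_ramp_strength = wt_ramp,
      arrhythmic_fraction = 0.05,
      sleep_bout_mean_min = wt_sleep, wake_bout_mean_min = wt_wake
    ),
    pink1_b9 = phenotype_preset(
      "pink1_b9",
      mean_daily_activity = 250, free_running_period_h = 26.2,
      morning_ramp_strength = 0, evening_ramp_strength = 0,
      arrhythmic_fraction = 0.35,
      sleep_bout_mean_min = c(light = 60, dark = 150),
      wake_bout_mean_min = c(light = 60, dark = 10)
    ),
    tim_usp14_kd = phenotype_preset(
      "tim_usp14_kd",
      mean_daily_activity = 500, free_running_period_h = 24.5,
      morning_ramp_strength = wt_ramp, evening_ramp_strength = wt_ramp,
      arrhythmic_fraction = 0.05,
      sleep_bout_mean_min = wt_sleep, wake_bout_mean_min = wt_wake
    ),
    pdf_usp14_kd = phenotype_preset(
      "pdf_usp14_kd",
      mean_daily_activity = 500, free_running_period_h = 24.2,
      morning_ramp_strength = wt_ramp, evening_ramp_strength = wt_ramp,
      arrhythmic_fraction = 0.05,
      sleep_bout_mean_min = wt_sleep, wake_bout_mean_min = wt_wake
    ),
    pink1_usp14_rescue = phenotype_preset(
      "pink1_usp14_rescue",
      mean_daily_activity = 500, free_running_period_h = 26.2,
      morning_ramp_strength = wt_ramp, evening_ramp_strength = wt_ramp,
      arrhythmic_fraction = 0.05,
      sleep_bout_mean_min = wt_sleep, wake_bout_mean_min = wt_wake
    )
  )
}

#' Built-in genotype presets
#'
#' Returns the registry of immutable phenotype presets emulating the
#' genotypes of the motivating study: `wild_type`, `pink1_b9`,
#' `tim_usp14_kd`, `pdf_usp14_kd`, and `pink1_usp14_rescue`.
#'
#' @return Named list of [phenotype_preset()] objects.
#' @export
builtin_presets <- function() .preset_table()

#' Look up one built-in preset by name
#'
#' @param name Preset name.
#' @return A [phenotype_preset()].
#' @export
dam_preset <- function(name) {
  tab <- .preset_table()
  if (!name %in% names(tab)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(tab), collapse = ", "), call. = FALSE)
  }
  tab[[name]]
}

# Subjective zeitgeber hour of each minute (0-based minutes from ZT0 of LD
# day 1). During LD subjective time equals clock ZT; once DD begins it
# advances at 24/tau circadian hours per clock hour, so the waveform
# free-runs with period tau.
subjective_zt_hours <- function(minutes, schedule, tau_h) {
  t_dd <- schedule$ld_days * 1440
  s <- ifelse(minutes < t_dd, minutes, t_dd + (minutes - t_dd) * 24 / tau_h)
  (s / 60) %% 24
}

# Rate modulation 1 + morning ramp + evening ramp, as a function of
# (subjective) ZT hours. Ramps rise linearly from 0 to full strength over
# the 3 h preceding lights-on (ZT 24) and lights-off (ZT photoperiod).
rate_modulation <- function(zt_h, schedule, morning, evening) {
  pp <- schedule$photoperiod_min / 60
  m <- ifelse(zt_h >= 21 & zt_h < 24, (zt_h - 21) / 3, 0)
  e <- ifelse(zt_h >= pp - 3 & zt_h < pp, (zt_h - (pp - 3)) / 3, 0)
  1 + morning * m + evening * e
}

# Time-average of the modulation over one day: each ramp integrates to
# strength * 1.5 h out of 24 h.
flat_modulation <- function(morning, evening) 1 + (morning + evening) * 1.5 / 24

# Stationary wake probability of the two-state renewal process.
wake_prob <- function(wake_mean, sleep_mean) wake_mean / (wake_mean + sleep_mean)

# Per-minute sleep (hs) and wake (hw) exit hazards implied by the preset:
# the reciprocal bout means of the phase each minute belongs to, with the
# siesta multiplier applied to the sleep mean in the light phase. Arrhythmic
# flies use phase-averaged means throughout.
sleep_wake_hazards <- function(zt_h, schedule, preset, arrhythmic) {
  sl <- preset$sleep_bout_mean_min
  wk <- preset$wake_bout_mean_min
  if (arrhythmic) {
    sl[] <- mean(sl)
    wk[] <- mean(wk)
  }
  light <- zt_h < schedule$photoperiod_min / 60
  ms <- ifelse(light, sl[["light"]], sl[["dark"]])
  if (!arrhythmic && preset$siesta_factor > 1) {
    ms <- ms * siesta_multiplier(zt_h, schedule, preset$siesta_factor)
  }
  list(hs = 1 / ms, hw = 1 / ifelse(light, wk[["light"]], wk[["dark"]]))
}

# Exact per-minute sleep probability over the periodic steady-state LD day:
# the two-state chain q(t) = q(t-1)(1 - hs(t-1)) + (1 - q(t-1)) hw(t-1)
# iterated to its daily fixed point. This is the closed form behind both
# the activity calibration and the sleep expectations (it includes the
# relaxation transients after each light transition).
ld_day_sleep_profile <- function(preset, schedule, arrhythmic = FALSE) {
  zt <- (0:1439) / 60
  hz <- sleep_wake_hazards(zt, schedule, preset, arrhythmic)
  hs <- hz$hs; hw <- hz$hw
  q <- rep(hw[1440] / (hw[1440] + hs[1440]), 1440)
  for (sweep in 1:4) {
    for (t in 1:1440) {
      tp <- if (t == 1) 1440L else t - 1L
      q[t] <- q[tp] * (1 - hs[tp]) + (1 - q[tp]) * hw[tp]
    }
  }
  q
}

# Base Poisson rate (counts per wake minute at modulation 1) calibrated so
# the expected activity on a steady-state LD day equals the preset mean.
base_rate <- function(preset, schedule, arrhythmic) {
  q <- ld_day_sleep_profile(preset, schedule, arrhythmic)
  zt <- (0:1439) / 60
  mod <- if (arrhythmic) {
    rep(flat_modulation(preset$morning_ramp_strength,
                        preset$evening_ramp_strength), 1440)
  } else {
    rate_modulation(zt, schedule, preset$morning_ramp_strength,
                    preset$evening_ramp_strength)
  }
  preset$mean_daily_activity / sum((1 - q) * mod)
}

# One sample path of the two-state chain; starts at the stationary point of
# the first minute's hazards.
markov_sleep_path <- function(hs, hw) {
  n <- length(hs)
  u <- stats::runif(n)
  asleep <- logical(n)
  asleep[1] <- u[1] < hw[1] / (hw[1] + hs[1])
  for (t in 2:n) {
    asleep[t] <- if (asleep[t - 1L]) u[t] >= hs[t - 1L] else u[t] < hw[t - 1L]
  }
  asleep
}

# Mid-light siesta multiplier on the sleep bout mean: 1 at the phase
# edges, siesta_factor at mid-light, linear in between; 1 outside light.
siesta_multiplier <- function(zt_h, schedule, factor) {
  pp <- schedule$photoperiod_min / 60
  ifelse(zt_h < pp, 1 + (factor - 1) * (1 - abs(zt_h - pp / 2) / (pp / 2)), 1)
}

# --- RNG streams ----------------------------------------------------------
# Per-fly randomness uses L'Ecuyer-CMRG streams advanced with
# parallel::nextRNGStream from a base state derived from the user seed.
# Seeding Mersenne-Twister generators with the outputs of another
# Mersenne-Twister (the naive "derive integer sub-seeds" scheme) produces
# measurably correlated fly series; CMRG streams are guaranteed
# non-overlapping and independent.

# Removing an absent .Random.seed would leave the session's generator kind
# switched to CMRG; materialise the seed first so save/restore always
# round-trips both state and kind.
ensure_rng_initialised <- function() {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  invisible()
}

rng_state_for_seed <- function(seed) {
  ensure_rng_initialised()
  withr::with_seed(as.integer(seed), .Random.seed,
                   .rng_kind = "L'Ecuyer-CMRG")
}

with_rng_state <- function(state, code) {
  ensure_rng_initialised()
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  assign(".Random.seed", state, envir = globalenv())
  force(code)
}

#' Simulate one fly's per-minute beam-cross series
#'
#' Draws a 1-minute activity series for the full LD+DD protocol of
#' `schedule` under the generative model described in
#' [phenotype_preset()]. Sleep minutes always emit count 0, so the latent
#' sleep state (returned as attribute `asleep`) is exact ground truth for
#' the 5-minute sleep scorer.
#'
#' @param preset A [phenotype_preset()].
#' @param schedule A [light_schedule()].
#' @param seed Integer seed; the output is a pure function of
#'   `(preset, schedule, seed)`.
#' @return Integer vector of counts, one per minute, with attributes
#'   `asleep` (latent per-minute sleep state) and `arrhythmic`.
#' @export
simulate_fly <- function(preset, schedule, seed) {
  stream <- parallel::nextRNGStream(rng_state_for_seed(seed))
  with_rng_state(stream, simulate_fly_impl(preset, schedule))
}

# Body of the simulation; consumes the current RNG state.
simulate_fly_impl <- function(preset, schedule) {
  n_min <- n_days(schedule) * 1440L
  tau <- preset$free_running_period_h
  arrhythmic <- stats::runif(1) < preset$arrhythmic_fraction

  minutes <- 0:(n_min - 1)
  zt <- subjective_zt_hours(minutes, schedule, tau)

  # two-state wake/sleep process with per-minute exit hazards 1/mean, so
  # bout lengths within a phase are geometric with the phase-appropriate
  # mean (memoryless); the hazard follows the (subjective) phase, so a
  # bout spanning a transition continues under the new phase's hazard
  hz <- sleep_wake_hazards(zt, schedule, preset, arrhythmic)
  asleep <- markov_sleep_path(hz$hs, hz$hw)

  base <- base_rate(preset, schedule, arrhythmic)
  lambda <- if (arrhythmic) {
    rep(base * flat_modulation(preset$morning_ramp_strength,
                               preset$evening_ramp_strength), n_min)
  } else {
    base * rate_modulation(zt, schedule, preset$morning_ramp_strength,
                           preset$evening_ramp_strength)
  }
  counts <- integer(n_min)
  wake_idx <- which(!asleep)
  counts[wake_idx] <- stats::rpois(length(wake_idx), lambda[wake_idx])
  attr(counts, "asleep") <- asleep
  attr(counts, "arrhythmic") <- arrhythmic
  counts
}

#' Simulate a group of flies as an activity table
#'
#' Simulates `n_flies` independent flies from one preset. Fly `i` consumes
#' the `i`-th L'Ecuyer-CMRG stream derived from `seed`, so the whole table
#' is a pure function of its arguments and fly 1 equals
#' `simulate_fly(preset, schedule, seed)`.
#'
#' @inheritParams simulate_fly
#' @param n_flies Number of flies.
#' @param id_prefix Prefix for fly identifiers (defaults to the preset
#'   name).
#' @return A 1-minute activity tibble with `genotype` set to the preset
#'   name.
#' @export
simulate_group <- function(preset, n_flies, schedule, seed,
                           id_prefix = preset$name) {
  n_min <- n_days(schedule) * 1440L
  phase <- phase_of_bins(schedule, n_min, 1L)
  stream <- rng_state_for_seed(seed)
  long <- purrr::map_dfr(seq_len(n_flies), function(i) {
    stream <<- parallel::nextRNGStream(stream)
    cnt <- with_rng_state(stream, simulate_fly_impl(preset, schedule))
    tibble(
      fly_id = sprintf("%s_%03d", id_prefix, i),
      genotype = preset$name,
      minute = 0:(n_min - 1),
      phase = phase,
      count = as.integer(cnt)
    )
  })
  new_dam_activity(long, 1L, schedule)
}

#' Closed-form expectations implied by a preset
#'
#' Expectations of the generative model on a steady-state LD day, used by
#' the calibration tests: daily activity, expected latent sleep minutes per
#' phase (from the exact two-state occupancy recursion, including the
#' relaxation transients after each light transition), and the geometric
#' bout means.
#'
#' @inheritParams simulate_fly
#' @return One-row tibble of expected values.
#' @export
preset_expectations <- function(preset, schedule) {
  q <- ld_day_sleep_profile(preset, schedule)
  pp <- schedule$photoperiod_min
  light <- seq_len(pp)
  tibble(
    mean_daily_activity = preset$mean_daily_activity,
    sleep_min_light = sum(q[light]),
    sleep_min_dark = sum(q[-light]),
    sleep_frac_light = mean(q[light]),
    sleep_frac_dark = mean(q[-light]),
    sleep_bout_mean_light = preset$sleep_bout_mean_min[["light"]],
    sleep_bout_mean_dark = preset$sleep_bout_mean_min[["dark"]]
  )
}
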