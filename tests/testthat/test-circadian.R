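# Total activity, anticipation indices, eduction profiles.

test_that("total_activity sums 24 h of counts per fly", {
  sch <- ld_only(2)
  act <- make_activity(list(a = rep(1L, 2880), b = rep(0L, 2880)), sch)
  ta <- total_activity(act, day = 2)
  expect_equal(ta$total_activity[ta$fly_id == "a"], 1440L)
  expect_equal(ta$total_activity[ta$fly_id == "b"], 0L)
  expect_error(total_activity(act, day = 3), "not fully covered")
})

test_that("mean wild-type LD-day-2 activity matches the calibration within 3 SE", {
  g <- simulate_group(dam_preset("wild_type"), 100, ld_only(2), seed = 61)
  daily <- total_activity(g, day = 2)$total_activity
  se <- sd(daily) / sqrt(length(daily))
  expect_lt(abs(mean(daily) - 500), 3 * se)
})

test_that("morning index reproduces the defining arithmetic", {
  sch <- ld_only(2)
  mk <- function(night6h) {
    x <- rep(1L, 2880)
    x[(1440 - 360 + 1):1440] <- as.integer(night6h)
    make_activity(list(a = x), sch)
  }
  # uniform activity -> 0 by symmetry
  expect_equal(morning_index(mk(rep(1, 360)), 2)$morning_index, 0)
  # all activity inside the final 3 h -> +0.5; the earlier 3 h -> -0.5
  z <- rep(0L, 2880)
  z[(1440 - 180 + 1):1440] <- 5L
  expect_equal(suppressMessages(morning_index(make_activity(list(a = z), sch), 2))$morning_index, 0.5)
  z2 <- rep(0L, 2880)
  z2[(1440 - 360 + 1):(1440 - 180)] <- 5L
  expect_equal(suppressMessages(morning_index(make_activity(list(a = z2), sch), 2))$morning_index, -0.5)
  # hand-computable worked example: per-30-min-bin counts (oldest to newest
  # over the 6 h) 1,1,1,1,1,1,3,3,3,3,3,3 -> 18/24 - 0.5 = 0.25; each bin's
  # count is placed on its first minute
  per_bin <- rep(c(1L, 3L), each = 6)
  night <- rep(0L, 360)
  night[(0:11) * 30 + 1] <- per_bin
  expect_equal(suppressMessages(morning_index(mk(night), 2))$morning_index, 0.25)
  # window before recording start
  expect_error(morning_index(mk(rep(1, 360)), 1), "before the recording")
})

test_that("morning index works on 30-min binned data directly", {
  sch <- ld_only(2)
  x <- rep(1L, 96)
  x[(48 - 12 + 1):48] <- rep(c(1L, 3L), each = 6)
  act <- make_activity(list(a = x), sch, bin_minutes = 30)
  expect_equal(morning_index(act, 2)$morning_index, 0.25)
})

test_that("evening index mirrors the construction around lights-off", {
  sch <- ld_only(2)
  x <- rep(1L, 2880)
  act <- make_activity(list(a = x), sch)
  expect_equal(evening_index(act, 2)$evening_index, 0)
  # all activity in the 3 h before lights-off of day 2 (minute 1440+720)
  z <- rep(0L, 2880)
  z[(2160 - 180 + 1):2160] <- 2L
  expect_equal(suppressMessages(evening_index(make_activity(list(a = z), sch), 2))$evening_index, 0.5)
  # mirrored worked example
  x2 <- rep(1L, 2880)
  x2[(2160 - 360 + 1):2160] <- rep(rep(c(1L, 3L), each = 6), each = 30)
  expect_equal(evening_index(make_activity(list(a = x2 * 30L), sch), 2)$evening_index,
               0.25, tolerance = 1e-12)
})

test_that("indices are invariant to positive scaling and NA when undefined", {
  sch <- ld_only(2)
  withr::with_seed(3, x <- rpois(2880, 2))
  a1 <- make_activity(list(a = x), sch)
  a3 <- make_activity(list(a = x * 7L), sch)
  expect_equal(morning_index(a1, 2)$morning_index,
               morning_index(a3, 2)$morning_index)
  expect_equal(evening_index(a1, 2)$evening_index,
               evening_index(a3, 2)$evening_index)

  zero <- make_activity(list(a = rep(0L, 2880)), sch)
  expect_message(mi <- morning_index(zero, 2), "undefined")
  expect_true(is.na(mi$morning_index))
  ant <- suppressMessages(anticipation(zero, 2))
  expect_true(is.na(ant$has_ma) && is.na(ant$has_ea))
})

test_that("anticipation flags use a strict positive cut-off", {
  sch <- ld_only(2)
  up <- rep(1L, 2880); up[(1440 - 180 + 1):1440] <- 3L
  ant <- anticipation(make_activity(list(a = up), sch), 2)
  expect_true(ant$has_ma)
  flat <- anticipation(make_activity(list(a = rep(2L, 2880)), sch), 2)
  expect_false(flat$has_ma)
  expect_false(flat$has_ea)
})

test_that("anticipation ramps drive the MA fraction from chance to near one", {
  sch <- ld_only(2)
  # active flies so the index is read on plentiful counts
  mk <- function(ramp) phenotype_preset(
    paste0("r", ramp), 1500, 24, ramp, 0, 0,
    sleep_bout_mean_min = c(light = 2, dark = 2),
    wake_bout_mean_min = c(light = 200, dark = 200))
  g0 <- simulate_group(mk(0), 60, sch, seed = 41)
  g2 <- simulate_group(mk(2), 60, sch, seed = 41)
  f0 <- mean(anticipation(g0, 2)$has_ma, na.rm = TRUE)
  f2 <- mean(anticipation(g2, 2)$has_ma, na.rm = TRUE)
  expect_lt(abs(f0 - 0.5), 0.2)
  expect_gt(f2, 0.9)
})

test_that("eduction profile averages the day and conserves totals", {
  sch <- ld_only(2)
  withr::with_seed(13, x <- rpois(2880, 3))
  act <- make_activity(list(a = x), sch)
  ed <- eduction_profile(act, day = 2)
  expect_equal(nrow(ed), 48L)
  expect_equal(ed$mean_counts,
               as.numeric(tapply(x[1441:2880], rep(1:48, each = 30), sum)))
  expect_equal(sum(ed$mean_counts),
               total_activity(act, 2)$total_activity)

  # multi-fly conservation: sum of genotype means = mean of fly totals
  g <- simulate_group(dam_preset("wild_type"), 8, ld_only(2), seed = 9)
  ed2 <- eduction_profile(g, day = 2)
  expect_equal(sum(ed2$mean_counts),
               mean(total_activity(g, 2)$total_activity))
})

test_that("wild-type eduction rises over the 6 bins before lights-on", {
  g <- simulate_group(dam_preset("wild_type"), 30, ld_only(2), seed = 19)
  ed <- eduction_profile(g, day = 2)
  pre_dawn <- ed$mean_counts[ed$bin >= 42]
  slope <- coef(lm(pre_dawn ~ seq_along(pre_dawn)))[2]
  expect_gt(slope, 0)
})
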