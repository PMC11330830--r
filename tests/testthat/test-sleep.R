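# 5-minute sleep scorer, bout extraction, per-phase summaries, profiles.

test_that("the 5-minute rule boundary is exact", {
  expect_equal(score_sleep(c(1, 0, 0, 0, 0, 0, 1)),
               c(FALSE, rep(TRUE, 5), FALSE))
  expect_equal(score_sleep(c(1, 0, 0, 0, 0, 1)), rep(FALSE, 6))
  # any count > 0 is wake regardless of magnitude
  expect_equal(score_sleep(c(0, 0, 0, 0, 0, 99, 0, 0, 0, 0, 0)),
               c(rep(TRUE, 5), FALSE, rep(TRUE, 5)))
})

test_that("scorer matches the naive scan on random days", {
  withr::with_seed(71, {
    for (i in 1:50) {
      x <- rbinom(1440, 1, runif(1, 0.05, 0.6)) * rpois(1440, 3)
      expect_identical(score_sleep(x), naive_sleep_scan(x))
    }
  })
})

test_that("bout extraction is maximal, disjoint, and conserves minutes", {
  sch <- ld_only(1)
  ph <- phase_of_bins(sch, 1440, 1)
  x <- rep(1L, 1440)
  x[101:130] <- 0L # one 30-min bout entirely in light
  a <- score_sleep(x)
  b <- sleep_bouts(a, ph)
  expect_equal(nrow(b), 1L)
  expect_equal(b$duration_min, 30L)
  expect_equal(b$phase_at_start, "L")
  expect_equal(b$start, 100L)

  # 20-min bout starting 10 min before lights-off (minute 720)
  x2 <- rep(1L, 1440)
  x2[711:730] <- 0L
  a2 <- score_sleep(x2)
  b2 <- sleep_bouts(a2, ph)
  expect_equal(nrow(b2), 1L)
  expect_equal(b2$phase_at_start, "L")
  expect_equal(sum(a2 & ph == "L"), 10L)
  expect_equal(sum(a2 & ph == "D"), 10L)

  withr::with_seed(5, {
    for (i in 1:20) {
      x <- rbinom(500, 1, 0.5) * 2L
      a <- score_sleep(x)
      bt <- sleep_bouts(a, phase_of_bins(sch, 500, 1))
      expect_equal(sum(bt$duration_min), sum(a))
      expect_true(all(bt$duration_min >= 5))
    }
  })
})

test_that("sleep summary handles saturation and refusal cases", {
  sch <- ld_only(2)
  allzero <- rep(0L, 2880)
  every4 <- rep(c(1L, 0L, 0L, 0L), 720)
  act <- make_activity(list(z = allzero, w = every4), sch)
  ss <- sleep_summary(act, day = 2)
  z <- ss[ss$fly_id == "z", ]
  expect_equal(z$sleep_min_light, 720L)
  expect_equal(z$sleep_min_dark, 720L)
  expect_equal(z$n_episodes_light + z$n_episodes_dark, 1L)
  w <- ss[ss$fly_id == "w", ]
  expect_equal(w$total_sleep_min, 0L)

  expect_error(sleep_summary(rebin_activity(act, 30), day = 2), "1-minute")
})

test_that("split accounting reconciles episodes with phase totals", {
  sch <- ld_only(2)
  withr::with_seed(23, {
    g <- simulate_group(dam_preset("pink1_b9"), 10, sch, seed = 23)
  })
  ss <- sleep_summary(g, day = 2)
  tot <- ss$n_episodes_light * ifelse(is.na(ss$mean_episode_len_light), 0,
                                      ss$mean_episode_len_light) +
    ss$n_episodes_dark * ifelse(is.na(ss$mean_episode_len_dark), 0,
                                ss$mean_episode_len_dark)
  expect_equal(tot, ss$total_sleep_min, tolerance = 1e-12)
  expect_equal(ss$sleep_min_light + ss$sleep_min_dark, ss$total_sleep_min)
  expect_true(all(ss$sleep_min_light <= 720 & ss$sleep_min_dark <= 720))
})

test_that("non-rhythmic flies are excluded when flags are given", {
  sch <- ld_only(2)
  act <- make_activity(list(a = rep(0L, 2880), b = rep(c(1L, 0L), 1440)), sch)
  flags <- tibble::tibble(fly_id = c("a", "b"), rhythmic = c(TRUE, FALSE))
  expect_message(ss <- sleep_summary(act, 2, rhythmic = flags), "non-rhythmic")
  expect_equal(ss$fly_id, "a")
})

test_that("scored sleep equals latent sleep up to sub-threshold bouts", {
  # replace wake counts by 1 so quiet wake cannot masquerade as sleep: the
  # scorer must then recover the latent state except in bouts shorter than
  # 5 minutes
  sch <- ld_only(2)
  p <- dam_preset("wild_type")
  seeds <- withr::with_seed(83L, sample.int(.Machine$integer.max, 20))
  for (s in seeds) {
    x <- simulate_fly(p, sch, s)
    latent <- attr(x, "asleep")
    det <- ifelse(latent, 0L, 1L)
    scored <- score_sleep(det)
    r <- rle(latent)
    short <- rep(r$values & r$lengths < 5, r$lengths)
    expect_identical(scored, latent & !short)
    expect_equal(sum(latent) - sum(scored),
                 sum(r$lengths[r$values & r$lengths < 5]))
  }
})

test_that("pink1 preset sleeps more in fewer, longer bouts than wild type", {
  sch <- ld_only(2)
  wt <- sleep_summary(simulate_group(dam_preset("wild_type"), 25, sch, 91), 2)
  pk <- sleep_summary(simulate_group(dam_preset("pink1_b9"), 25, sch, 92), 2)
  expect_gt(mean(pk$total_sleep_min), mean(wt$total_sleep_min))
  expect_lt(mean(pk$n_episodes_light), mean(wt$n_episodes_light))
  expect_lt(mean(pk$n_episodes_dark), mean(wt$n_episodes_dark))
  expect_gt(mean(pk$mean_episode_len_light, na.rm = TRUE),
            mean(wt$mean_episode_len_light, na.rm = TRUE))
  expect_gt(mean(pk$mean_episode_len_dark, na.rm = TRUE),
            mean(wt$mean_episode_len_dark, na.rm = TRUE))
})

test_that("sleep profile saturates, conserves, and shows a siesta when configured", {
  sch <- ld_only(2)
  act <- make_activity(list(z = rep(0L, 2880)), sch)
  pr <- sleep_profile(act, day = 2)
  expect_equal(nrow(pr), 48L)
  expect_true(all(pr$mean_sleep_min == 30))
  expect_equal(sum(pr$mean_sleep_min),
               sleep_summary(act, 2)$total_sleep_min)

  wt <- dam_preset("wild_type")
  siesta <- phenotype_preset("siesta", wt$mean_daily_activity, 24,
                             2, 2, 0, wt$sleep_bout_mean_min,
                             wt$wake_bout_mean_min, siesta_factor = 4)
  g <- simulate_group(siesta, 40, sch, seed = 37)
  prof <- sleep_profile(g, day = 2)
  mid <- mean(prof$mean_sleep_min[prof$bin %in% 8:15])   # ZT4-8
  edges <- mean(prof$mean_sleep_min[prof$bin %in% c(0:3, 20:23)])
  expect_gt(mid, edges)
})
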