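# Binomial SD, Fisher's exact, Student's t, ANOVA/Tukey, dispatch.

test_that("binomial SD follows sqrt(npq)", {
  expect_equal(binomial_sd(100, 0.5), 5)
  expect_equal(binomial_sd(73, 0), 0)
  expect_equal(binomial_sd(73, 1), 0)
  withr::with_seed(7, {
    draws <- rbinom(1e5, 80, 0.3)
  })
  expect_lt(abs(sd(draws) - binomial_sd(80, 0.3)) / binomial_sd(80, 0.3), 0.03)
})

test_that("star annotation is a pure threshold function of p", {
  expect_equal(p_stars(c(0.2, 0.049, 0.009, 0.0009, 0.00009)),
               c("", "*", "**", "***", "****"))
  expect_equal(p_stars(0.05), "")
  expect_true(is.na(p_stars(NA)))
})

test_that("Fisher 2x2 equals exhaustive enumeration on all small tables", {
  # every 2x2 table with total <= 30 and no zero margin
  for (n in 2:30) {
    parts <- expand.grid(a = 0:n, b = 0:n, c = 0:n)
    parts <- parts[parts$a + parts$b + parts$c <= n, ]
    # subsample for speed while keeping full coverage of small totals
    if (n > 12) parts <- parts[seq(1, nrow(parts), by = 17), ]
    for (i in seq_len(nrow(parts))) {
      tab <- matrix(c(parts$a[i], parts$b[i], parts$c[i],
                      n - parts$a[i] - parts$b[i] - parts$c[i]), 2,
                    byrow = TRUE)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
      expect_equal(fisher_exact_2x2(tab), enum_fisher_p(tab),
                   tolerance = 1e-9)
    }
  }
})

test_that("Fisher 2x2 handles balance, zero margins, and symmetry", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2)), 1, tolerance = 1e-12)
  expect_message(p0 <- fisher_exact_2x2(matrix(c(0, 0, 3, 7), 2, byrow = TRUE)),
                 "zero margin")
  expect_equal(p0, 1)
  tab <- matrix(c(10, 0, 0, 10), 2)
  expect_equal(fisher_exact_2x2(tab), enum_fisher_p(tab), tolerance = 1e-12)
  # invariance under row and column swaps
  tab2 <- matrix(c(3, 9, 6, 2), 2, byrow = TRUE)
  expect_equal(fisher_exact_2x2(tab2), fisher_exact_2x2(tab2[2:1, ]))
  expect_equal(fisher_exact_2x2(tab2), fisher_exact_2x2(tab2[, 2:1]))
})

test_that("Student's t handles identical and degenerate samples", {
  a <- c(1, 2, 3, 4)
  tt <- t_test_two_tailed(a, a)
  expect_equal(tt$statistic, 0)
  expect_equal(tt$p_value, 1)

  expect_equal(t_test_two_tailed(c(2, 2), c(2, 2))$p_value, 1)
  expect_warning(z <- t_test_two_tailed(c(2, 2), c(3, 3)), "zero variance")
  expect_equal(z$p_value, 0)
})

test_that("t squared equals the one-way ANOVA F on two groups", {
  withr::with_seed(15, {
    a <- rnorm(8, 1); b <- rnorm(6)
  })
  tt <- t_test_two_tailed(a, b)
  an <- suppressWarnings(anova_tukey(c(a, b), rep(c("a", "b"), c(8, 6))))
  expect_equal(tt$statistic^2, an$anova$f_statistic, tolerance = 1e-10)
  expect_equal(tt$p_value, an$anova$p_value, tolerance = 1e-10)
})

test_that("Student's t agrees with a permutation oracle on small samples", {
  withr::with_seed(29, {
    a <- rpois(6, 5); b <- rpois(6, 9)
    p_perm <- perm_test_p(a, b, reps = 2e4)
  })
  p_t <- t_test_two_tailed(a, b)$p_value
  se <- sqrt(p_perm * (1 - p_perm) / 2e4)
  expect_lt(abs(p_t - p_perm), max(4 * se, 0.02))
})

test_that("Tukey HSD dominates the unadjusted LSD p on random data", {
  withr::with_seed(33, {
    for (i in 1:100) {
      g <- rep(c("a", "b", "c"), each = 5)
      v <- rnorm(15, mean = rep(runif(3, 0, 2), each = 5))
      at <- anova_tukey(v, g)
      fit <- aov(v ~ factor(g))
      mse <- sum(residuals(fit)^2) / fit$df.residual
      for (j in seq_len(nrow(at$pairwise))) {
        pr <- strsplit(at$pairwise$comparison[j], "-", fixed = TRUE)[[1]]
        d <- mean(v[g == pr[1]]) - mean(v[g == pr[2]])
        p_lsd <- 2 * pt(-abs(d / sqrt(mse * 2 / 5)), fit$df.residual)
        expect_gte(at$pairwise$p_adj[j] + 1e-12, p_lsd)
      }
    }
  })
})

test_that("identical groups give F near 0 and Tukey p near 1", {
  v <- rep(c(1, 2, 3, 4), 3)
  g <- rep(c("a", "b", "c"), each = 4)
  at <- anova_tukey(v, g)
  expect_lt(at$anova$f_statistic, 1e-20)
  expect_true(all(at$pairwise$p_adj > 0.999))
})

test_that("summarize_metric dispatches by metric type", {
  # binary phenotype: 40/73 vs 120/137 successes
  d <- tibble::tibble(
    genotype = rep(c("mut", "ctrl"), c(73, 137)),
    rhythmic = c(rep(c(TRUE, FALSE), c(40, 33)), rep(c(TRUE, FALSE), c(120, 17)))
  )
  gc <- summarize_metric(d, "rhythmic", control = "ctrl")
  expect_equal(gc$type, "binary")
  s <- gc$summary
  expect_equal(s$proportion[s$group == "mut"], 40 / 73, tolerance = 1e-6)
  expect_equal(s$proportion[s$group == "ctrl"], 120 / 137, tolerance = 1e-6)
  expect_equal(s$binomial_sd[s$group == "mut"], sqrt(73 * (40 / 73) * (33 / 73)))
  tab <- matrix(c(120, 17, 40, 33), 2, byrow = TRUE)
  expect_equal(gc$tests$p_value, enum_fisher_p(tab), tolerance = 1e-9)
  expect_equal(gc$tests$stars, p_stars(gc$tests$p_value))

  # single genotype: summary only, no test
  withr::with_seed(2, d$total <- rnorm(nrow(d), 100, 10))
  solo <- summarize_metric(d[d$genotype == "mut", ], "total")
  expect_equal(nrow(solo$tests), 0L)

  # two continuous groups: Student's t
  two <- summarize_metric(d, "total")
  expect_equal(two$method, "t_two_tailed")
  expect_equal(two$summary$sem,
               vapply(two$summary$group,
                      function(gg) sd(d$total[d$genotype == gg]) /
                        sqrt(sum(d$genotype == gg)), numeric(1)),
               ignore_attr = TRUE)

  # four genotypes: ANOVA + Tukey path
  d4 <- withr::with_seed(4, tibble::tibble(genotype = rep(letters[1:4], each = 6),
                                           total = rnorm(24)))
  four <- summarize_metric(d4, "total", pairwise = "all")
  expect_equal(four$method, "anova_tukey")
  expect_equal(nrow(four$tests), 6L)
  ctrl <- summarize_metric(d4, "total", control = "a")
  expect_equal(nrow(ctrl$tests), 3L)
  expect_true(all(grepl("a", ctrl$tests$comparison)))

  expect_equal(nrow(tidy(four)), 6L)
  expect_equal(glance(four)$n_groups, 4L)
})
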