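# Independent oracles, coded without reference to the package internals.

# Naive scan for the 5-min rule: walk the series, find each maximal zero
# run, mark it asleep iff long enough.
naive_sleep_scan <- function(counts, k = 5) {
  n <- length(counts)
  asleep <- logical(n)
  i <- 1
  while (i <= n) {
    if (counts[i] == 0) {
      j <- i
      while (j < n && counts[j + 1] == 0) j <- j + 1
      if (j - i + 1 >= k) asleep[i:j] <- TRUE
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  asleep
}

# Direct fold-and-average chi-square periodogram statistic for one trial
# period of p bins: columns gathered by stride, no matrix reshaping.
brute_force_q <- function(x, p) {
  k <- length(x) %/% p
  used <- x[seq_len(k * p)]
  col_means <- vapply(seq_len(p),
                      function(h) mean(used[seq(h, k * p, by = p)]),
                      numeric(1))
  gm <- mean(used)
  denom <- sum((used - gm)^2)
  if (denom == 0) return(NA_real_)
  k^2 * p * sum((col_means - gm)^2) / denom
}

# Two-sided Fisher p by full enumeration of tables with the observed
# margins (probability-mass rule).
enum_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  a_range <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(a_range, r1, r2, c1)
  p_obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Monte-Carlo permutation p for the difference in means.
perm_test_p <- function(a, b, reps = 1e4) {
  obs <- abs(mean(a) - mean(b))
  pool <- c(a, b)
  na <- length(a)
  hits <- 0
  for (i in seq_len(reps)) {
    idx <- sample(length(pool), na)
    if (abs(mean(pool[idx]) - mean(pool[-idx])) >= obs - 1e-12) hits <- hits + 1
  }
  hits / reps
}

# Small activity table built directly from a list of per-fly count vectors.
make_activity <- function(series, schedule, bin_minutes = 1L,
                          genotype = "gt") {
  n <- length(series[[1]])
  if (is.null(names(series))) {
    names(series) <- sprintf("fly%02d", seq_along(series))
  }
  phase <- phase_of_bins(schedule, n, bin_minutes)
  long <- purrr::map_dfr(names(series), function(id) {
    tibble::tibble(
      fly_id = id,
      genotype = if (length(genotype) > 1) genotype[[id]] else genotype,
      minute = (seq_len(n) - 1L) * bin_minutes,
      phase = phase,
      count = as.integer(series[[id]])
    )
  })
  as_dam_activity(long, schedule, bin_minutes)
}

ld_only <- function(days = 2) light_schedule(ld_days = days, dd_days = 0)
full_protocol <- function() light_schedule(ld_days = 3, dd_days = 7)
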