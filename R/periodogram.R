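#' Sokolove-Bushell chi-square periodogram for one activity series
#'
#' For each trial period P (an integer number of bins p) the series is
#' folded into `K = floor(N / p)` complete cycles; with column means `M_h`
#' over the p columns and grand mean `M` over the `K * p` used points, the
#' statistic is
#'
#'   `Q_P = K^2 * p * sum_h (M_h - M)^2 / sum_i (x_i - M)^2`
#'
#' where the denominator also runs over the `K * p` used points
#' (equivalently `K * sum_h (M_h - M)^2 / s^2` with `s^2` the plug-in
#' variance of the used points). Under the
#' null of no rhythm, `Q_P` is approximately chi-square with `p - 1`
#' degrees of freedom; the significance line is the `1 - alpha` quantile of
#' that distribution. "Power" is the peak `Q` minus the significance line
#' at the peak, and a series is called rhythmic when power meets
#' `power_threshold` (the conventional cut-off is 20). Widely used
#' periodogram software follows the same construction but rarely documents
#' it; absolute power values depend on this definition, which is therefore
#' stated here explicitly.
#'
#' @param counts Numeric vector: one fly's counts at uniform bins.
#' @param bin_minutes Bin width of `counts`, in minutes (circadian analysis
#'   conventionally uses 30).
#' @param period_range_h Search range in hours (default 16-32).
#' @param step_h Trial-period step in hours; must be a positive integer
#'   multiple of the bin width (default: one bin).
#' @param alpha Significance level for the chi-square line.
#' @param power_threshold Power required to call the series rhythmic.
#' @return A `chi_sq_periodogram` object with elements `period_h`,
#'   `q_stat`, `sig_line`, `peak_period_h`, `power`, `rhythmic`. Ties at
#'   the peak are broken toward the period closest to 24 h. A constant
#'   (zero-variance) series yields `rhythmic = FALSE` and power 0.
#' @examples
#' x <- rep(c(rep(0, 24), rep(10, 24)), 7) # square wave, period 24 h
#' chi_sq_periodogram(x, bin_minutes = 30)
#' @export
chi_sq_periodogram <- function(counts, bin_minutes = 30,
                               period_range_h = c(16, 32), step_h = NULL,
                               alpha = 0.05, power_threshold = 20) {
  bw_h <- bin_minutes / 60
  if (is.null(step_h)) step_h <- bw_h
  step_bins <- step_h / bw_h
  if (abs(step_bins - round(step_bins)) > 1e-9 || step_bins < 1) {
    stop("`step_h` must be a positive integer multiple of the bin width",
         call. = FALSE)
  }
  step_bins <- as.integer(round(step_bins))
  p_lo <- as.integer(ceiling(period_range_h[1] / bw_h - 1e-9))
  p_hi <- as.integer(floor(period_range_h[2] / bw_h + 1e-9))
  p_bins <- seq.int(p_lo, p_hi, by = step_bins)
  n <- length(counts)
  if (n < 2L * p_hi) {
    stop(sprintf("series too short: %d bins, need >= %d (twice the longest trial period)",
                 n, 2L * p_hi), call. = FALSE)
  }

  q <- vapply(p_bins, function(p) {
    k <- n %/% p
    x <- counts[seq_len(k * p)]
    m <- mean(x)
    ss_tot <- sum((x - m)^2)
    if (ss_tot == 0) return(NA_real_)
    col_means <- colMeans(matrix(x, nrow = k, byrow = TRUE))
    k^2 * p * sum((col_means - m)^2) / ss_tot
  }, numeric(1))
  sig <- stats::qchisq(1 - alpha, df = p_bins - 1L)
  period_h <- p_bins * bw_h

  if (all(is.na(q))) {
    message("constant series: periodogram undefined, reported as non-rhythmic")
    q <- rep(0, length(p_bins))
    peak <- which.min(abs(period_h - 24))
    power <- 0
  } else {
    score <- q - sig
    best <- max(score, na.rm = TRUE)
    cand <- which(!is.na(score) & abs(score - best) < 1e-12)
    peak <- cand[which.min(abs(period_h[cand] - 24))]
    power <- score[peak]
  }

  structure(
    list(
      period_h = period_h,
      q_stat = q,
      sig_line = sig,
      peak_period_h = period_h[peak],
      power = power,
      rhythmic = power >= power_threshold,
      alpha = alpha,
      power_threshold = power_threshold,
      bin_minutes = bin_minutes
    ),
    class = "chi_sq_periodogram"
  )
}

#' @export
print.chi_sq_periodogram <- function(x, ...) {
  cat(sprintf(
    "<chi_sq_periodogram> peak %.2f h, power %.1f (threshold %.0f) -> %s\n",
    x$peak_period_h, x$power, x$power_threshold,
    if (x$rhythmic) "rhythmic" else "arrhythmic"
  ))
  invisible(x)
}

#' @rdname chi_sq_periodogram
#' @param x A `chi_sq_periodogram` object.
#' @param ... Unused.
#' @method tidy chi_sq_periodogram
#' @export
tidy.chi_sq_periodogram <- function(x, ...) {
  tibble(period_h = x$period_h, q_stat = x$q_stat, sig_line = x$sig_line,
         power = x$q_stat - x$sig_line)
}

#' @rdname chi_sq_periodogram
#' @method glance chi_sq_periodogram
#' @export
glance.chi_sq_periodogram <- function(x, ...) {
  tibble(peak_period_h = x$peak_period_h, power = x$power,
         rhythmic = x$rhythmic, alpha = x$alpha,
         power_threshold = x$power_threshold)
}

#' @rdname chi_sq_periodogram
#' @param object A `chi_sq_periodogram` object.
#' @method autoplot chi_sq_periodogram
#' @export
autoplot.chi_sq_periodogram <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$period_h)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$q_stat)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$sig_line), linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$peak_period_h,
                        linetype = "dotted", colour = "grey40") +
    ggplot2::labs(x = "trial period (h)", y = "Q statistic",
                  title = sprintf("peak %.2f h, power %.1f",
                                  object$peak_period_h, object$power)) +
    ggplot2::theme_minimal()
}

#' Per-fly periodogram summary over the free-running window
#'
#' Runs [chi_sq_periodogram()] on every fly, restricted by default to DD
#' days 2 through the end (the first DD day is excluded as an entrainment
#' transition). Circadian analysis conventionally uses 30-minute bins;
#' rebin first with [rebin_activity()].
#'
#' @inheritParams bin_minutes
#' @inheritParams chi_sq_periodogram
#' @param window `"dd"` (default) for DD days 2+, `"all"` for the whole
#'   recording, or an integer vector of 0-based minutes `c(from, to)`
#'   (half-open).
#' @return Tibble with `fly_id`, `genotype`, `peak_period_h`, `power`,
#'   `rhythmic`.
#' @export
periodogram_summary <- function(activity, period_range_h = c(16, 32),
                                step_h = NULL, alpha = 0.05,
                                power_threshold = 20, window = "dd") {
  bw <- bin_minutes(activity)
  schedule <- activity_schedule(activity)
  if (identical(window, "dd")) {
    if (schedule$dd_days < 2) {
      stop("free-running period estimation needs at least 2 DD days", call. = FALSE)
    }
    from <- (schedule$ld_days + 1L) * 1440L
    to <- (schedule$ld_days + schedule$dd_days) * 1440L
  } else if (identical(window, "all")) {
    from <- 0L; to <- max(activity$minute) + bw
  } else {
    from <- window[1]; to <- window[2]
  }
  sub <- dplyr::filter(as_tibble(activity),
                       .data$minute >= from, .data$minute < to)
  series <- split(sub$count[order(sub$fly_id, sub$minute)],
                  sub$fly_id[order(sub$fly_id, sub$minute)])
  res <- purrr::map_dfr(names(series), function(id) {
    pg <- suppressMessages(chi_sq_periodogram(
      series[[id]], bin_minutes = bw, period_range_h = period_range_h,
      step_h = step_h, alpha = alpha, power_threshold = power_threshold
    ))
    tibble(fly_id = id, peak_period_h = pg$peak_period_h,
           power = pg$power, rhythmic = pg$rhythmic)
  })
  dplyr::left_join(fly_table(activity), res, by = "fly_id")
}
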