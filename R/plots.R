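#' Eduction bar chart
#'
#' Average-day activity per 30-min bin, one panel per genotype, with the
#' light/dark bar along the x axis implied by ZT (lights off at ZT12 for a
#' 12:12 schedule).
#'
#' @param eduction Tibble from [eduction_profile()] (or a `dam_experiment`).
#' @return A ggplot object.
#' @export
plot_eduction <- function(eduction) {
  if (inherits(eduction, "dam_experiment")) eduction <- eduction$eduction
  ggplot2::ggplot(eduction,
                  ggplot2::aes(x = .data$zt_h, y = .data$mean_counts)) +
    ggplot2::geom_col(width = 0.45, fill = "grey25") +
    ggplot2::facet_wrap(~genotype, ncol = 1) +
    ggplot2::labs(x = "zeitgeber time (h)", y = "beam crosses / 30 min") +
    ggplot2::theme_minimal()
}

#' Average daily sleep profile
#'
#' @param profile Tibble from [sleep_profile()] (or a `dam_experiment`).
#' @return A ggplot object.
#' @export
plot_sleep_profile <- function(profile) {
  if (inherits(profile, "dam_experiment")) profile <- profile$sleep_profile
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$zt_h, y = .data$mean_sleep_min,
                               colour = .data$genotype)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::ylim(0, 30) +
    ggplot2::labs(x = "zeitgeber time (h)", y = "sleep (min / 30 min)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of one group comparison
#'
#' Continuous metrics: mean with SEM error bars. Binary phenotypes:
#' percentage of flies with the binomial-SD error bar.
#'
#' @param comparison A `group_comparison` from [summarize_metric()].
#' @return A ggplot object.
#' @export
plot_group_metric <- function(comparison) {
  s <- comparison$summary
  if (comparison$type == "binary") {
    d <- dplyr::mutate(s, y = 100 * .data$proportion,
                       err = 100 * .data$binomial_sd / .data$n)
    ylab <- paste0("% flies: ", comparison$metric)
  } else {
    d <- dplyr::mutate(s, y = .data$mean, err = .data$sem)
    ylab <- comparison$metric
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$y)) +
    ggplot2::geom_col(fill = "grey70", colour = "black", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$y - .data$err,
                                        ymax = .data$y + .data$err),
                           width = 0.15) +
    ggplot2::labs(x = NULL, y = ylab) +
    ggplot2::theme_classic()
}

#' Box plot of a per-fly sleep metric
#'
#' Median with quartiles and whiskers to the 0th/100th percentiles,
#' matching the field's sleep-figure convention.
#'
#' @param per_fly Per-fly tibble (e.g. `run_experiment()$per_fly`).
#' @param metric Column to plot (string), e.g. `"total_sleep_min"`.
#' @return A ggplot object.
#' @export
plot_sleep_box <- function(per_fly, metric = "total_sleep_min") {
  d <- per_fly[!is.na(per_fly[[metric]]), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$genotype,
                                  y = .data[[metric]])) +
    ggplot2::geom_boxplot(coef = Inf, width = 0.5) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_classic()
}

#' @rdname run_experiment
#' @param which One of `"eduction"`, `"sleep_profile"`, or a metric name
#'   present in the experiment's comparisons.
#' @method autoplot dam_experiment
#' @export
autoplot.dam_experiment <- function(object, which = "eduction", ...) {
  if (which == "eduction") return(plot_eduction(object))
  if (which == "sleep_profile") return(plot_sleep_profile(object))
  if (which %in% names(object$comparisons)) {
    return(plot_group_metric(object$comparisons[[which]]))
  }
  stop("unknown panel '", which, "'", call. = FALSE)
}

#' Save the standard figure set of an experiment
#'
#' Writes the eduction chart, sleep profile, one bar chart per group
#' comparison, and box plots of the sleep metrics as PNG files. Metrics
#' without data are skipped with a warning.
#'
#' @param x A `dam_experiment`.
#' @param dir Output directory.
#' @return Character vector of files written, invisibly.
#' @export
render_figures <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  save_plot <- function(p, name) {
    f <- file.path(dir, paste0(name, ".png"))
    ggplot2::ggsave(f, p, width = 6, height = 4, dpi = 120)
    written <<- c(written, f)
  }
  if (nrow(x$eduction)) save_plot(plot_eduction(x), "eduction") else
    warning("no eduction data; skipped", call. = FALSE)
  if (nrow(x$sleep_profile)) save_plot(plot_sleep_profile(x), "sleep_profile")
  for (m in names(x$comparisons)) {
    save_plot(plot_group_metric(x$comparisons[[m]]), paste0("bar_", m))
  }
  for (m in c("total_sleep_min", "sleep_min_light", "sleep_min_dark")) {
    if (m %in% names(x$per_fly) && any(!is.na(x$per_fly[[m]]))) {
      save_plot(plot_sleep_box(x$per_fly, m), paste0("box_", m))
    }
  }
  invisible(written)
}
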