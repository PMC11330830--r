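#' Standard deviation of a binomial count
#'
#' `sigma = sqrt(n * p * q)` with `q = 1 - p`: the error bar used for
#' percentage-of-flies phenotypes (rhythmicity, morning/evening
#' anticipation).
#'
#' @param n Number of flies.
#' @param p Proportion showing the phenotype.
#' @return `sqrt(n * p * (1 - p))`, vectorised.
#' @examples
#' binomial_sd(100, 0.5) # 5
#' @export
binomial_sd <- function(n, p) {
  stopifnot(all(n >= 1), all(p >= 0 & p <= 1))
  sqrt(n * p * (1 - p))
}

#' Significance stars for a p-value
#'
#' `*` p < 0.05, `**` p < 0.01, `***` p < 0.001, `****` p < 0.0001;
#' empty string otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star strings.
#' @export
p_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 1e-4 ~ "****",
    p < 1e-3 ~ "***",
    p < 1e-2 ~ "**",
    p < 0.05 ~ "*",
    .default = ""
  )
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact two-sided p-value by the probability-mass rule: the sum of
#' hypergeometric probabilities of all tables with the observed margins
#' that are no more probable than the observed one. A table with a zero
#' margin carries no information and returns p = 1.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return The two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0), all(tab == round(tab)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    message("Fisher 2x2: zero margin, p = 1")
    return(1)
  }
  stats::fisher.test(tab)$p.value
}

#' Two-tailed Student's t-test (equal variances)
#'
#' Classic equal-variance Student's t, the convention for pairwise
#' activity/period/sleep comparisons here; set `welch = TRUE` for the
#' unequal-variance form. Degenerate inputs are resolved explicitly: two
#' zero-variance samples with equal means give p = 1; zero variance with
#' different means gives p = 0 with a warning.
#'
#' @param a,b Numeric vectors (each of length >= 2).
#' @param welch Use the Welch correction instead of pooled variance.
#' @return One-row tibble with `statistic`, `df`, `p_value`,
#'   `mean_diff`.
#' @export
t_test_two_tailed <- function(a, b, welch = FALSE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(tibble(statistic = 0, df = length(a) + length(b) - 2,
                    p_value = 1, mean_diff = 0))
    }
    warning("zero variance with different means: p reported as 0", call. = FALSE)
    return(tibble(statistic = Inf, df = length(a) + length(b) - 2,
                  p_value = 0, mean_diff = mean(a) - mean(b)))
  }
  ht <- stats::t.test(a, b, var.equal = !welch, alternative = "two.sided")
  tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value, mean_diff = mean(a) - mean(b))
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' @param values Numeric response vector.
#' @param groups Group labels, same length as `values`; at least 2 values
#'   per group. With fewer than 3 groups the call falls through to
#'   [t_test_two_tailed()] with a warning.
#' @return List with `anova` (one-row tibble: `f_statistic`, `df1`, `df2`,
#'   `p_value`) and `pairwise` (tibble: `comparison`, `mean_diff`,
#'   `p_adj`).
#' @export
anova_tukey <- function(values, groups) {
  groups <- as.factor(as.character(groups))
  stopifnot(length(values) == length(groups))
  if (nlevels(groups) < 3) {
    warning("fewer than 3 groups: using Student's t-test instead of ANOVA",
            call. = FALSE)
    lv <- levels(groups)
    tt <- t_test_two_tailed(values[groups == lv[1]], values[groups == lv[2]])
    return(list(
      anova = tibble(f_statistic = tt$statistic^2, df1 = 1, df2 = tt$df,
                     p_value = tt$p_value),
      pairwise = tibble(comparison = paste(lv[2], lv[1], sep = "-"),
                        mean_diff = -tt$mean_diff, p_adj = tt$p_value)
    ))
  }
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$groups
  list(
    anova = tibble(f_statistic = an[1, "F value"], df1 = an[1, "Df"],
                   df2 = an[2, "Df"], p_value = an[1, "Pr(>F)"]),
    pairwise = tibble(comparison = rownames(tk),
                      mean_diff = unname(tk[, "diff"]),
                      p_adj = unname(tk[, "p adj"]))
  )
}

#' Group summary and test for one per-fly metric
#'
#' Reproduces the field's reporting conventions. Continuous metrics get
#' per-genotype mean +/- SEM and a two-tailed Student's t-test (2 groups)
#' or one-way ANOVA with Tukey HSD (3+ groups). Binary phenotypes
#' (rhythmic, has_ma, has_ea) get the percentage of flies with the
#' binomial SD `sqrt(npq)` as error bar, compared by Fisher's exact test
#' -- against the control group by default, or all pairs. Flies with a
#' missing value are dropped from that metric's denominator. No correction
#' is applied across metrics (only Tukey within a metric).
#'
#' @param data Per-fly tibble (e.g. from [run_experiment()]'s `per_fly`).
#' @param metric Name of the metric column (string). Logical columns are
#'   treated as binary phenotypes, numeric ones as continuous.
#' @param group Name of the grouping column (default `"genotype"`).
#' @param control Reference level for vs-control comparisons; defaults to
#'   the first group in order of appearance.
#' @param pairwise `"control"` (default) or `"all"`.
#' @param welch Use Welch's t instead of Student's for continuous 2-group
#'   contrasts.
#' @return A `group_comparison` object: list with `metric`, `type`,
#'   `summary` (per-group tibble) and `tests` (tibble with `comparison`,
#'   `p_value`, `stars`).
#' @export
summarize_metric <- function(data, metric, group = "genotype",
                             control = NULL, pairwise = c("control", "all"),
                             welch = FALSE) {
  pairwise <- match.arg(pairwise)
  stopifnot(metric %in% names(data), group %in% names(data))
  v <- data[[metric]]
  g <- as.character(data[[group]])
  ok <- !is.na(v) & !is.na(g)
  v <- v[ok]; g <- g[ok]
  lv <- unique(g)
  if (is.null(control)) control <- lv[1]
  if (!control %in% lv) stop("control group '", control, "' not present", call. = FALSE)
  binary <- is.logical(v)

  if (binary) {
    summ <- tibble(group = lv) |>
      dplyr::rowwise() |>
      dplyr::mutate(
        n = sum(g == .data$group),
        successes = sum(v[g == .data$group]),
        proportion = .data$successes / .data$n,
        binomial_sd = binomial_sd(.data$n, .data$proportion)
      ) |>
      dplyr::ungroup()
    pairs <- metric_pairs(lv, control, pairwise)
    tests <- purrr::map_dfr(pairs, function(pr) {
      tab <- rbind(
        c(sum(v[g == pr[1]]), sum(!v[g == pr[1]])),
        c(sum(v[g == pr[2]]), sum(!v[g == pr[2]]))
      )
      tibble(comparison = paste(pr[2], pr[1], sep = " vs "),
             p_value = fisher_exact_2x2(tab))
    })
    method <- "fisher_exact"
  } else {
    summ <- tibble(group = lv) |>
      dplyr::rowwise() |>
      dplyr::mutate(
        n = sum(g == .data$group),
        mean = mean(v[g == .data$group]),
        sem = stats::sd(v[g == .data$group]) / sqrt(.data$n)
      ) |>
      dplyr::ungroup()
    small <- summ$group[summ$n < 2]
    if (length(small)) {
      warning("dropping group(s) with n < 2: ", paste(small, collapse = ", "),
              call. = FALSE)
      keep <- !g %in% small
      v <- v[keep]; g <- g[keep]; lv <- setdiff(lv, small)
    }
    if (length(lv) < 2) {
      tests <- tibble(comparison = character(), p_value = numeric())
      method <- "none"
    } else if (length(lv) == 2) {
      tt <- t_test_two_tailed(v[g == lv[1]], v[g == lv[2]], welch = welch)
      tests <- tibble(comparison = paste(lv[2], lv[1], sep = " vs "),
                      p_value = tt$p_value)
      method <- if (welch) "welch_t" else "t_two_tailed"
    } else {
      at <- anova_tukey(v, g)
      # TukeyHSD labels pairs "b-a"; group labels here never contain "-"
      tests <- dplyr::transmute(
        at$pairwise,
        comparison = sub("-", " vs ", .data$comparison, fixed = TRUE),
        p_value = .data$p_adj
      )
      if (pairwise == "control") {
        keep <- vapply(strsplit(tests$comparison, " vs ", fixed = TRUE),
                       function(x) control %in% x, logical(1))
        tests <- tests[keep, ]
      }
      attr(tests, "anova_p") <- at$anova$p_value
      method <- "anova_tukey"
    }
  }
  tests$stars <- p_stars(tests$p_value)
  structure(
    list(metric = metric, type = if (binary) "binary" else "continuous",
         method = method, control = control, summary = summ, tests = tests),
    class = "group_comparison"
  )
}

metric_pairs <- function(lv, control, pairwise) {
  if (pairwise == "all") {
    cmb <- utils::combn(lv, 2, simplify = FALSE)
  } else {
    cmb <- lapply(setdiff(lv, control), function(x) c(control, x))
  }
  cmb
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s (%s, %s)\n", x$metric, x$type, x$method))
  print(x$summary)
  if (nrow(x$tests)) print(x$tests)
  invisible(x)
}

#' @rdname summarize_metric
#' @param x,object A `group_comparison` object.
#' @param ... Unused.
#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) {
  if (!nrow(x$tests)) return(tibble(metric = character(), comparison = character(),
                                    p_value = numeric(), stars = character()))
  dplyr::mutate(x$tests, metric = x$metric, method = x$method,
                .before = 1)
}

#' @rdname summarize_metric
#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  tibble(metric = x$metric, type = x$type, method = x$method,
         n_groups = nrow(x$summary),
         min_p = if (nrow(x$tests)) min(x$tests$p_value) else NA_real_)
}
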