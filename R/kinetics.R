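#' Population-level percent-positive death curves
#'
#' Fraction mode (default): for each population,
#' `value(t) = 100 * #(death_time <= t) / N0` with `N0` the population's
#' initial cell count (denominators are fixed at t0, so curves are
#' non-decreasing and bounded by \[0, 100\]). Count-per-confluency mode:
#' `value(t) = #(positive at t) / confluency(t)`, an unbounded object count
#' in arbitrary units, pooled over populations.
#'
#' @param death_times per-cell event times in minutes (`NA` = censored); an
#'   `event_table` column such as `draq7_time`, or the `death_time` column of
#'   [call_death()] output.
#' @param populations per-cell population labels (same length).
#' @param times frame times (minutes, strictly increasing) at which to
#'   evaluate the curves.
#' @param mode `"fraction_of_population"` or `"count_per_confluency"`.
#' @param confluency confluency fraction per time point (required for
#'   count-per-confluency mode).
#' @return a `population_curve`: data frame with `time`, `population`,
#'   `value`; attributes `mode` and `population_sizes`.
#' @examples
#' population_curves(c(10, NA, 20, NA), rep("bystander", 4), times = c(0, 15, 30))
#' @export
population_curves <- function(death_times, populations, times,
                              mode = c("fraction_of_population",
                                       "count_per_confluency"),
                              confluency = NULL) {
  mode <- match.arg(mode)
  if (length(death_times) != length(populations))
    stopf("`death_times` and `populations` must have equal length")
  if (any(diff(times) <= 0)) stopf("`times` must be strictly increasing")
  if (mode == "fraction_of_population") {
    pops <- sort(unique(populations))
    out <- do.call(rbind, lapply(pops, function(p) {
      sel <- populations == p
      n0 <- sum(sel)
      if (n0 == 0L) stopf("empty population `%s`", p)
      vals <- vapply(times, function(t)
        100 * sum(!is.na(death_times[sel]) & death_times[sel] <= t) / n0,
        numeric(1))
      data.frame(time = times, population = p, value = vals,
                 stringsAsFactors = FALSE)
    }))
    sizes <- table(populations)
  } else {
    if (is.null(confluency) || length(confluency) != length(times))
      stopf("count-per-confluency mode needs one `confluency` value per time")
    if (any(confluency <= 0)) stopf("confluency must be > 0")
    counts <- vapply(times, function(t)
      sum(!is.na(death_times) & death_times <= t), numeric(1))
    out <- data.frame(time = times, population = "all",
                      value = counts / confluency, stringsAsFactors = FALSE)
    sizes <- c(all = length(death_times))
  }
  attr(out, "mode") <- mode
  attr(out, "population_sizes") <- sizes
  class(out) <- c("population_curve", "data.frame")
  out
}

#' Percent area under a kinetics curve
#'
#' Trapezoidal area under a percent-positive curve over `[t0, t_last]`,
#' normalized by the maximal attainable area (a curve pinned at 100%), times
#' 100: a saturated death curve scores 100, no death scores 0, a linear
#' 0-to-100 ramp scores 50. The statistic is linear in the curve and
#' invariant to affine rescaling of the time axis.
#'
#' @param x a `population_curve` (one value per population is returned) or a
#'   numeric vector of curve values.
#' @param times frame times when `x` is a plain vector.
#' @return for curves: data frame `population`, `pct_auc`, `span_min`;
#'   for vectors: a single `pct_auc` value.
#' @examples
#' pct_auc(seq(0, 100, length.out = 11), times = 0:10)  # 50
#' @export
pct_auc <- function(x, times = NULL) {
  trap <- function(t, v) {
    if (length(t) < 2L) stopf("%%AUC needs at least 2 time points")
    if (any(diff(t) <= 0)) stopf("`times` must be strictly increasing")
    auc <- sum(diff(t) * (head(v, -1L) + v[-1L]) / 2)
    100 * auc / (100 * (t[length(t)] - t[1L]))
  }
  if (inherits(x, "population_curve")) {
    if (!identical(attr(x, "mode"), "fraction_of_population"))
      stopf("%%AUC is defined for fraction-of-population curves")
    pops <- unique(x$population)
    data.frame(population = pops,
               pct_auc = vapply(pops, function(p) {
                 sub <- x[x$population == p, , drop = FALSE]
                 trap(sub$time, sub$value)
               }, numeric(1)),
               span_min = max(x$time) - min(x$time),
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    if (is.null(times)) stopf("`times` required for a plain value vector")
    trap(times, x)
  }
}

#' Summarize uncensored event times
#'
#' Mean, minimum and maximum of the observed (uncensored) event times, with
#' the censored count reported separately — censored times are never
#' imputed. With all times censored the summary is undefined and flagged.
#'
#' @param times event times in minutes, `NA` = censored. Pass e.g.
#'   `events$blebbing_time[events$cause == "opto"]` for the time from
#'   activation to blebbing of directly activated cells.
#' @return list with `mean`, `min`, `max`, `n`, `n_censored`,
#'   `all_censored`.
#' @examples
#' time_to_event_summary(c(13, 17, 20))$mean  # 16.67
#' @export
time_to_event_summary <- function(times) {
  if (!length(times)) stopf("empty group")
  obs <- times[!is.na(times)]
  n_cens <- sum(is.na(times))
  if (!length(obs)) {
    return(list(mean = NA_real_, min = NA_real_, max = NA_real_, n = 0L,
                n_censored = n_cens, all_censored = TRUE))
  }
  list(mean = mean(obs), min = min(obs), max = max(obs), n = length(obs),
       n_censored = n_cens, all_censored = FALSE)
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' Routine group comparison used for %AUC panels and oxidation-ratio
#' summaries: standard one-way ANOVA F and p, with Tukey honest significant
#' difference adjusted p-values for all pairs. If the within-group variance
#' is (numerically) zero the F statistic is undefined and the result is
#' flagged `degenerate` rather than reporting a spurious value.
#'
#' @param values numeric response.
#' @param groups group labels (>= 2 groups with >= 2 values each).
#' @return list with `f`, `p`, `df`, `pairwise` (data frame `comparison`,
#'   `diff`, `lwr`, `upr`, `p_adj`) and `degenerate`.
#' @export
compare_groups <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stopf("need at least 2 groups")
  if (any(table(groups) < 2L)) stopf("every group needs at least 2 values")
  fit <- aov(values ~ groups)
  an <- summary(fit)[[1L]]
  ss_within <- an["Residuals", "Sum Sq"]
  scale <- sum(values^2) + 1
  if (ss_within / scale < 1e-12) {
    return(list(f = NA_real_, p = NA_real_,
                df = unname(an[, "Df"]), pairwise = NULL, degenerate = TRUE))
  }
  tk <- TukeyHSD(fit)$groups
  pw <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                   lwr = tk[, "lwr"], upr = tk[, "upr"],
                   p_adj = tk[, "p adj"], row.names = NULL,
                   stringsAsFactors = FALSE)
  list(f = an["groups", "F value"], p = an["groups", "Pr(>F)"],
       df = unname(an[, "Df"]), pairwise = pw, degenerate = FALSE)
}
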