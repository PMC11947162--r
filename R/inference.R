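#' Estimate the per-contact spread probability by chain-binomial likelihood
#'
#' Time is discretized at `dt`. A cell "newly dead" in a step is one whose
#' blebbing time falls in that step; every alive, unconverted cell with `k`
#' newly dead contact neighbours that step is a chain-binomial exposure with
#' escape probability `(1 - p)^k`. Conversion itself is unobservable — only
#' the oxidation onset, which lags conversion by a positive delay — so a
#' converted cell's onset is attributed to its exposures inside the delay
#' window: with `window = c(w_lo, w_hi)`, exposures at `t` with
#' `w_lo <= onset - t <= w_hi` are bracketed into one
#' "at least one of these converted me" term `1 - (1 - p)^K`
#' (`K` = summed neighbour count over the bracket); exposures older than
#' `w_hi` before onset are escape trials; exposures more recent than `w_lo`
#' (almost surely after the true conversion) are ignored. For never-converted
#' cells an exposure at `t` is an escape only insofar as a conversion there
#' would already be visible by `censor_time`; its likelihood term is
#' `1 - (1 - (1 - p)^k) F(censor_time - t)`, with the delay CDF `F`
#' approximated as a linear ramp from 0 at `w_lo` to 1 at `w_hi` (a plain
#' escape for old exposures, uninformative for exposures at the very end of
#' the assay). Converted cells with no bracketed exposure
#' (directly activated cells, background deaths) contribute only their escape
#' trials. The likelihood is maximized over `p` on \[0, 1\] by grid
#' evaluation refined with golden-section search; boundary maxima return
#' exactly 0 or 1.
#'
#' @param events an `event_table`.
#' @param graph the `contact_graph` over the same cells.
#' @param dt discretization step, minutes; should match the observation
#'   cadence (defaults to the event table's `dt`).
#' @param window attribution window in minutes: `c(w_lo, w_hi)` bounds on the
#'   plausible conversion-to-onset delay (a single number is taken as
#'   `c(0, window)`). The default brackets the 0.1-99.9% range of the
#'   generator's default lognormal onset delay.
#' @param censor_time end of observation, minutes (defaults to the event
#'   table's `t_end`).
#' @param grid_n number of grid points for the likelihood profile.
#' @return a `spread_fit`: list with `p_hat`, `profile` (data frame `p`,
#'   `loglik`), `exposures` (number of likelihood terms), `conversions`
#'   (number of success terms), `window`, `dt`.
#' @export
fit_spread_probability <- function(events, graph, dt = attr(events, "dt"),
                                   window = c(8, 110),
                                   censor_time = attr(events, "t_end"),
                                   grid_n = 1001L) {
  if (is.null(dt)) stopf("`dt` is required")
  check_pos(dt, "dt")
  if (length(window) == 1L) window <- c(0, window)
  if (length(window) != 2L || window[1L] < 0 || window[2L] <= window[1L])
    stopf("`window` must be c(w_lo, w_hi) with 0 <= w_lo < w_hi")
  ids <- events$id
  nbrs <- adjacency_list(graph, ids)
  n <- length(ids)
  bleb <- events$blebbing_time
  ox <- events$ox_onset_time
  t_max <- suppressWarnings(max(c(bleb, ox), na.rm = TRUE))
  if (!is.finite(t_max)) stopf("no observed events")
  censor_time <- censor_time %||% t_max
  steps <- seq(dt, ceiling(t_max / dt) * dt, by = dt)

  # exposure lists: step times and neighbour counts per cell while alive
  exp_t <- vector("list", n)
  exp_k <- vector("list", n)
  for (t in steps) {
    nd <- which(!is.na(bleb) & bleb > t - dt & bleb <= t)
    if (!length(nd)) next
    k <- integer(n)
    for (i in nd) {
      nb <- nbrs[[i]]
      if (length(nb)) k[nb] <- k[nb] + 1L
    }
    cand <- which(k > 0L & (is.na(bleb) | bleb > t))
    for (i in cand) {
      exp_t[[i]] <- c(exp_t[[i]], t)
      exp_k[[i]] <- c(exp_k[[i]], k[i])
    }
  }

  # delay-visibility ramp: 0 below w_lo, 1 above w_hi
  vis <- function(lag) pmin(1, pmax(0, (lag - window[1L]) /
                                      (window[2L] - window[1L])))
  k_succ <- integer(0)   # bracketed neighbour totals, one per conversion
  k_fail <- integer(0)   # neighbour counts of escape terms
  f_fail <- numeric(0)   # visibility weight of each escape term
  for (i in seq_len(n)) {
    et <- exp_t[[i]]
    if (is.null(et)) next
    ek <- exp_k[[i]]
    if (!is.na(ox[i])) {
      lag <- ox[i] - et
      brk <- lag >= window[1L] & lag <= window[2L]
      if (any(brk)) k_succ <- c(k_succ, sum(ek[brk]))
      esc <- lag > window[2L]
      k_fail <- c(k_fail, ek[esc])
      f_fail <- c(f_fail, rep(1, sum(esc)))
    } else {
      fv <- vis(censor_time - et)
      inf_ <- fv > 0
      k_fail <- c(k_fail, ek[inf_])
      f_fail <- c(f_fail, fv[inf_])
    }
  }
  n_trials <- length(k_succ) + length(k_fail)
  if (n_trials == 0L)
    stopf("zero exposure opportunities: spread probability unidentifiable")

  loglik <- function(p) {
    if (p <= 0) return(if (length(k_succ)) -Inf else 0)
    if (p >= 1) {
      if (any(f_fail >= 1)) return(-Inf)
      return(sum(log1p(-f_fail)))
    }
    q_fail <- 1 - (1 - p)^k_fail
    sum(log1p(-(1 - p)^k_succ)) + sum(log1p(-q_fail * f_fail))
  }
  p_grid <- seq(0, 1, length.out = grid_n)
  ll <- vapply(p_grid, loglik, numeric(1))
  p_hat <- if (!length(k_succ)) 0
  else if (!length(k_fail)) 1
  else {
    i0 <- which.max(ll)
    lo <- p_grid[max(1L, i0 - 1L)]
    hi <- p_grid[min(grid_n, i0 + 1L)]
    opt <- optimize(loglik, lower = lo, upper = hi, maximum = TRUE,
                    tol = 1e-8)
    opt$maximum
  }
  structure(list(p_hat = p_hat,
                 profile = data.frame(p = p_grid, loglik = ll),
                 exposures = n_trials, conversions = length(k_succ),
                 window = window, dt = dt),
            class = "spread_fit")
}

#' @export
print.spread_fit <- function(x, ...) {
  cat(sprintf("chain-binomial spread fit: p_hat = %.3f (%d conversions / %d trials)\n",
              x$p_hat, x$conversions, x$exposures))
  invisible(x)
}

#' Composite propagation-versus-random decision
#'
#' Combines the two spatial lines of evidence for contact-dependent spread:
#' the Hopkins cluster tendency of the dead-cell pattern, and a permutation
#' test of whether dead bystanders sit closer to dead transfected cells than
#' expected when death strikes each population at random over the fixed
#' monolayer geometry. Verdict: `"propagating"` when the permutation p-value
#' is below `alpha` *and* `H_mean > h_threshold`; `"random"` when the
#' p-value is at or above `alpha`; `"inconclusive"` otherwise.
#'
#' @param events an `event_table`.
#' @param cells the matching `cell_table` (geometry and population labels).
#' @param reps permutation replicates.
#' @param seed integer seed (drives the Hopkins resampling and the
#'   permutation null).
#' @param alpha significance level for the permutation test.
#' @param h_threshold Hopkins cut-off for calling clustering.
#' @param hopkins_reps Hopkins replicates.
#' @return a `propagation_report`: list with `H_mean`, `H_sd`,
#'   `observed_median_um`, `p_value`, `verdict`, `alpha`, `h_threshold`,
#'   and counts `n_dead_source` / `n_dead_target`.
#' @export
propagation_test <- function(events, cells, reps = 999L, seed = 1L,
                             alpha = 0.05, h_threshold = 0.5,
                             hopkins_reps = 100L) {
  dead <- !is.na(events$draq7_time) | !is.na(events$blebbing_time)
  dead <- dead[match(cells$id, events$id)]
  d_src <- dead & cells$population == "bystander"
  d_tgt <- dead & cells$population == "transfected"
  if (sum(d_src) < 5L || sum(d_tgt) < 5L)
    stopf("need >= 5 dead cells in each population (got %d bystander, %d transfected)",
          sum(d_src), sum(d_tgt))
  win <- c(min(cells$x), max(cells$x), min(cells$y), max(cells$y))
  hp <- hopkins(point_pattern(cells$x[dead], cells$y[dead], win),
                reps = hopkins_reps, seed = seed)
  obs <- median(nearest_neighbor_distances(
    point_pattern(cells$x[d_src], cells$y[d_src], win),
    point_pattern(cells$x[d_tgt], cells$y[d_tgt], win)))
  null <- distance_permutation_null(cells, observed_median = obs,
                                    n_dead_source = sum(d_src),
                                    n_dead_target = sum(d_tgt),
                                    reps = reps, seed = seed)
  verdict <- if (null$p_value < alpha && hp$H_mean > h_threshold) "propagating"
  else if (null$p_value >= alpha) "random"
  else "inconclusive"
  structure(list(H_mean = hp$H_mean, H_sd = hp$H_sd,
                 observed_median_um = obs, p_value = null$p_value,
                 verdict = verdict, alpha = alpha, h_threshold = h_threshold,
                 n_dead_source = sum(d_src), n_dead_target = sum(d_tgt)),
            class = "propagation_report")
}

#' @export
print.propagation_report <- function(x, ...) {
  cat(sprintf(paste0("propagation report: verdict = %s\n",
                     "  Hopkins H = %.3f +/- %.3f; median cross-NN = %.1f um; ",
                     "permutation p = %.4g\n"),
              x$verdict, x$H_mean, x$H_sd, x$observed_median_um, x$p_value))
  invisible(x)
}
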