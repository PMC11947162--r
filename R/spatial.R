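#' Construct a planar point pattern
#'
#' @param x,y coordinates in micrometres (image convention, y downward).
#' @param window observation window `c(xmin, xmax, ymin, ymax)`; defaults to
#'   the bounding box of the points. For dead-cell analyses pass the bounding
#'   box of the *full* cell population: the field of view is the sampling
#'   frame, and a window shrunk to the dead cells would bias cluster-tendency
#'   statistics upward.
#' @return a `point_pattern`: list with `x`, `y`, `window`, `n`.
#' @export
point_pattern <- function(x, y, window = NULL) {
  if (length(x) != length(y)) stopf("`x` and `y` must have equal length")
  if (is.null(window)) {
    window <- if (length(x)) c(min(x), max(x), min(y), max(y))
              else c(0, 1, 0, 1)
  }
  if (length(window) != 4L || window[2L] < window[1L] || window[4L] < window[3L])
    stopf("`window` must be c(xmin, xmax, ymin, ymax)")
  if (length(x) && (any(x < window[1L] | x > window[2L]) ||
                    any(y < window[3L] | y > window[4L])))
    stopf("all points must lie inside the window")
  structure(list(x = as.numeric(x), y = as.numeric(y), window = window,
                 n = length(x)), class = "point_pattern")
}

as_point_pattern <- function(p, window = NULL) {
  if (inherits(p, "point_pattern")) return(p)
  point_pattern(p$x, p$y, window)
}

# distance from each of (px, py) to the nearest of (qx, qy)
min_dist_to <- function(px, py, qx, qy) {
  d2 <- outer(px, qx, "-")^2 + outer(py, qy, "-")^2
  sqrt(apply(d2, 1L, min))
}

#' Hopkins cluster-tendency statistic
#'
#' Per replicate, `m` sampling locations are drawn uniformly in the window
#' and `m` events are drawn without replacement from the pattern. With
#' `u_i` the distance from sampling location `i` to the nearest event and
#' `w_i` the distance from sampled event `i` to its nearest other event,
#' \deqn{H = \frac{\sum u_i^d}{\sum u_i^d + \sum w_i^d}.}
#' `H` is about 0.5 under complete spatial randomness, approaches 1 for
#' clustered patterns, and falls below 0.5 for regular (inhibited) patterns.
#' The statistic is reported as mean and SD over `reps` replicates.
#'
#' @param pattern a `point_pattern` with at least 5 events.
#' @param m sampling size, `1 <= m <= n - 1`; default `max(5, round(0.1 n))`.
#' @param d distance exponent (2 = squared distances, the common convention).
#' @param reps number of replicates.
#' @param seed integer seed.
#' @return a `hopkins_result`: list with `H_mean`, `H_sd`, `H` (per-replicate
#'   values), `m`, `d`, `reps`, `seed`.
#' @examples
#' set.seed(1)
#' p <- point_pattern(runif(100), runif(100), c(0, 1, 0, 1))
#' hopkins(p, m = 10, reps = 50, seed = 1)$H_mean
#' @export
hopkins <- function(pattern, m = NULL, d = 2, reps = 100, seed = 1L) {
  pattern <- as_point_pattern(pattern)
  n <- pattern$n
  if (n < 5L) stopf("need at least 5 events (got %d)", n)
  m <- m %||% max(5L, round(0.1 * n))
  if (m < 1L || m > n - 1L) stopf("`m` must be in [1, n - 1]")
  w <- pattern$window
  if ((w[2L] - w[1L]) <= 0 || (w[4L] - w[3L]) <= 0)
    stopf("degenerate (zero-area) window")
  check_pos(d, "d")
  H <- withr::with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      ux <- runif(m, w[1L], w[2L])
      uy <- runif(m, w[3L], w[4L])
      u <- min_dist_to(ux, uy, pattern$x, pattern$y)
      ev <- sample.int(n, m)
      d2 <- outer(pattern$x[ev], pattern$x, "-")^2 +
        outer(pattern$y[ev], pattern$y, "-")^2
      d2[cbind(seq_len(m), ev)] <- Inf   # exclude self
      wi <- sqrt(apply(d2, 1L, min))
      su <- sum(u^d)
      sw <- sum(wi^d)
      if (su + sw == 0) return(0.5)
      su / (su + sw)
    }, numeric(1))
  })
  structure(list(H_mean = mean(H), H_sd = if (reps > 1L) sd(H) else NA_real_,
                 H = H, m = m, d = d, reps = reps, seed = seed),
            class = "hopkins_result")
}

#' @export
print.hopkins_result <- function(x, ...) {
  cat(sprintf("Hopkins H = %.3f +/- %.3f (m = %d, d = %g, %d reps)\n",
              x$H_mean, x$H_sd, x$m, x$d, x$reps))
  invisible(x)
}

#' Nearest-neighbour distances within or across point patterns
#'
#' With a `target` pattern: for every source point, the Euclidean distance to
#' the nearest target point (cross-type, e.g. dead bystander to dead
#' transfected). Without one: the distance to the nearest *other* point of
#' the source pattern. Distances are centroid-to-centroid with no edge
#' correction; near-boundary distances therefore carry the usual outward
#' bias.
#'
#' @param source a `point_pattern` (or list/data frame with `x`, `y`),
#'   non-empty.
#' @param target optional second pattern; must be non-empty when given.
#' @return a `distance_set`: numeric vector, one distance per source point,
#'   with attributes `mode` (`"cross"`/`"within"`) and `nn_index` (index of
#'   the matched neighbour, ties broken toward the lowest index).
#' @examples
#' nearest_neighbor_distances(point_pattern(0, 0),
#'                            point_pattern(3, 4))  # 5
#' @export
nearest_neighbor_distances <- function(source, target = NULL) {
  source <- as_point_pattern(source)
  if (source$n < 1L) stopf("`source` must be non-empty")
  if (!is.null(target)) {
    target <- as_point_pattern(target)
    if (target$n < 1L) stopf("`target` must be non-empty")
    d2 <- outer(source$x, target$x, "-")^2 + outer(source$y, target$y, "-")^2
    nn <- apply(d2, 1L, which.min)   # which.min takes the lowest index on ties
    dist <- sqrt(d2[cbind(seq_len(source$n), nn)])
    mode <- "cross"
  } else {
    if (source$n < 2L) stopf("within-pattern distances need >= 2 points")
    d2 <- outer(source$x, source$x, "-")^2 + outer(source$y, source$y, "-")^2
    diag(d2) <- Inf
    nn <- apply(d2, 1L, which.min)
    dist <- sqrt(d2[cbind(seq_len(source$n), nn)])
    mode <- "within"
  }
  structure(dist, mode = mode, nn_index = nn, class = "distance_set")
}

#' Permutation null for the median cross-type nearest-neighbour distance
#'
#' Holds the monolayer geometry fixed and resamples *which* cells died:
#' per replicate, `n_dead_source` cells are drawn uniformly from the source
#' population and `n_dead_target` from the target population, and the median
#' source-to-target nearest-neighbour distance is computed. The p-value for
#' an observed median uses the add-one rule
#' `p = (1 + #\{null <= observed\}) / (reps + 1)` (small = observed distances
#' shorter than expected under spatially random death).
#'
#' @param cells data frame with `x`, `y`, `population`.
#' @param observed_median observed median cross-NN distance (um), or `NA` to
#'   return the null distribution only.
#' @param n_dead_source,n_dead_target number of dead cells per population.
#' @param source_population,target_population population labels.
#' @param reps replicates.
#' @param seed integer seed.
#' @return list with `null` (numeric vector of null medians), `observed`,
#'   `p_value` (`NA` when no observed value given), `reps`, `seed`.
#' @export
distance_permutation_null <- function(cells, observed_median = NA_real_,
                                      n_dead_source, n_dead_target,
                                      source_population = "bystander",
                                      target_population = "transfected",
                                      reps = 999L, seed = 1L) {
  src_pool <- which(cells$population == source_population)
  tgt_pool <- which(cells$population == target_population)
  if (n_dead_source < 1L || n_dead_source > length(src_pool))
    stopf("infeasible `n_dead_source` (%d of %d available)",
          n_dead_source, length(src_pool))
  if (n_dead_target < 1L || n_dead_target > length(tgt_pool))
    stopf("infeasible `n_dead_target` (%d of %d available)",
          n_dead_target, length(tgt_pool))
  null <- withr::with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      s <- resample(src_pool, n_dead_source)
      t <- resample(tgt_pool, n_dead_target)
      median(min_dist_to(cells$x[s], cells$y[s], cells$x[t], cells$y[t]))
    }, numeric(1))
  })
  p <- if (is.na(observed_median)) NA_real_
       else (1 + sum(null <= observed_median)) / (reps + 1)
  list(null = null, observed = observed_median, p_value = p,
       reps = reps, seed = seed)
}
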