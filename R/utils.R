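`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Draw from a truncated normal distribution
#'
#' Inverse-CDF sampler for a normal distribution restricted to
#' `[lower, upper]`. Used for opto-triggered death times (bounded to the
#' observed single-cell range) and for non-negative onset-to-death delays.
#'
#' @param n number of draws.
#' @param mean,sd mean and standard deviation of the parent normal (minutes).
#' @param lower,upper truncation bounds.
#' @return numeric vector of length `n`.
#' @keywords internal
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd <= 0) return(rep(min(max(mean, lower), upper), n))
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  if (phi <= plo) return(rep(min(max(mean, lower), upper), n))
  qnorm(runif(n, plo, phi), mean, sd)
}

# sample() treats a length-1 numeric x as 1:x; this does not
resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_prob <- function(x, name) {
  if (!is_scalar_number(x) || x < 0 || x > 1)
    stopf("`%s` must be a single number in [0, 1] (got %s)", name,
          paste(format(x), collapse = ", "))
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is_scalar_number(x) || x < 0)
    stopf("`%s` must be a single non-negative number", name)
  invisible(x)
}

check_pos <- function(x, name) {
  if (!is_scalar_number(x) || x <= 0)
    stopf("`%s` must be a single positive number", name)
  invisible(x)
}

# 1-D Otsu split: threshold maximizing between-class variance over all
# midpoints between consecutive sorted unique values. Returns the threshold;
# attribute "separation" carries (|m2 - m1| / pooled within-class sd), a crude
# bimodality score used by classify_populations("auto").
otsu_split <- function(v) {
  u <- sort(unique(v))
  if (length(u) < 2L) stopf("cannot split a constant distribution")
  cand <- (head(u, -1L) + u[-1L]) / 2
  best <- -Inf
  best_th <- cand[1L]
  for (th in cand) {
    lo <- v[v < th]; hi <- v[v >= th]
    bc <- length(lo) * length(hi) * (mean(hi) - mean(lo))^2
    if (bc > best) { best <- bc; best_th <- th }
  }
  lo <- v[v < best_th]; hi <- v[v >= best_th]
  sw <- sqrt((sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)) /
               max(1L, length(v) - 2L))
  sep <- if (sw == 0) Inf else abs(mean(hi) - mean(lo)) / sw
  structure(best_th, separation = sep)
}
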