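#' Simulate contact-dependent death propagation on a monolayer
#'
#' Discrete-time chain-binomial simulation with step `dt`:
#'
#' 1. At t = 0 every illuminated transfected cell converts (oxidation onset
#'    0) and its blebbing time is drawn from a truncated normal on
#'    `[opto_death_min, opto_death_max]` (cause `"opto"`).
#' 2. At each step, every alive unconverted cell with `k` contact neighbours
#'    that blebbed during that step converts with probability
#'    `1 - (1 - p_eff)^k`, where
#'    `p_eff = p_spread * iron_factor * fer1(t) * contacts_enabled` and
#'    `fer1(t)` is `fer1_efficacy` once `t >= fer1_time`, 1 before.
#'    Converted cells receive `ox_onset = t + lognormal delay` and
#'    `blebbing = ox_onset + truncated-normal onset-to-death delay`
#'    (cause `"propagated"`).
#' 3. If `bilayer_range` is set, newly dead cells additionally expose
#'    non-contacting cells within that range, with per-pair probability
#'    `p_spread * iron_factor * fer1(t) * (1 - distance / bilayer_range)`
#'    (not gated by `contacts_enabled`: this channel models oxidation
#'    travelling along a supported bilayer rather than through junctions).
#' 4. A background hazard (per-minute probability, compounded per step)
#'    applies to all alive unconverted cells (cause `"background"`;
#'    onset at the step, death after an onset-to-death delay).
#' 5. `draq7_time = blebbing_time + draq7_lag`.
#'
#' Times beyond `t_end` are censored to `NA`; a cell whose oxidation onset
#' itself falls beyond `t_end` is reported entirely unobserved
#' (cause `"none"`).
#'
#' @param cells a `cell_table` from [generate_monolayer()].
#' @param graph a `contact_graph` over the same cells.
#' @param config the [simulation_config()] (its `seed` drives all draws).
#' @return an `event_table`: data frame with `id`, `ox_onset_time`,
#'   `blebbing_time`, `draq7_time` (minutes or `NA` when censored) and
#'   `cause` (`"opto"`, `"propagated"`, `"background"`, `"none"`);
#'   attributes `t_end`, `dt`, `config`.
#' @export
simulate_propagation <- function(cells, graph, config) {
  validate_simulation_config(config)
  n <- nrow(cells)
  nbrs <- adjacency_list(graph, cells$id)
  mods <- config$modifiers
  if (config$n_illuminated > 0 &&
      !any(cells$illuminated & cells$population == "transfected"))
    stopf("no illuminated transfected cells present")
  if (any(cells$illuminated & cells$population != "transfected"))
    stopf("illuminated cells must be transfected")

  bil <- !is.null(mods$bilayer_range)
  if (bil) {
    dmat <- as.matrix(dist(cbind(cells$x, cells$y)))
    contact <- matrix(FALSE, n, n)
    if (nrow(graph$edges)) {
      i <- match(graph$edges$from, cells$id)
      j <- match(graph$edges$to, cells$id)
      contact[cbind(i, j)] <- TRUE
      contact[cbind(j, i)] <- TRUE
    }
  }

  withr::with_seed(config$seed, {
    conv <- rep(NA_real_, n)   # conversion (exposure-success) time
    ox   <- rep(NA_real_, n)
    bleb <- rep(NA_real_, n)
    cause <- rep("none", n)

    illum <- which(cells$illuminated)
    if (length(illum)) {
      conv[illum] <- 0
      ox[illum] <- 0
      bleb[illum] <- rtruncnorm(length(illum), config$opto_death_mean,
                                config$opto_death_sd, config$opto_death_min,
                                config$opto_death_max)
      cause[illum] <- "opto"
    }

    convert <- function(idx, t, why) {
      if (!length(idx)) return()
      conv[idx] <<- t
      ox[idx] <<- t + rlnorm(length(idx), config$onset_delay_meanlog,
                             config$onset_delay_sdlog)
      bleb[idx] <<- ox[idx] + rtruncnorm(length(idx),
                                         config$onset_to_death_mean,
                                         config$onset_to_death_sd, lower = 0)
      cause[idx] <<- why
    }

    p_bg_step <- 1 - (1 - config$background_hazard)^config$dt
    reported <- rep(FALSE, n)
    for (t in seq(config$dt, config$t_end, by = config$dt)) {
      new_dead <- which(!reported & !is.na(bleb) & bleb <= t)
      reported[new_dead] <- TRUE
      fer1_mult <- if (!is.null(mods$fer1_time) && t >= mods$fer1_time)
        mods$fer1_efficacy else 1
      p_base <- config$p_spread * mods$iron_factor * fer1_mult
      if (length(new_dead) && p_base >= 0) {
        p_eff <- p_base * as.numeric(mods$contacts_enabled)
        k <- integer(n)
        for (i in new_dead) {
          nb <- nbrs[[i]]
          if (length(nb)) k[nb] <- k[nb] + 1L
        }
        cand <- which(is.na(conv) & k > 0L)
        if (length(cand)) {
          p_conv <- 1 - (1 - p_eff)^k[cand]
          hit <- runif(length(cand)) < p_conv
          convert(cand[hit], t, "propagated")
        }
        if (bil) {
          cand2 <- which(is.na(conv))
          if (length(cand2)) {
            sub <- dmat[cand2, new_dead, drop = FALSE]
            ct <- contact[cand2, new_dead, drop = FALSE]
            q <- p_base * pmax(1 - sub / mods$bilayer_range, 0)
            q[ct] <- 0          # contact pairs already handled above
            p_exp <- 1 - apply(1 - q, 1L, prod)
            hit2 <- runif(length(cand2)) < p_exp
            convert(cand2[hit2], t, "propagated")
          }
        }
      }
      if (p_bg_step > 0) {
        cand <- which(is.na(conv))
        if (length(cand)) {
          hit <- runif(length(cand)) < p_bg_step
          bg <- cand[hit]
          if (length(bg)) {
            conv[bg] <- t
            ox[bg] <- t
            bleb[bg] <- t + rtruncnorm(length(bg), config$onset_to_death_mean,
                                       config$onset_to_death_sd, lower = 0)
            cause[bg] <- "background"
          }
        }
      }
    }

    draq7 <- bleb + mods$draq7_lag
    censor <- function(x) ifelse(!is.na(x) & x <= config$t_end, x, NA_real_)
    ox_o <- censor(ox); bleb_o <- censor(bleb); draq7_o <- censor(draq7)
    unobserved <- is.na(ox_o)
    bleb_o[unobserved] <- NA_real_
    draq7_o[unobserved] <- NA_real_
    cause_o <- ifelse(unobserved, "none", cause)

    ev <- data.frame(id = cells$id, ox_onset_time = ox_o,
                     blebbing_time = bleb_o, draq7_time = draq7_o,
                     cause = cause_o, stringsAsFactors = FALSE)
    attr(ev, "t_end") <- config$t_end
    attr(ev, "dt") <- config$dt
    attr(ev, "config") <- config
    class(ev) <- c("event_table", "data.frame")
    ev
  })
}

#' Read and write event tables as CSV
#'
#' Censored times are stored as empty cells; `t_end` travels in a
#' `t_end` column (constant).
#'
#' @param events an `event_table`.
#' @param path CSV path.
#' @return the reader returns an `event_table`; the writer returns `path`
#'   invisibly.
#' @export
write_event_table <- function(events, path) {
  df <- as.data.frame(events)
  df$t_end <- attr(events, "t_end") %||% NA_real_
  df$dt <- attr(events, "dt") %||% NA_real_
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  t_end <- if ("t_end" %in% names(df)) df$t_end[1L] else NA_real_
  dt <- if ("dt" %in% names(df)) df$dt[1L] else NA_real_
  df$t_end <- NULL; df$dt <- NULL
  attr(df, "t_end") <- t_end
  attr(df, "dt") <- dt
  class(df) <- c("event_table", "data.frame")
  df
}
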