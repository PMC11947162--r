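# Shared fixtures: everything is generated in code at test time.

# a compact monolayer for fast unit tests (~75 cells)
small_cfg <- function(seed = 42L, n_illuminated = 3, ...) {
  simulation_config(field_size = 250, n_illuminated = n_illuminated,
                    seed = seed, ...)
}

sim_triplet <- function(cfg, kappa = 1.5) {
  cells <- generate_monolayer(cfg)
  graph <- build_contact_graph(cells, kappa = kappa)
  events <- simulate_propagation(cells, graph, cfg)
  list(cells = cells, graph = graph, events = events)
}

# an all-censored event table (nobody dies) for renderer-only tests
events_none <- function(cells, t_end = 10, dt = 2) {
  n <- nrow(cells)
  ev <- data.frame(id = cells$id, ox_onset_time = rep(NA_real_, n),
                   blebbing_time = rep(NA_real_, n),
                   draq7_time = rep(NA_real_, n),
                   cause = rep("none", n), stringsAsFactors = FALSE)
  attr(ev, "t_end") <- t_end
  attr(ev, "dt") <- dt
  class(ev) <- c("event_table", "data.frame")
  ev
}

# hand-built timecourses: one channel, values[cell, frame]
make_tc <- function(values, times, channel = "draq7") {
  nc <- nrow(values); nt <- ncol(values)
  tc <- data.frame(cell = rep(seq_len(nc), times = nt),
                   frame = rep(seq_len(nt), each = nc),
                   time = rep(times, each = nc),
                   channel = channel,
                   value = as.numeric(values),
                   stringsAsFactors = FALSE)
  attr(tc, "frame_times") <- times
  attr(tc, "channels") <- channel
  class(tc) <- c("cell_timecourses", "data.frame")
  tc
}

# a hand-built three-cell chain: cell 1 dies at t = 10, exposing cells 2 and 3
chain_events <- function(ox2, ox3, t_end = 400) {
  ev <- data.frame(id = 1:3,
                   ox_onset_time = c(0, ox2, ox3),
                   blebbing_time = c(10, ox2 + 60, ox3 + 60),
                   draq7_time = c(14, ox2 + 64, ox3 + 64),
                   cause = c("opto", "propagated", "propagated"),
                   stringsAsFactors = FALSE)
  ev$blebbing_time[is.na(ev$ox_onset_time)] <- NA
  ev$draq7_time[is.na(ev$ox_onset_time)] <- NA
  ev$cause[is.na(ev$ox_onset_time)] <- "none"
  attr(ev, "t_end") <- t_end
  attr(ev, "dt") <- 2
  class(ev) <- c("event_table", "data.frame")
  ev
}
chain_graph <- function() {
  structure(list(edges = data.frame(from = c(1L, 1L), to = c(2L, 3L)),
                 kappa = 1, ids = 1:3), class = "contact_graph")
}

# independent brute-force nearest-neighbour oracle (explicit loop per point)
brute_nn <- function(sx, sy, tx = NULL, ty = NULL) {
  if (is.null(tx)) {
    vapply(seq_along(sx), function(i) {
      d <- sqrt((sx[i] - sx[-i])^2 + (sy[i] - sy[-i])^2)
      min(d)
    }, numeric(1))
  } else {
    vapply(seq_along(sx), function(i) {
      min(sqrt((sx[i] - tx)^2 + (sy[i] - ty)^2))
    }, numeric(1))
  }
}

# percent-positive curve by direct counting (oracle for population_curves)
count_curve <- function(death_times, times, n0) {
  vapply(times, function(t)
    100 * sum(!is.na(death_times) & death_times <= t) / n0, numeric(1))
}
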