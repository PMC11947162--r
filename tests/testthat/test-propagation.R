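test_that("with no spread channel the dead set is exactly the activated cells", {
  trip <- sim_triplet(small_cfg(p_spread = 0, background_hazard = 0))
  ev <- trip$events
  dead <- ev$id[!is.na(ev$blebbing_time)]
  expect_setequal(dead, trip$cells$id[trip$cells$illuminated])
  expect_true(all(ev$cause[!is.na(ev$blebbing_time)] == "opto"))
  # opto blebbing times respect the truncation bounds
  bt <- ev$blebbing_time[!is.na(ev$blebbing_time)]
  expect_true(all(bt >= 13 & bt <= 20))
})

test_that("disabling contacts is draw-for-draw equivalent to p_spread = 0", {
  cfg0 <- small_cfg(p_spread = 0)
  cfgc <- small_cfg(modifiers = modifier_set(contacts_enabled = FALSE))
  cells <- generate_monolayer(small_cfg())
  g <- build_contact_graph(cells)
  ev0 <- simulate_propagation(cells, g, cfg0)
  evc <- simulate_propagation(cells, g, cfgc)
  expect_equal(ev0$blebbing_time, evc$blebbing_time)
  expect_equal(ev0$cause, evc$cause)
})

test_that("at p_spread = 1 the dead set equals graph reachability from activated cells", {
  skip_if_not_installed("igraph")
  cfg <- simulation_config(field_size = 200, n_illuminated = 2, t_end = 4000,
                           p_spread = 1, seed = 5L)
  trip <- sim_triplet(cfg)
  dead <- trip$cells$id[!is.na(trip$events$blebbing_time)]
  ig <- igraph::graph_from_data_frame(
    trip$graph$edges, directed = FALSE,
    vertices = data.frame(name = trip$cells$id))
  comp <- igraph::components(ig)
  seeds <- as.character(trip$cells$id[trip$cells$illuminated])
  reach <- trip$cells$id[comp$membership %in% comp$membership[seeds]]
  expect_setequal(dead, reach)
})

test_that("event tables satisfy their causal invariants", {
  trip <- sim_triplet(small_cfg(background_hazard = 0.0005, seed = 9L))
  ev <- trip$events
  cells <- trip$cells
  full <- !is.na(ev$ox_onset_time) & !is.na(ev$blebbing_time) &
    !is.na(ev$draq7_time)
  expect_true(all(ev$ox_onset_time[full] <= ev$blebbing_time[full]))
  expect_true(all(ev$blebbing_time[full] <= ev$draq7_time[full]))
  # opto cause only on illuminated transfected cells
  expect_true(all(cells$illuminated[ev$cause == "opto"]))
  # propagated implies a contact neighbour with earlier blebbing
  nb <- lapply(seq_len(nrow(cells)), function(i) {
    e <- trip$graph$edges
    c(e$to[e$from == cells$id[i]], e$from[e$to == cells$id[i]])
  })
  for (i in which(ev$cause == "propagated")) {
    nbt <- ev$blebbing_time[match(nb[[i]], ev$id)]
    expect_true(any(!is.na(nbt) & nbt < ev$ox_onset_time[i]))
  }
})

test_that("each modifier null abolishes propagated deaths without touching opto deaths", {
  cells <- generate_monolayer(small_cfg())
  g <- build_contact_graph(cells)
  base <- simulate_propagation(cells, g, small_cfg())
  expect_gt(sum(base$cause == "propagated"), 0)
  nulls <- list(
    modifier_set(fer1_time = 0, fer1_efficacy = 0),
    modifier_set(iron_factor = 0),
    modifier_set(contacts_enabled = FALSE)
  )
  for (m in nulls) {
    ev <- simulate_propagation(cells, g, small_cfg(modifiers = m))
    expect_identical(sum(ev$cause == "propagated"), 0L)
    opto <- base$cause == "opto"
    expect_equal(ev$blebbing_time[opto], base$blebbing_time[opto])
  }
})

test_that("late Fer-1 blocks conversions only from the treatment time on", {
  cells <- generate_monolayer(small_cfg())
  g <- build_contact_graph(cells)
  ev <- simulate_propagation(cells, g, small_cfg(
    modifiers = modifier_set(fer1_time = 60, fer1_efficacy = 0)))
  conv <- ev$ox_onset_time[ev$cause == "propagated"]
  expect_true(all(conv > 0))
  ev_full <- simulate_propagation(cells, g, small_cfg())
  expect_lt(sum(ev$cause == "propagated"), sum(ev_full$cause == "propagated"))
})

test_that("the bilayer channel spreads death without cell contact", {
  cells <- generate_monolayer(small_cfg(seed = 21L))
  g <- build_contact_graph(cells)
  ev <- simulate_propagation(cells, g, small_cfg(
    seed = 21L,
    modifiers = modifier_set(contacts_enabled = FALSE, bilayer_range = 60)))
  expect_gt(sum(ev$cause == "propagated"), 0)
})

test_that("mean dead-bystander count is non-decreasing in the spread probability", {
  cells <- generate_monolayer(simulation_config(field_size = 300, seed = 8L,
                                                t_end = 240))
  g <- build_contact_graph(cells)
  byst <- cells$population == "bystander"
  mean_dead <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(p) {
    mean(vapply(1:20, function(r) {
      cfg <- simulation_config(field_size = 300, t_end = 240, p_spread = p,
                               seed = 8000L + r)
      ev <- simulate_propagation(cells, g, cfg)
      sum(byst & !is.na(ev$blebbing_time))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_dead) >= 0))
})

test_that("simulation is deterministic and event tables round-trip through CSV", {
  cfg <- small_cfg(seed = 13L)
  trip1 <- sim_triplet(cfg)
  trip2 <- sim_triplet(cfg)
  expect_identical(trip1$events, trip2$events)
  p <- withr::local_tempfile(fileext = ".csv")
  write_event_table(trip1$events, p)
  back <- read_event_table(p)
  expect_equal(back$blebbing_time, trip1$events$blebbing_time)
  expect_equal(attr(back, "t_end"), attr(trip1$events, "t_end"))
})
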