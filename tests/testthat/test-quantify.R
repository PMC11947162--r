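test_that("a noise-only frame yields an empty label map", {
  set.seed(1)
  blank <- matrix(rnorm(200 * 200, 10, 2), 200, 200)
  lm <- segment_cells(blank)
  expect_identical(nrow(lm$table), 0L)
  expect_true(all(lm$labels == 0L))
  flat <- matrix(5, 50, 50)
  expect_identical(nrow(segment_cells(flat)$table), 0L)
})

test_that("a single high-contrast blob is segmented with an accurate centroid", {
  cells <- data.frame(id = 1L, x = 42, y = 61, diameter = 23,
                      population = "transfected", illuminated = FALSE)
  attr(cells, "field_size") <- 100
  stk <- render_frames(cells, events_none(cells), imaging_config(noise_sd = 0))
  lm <- segment_cells(get_frame(stk, 1, "marker"), pixel_size = stk$pixel_size)
  expect_identical(nrow(lm$table), 1L)
  expect_lt(abs(lm$table$x - 42), 1)
  expect_lt(abs(lm$table$y - 61), 1)
})

test_that("a rendered monolayer is segmented one-to-one against ground truth", {
  cfg <- simulation_config(field_size = 210, n_illuminated = 2, seed = 14L)
  cells <- generate_monolayer(cfg)
  stk <- render_frames(cells, events_none(cells),
                       imaging_config(seed = 14L), t_end = 10)
  lm <- segment_cells(get_frame(stk, 1, "bodipy_red"),
                      pixel_size = stk$pixel_size)
  # label count within +/- 2 of the generator's
  expect_lte(abs(nrow(lm$table) - nrow(cells)), 2)
  d2 <- outer(lm$table$x, cells$x, "-")^2 + outer(lm$table$y, cells$y, "-")^2
  nn <- apply(d2, 1L, which.min)
  dmin <- sqrt(d2[cbind(seq_len(nrow(lm$table)), nn)])
  matched <- sum(dmin <= 2 * stk$pixel_size & !duplicated(nn))
  expect_gte(matched, nrow(cells) - 2)
})

test_that("equivalent-circle diameters follow the area scaling law", {
  expect_equal(estimate_cell_diameter(pi * 10^2)$mean, 20)
  est <- estimate_cell_diameter(c(100, 400))
  expect_equal(est$diameters[2] / est$diameters[1], 2)
  expect_error(estimate_cell_diameter(numeric(0)), "no cells")
  # generator-truth label maps recover the configured diameter
  cfg <- simulation_config(field_size = 210, n_illuminated = 2, seed = 14L)
  cells <- generate_monolayer(cfg)
  stk <- render_frames(cells, events_none(cells),
                       imaging_config(seed = 14L), t_end = 10)
  est2 <- estimate_cell_diameter(stk$label_map)
  expect_lt(abs(est2$mean - 23) / 23, 0.05)
})

test_that("background-corrected timecourses are size-invariant and recover amplitudes", {
  # uniform image: corrected values ~ 0 for any labels
  cells <- data.frame(id = 1:2, x = c(20, 60), y = c(30, 30),
                      diameter = c(16, 30), population = "bystander",
                      illuminated = FALSE)
  attr(cells, "field_size") <- 90
  stk <- render_frames(cells, events_none(cells),
                       imaging_config(noise_sd = 0, gains = c(
                         marker = 0, draq7 = 0, bodipy_green = 0,
                         bodipy_red = 0)))
  tc <- extract_timecourses(stk)
  expect_lt(max(tc$value), 1e-9)
  # two cells, same amplitude, different areas: equal mean intensities
  stk2 <- render_frames(cells, events_none(cells),
                        imaging_config(noise_sd = 0))
  tc2 <- extract_timecourses(stk2)
  red <- tc2[tc2$channel == "bodipy_red" & tc2$frame == 1, ]
  expect_equal(red$value[red$cell == 1], red$value[red$cell == 2],
               tolerance = 0.15)
  # a well-separated cell's corrected mean approaches the blob mean over the disc
  one <- data.frame(id = 1L, x = 45, y = 45, diameter = 23,
                    population = "transfected", illuminated = FALSE)
  attr(one, "field_size") <- 90
  stk3 <- render_frames(one, events_none(one), imaging_config(noise_sd = 0))
  tc3 <- extract_timecourses(stk3, background = "global")
  v <- tc3$value[tc3$channel == "marker" & tc3$frame == 1]
  r_px <- 11.5; sigma <- sqrt(5.75^2 + 1.5^2)
  expected <- 120 * (2 * sigma^2 / r_px^2) * (1 - exp(-r_px^2 / (2 * sigma^2)))
  expect_equal(v, expected, tolerance = 0.05)
})

test_that("population classification is exact on well-separated markers", {
  m <- rbind(rep(0, 3), rep(120, 3))
  tc <- make_tc(m, times = c(0, 10, 20), channel = "marker")
  cls <- classify_populations(tc, threshold = 50)
  expect_identical(cls$population, c("bystander", "transfected"))
  # auto threshold on a bimodal population: misclassification <= 2%
  set.seed(7)
  truth <- rep(c("bystander", "transfected"), each = 100)
  vals <- c(abs(rnorm(100, 2, 1.5)), rnorm(100, 110, 12))
  tcm <- make_tc(matrix(vals, ncol = 1), times = 0, channel = "marker")
  cls2 <- classify_populations(tcm, threshold = "auto")
  expect_lte(mean(cls2$population != truth), 0.02)
  # unimodal marker distribution is refused under "auto"
  tcu <- make_tc(matrix(rnorm(200, 50, 5), ncol = 1), times = 0,
                 channel = "marker")
  expect_error(classify_populations(tcu, threshold = "auto"), "unimodal")
})

test_that("death calling obeys threshold, persistence and censoring rules", {
  times <- seq(0, 60, by = 10)
  traces <- rbind(
    c(0, 0, 0, 0, 0, 0, 0),        # never above -> censored
    c(0, 0, 50, 50, 50, 50, 50),   # clean step at frame 3
    c(0, 50, 0, 0, 0, 0, 0),       # one-frame spike -> censored
    c(0, 0, 0, 0, 0, 0, 50)        # step at final frame -> censored
  )
  tc <- make_tc(traces, times)
  dc <- call_death(tc, threshold = 25, persistence = 2)
  expect_true(dc$censored[1])
  expect_equal(dc$death_time[2], 20)
  expect_true(dc$censored[3])
  expect_true(dc$censored[4])
  expect_equal(attr(dc, "censor_time"), 60)
  # persistence 1 accepts the spike
  dc1 <- call_death(tc, threshold = 25, persistence = 1)
  expect_equal(dc1$death_time[3], 10)
})

test_that("raising the death threshold never yields an earlier call", {
  set.seed(5)
  times <- seq(0, 120, by = 10)
  traces <- matrix(pmax(0, rnorm(13 * 40, 1)), 40, 13)
  late <- outer(seq_len(40), seq_len(13),
                function(i, k) ifelse(k >= (i %% 10) + 3, 30 + i, 0))
  traces <- traces + late
  tc <- make_tc(traces, times)
  lo <- call_death(tc, threshold = 10, persistence = 2)
  hi <- call_death(tc, threshold = 40, persistence = 2)
  both <- !is.na(lo$death_time) & !is.na(hi$death_time)
  expect_true(all(hi$death_time[both] >= lo$death_time[both]))
  expect_true(all(is.na(hi$death_time[is.na(lo$death_time)])))
})

test_that("oxidation ratio handles boundaries, scaling and undefined input", {
  expect_equal(oxidation_ratio(100, 0), 1)
  expect_equal(oxidation_ratio(0, 100), 0)
  expect_equal(oxidation_ratio(50, 50), 0.5)
  # scale invariance
  g <- c(3, 10, 250); r <- c(7, 90, 50)
  expect_equal(as.numeric(oxidation_ratio(5 * g, 5 * r)),
               as.numeric(oxidation_ratio(g, r)))
  # undefined entries flagged, not zeroed
  out <- oxidation_ratio(c(10, 0), c(10, 0))
  expect_true(is.na(out[2]))
  expect_identical(attr(out, "undefined"), 2L)
  expect_error(oxidation_ratio(-1, 5), "non-negative")
  # the garbled-text variant is exposed and consistent
  expect_equal(oxidation_ratio(50, 100, formula = "total_over_green"), 3)
})
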