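test_that("an empty cell table renders to offset plus noise only", {
  cells <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                      diameter = numeric(0), population = character(0),
                      illuminated = logical(0))
  attr(cells, "field_size") <- 60
  ev <- events_none(cells)
  stk <- render_frames(cells, ev, imaging_config(noise_sd = 2, seed = 2L))
  m <- get_frame(stk, 1, "marker")
  expect_equal(mean(m), 10, tolerance = 0.05)       # offset
  expect_equal(sd(as.numeric(m)), 2, tolerance = 0.1)  # noise
  stk0 <- render_frames(cells, ev, imaging_config(noise_sd = 0))
  expect_true(all(get_frame(stk0, 1, "draq7") == 10))
})

test_that("a noiseless single cell renders a calibrated Gaussian blob", {
  cells <- data.frame(id = 1L, x = 50, y = 40, diameter = 23,
                      population = "transfected", illuminated = FALSE)
  attr(cells, "field_size") <- 100
  img <- imaging_config(noise_sd = 0)
  stk <- render_frames(cells, events_none(cells), img)
  m <- get_frame(stk, 1, "marker") - 10   # remove offset
  peak <- which(m == max(m), arr.ind = TRUE)[1, ]
  # pixel centres: col c covers x in [c-1, c]
  expect_lt(abs((peak["col"] - 0.5) * stk$pixel_size - 50), 1)
  expect_lt(abs((peak["row"] - 0.5) * stk$pixel_size - 40), 1)
  # integrated intensity matches the closed-form 2-D Gaussian mass
  sigma <- sqrt((0.25 * 23)^2 + (1.5 * stk$pixel_size)^2)
  mass_expected <- 120 * 2 * pi * sigma^2 / stk$pixel_size^2
  expect_equal(sum(m), mass_expected, tolerance = 0.01)
  # nuclear dye blob is narrower: check the draq7 mass with its own width
  ev <- events_none(cells); ev$draq7_time <- 0; ev$blebbing_time <- 0
  ev$ox_onset_time <- 0; ev$cause <- "opto"
  stk2 <- render_frames(cells, ev, img)
  d <- get_frame(stk2, 1, "draq7") - 10
  sig_n <- sqrt((0.125 * 23)^2 + (1.5 * stk$pixel_size)^2)
  expect_equal(sum(d), 150 * 2 * pi * sig_n^2 / stk$pixel_size^2,
               tolerance = 0.01)
})

test_that("channel dynamics follow the event table and conserve the probe", {
  cells <- data.frame(id = 1L, x = 30, y = 30, diameter = 23,
                      population = "bystander", illuminated = FALSE)
  attr(cells, "field_size") <- 60
  ev <- events_none(cells, t_end = 60)
  ev$ox_onset_time <- 20; ev$blebbing_time <- 40; ev$draq7_time <- 44
  ev$cause <- "propagated"
  stk <- render_frames(cells, ev, imaging_config(noise_sd = 0,
                                                 frame_interval = 10))
  tc_g <- vapply(seq_along(stk$frame_times), function(k)
    max(get_frame(stk, k, "bodipy_green")) - 10, numeric(1))
  tc_r <- vapply(seq_along(stk$frame_times), function(k)
    max(get_frame(stk, k, "bodipy_red")) - 10, numeric(1))
  tc_d <- vapply(seq_along(stk$frame_times), function(k)
    max(get_frame(stk, k, "draq7")) - 10, numeric(1))
  # green rises and red falls after onset (frame times 0..60 by 10)
  expect_true(all(diff(tc_g[3:7]) > 0))
  expect_true(all(diff(tc_r[3:7]) < 0))
  tot <- tc_g + tc_r
  expect_equal(tot, rep(tot[1], 7), tolerance = 1e-9)   # conservation
  expect_equal(tot[1], 100, tolerance = 0.02)           # peak-pixel sampling
  expect_true(all(tc_d[1:5] < 1))                 # dark before draq7_time
  expect_true(all(tc_d[6:7] > 100))               # bright at 50, 60
  # bystander: marker stays dark
  expect_lt(max(get_frame(stk, 1, "marker")) - 10, 1e-9)
})

test_that("frame stacks round-trip through TIFF plus JSON sidecar", {
  cells <- generate_monolayer(simulation_config(field_size = 120,
                                                n_illuminated = 1, seed = 6L))
  g <- build_contact_graph(cells)
  cfg <- simulation_config(field_size = 120, n_illuminated = 1, seed = 6L,
                           t_end = 60)
  ev <- simulate_propagation(cells, g, cfg)
  stk <- render_frames(cells, ev, imaging_config(frame_interval = 20))
  path <- withr::local_tempfile(fileext = ".tif")
  write_frame_stack(stk, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- read_frame_stack(path)
  expect_equal(back$frame_times, stk$frame_times)
  expect_equal(back$channels, stk$channels)
  expect_equal(back$pixel_size, stk$pixel_size)
  # 16-bit quantization: tolerance of one grey level across the dynamic range
  rngtol <- (max(stk$frames) - min(stk$frames)) / 65535
  expect_lt(max(abs(back$frames - stk$frames)), 2 * rngtol)
})

test_that("a pixel field too small for the cells is rejected", {
  cells <- data.frame(id = 1L, x = 500, y = 500, diameter = 23,
                      population = "bystander", illuminated = FALSE)
  attr(cells, "field_size") <- 100
  expect_error(render_frames(cells, events_none(cells), imaging_config()),
               "too small")
})
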