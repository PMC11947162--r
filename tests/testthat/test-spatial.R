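test_that("hopkins is exactly 1 for a coincident cluster and errors on bad input", {
  p <- point_pattern(rep(3, 10), rep(4, 10), window = c(0, 10, 0, 10))
  h <- hopkins(p, m = 5, reps = 20, seed = 1)
  expect_true(all(h$H == 1))
  expect_error(hopkins(point_pattern(1:3, 1:3)), "at least 5")
  expect_error(hopkins(point_pattern(1:6, rep(1, 6), c(0, 6, 1, 1))),
               "degenerate")
  expect_error(hopkins(point_pattern(1:6, 1:6), m = 6), "m")
})

test_that("hopkins calibrates near 0.5 under spatial randomness and below for grids", {
  set.seed(2)
  csr <- point_pattern(runif(150), runif(150), c(0, 1, 0, 1))
  h <- hopkins(csr, m = 15, d = 2, reps = 200, seed = 2)
  expect_gt(h$H_mean, 0.44)
  expect_lt(h$H_mean, 0.56)
  gx <- (rep(1:15, 15) - 0.5) / 15
  gy <- (rep(1:15, each = 15) - 0.5) / 15
  grid <- point_pattern(gx, gy, c(0, 1, 0, 1))
  hg <- hopkins(grid, m = 15, reps = 200, seed = 2)
  expect_lt(hg$H_mean, 0.5)
  expect_true(all(h$H >= 0 & h$H <= 1))
})

test_that("hopkins is invariant under uniform rescaling and deterministic in the seed", {
  set.seed(3)
  x <- runif(60, 0, 100); y <- runif(60, 0, 100)
  p1 <- point_pattern(x, y, c(0, 100, 0, 100))
  p2 <- point_pattern(10 * x, 10 * y, c(0, 1000, 0, 1000))
  h1 <- hopkins(p1, m = 10, reps = 50, seed = 9)
  h2 <- hopkins(p2, m = 10, reps = 50, seed = 9)
  expect_equal(h1$H, h2$H)
  expect_equal(hopkins(p1, m = 10, reps = 50, seed = 9)$H, h1$H)
})

test_that("nearest-neighbour distances match the brute-force oracle exactly", {
  expect_equal(as.numeric(nearest_neighbor_distances(
    point_pattern(0, 0), point_pattern(3, 4))), 5)
  coin <- point_pattern(c(1, 1, 1), c(2, 2, 2))
  expect_true(all(nearest_neighbor_distances(coin, coin) == 0))
  expect_error(nearest_neighbor_distances(point_pattern(1, 1)), ">= 2")
  expect_error(nearest_neighbor_distances(
    point_pattern(1, 1), point_pattern(numeric(0), numeric(0))), "non-empty")
  set.seed(11)
  for (rep in 1:20) {
    ns <- sample(2:80, 1); nt <- sample(1:80, 1)
    sx <- runif(ns, 0, 50); sy <- runif(ns, 0, 50)
    tx <- runif(nt, 0, 50); ty <- runif(nt, 0, 50)
    expect_equal(as.numeric(nearest_neighbor_distances(
      point_pattern(sx, sy), point_pattern(tx, ty))),
      brute_nn(sx, sy, tx, ty))
    expect_equal(as.numeric(nearest_neighbor_distances(point_pattern(sx, sy))),
                 brute_nn(sx, sy))
  }
})

test_that("nearest-neighbour ties resolve to the lowest index", {
  src <- point_pattern(0, 0)
  tgt <- point_pattern(c(1, -1, 1), c(0, 0, 0))   # two targets at distance 1
  d <- nearest_neighbor_distances(src, tgt)
  expect_identical(attr(d, "nn_index"), 1L)
})

test_that("the permutation p-value follows the add-one rule and is reproducible", {
  cells <- generate_monolayer(small_cfg())
  # an observed median smaller than any null replicate
  res <- distance_permutation_null(cells, observed_median = 0,
                                   n_dead_source = 10, n_dead_target = 5,
                                   reps = 999, seed = 4)
  expect_equal(res$p_value, 1 / 1000)
  res2 <- distance_permutation_null(cells, observed_median = 0,
                                    n_dead_source = 10, n_dead_target = 5,
                                    reps = 999, seed = 4)
  expect_identical(res$null, res2$null)
  expect_error(distance_permutation_null(cells, 0, n_dead_source = 1e5,
                                         n_dead_target = 5), "infeasible")
})

test_that("the permutation p-value is approximately uniform under its own null", {
  cells <- generate_monolayer(small_cfg(seed = 77L))
  ps <- vapply(1:200, function(i) {
    obs <- distance_permutation_null(cells, NA, n_dead_source = 25,
                                     n_dead_target = 12, reps = 1,
                                     seed = 50000L + i)$null
    distance_permutation_null(cells, obs, n_dead_source = 25,
                              n_dead_target = 12, reps = 99,
                              seed = 90000L + i)$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("contact propagation yields clustered dead cells and short cross distances", {
  cfg <- small_cfg(seed = 31L)
  trip <- sim_triplet(cfg)
  cells <- trip$cells
  dead <- !is.na(trip$events$blebbing_time)
  win <- c(0, cfg$field_size, 0, cfg$field_size)
  h <- hopkins(point_pattern(cells$x[dead], cells$y[dead], win), seed = 31)
  expect_gt(h$H_mean, 0.6)
  db <- dead & cells$population == "bystander"
  dtr <- dead & cells$population == "transfected"
  obs <- median(nearest_neighbor_distances(
    point_pattern(cells$x[db], cells$y[db], win),
    point_pattern(cells$x[dtr], cells$y[dtr], win)))
  null <- distance_permutation_null(cells, obs, sum(db), sum(dtr),
                                    reps = 199, seed = 31)
  expect_lt(obs, median(null$null))
  expect_lt(null$p_value, 0.05)
})
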