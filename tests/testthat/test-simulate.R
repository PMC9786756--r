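test_that("simulation is deterministic in the seed and thins zero histories", {
  sc <- rw_scr_config()
  ds1 <- simulate_scr_dataset(sc$config, seed = 14)
  ds2 <- simulate_scr_dataset(sc$config, seed = 14)
  expect_identical(ds1$y, ds2$y)
  expect_identical(ds1$truth$paths, ds2$truth$paths)
  ds3 <- simulate_scr_dataset(sc$config, seed = 15)
  expect_false(identical(ds1$y, ds3$y))
  # every retained individual has at least one detection
  expect_true(all(apply(ds1$y, 1, sum) >= 1))
  expect_lte(dim(ds1$y)[1], ds1$truth$N)
})

test_that("zero baseline detection yields an empty dataset with a warning", {
  sc <- rw_scr_config()
  cfg <- sc$config
  cfg$det <- gauss_det(0, 1)
  expect_warning(ds <- simulate_scr_dataset(cfg, seed = 3), "no individuals")
  expect_equal(dim(ds$y)[1], 0L)
  s <- summarize_dataset(ds)
  expect_equal(s$n, 0L)
  expect_equal(s$total_detections, 0L)
  expect_equal(s$spatial_recaptures, 0L)
})

test_that("retention probability matches the closed-form thinning rate", {
  # static individuals: P(detected) = 1 - prod_jt (1 - p_ijt); compare the
  # empirical retention frequency with the per-individual closed form
  traps <- trap_grid(3, spacing = 2, origin = c(2, 2))
  r <- flat_raster(extent = 10, cell = 0.5)
  cfg <- scr_sim_config(r, traps, T_occasions = 4, det = gauss_det(0.4, 1),
                        population = fixed_n_pp(4000))
  ds <- simulate_scr_dataset(cfg, seed = 8)
  p <- encounter_prob_tensor(traps, ds$truth$paths, gauss_det(0.4, 1))
  p_detect <- 1 - apply(1 - p, 1, prod)
  expected_n <- sum(p_detect)
  sd_n <- sqrt(sum(p_detect * (1 - p_detect)))
  expect_lt(abs(dim(ds$y)[1] - expected_n), 3 * sd_n)
})

test_that("degenerate limit with certain detection detects everyone always", {
  # individuals cannot move (sigma -> 0), traps cover every pixel center,
  # and p0 = 1 with a wide scale: everyone is detected on every occasion
  r <- flat_raster(extent = 3, cell = 1)
  traps <- trap_grid(3, spacing = 1, origin = c(0.5, 0.5))  # at pixel centers
  cfg2 <- scr_sim_config(r, traps, T_occasions = 3,
                         det = gauss_det(1, 50),
                         population = fixed_n_pp(5),
                         movement = move_rw(0))
  ds2 <- simulate_scr_dataset(cfg2, seed = 2)
  expect_equal(dim(ds2$y)[1], 5L)
  expect_true(all(apply(ds2$y, c(1, 3), max) == 1L))
})

test_that("transients disperse more than residents in mixed populations", {
  sc <- rw_scr_config()
  cfg <- sc$config
  cfg$movement <- list(resident = move_rw(sigma2 = 1),
                       transient = move_rw(sigma2 = 25))
  cfg$phi <- 0.5
  for (seed in 1:5) {
    ds <- simulate_scr_dataset(cfg, seed = seed)
    paths <- ds$truth$paths
    step_len <- function(i) {
      mean(sqrt(diff(paths[i, , 1])^2 + diff(paths[i, , 2])^2))
    }
    res <- vapply(which(ds$truth$classes == 1L), step_len, numeric(1))
    tra <- vapply(which(ds$truth$classes == 2L), step_len, numeric(1))
    expect_gt(mean(tra), mean(res))
  }
})

test_that("telemetry adds exactly the specified measurement error", {
  tr <- simulate_path(move_rw(2), c(0, 0), 200, seed = 5)
  attr(tr, "individual") <- 7L
  # no error: u = mu exactly
  tel0 <- simulate_telemetry(tr, telemetry_spec(0), seed = 1)
  expect_identical(tel0$x, tr$x)
  expect_identical(tel0$y, tr$y)
  expect_equal(unique(tel0$individual), 7L)
  # error covariance recovered from many draws
  Su <- matrix(c(0.5, 0.2, 0.2, 1.2), 2, 2)
  long <- simulate_path(move_rw(1), c(0, 0), 1e5, seed = 6)
  tel <- simulate_telemetry(long, telemetry_spec(Su), seed = 7)
  err <- cbind(tel$x - long$x, tel$y - long$y)
  expect_true(all(abs(var(err) - Su) / max(abs(Su)) < 0.03))
  # requesting times outside the trajectory is an error
  expect_error(simulate_telemetry(tr, telemetry_spec(0, times = 500)),
               "outside")
  # subsetting times works
  tel_sub <- simulate_telemetry(tr, telemetry_spec(0, times = c(3, 9)), seed = 2)
  expect_equal(tel_sub$t, c(3, 9))
})

test_that("dataset summaries count spatial recaptures by hand-checkable rules", {
  y <- array(0L, c(2, 3, 4))
  y[1, 1, 1] <- 1L                 # individual 1: one detection, one trap
  y[2, 2, 1] <- 1L; y[2, 2, 3] <- 1L; y[2, 3, 4] <- 1L  # two distinct traps
  ds <- structure(list(y = y, traps = trap_array(cbind(0:2, 0:2)),
                       T_occasions = 4L), class = "scr_data")
  s <- summarize_dataset(ds)
  expect_equal(s$n, 2L)
  expect_equal(s$total_detections, 4L)
  expect_equal(s$detections_per_individual, c(1L, 3L))
  expect_equal(s$spatial_recaptures, 1L)
})

test_that("tagged individuals appear in the telemetry stream with shared ids", {
  sc <- rw_scr_config()
  cfg <- sc$config
  cfg$telemetry <- telemetry_spec(0.1)
  cfg$n_tags <- 5L
  ds <- simulate_scr_dataset(cfg, seed = 9)
  expect_false(is.null(ds$telemetry))
  expect_lte(length(unique(ds$telemetry$individual)), 5L)
  expect_true(all(ds$telemetry$t %in% seq_len(ds$T_occasions)))
  # telemetry tracks the true paths up to measurement error
  i1 <- ds$telemetry$individual[1]
  rows <- ds$telemetry[ds$telemetry$individual == i1, ]
  truth_x <- ds$truth$paths[i1, rows$t, 1]
  expect_lt(max(abs(rows$x - truth_x)), 5 * sqrt(0.1) + 1)
})
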