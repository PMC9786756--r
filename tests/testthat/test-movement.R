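test_that("rotation matrix handles identity, collapse, and quarter turns", {
  expect_equal(rotation_matrix(1, 0), diag(2))
  expect_equal(rotation_matrix(0, 1.234), matrix(0, 2, 2))
  expect_equal(as.numeric(rotation_matrix(1, pi / 2) %*% c(1, 0)), c(0, 1),
               tolerance = 1e-12)
})

test_that("step means follow each kernel's recursion", {
  expect_equal(step_mean(move_rw(1), c(3, -1)), c(3, -1))
  expect_equal(step_mean(move_crw(gamma = 1, beta_turn = 0), c(1, 0), c(0, 0)),
               c(2, 0))
  expect_equal(step_mean(move_brw(rho = 1, a = c(5, 5)), c(0, 0)), c(5, 5))
  # both BCRW terms at once
  expect_equal(step_mean(move_bcrw(gamma = 1, beta_turn = 0, rho = 0.5,
                                   a = c(4, 0)), c(2, 0), c(1, 0)),
               c(2, 0) + 0.5 * c(2, 0) + c(1, 0))
  # Langevin with all delta = 0 reduces to the simple-RW mean
  r <- bowl_raster()
  expect_equal(step_mean(move_langevin(c(bowl = 0, ramp = 0)), c(7, 7),
                         raster = r), c(7, 7))
  # missing history / raster violate the contract
  expect_error(step_mean(move_crw(0.5), c(0, 0)), "mu_prev2")
  expect_error(step_mean(move_langevin(c(bowl = 1)), c(7, 7)), "raster")
})

test_that("transition density is a proper bivariate normal", {
  m <- move_rw(1)
  expect_equal(transition_density(m, c(2, 3), c(2, 3)), 1 / (2 * pi))
  # symmetry about the mean
  v <- c(0.3, -0.8)
  expect_equal(transition_density(m, c(1, 1) + v, c(1, 1)),
               transition_density(m, c(1, 1) - v, c(1, 1)))
  # integrates to 1 over a wide grid (midpoint quadrature oracle)
  h <- 0.05
  gx <- seq(-6, 8, by = h)
  mb <- move_brw(0.4, a = c(3, 1), sigma2 = 1.7)
  dens <- outer(gx, gx, Vectorize(function(x, y) {
    transition_density(mb, c(x, y), c(0.5, -0.2))
  }))
  expect_lt(abs(sum(dens) * h^2 - 1), 1e-4)
  expect_error(transition_density(move_rw(0), c(0, 0), c(0, 0)), "singular")
})

test_that("path simulation honours degenerate and deterministic limits", {
  tr <- simulate_path(move_rw(1), c(2, 5), 1, seed = 1)
  expect_equal(nrow(tr), 1L)
  expect_equal(c(tr$x, tr$y), c(2, 5))

  # noiseless BRW halves the distance to a each step
  tr2 <- simulate_path(move_brw(0.5, a = c(0, 0), sigma2 = 0), c(8, 0), 4,
                       seed = 1)
  expect_equal(tr2$x, c(8, 4, 2, 1))
  expect_equal(tr2$y, rep(0, 4))
})

test_that("kernels with null parameters reproduce the simple RW bit-for-bit", {
  r <- bowl_raster()
  base <- simulate_path(move_rw(1), c(7, 7), 200, seed = 42)
  variants <- list(
    simulate_path(move_crw(gamma = 0, sigma2 = 1), c(7, 7), 200, seed = 42),
    simulate_path(move_brw(rho = 0, a = c(3, 3), sigma2 = 1), c(7, 7), 200,
                  seed = 42),
    simulate_path(move_bcrw(gamma = 0, rho = 0, a = c(3, 3), sigma2 = 1),
                  c(7, 7), 200, seed = 42),
    simulate_path(move_potential(c(bowl = 0, ramp = 0), sigma2 = 1), c(7, 7),
                  200, seed = 42, raster = r),
    simulate_path(move_langevin(c(bowl = 0, ramp = 0), sigma2 = 1), c(7, 7),
                  200, seed = 42, raster = r))
  for (v in variants) {
    expect_identical(base$x, v$x)
    expect_identical(base$y, v$y)
  }
})

test_that("simple RW mean squared displacement follows the 2D diffusion law", {
  # Fig-3a-style paths: sigma^2 = 1, T = 1500; MSD at lag 100 should be
  # 2 * 100 (two dimensions); averaged over 200 replicates and all start
  # times within each path
  set.seed(8)
  lag <- 100
  msd <- replicate(200, {
    tr <- simulate_path(move_rw(1), c(0, 0), 1500)
    dx <- diff(tr$x, lag = lag); dy <- diff(tr$y, lag = lag)
    mean(dx^2 + dy^2)
  })
  expect_rel_equal(mean(msd), 2 * lag, 0.10)
})

test_that("boundary policies confine paths and reject impossible masks", {
  r <- flat_raster(10)
  sp <- state_space(r)
  tr <- simulate_path(move_rw(4), c(5, 5), 500, seed = 2, space = sp,
                      boundary_policy = "reject_resample")
  expect_true(all(tr$x >= 0 & tr$x <= 10 & tr$y >= 0 & tr$y <= 10))
  tr2 <- simulate_path(move_rw(4), c(5, 5), 500, seed = 2, space = sp,
                       boundary_policy = "reflect")
  expect_true(all(tr2$x >= 0 & tr2$x <= 10 & tr2$y >= 0 & tr2$y <= 10))
  expect_error(simulate_path(move_rw(1), c(20, 20), 5, seed = 1, space = sp,
                             boundary_policy = "reject_resample"), "inside")
  # a drift that always jumps far outside the mask exhausts the retry cap
  expect_error(
    simulate_path(move_brw(1, a = c(500, 500), sigma2 = 1e-6), c(5, 5), 5,
                  seed = 1, space = sp, boundary_policy = "reject_resample",
                  max_tries = 50),
    "rejection cap")
})

test_that("BRW limiting covariance matches the closed form and long-run MC", {
  expect_equal(limiting_covariance_brw(1, 1.5), diag(2) * 1.5)
  expect_equal(limiting_covariance_brw(0.1, 1), diag(2) / (1 - 0.9^2))
  expect_error(limiting_covariance_brw(0, 1), "limiting")
  expect_error(limiting_covariance_brw(-0.2, 1), "limiting")
  # moderate-length Monte Carlo agreement (the full Fig-3c-scale run lives
  # in the acceptance suite)
  tr <- simulate_path(move_brw(0.2, c(0, 0), sigma2 = 1), c(0, 0), 50000,
                      seed = 31)
  V <- var(cbind(tr$x, tr$y))
  Vt <- limiting_covariance_brw(0.2, 1)
  expect_rel_equal(V[1, 1], Vt[1, 1], 0.08)
  expect_rel_equal(V[2, 2], Vt[2, 2], 0.08)
})

test_that("state-switching paths mix states per the chain and scale steps", {
  chain <- matrix(c(0.8, 0.2, 0.4, 0.6), 2, 2, byrow = TRUE)
  m <- move_switch(sigma2_1 = 1, sigma2_2 = 25, gamma = 0.5,
                   state_chain = chain)
  tr <- simulate_path(m, c(0, 0), 20000, seed = 6)
  # stationary distribution of the chain is (2/3, 1/3)
  expect_equal(mean(tr$state == 1), 2 / 3, tolerance = 0.03)
  # exploratory steps disperse more
  step <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)
  expect_gt(mean(step[tr$state[-1] == 2]), mean(step[tr$state[-1] == 1]))
  expect_error(move_switch(5, 1, gamma = 0.5), "sigma2_1 < sigma2_2")
})

test_that("the RSF limiting surface is normalized and scale-invariant", {
  r <- bowl_raster()
  sp <- state_space(r)
  p0 <- rsf_limiting_distribution(c(bowl = 0, ramp = 0), r, sp)
  expect_equal(p0, rep(1 / 225, 225))
  p1 <- rsf_limiting_distribution(c(bowl = 3, ramp = 1), r, sp)
  expect_equal(sum(p1), 1, tolerance = 1e-12)
  # scaling covariates by alpha and coefficients by 1/alpha changes nothing
  alpha <- 2.7
  r2 <- cov_raster(lapply(r$layers, function(m) alpha * m),
                   origin = r$origin, cell_size = r$cell_size)
  p2 <- rsf_limiting_distribution(c(bowl = 3, ramp = 1) / alpha, r2,
                                  state_space(r2))
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("a steep potential on a distance-to-habitat layer confines movement", {
  # preferred habitat: disk of radius 300 m centered in an 800 m square;
  # covariate is distance to the habitat in km, delta = -50000
  n <- 80; cell <- 10
  xs <- (1:n - 0.5) * cell
  d_hab <- outer(xs, xs, function(y, x) {
    pmax(sqrt((x - 400)^2 + (y - 400)^2) - 300, 0) / 1000
  })
  r <- cov_raster(list(dist_hab = d_hab), cell_size = cell)
  m <- move_potential(c(dist_hab = -5e4), sigma2 = 25)
  tr <- simulate_path(m, c(400, 400), 2000, seed = 9, raster = r)
  inside <- sqrt((tr$x - 400)^2 + (tr$y - 400)^2) <= 300
  expect_gt(mean(inside), 0.99)
})
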