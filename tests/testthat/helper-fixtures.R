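# small landscape / dataset builders shared across test files

# flat (covariate-free) square landscape: side `extent` starting at `origin`
flat_raster <- function(extent = 20, cell = 1, origin = c(0, 0)) {
  n <- round(extent / cell)
  cov_raster(list(flat = matrix(0, n, n)), origin = origin, cell_size = cell)
}

# smooth two-covariate landscape: quadratic bowl (peak at the center) and a
# linear ramp in x; side 15, cell 1
bowl_raster <- function(n = 15, bowl_scale = 50) {
  xs <- (1:n) - 0.5
  bowl <- -outer(xs, xs, function(y, x) ((x - n / 2)^2 + (y - n / 2)^2)) / bowl_scale
  ramp <- outer(xs, xs, function(y, x) x / n)
  cov_raster(list(bowl = bowl, ramp = ramp), cell_size = 1)
}

# study conditions for the classic static-center SCR design: 10 x 10 traps
# spaced 1.5 sigma_det, T = 5, p0 = 0.3, E[N] = 100 over the buffered region
static_scr_config <- function() {
  traps <- trap_grid(10, spacing = 1.5)
  r <- cov_raster(list(flat = matrix(0, 43, 43)), origin = c(-4, -4),
                  cell_size = 0.5)
  D <- 100 / (21.5^2)
  list(config = scr_sim_config(r, traps, T_occasions = 5,
                               det = gauss_det(0.3, 1),
                               population = poisson_pp(beta0 = log(D))),
       truth = list(dens = D, p0 = 0.3, sigma_det = 1, Lambda = 100),
       grid_cell = 0.5)
}

# study conditions for the transient (simple random walk) dynamic model:
# 7 x 7 traps spaced 2, T = 5, sigma_move = 2, E[N] = 60, coarse unit grid
rw_scr_config <- function(sigma_move = 2, Lambda = 60) {
  traps <- trap_grid(7, spacing = 2)
  r <- cov_raster(list(flat = matrix(0, 20, 20)), origin = c(-4, -4),
                  cell_size = 1)
  D <- Lambda / 400
  list(config = scr_sim_config(r, traps, T_occasions = 5,
                               det = gauss_det(0.3, 1),
                               population = poisson_pp(beta0 = log(D)),
                               movement = move_rw(sigma2 = sigma_move^2)),
       truth = list(dens = D, p0 = 0.3, sigma_det = 1,
                    sigma_move = sigma_move, Lambda = Lambda),
       grid_cell = 1)
}

# exhaustive-enumeration oracle for the forward filter: total probability of
# an emission sequence summed over every pixel path (vectorized over paths,
# no recursion shared with the filter implementation)
enumerate_loglik <- function(trans, emissions) {
  P <- as.matrix(trans$P)
  npix <- nrow(P)
  T_occ <- ncol(emissions)
  paths <- as.matrix(expand.grid(rep(list(seq_len(npix)), T_occ)))
  pr <- trans$pi1[paths[, 1]] * emissions[cbind(paths[, 1], 1)]
  for (t in 2:T_occ) {
    pr <- pr * P[cbind(paths[, t - 1], paths[, t])] *
      emissions[cbind(paths[, t], t)]
  }
  log(sum(pr))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
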