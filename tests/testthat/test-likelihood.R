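test_that("transition matrices are row-stochastic with local support", {
  g <- scr_grid(state_space(flat_raster(8)), cell = 1)
  tr <- suppressWarnings(build_transition_matrix(move_rw(0.8), g, r = 3))
  expect_lt(max(abs(Matrix::rowSums(tr$P) - 1)), 1e-12)
  expect_equal(sum(tr$pi1), 1)
  # no mass beyond the neighborhood radius
  P <- as.matrix(tr$P)
  ctr <- g$centers
  for (i in c(1, 17, 40)) {
    far <- which(abs(ctr[, 1] - ctr[i, 1]) > 3 | abs(ctr[, 2] - ctr[i, 2]) > 3)
    expect_true(all(P[i, far] == 0))
  }
  # degenerate kernel freezes in place
  tr0 <- build_transition_matrix(move_rw(0), g)
  expect_equal(as.matrix(tr0$P), diag(g$npix), ignore_attr = TRUE)
  # static (NULL) kernel is the identity too
  trs <- build_transition_matrix(NULL, g)
  expect_equal(as.matrix(trs$P), diag(g$npix), ignore_attr = TRUE)
  # CRW needs pair-state augmentation, so the pixel HMM rejects it
  expect_error(build_transition_matrix(move_crw(0.5), g), "not Markov")
})

test_that("a 1-row space matches direct normal-mass renormalization", {
  r <- cov_raster(list(c = matrix(0, 1, 3)), cell_size = 1)
  g <- scr_grid(state_space(r))
  tr <- suppressWarnings(build_transition_matrix(move_rw(1), g, r = 2))
  dens <- function(from, to) dnorm(to - from, sd = 1) * dnorm(0, sd = 1)
  ctr <- g$centers[, 1]
  Pexp <- outer(ctr, ctr, dens)
  Pexp <- Pexp / rowSums(Pexp)
  expect_equal(as.matrix(tr$P), Pexp, ignore_attr = TRUE, tolerance = 1e-12)
  # symmetric kernel: interior symmetry up to boundary renormalization
  expect_equal(tr$P[2, 1], tr$P[2, 3])
})

test_that("drifted kernels shift transition mass toward the target", {
  g <- scr_grid(state_space(flat_raster(10)), cell = 1)
  a <- c(8.5, 8.5)
  tr <- suppressWarnings(build_transition_matrix(move_brw(0.6, a, 1), g, r = 8))
  expect_lt(max(abs(Matrix::rowSums(tr$P) - 1)), 1e-12)
  i <- which(g$centers[, 1] == 2.5 & g$centers[, 2] == 2.5)
  nxt <- as.numeric(tr$P[i, ])
  mean_next <- colSums(g$centers * nxt)
  target <- c(2.5, 2.5) + 0.6 * (a - c(2.5, 2.5))
  expect_equal(as.numeric(mean_next), target, tolerance = 0.05)
})

test_that("emission vectors multiply per-trap Bernoulli terms", {
  g <- scr_grid(state_space(flat_raster(4)), cell = 1)
  traps <- trap_array(cbind(c(1.5, 2.5), c(1.5, 2.5)))
  det <- gauss_det(0.4, 1)
  # all-zero occasion with p0 = 0: no information, all ones
  e <- emission_vector(c(0, 0), traps, gauss_det(0, 1), g)
  expect_equal(e, rep(1, g$npix))
  # J = 2 hand-computed products
  y <- c(1, 0)
  e2 <- emission_vector(y, traps, det, g)
  for (z in c(1, 7, 16)) {
    d1 <- sqrt(sum((traps$xy[1, ] - g$centers[z, ])^2))
    d2 <- sqrt(sum((traps$xy[2, ] - g$centers[z, ])^2))
    expect_equal(e2[z], p_gauss(det, d1) * (1 - p_gauss(det, d2)),
                 ignore_attr = TRUE)
  }
  # certain detection with a point-mass scale concentrates on the trap pixel
  e3 <- emission_vector(c(1, 0), traps, gauss_det(1, 1e-3), g)
  expect_equal(which(e3 > 1e-10), which(g$centers[, 1] == 1.5 &
                                          g$centers[, 2] == 1.5))
})

test_that("the forward filter equals exhaustive trajectory enumeration", {
  g <- scr_grid(state_space(flat_raster(3)), cell = 1)  # 9 states
  traps <- trap_array(cbind(c(0.5, 2.5), c(1.5, 1.0)))
  det <- gauss_det(0.35, 0.8)
  set.seed(13)
  for (case in 1:5) {
    trans <- suppressWarnings(
      build_transition_matrix(move_rw(runif(1, 0.2, 1)), g, r = 2))
    T_occ <- sample(2:4, 1)
    y <- matrix(rbinom(2 * T_occ, 1, 0.4), 2, T_occ)
    E <- sapply(seq_len(T_occ), function(t) emission_vector(y[, t], traps, det, g))
    ll <- forward_loglik(trans, E)
    expect_rel_equal(ll, enumerate_loglik(trans, E), 1e-10)
  }
  # T = 1: no transition, plain mixture over pi1
  e1 <- emission_vector(c(1, 0), traps, det, g)
  trans <- suppressWarnings(build_transition_matrix(move_rw(0.5), g, r = 2))
  expect_equal(forward_loglik(trans, matrix(e1, ncol = 1)),
               log(sum(trans$pi1 * e1)))
  # all-ones emissions carry probability one through the chain
  expect_equal(forward_loglik(trans, matrix(1, g$npix, 6)), 0)
  # impossible data yield -Inf, not an error
  expect_identical(forward_loglik(trans, matrix(0, g$npix, 2)), -Inf)
})

test_that("pstar matches closed forms and is monotone in effort", {
  g <- scr_grid(state_space(flat_raster(8)), cell = 0.5)
  traps <- trap_grid(3, spacing = 2, origin = c(2, 2))
  det <- gauss_det(0.3, 1)
  trans <- suppressWarnings(build_transition_matrix(move_rw(1), g, r = 6))
  # p0 = 0 never detects
  expect_equal(pstar(trans, traps, gauss_det(0, 1), g, 5), 0)
  # T = 1 closed form: 1 - mean_z prod_j (1 - p_jz)
  pd <- t(sapply(seq_len(traps$J), function(j) {
    p_gauss(det, sqrt(colSums((t(g$centers) - traps$xy[j, ])^2)))
  }))
  expect_equal(pstar(trans, traps, det, g, 1),
               1 - mean(apply(1 - pd, 2, prod)), tolerance = 1e-12)
  # monotone in occasions, baseline detection, and trap count
  ps_T <- sapply(1:6, function(T_occ) pstar(trans, traps, det, g, T_occ))
  expect_true(all(diff(ps_T) > 0))
  ps_p0 <- sapply(c(0.1, 0.2, 0.4), function(p0) {
    pstar(trans, traps, gauss_det(p0, 1), g, 3)
  })
  expect_true(all(diff(ps_p0) > 0))
  traps_fewer <- trap_array(data.frame(trap = traps$ids[1:5],
                                       x = traps$xy[1:5, 1],
                                       y = traps$xy[1:5, 2]))
  expect_lt(pstar(trans, traps_fewer, det, g, 3),
            pstar(trans, traps, det, g, 3))
})

test_that("the semi-complete likelihood reduces to hand-computable cases", {
  sc <- rw_scr_config()
  ds <- simulate_scr_dataset(sc$config, seed = 30)
  g <- scr_grid(state_space(sc$config$raster), cell = 1)
  model <- scr_model("rw", r = 8)
  theta <- sc$truth[c("dens", "p0", "sigma_det", "sigma_move")]

  # n = 0: log L = -Lambda p*
  ds0 <- ds
  ds0$y <- ds$y[0, , , drop = FALSE]
  ll0 <- suppressWarnings(scr_loglik(theta, ds0, g, model))
  trans <- suppressWarnings(build_transition_matrix(move_rw(4), g, r = 8))
  ps <- pstar(trans, ds$traps, gauss_det(0.3, 1), g, 5)
  expect_equal(ll0, -theta$dens * g$area * ps, tolerance = 1e-10)

  # single-pixel state space: product-Bernoulli likelihood by hand
  r1 <- cov_raster(list(f = matrix(0, 1, 1)), cell_size = 1)
  g1 <- scr_grid(state_space(r1))
  traps1 <- trap_array(cbind(0.7, 0.6))  # distance 0.224 from the center
  y1 <- array(c(1L, 0L, 1L), c(1, 1, 3))
  dimnames(y1) <- list(individual = "1", trap = 1, occasion = 1:3)
  ds1 <- structure(list(y = y1, traps = traps1, T_occasions = 3L,
                        telemetry = NULL), class = "scr_data")
  th1 <- list(dens = 2, p0 = 0.4, sigma_det = 1)
  p_z <- 0.4 * exp(-sum((c(0.7, 0.6) - c(0.5, 0.5))^2) / 2)
  ll_hand <- 1 * log(2 * 1) - 2 * (1 - (1 - p_z)^3) - lfactorial(1) +
    log(p_z^2 * (1 - p_z))
  expect_equal(scr_loglik(th1, ds1, g1, scr_model("static")), ll_hand,
               tolerance = 1e-12)
  # the dynamic model on one pixel collapses to the same product-Bernoulli
  th1_rw <- c(th1, list(sigma_move = 0.5))
  expect_equal(suppressWarnings(scr_loglik(th1_rw, ds1, g1,
                                           scr_model("rw", r = 1))),
               ll_hand, tolerance = 1e-12)
})

test_that("the mixture collapses to its pure classes at phi = 0 and 1", {
  r <- bowl_raster()
  cfg <- scr_sim_config(r, trap_grid(4, spacing = 3, origin = c(2, 2)),
                        T_occasions = 4, det = gauss_det(0.4, 1),
                        population = fixed_n_pp(80),
                        movement = list(resident = move_langevin(c(bowl = 3, ramp = 0), 1),
                                        transient = move_rw(9)),
                        phi = 0.6)
  ds <- simulate_scr_dataset(cfg, seed = 41)
  g <- scr_grid(state_space(r), cell = 1)
  model <- scr_model("mixture", delta = c(bowl = 3, ramp = 0), r = 6)
  th <- list(dens = 80 / 225, p0 = 0.4, sigma_det = 1, sigma_1 = 1,
             sigma_2 = 3, phi = 1)
  ll_phi1 <- suppressWarnings(scr_loglik(th, ds, g, model))
  # pure-resident likelihood assembled directly
  pi_res <- initial_distribution(g, "rsf", delta = c(bowl = 3, ramp = 0))
  trans_res <- suppressWarnings(
    build_transition_matrix(move_langevin(c(bowl = 3, ramp = 0), 1),
                            g, r = 6, pi1 = pi_res))
  det <- gauss_det(0.4, 1)
  n <- dim(ds$y)[1]
  ll_manual <- n * log(th$dens * g$area) -
    th$dens * g$area * pstar(trans_res, ds$traps, det, g, 4) - lfactorial(n)
  for (i in seq_len(n)) {
    E <- sapply(1:4, function(t) emission_vector(ds$y[i, , t], ds$traps, det, g))
    ll_manual <- ll_manual + forward_loglik(trans_res, E)
  }
  expect_equal(ll_phi1, ll_manual, tolerance = 1e-8)
  # phi in the interior lies between the pure-class likelihoods' envelope
  th0 <- th; th0$phi <- 0
  ll_phi0 <- suppressWarnings(scr_loglik(th0, ds, g, model))
  thm <- th; thm$phi <- 0.6
  ll_mix <- suppressWarnings(scr_loglik(thm, ds, g, model))
  expect_true(is.finite(ll_mix))
  expect_gt(ll_mix, min(ll_phi0, ll_phi1) - 1e-9)
})

test_that("likelihood is invariant to individual and trap relabeling", {
  sc <- rw_scr_config()
  ds <- simulate_scr_dataset(sc$config, seed = 52)
  g <- scr_grid(state_space(sc$config$raster), cell = 1)
  model <- scr_model("rw", r = 8)
  theta <- sc$truth[c("dens", "p0", "sigma_det", "sigma_move")]
  ll <- suppressWarnings(scr_loglik(theta, ds, g, model))
  # permute individuals
  n <- dim(ds$y)[1]
  perm <- sample(n)
  ds_p <- ds
  ds_p$y <- ds$y[perm, , , drop = FALSE]
  expect_equal(suppressWarnings(scr_loglik(theta, ds_p, g, model)), ll,
               tolerance = 1e-10)
  # permute traps consistently in the array and the tensor
  Jp <- sample(ds$traps$J)
  ds_t <- ds
  ds_t$y <- ds$y[, Jp, , drop = FALSE]
  ds_t$traps <- trap_array(data.frame(trap = ds$traps$ids[Jp],
                                      x = ds$traps$xy[Jp, 1],
                                      y = ds$traps$xy[Jp, 2]))
  expect_equal(suppressWarnings(scr_loglik(theta, ds_t, g, model)), ll,
               tolerance = 1e-10)
})

test_that("halving the pixel size barely moves the log-likelihood", {
  sc <- rw_scr_config()
  ds <- simulate_scr_dataset(sc$config, seed = 61)
  model <- scr_model("rw", r = 8)
  theta <- sc$truth[c("dens", "p0", "sigma_det", "sigma_move")]
  sp <- state_space(sc$config$raster)
  ll_coarse <- suppressWarnings(scr_loglik(theta, ds, scr_grid(sp, cell = 1),
                                           scr_model("rw", r = 8)))
  ll_fine <- suppressWarnings(scr_loglik(theta, ds, scr_grid(sp, cell = 0.5),
                                         scr_model("rw", r = 16)))
  expect_lt(abs(ll_fine - ll_coarse) / abs(ll_fine), 0.005)
})

test_that("telemetry terms multiply in the marginal observation density", {
  # single pixel: the telemetry factor is exactly the bivariate normal
  # density of u about the pixel center with variance sigma_det^2 + sigma_u^2
  r1 <- cov_raster(list(f = matrix(0, 1, 1)), cell_size = 1)
  g1 <- scr_grid(state_space(r1))
  traps1 <- trap_array(cbind(0.7, 0.6))
  y1 <- array(c(1L, 0L), c(1, 1, 2))
  dimnames(y1) <- list(individual = "1", trap = 1, occasion = 1:2)
  tel <- data.frame(individual = 1L, t = 2L, x = 0.9, y = 0.2)
  ds1 <- structure(list(y = y1, traps = traps1, T_occasions = 2L,
                        telemetry = tel), class = "scr_data")
  th <- list(dens = 1, p0 = 0.4, sigma_det = 0.8)
  ll_no_tel <- scr_loglik(th, ds1, g1, scr_model("static"))
  ll_tel <- scr_loglik(th, ds1, g1, scr_model("static", Sigma_u = 0.3))
  S <- 0.3 + 0.8^2
  extra <- dnorm(0.9, 0.5, sqrt(S)) * dnorm(0.2, 0.5, sqrt(S))
  expect_equal(ll_tel - ll_no_tel, log(extra), tolerance = 1e-10)
})
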