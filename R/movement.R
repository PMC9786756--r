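#' Discrete-time movement kernels
#'
#' Constructors for the movement models used throughout the package. All
#' kernels share the general form \eqn{\mu_t \sim N(\mu^*_t, \Sigma)} with a
#' unit time step between occasions; they differ only in the mean
#' \eqn{\mu^*_t}:
#'
#' * `move_rw()`: simple random walk, \eqn{\mu^*_t = \mu_{t-1}}.
#' * `move_crw()`: correlated random walk,
#'   \eqn{\mu^*_t = \mu_{t-1} + R(\mu_{t-1} - \mu_{t-2})} with rotation
#'   matrix `R` from [rotation_matrix()].
#' * `move_brw()`: biased random walk with attraction toward `a`,
#'   \eqn{\mu^*_t = \mu_{t-1} + \rho(a - \mu_{t-1})}.
#' * `move_bcrw()`: biased correlated random walk (both terms).
#' * `move_switch()`: two-state behavioural switching between an "encamped"
#'   simple RW (dispersion `sigma2_1`, state 1) and an "exploratory" CRW
#'   (dispersion `sigma2_2`, state 2), with a first-order Markov chain on the
#'   state; requires `sigma2_1 < sigma2_2` for identifiability.
#' * `move_potential()`: potential-function kernel climbing covariate
#'   gradients, \eqn{\mu^*_t = \mu_{t-1} + \sum_k \delta_k \nabla
#'   c_k(\mu_{t-1})}; with `langevin_scaling = TRUE` the drift is
#'   premultiplied by \eqn{\sigma^2/2}, giving the approximate Langevin
#'   diffusion resource-selection kernel (`move_langevin()` is that
#'   shorthand), whose limiting distribution is the standard RSF surface
#'   (see [rsf_limiting_distribution()]).
#' * `move_rr_langevin()`: range-resident Langevin variant adding a
#'   per-individual center of attraction: the Langevin drift plus
#'   \eqn{\rho(a - \mu_{t-1})}.
#'
#' `sigma2` may be a scalar (isotropic, \eqn{\Sigma = \sigma^2 I}) or a full
#' symmetric positive-definite 2x2 covariance matrix.
#'
#' @param sigma2 step variance (scalar) or 2x2 covariance matrix.
#' @param gamma damping parameter in `[0, 1]`.
#' @param beta_turn mean turn angle in `(-pi, pi]`, radians,
#'   counterclockwise positive.
#' @param rho attraction strength in `[0, 1]`.
#' @param a center of attraction (length-2 point).
#' @param sigma2_1,sigma2_2 state-specific step variances (scalars),
#'   `sigma2_1 < sigma2_2`.
#' @param state_chain 2x2 row-stochastic state transition matrix.
#' @param delta named numeric vector of covariate response coefficients
#'   \eqn{\delta_k}; names are raster layer names.
#' @param langevin_scaling logical; premultiply the drift by
#'   \eqn{\sigma^2/2}.
#' @return an object of class `move_model`.
#' @name move_model
NULL

.as_Sigma <- function(sigma2) {
  if (is.matrix(sigma2)) {
    stopifnot(identical(dim(sigma2), c(2L, 2L)))
    if (max(abs(sigma2 - t(sigma2))) > 1e-12) stop("Sigma must be symmetric")
    S <- (sigma2 + t(sigma2)) / 2
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop("Sigma must be positive-definite")
    S
  } else {
    stopifnot(is.numeric(sigma2), length(sigma2) == 1L, sigma2 >= 0)
    diag(2) * sigma2
  }
}

.new_move <- function(kind, ..., sigma2) {
  S <- .as_Sigma(sigma2)
  structure(list(kind = kind, Sigma = S, ...), class = "move_model")
}

#' @rdname move_model
#' @export
move_rw <- function(sigma2 = 1) .new_move("rw", sigma2 = sigma2)

#' @rdname move_model
#' @export
move_crw <- function(gamma, beta_turn = 0, sigma2 = 1) {
  stopifnot(gamma >= 0, gamma <= 1, beta_turn > -pi - 1e-12, beta_turn <= pi + 1e-12)
  .new_move("crw", gamma = gamma, beta_turn = beta_turn, sigma2 = sigma2)
}

#' @rdname move_model
#' @export
move_brw <- function(rho, a, sigma2 = 1) {
  stopifnot(rho >= 0, rho <= 1, length(a) == 2L, all(is.finite(a)))
  .new_move("brw", rho = rho, a = as.numeric(a), sigma2 = sigma2)
}

#' @rdname move_model
#' @export
move_bcrw <- function(gamma, beta_turn = 0, rho, a, sigma2 = 1) {
  stopifnot(gamma >= 0, gamma <= 1, rho >= 0, rho <= 1, length(a) == 2L)
  .new_move("bcrw", gamma = gamma, beta_turn = beta_turn, rho = rho,
            a = as.numeric(a), sigma2 = sigma2)
}

#' @rdname move_model
#' @export
move_switch <- function(sigma2_1, sigma2_2, gamma, beta_turn = 0,
                        state_chain = matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE)) {
  stopifnot(sigma2_1 > 0, sigma2_2 > 0, sigma2_1 < sigma2_2)
  state_chain <- as.matrix(state_chain)
  stopifnot(identical(dim(state_chain), c(2L, 2L)), all(state_chain >= 0),
            max(abs(rowSums(state_chain) - 1)) < 1e-10)
  .new_move("switch", sigma2_1 = sigma2_1, sigma2_2 = sigma2_2,
            gamma = gamma, beta_turn = beta_turn, state_chain = state_chain,
            sigma2 = sigma2_1)
}

#' @rdname move_model
#' @export
move_potential <- function(delta, sigma2 = 1, langevin_scaling = FALSE) {
  stopifnot(is.numeric(delta), length(delta) >= 1L, all(is.finite(delta)),
            !is.null(names(delta)), all(nzchar(names(delta))))
  .new_move("potential", delta = delta, langevin_scaling = isTRUE(langevin_scaling),
            sigma2 = sigma2)
}

#' @rdname move_model
#' @export
move_langevin <- function(delta, sigma2 = 1) {
  move_potential(delta, sigma2 = sigma2, langevin_scaling = TRUE)
}

#' @rdname move_model
#' @export
move_rr_langevin <- function(delta, rho, a, sigma2 = 1) {
  stopifnot(rho >= 0, rho <= 1, length(a) == 2L)
  .new_move("rr_langevin", delta = delta, rho = rho, a = as.numeric(a),
            langevin_scaling = TRUE, sigma2 = sigma2)
}

#' @export
print.move_model <- function(x, ...) {
  cat(sprintf("move_model '%s', Sigma diag = (%g, %g)\n",
              x$kind, x$Sigma[1, 1], x$Sigma[2, 2]))
  invisible(x)
}

#' Rotation component of the correlated random walk
#'
#' Returns \eqn{\gamma \left[\begin{matrix} \cos\beta & -\sin\beta \\
#' \sin\beta & \cos\beta \end{matrix}\right]}: a counterclockwise rotation by
#' the mean turn angle `beta_turn`, damped by `gamma`. `gamma = 0` collapses
#' the correlated random walk to a simple random walk.
#'
#' @param gamma damping in `[0, 1]`.
#' @param beta_turn mean turn angle, radians.
#' @return 2x2 matrix.
#' @export
rotation_matrix <- function(gamma, beta_turn) {
  stopifnot(gamma >= 0, gamma <= 1)
  gamma * matrix(c(cos(beta_turn), sin(beta_turn),
                   -sin(beta_turn), cos(beta_turn)), 2, 2)
}

# combined drift of a potential/Langevin kernel at a location (internal)
.potential_drift <- function(model, mu, raster) {
  g <- c(0, 0)
  for (k in names(model$delta)) {
    g <- g + model$delta[[k]] * gradient_at(raster, mu, k)
  }
  if (isTRUE(model$langevin_scaling)) g <- g * model$Sigma[1, 1] / 2
  g
}

# drift evaluator closure for the path-simulation hot loop: the bilinear
# surface is linear in layer values, so the gradient of sum(delta_k c_k)
# equals the delta-weighted sum of per-layer gradients (internal)
.make_drift_fn <- function(model, raster) {
  comb <- Reduce(`+`, lapply(names(model$delta), function(k) {
    model$delta[[k]] * .raster_layer(raster, k)
  }))
  scale <- if (isTRUE(model$langevin_scaling)) model$Sigma[1, 1] / 2 else 1
  x0 <- raster$origin[1]; y0 <- raster$origin[2]; h <- raster$cell_size
  nc <- raster$n_cols; nr <- raster$n_rows
  function(mu) {
    gx_f <- (mu[1] - x0) / h - 0.5
    gy_f <- (mu[2] - y0) / h - 0.5
    cx <- gx_f < 0 || gx_f > nc - 1
    cy <- gy_f < 0 || gy_f > nr - 1
    if (cx) gx_f <- min(max(gx_f, 0), nc - 1)
    if (cy) gy_f <- min(max(gy_f, 0), nr - 1)
    j0 <- min(floor(gx_f), nc - 2 + (nc == 1)); i0 <- min(floor(gy_f), nr - 2 + (nr == 1))
    tx <- gx_f - j0; ty <- gy_f - i0
    j1 <- if (nc == 1) j0 else j0 + 1
    i1 <- if (nr == 1) i0 else i0 + 1
    c00 <- comb[i0 + 1, j0 + 1]; c10 <- comb[i0 + 1, j1 + 1]
    c01 <- comb[i1 + 1, j0 + 1]; c11 <- comb[i1 + 1, j1 + 1]
    gx <- if (cx || nc == 1) 0 else ((1 - ty) * (c10 - c00) + ty * (c11 - c01)) / h
    gy <- if (cy || nr == 1) 0 else ((1 - tx) * (c01 - c00) + tx * (c11 - c10)) / h
    c(gx * scale, gy * scale)
  }
}

#' Expected next location of a movement kernel
#'
#' Computes \eqn{\mu^*_t} for the selected kernel. Kernels with a rotational
#' term require the previous-but-one location `mu_prev2`; potential/Langevin
#' kernels require the covariate `raster`.
#'
#' @param model a [move_model].
#' @param mu_prev location at time t-1.
#' @param mu_prev2 location at time t-2 (CRW-family kernels only).
#' @param raster a [cov_raster()] (potential-family kernels only).
#' @param state behavioural state at time t (switching kernel only; 1 or 2).
#' @return length-2 point \eqn{\mu^*_t}.
#' @export
step_mean <- function(model, mu_prev, mu_prev2 = NULL, raster = NULL,
                      state = NULL) {
  stopifnot(inherits(model, "move_model"))
  mu_prev <- as.numeric(mu_prev)
  need_hist <- function() {
    if (is.null(mu_prev2)) stop("kernel '", model$kind, "' requires mu_prev2")
    as.numeric(mu_prev2)
  }
  need_raster <- function() {
    if (is.null(raster)) stop("kernel '", model$kind, "' requires a covariate raster")
    raster
  }
  switch(model$kind,
    rw = mu_prev,
    crw = {
      p2 <- need_hist()
      R <- rotation_matrix(model$gamma, model$beta_turn)
      mu_prev + as.numeric(R %*% (mu_prev - p2))
    },
    brw = mu_prev + model$rho * (model$a - mu_prev),
    bcrw = {
      p2 <- need_hist()
      R <- rotation_matrix(model$gamma, model$beta_turn)
      mu_prev + model$rho * (model$a - mu_prev) +
        as.numeric(R %*% (mu_prev - p2))
    },
    switch = {
      if (is.null(state)) stop("switching kernel requires the behavioural state")
      if (state == 1L) mu_prev
      else {
        p2 <- need_hist()
        R <- rotation_matrix(model$gamma, model$beta_turn)
        mu_prev + as.numeric(R %*% (mu_prev - p2))
      }
    },
    potential = mu_prev + .potential_drift(model, mu_prev, need_raster()),
    rr_langevin = mu_prev + .potential_drift(model, mu_prev, need_raster()) +
      model$rho * (model$a - mu_prev),
    stop("unknown kernel kind: ", model$kind)
  )
}

# state-specific Sigma (switching kernel), else model Sigma
.step_Sigma <- function(model, state = NULL) {
  if (model$kind == "switch") {
    if (is.null(state)) stop("switching kernel requires the behavioural state")
    diag(2) * (if (state == 1L) model$sigma2_1 else model$sigma2_2)
  } else model$Sigma
}

# bivariate normal log-density with covariance S (internal)
.dmvnorm2 <- function(x, mean, S, log = FALSE) {
  d <- as.numeric(x) - as.numeric(mean)
  det_S <- S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]
  if (det_S <= 0) stop("singular step covariance")
  q <- (d[1]^2 * S[2, 2] - 2 * d[1] * d[2] * S[1, 2] + d[2]^2 * S[1, 1]) / det_S
  ld <- -log(2 * pi) - 0.5 * log(det_S) - 0.5 * q
  if (log) ld else exp(ld)
}

#' One-step transition density of a movement kernel
#'
#' Bivariate normal density \eqn{N(\mu^*_t, \Sigma)} evaluated at `mu_t`,
#' where \eqn{\mu^*_t} comes from [step_mean()].
#'
#' @param model a [move_model].
#' @param mu_t evaluation point (location at time t).
#' @param mu_prev,mu_prev2,raster,state as in [step_mean()].
#' @param log return the log-density.
#' @return nonnegative density value (or its log).
#' @export
transition_density <- function(model, mu_t, mu_prev, mu_prev2 = NULL,
                               raster = NULL, state = NULL, log = FALSE) {
  ms <- step_mean(model, mu_prev, mu_prev2 = mu_prev2, raster = raster,
                  state = state)
  .dmvnorm2(mu_t, ms, .step_Sigma(model, state), log = log)
}

#' Stationary distribution of a 2x2 Markov chain (internal helper)
#' @noRd
.chain_stationary <- function(P) {
  p12 <- P[1, 2]; p21 <- P[2, 1]
  if (p12 + p21 <= 0) return(c(0.5, 0.5))
  c(p21, p12) / (p12 + p21)
}

#' Simulate a movement path
#'
#' Draws \eqn{\mu_t \sim N(\mu^*_t, \Sigma)} sequentially for `T_steps`
#' occasions starting from `mu1`. For CRW-family kernels the first step is
#' taken as a simple-RW step (equivalently \eqn{\mu_0 := \mu_1}), which is
#' parameter-free and reduces correctly when `gamma = 0`. For the switching
#' kernel the behavioural state is simulated from its Markov chain, with the
#' initial state drawn from the chain's stationary distribution.
#'
#' Boundary policies against the state space `M`:
#' * `"none"`: unconstrained (default when `space` is missing);
#' * `"reject_resample"`: redraw any step landing outside `M` (truncation);
#'   more than `max_tries` redraws for one step raises an error;
#' * `"reflect"`: reflect off the raster extent box, then resample if still
#'   outside the mask (suited to rectangular masks).
#'
#' @param model a [move_model].
#' @param mu1 initial location (must be inside `M` when a policy is active).
#' @param T_steps number of occasions (path length), `>= 1`.
#' @param seed optional integer seed (local to this call).
#' @param space optional [state_space()].
#' @param boundary_policy one of `"none"`, `"reject_resample"`, `"reflect"`.
#' @param raster covariate raster (potential-family kernels); defaults to
#'   `space$raster` when a space is supplied.
#' @param max_tries rejection cap per step.
#' @return a `trajectory`: data frame with columns `t`, `x`, `y` and, for
#'   switching kernels, `state`; the individual id is carried in
#'   `attr(, "individual")`.
#' @export
simulate_path <- function(model, mu1, T_steps, seed = NULL, space = NULL,
                          boundary_policy = c("none", "reject_resample", "reflect"),
                          raster = NULL, max_tries = 1000L) {
  stopifnot(inherits(model, "move_model"), T_steps >= 1)
  boundary_policy <- match.arg(boundary_policy)
  if (is.null(space) && boundary_policy != "none") {
    stop("boundary policy '", boundary_policy, "' requires a state space")
  }
  if (is.null(raster) && !is.null(space)) raster <- space$raster
  if (!is.null(seed)) set.seed(seed)
  if (boundary_policy != "none" && !sp_contains(space, mu1)) {
    stop("mu1 must lie inside the state space under boundary policy '",
         boundary_policy, "'")
  }

  pos <- matrix(NA_real_, T_steps, 2)
  pos[1, ] <- as.numeric(mu1)
  switching <- model$kind == "switch"
  states <- if (switching) integer(T_steps) else NULL
  if (switching) {
    pst <- .chain_stationary(model$state_chain)
    states[1] <- 1L + (stats::runif(1) > pst[1])
  }
  if (T_steps == 1L) {
    return(.new_trajectory(pos, states))
  }

  ex <- ey <- NULL
  if (boundary_policy == "reflect") {
    r <- space$raster
    ex <- r$origin[1] + c(0, r$n_cols * r$cell_size)
    ey <- r$origin[2] + c(0, r$n_rows * r$cell_size)
  }
  reflect1 <- function(v, lo, hi) {
    width <- hi - lo
    v <- (v - lo) %% (2 * width)
    lo + ifelse(v > width, 2 * width - v, v)
  }

  potential_like <- model$kind %in% c("potential", "rr_langevin")
  drift_fn <- if (potential_like) {
    if (is.null(raster)) stop("kernel '", model$kind, "' requires a covariate raster")
    .make_drift_fn(model, raster)
  }
  chol_or_zero <- function(S) if (max(abs(S)) == 0) S else chol(S)
  L_fixed <- if (!switching) chol_or_zero(model$Sigma)
  for (t in 2:T_steps) {
    if (switching) {
      pr <- model$state_chain[states[t - 1], ]
      states[t] <- 1L + (stats::runif(1) > pr[1])
    }
    mu_prev <- pos[t - 1, ]
    mu_prev2 <- if (t >= 3) pos[t - 2, ] else pos[t - 1, ]  # mu_0 := mu_1
    ms <- if (potential_like) {
      out <- mu_prev + drift_fn(mu_prev)
      if (model$kind == "rr_langevin") out + model$rho * (model$a - mu_prev) else out
    } else {
      step_mean(model, mu_prev, mu_prev2 = mu_prev2, raster = raster,
                state = if (switching) states[t] else NULL)
    }
    S <- .step_Sigma(model, if (switching) states[t] else NULL)
    L <- if (switching) chol_or_zero(S) else L_fixed
    repeat_count <- 0L
    repeat {
      z <- stats::rnorm(2)
      prop <- ms + as.numeric(crossprod(L, z))
      if (boundary_policy == "none") break
      if (boundary_policy == "reflect") {
        prop <- c(reflect1(prop[1], ex[1], ex[2]), reflect1(prop[2], ey[1], ey[2]))
      }
      if (sp_contains(space, prop)) break
      repeat_count <- repeat_count + 1L
      if (repeat_count >= max_tries) {
        stop("boundary rejection cap reached: mask/kernel combination ",
             "leaves almost no admissible step mass")
      }
    }
    pos[t, ] <- prop
  }
  .new_trajectory(pos, states)
}

.new_trajectory <- function(pos, states = NULL, individual = NA_integer_) {
  df <- data.frame(t = seq_len(nrow(pos)), x = pos[, 1], y = pos[, 2])
  if (!is.null(states)) df$state <- states
  attr(df, "individual") <- individual
  class(df) <- c("trajectory", "data.frame")
  df
}

#' Limiting covariance of the biased random walk
#'
#' The biased random walk with attraction strength \eqn{\rho > 0} is
#' stationary with limiting distribution
#' \eqn{N\!\left(a,\ (1-(1-\rho)^2)^{-1}\Sigma\right)}; this returns that
#' covariance matrix. As \eqn{\rho \to 0} the variance grows without bound
#' (the simple random walk has no limiting distribution), so `rho <= 0` is an
#' error.
#'
#' @param rho attraction strength in `(0, 1]`.
#' @param sigma2 step variance (scalar) or 2x2 covariance.
#' @return 2x2 covariance matrix.
#' @export
limiting_covariance_brw <- function(rho, sigma2 = 1) {
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0 || rho > 1) {
    stop("no limiting distribution: rho must lie in (0, 1]")
  }
  .as_Sigma(sigma2) / (1 - (1 - rho)^2)
}

#' Limiting distribution of the Langevin RSF kernel over the pixel grid
#'
#' The approximate Langevin diffusion kernel has (as the step size shrinks)
#' the standard resource-selection-function surface as its limiting
#' distribution:
#' \deqn{\pi_{LD}(\mu) = \frac{\exp\{\sum_k \delta_k c_k(\mu)\}}
#'   {\int_M \exp\{\sum_k \delta_k c_k(z)\}\,dz}.}
#' The integral is approximated by pixel-midpoint quadrature at the raster
#' resolution, so the result is a probability vector over masked-in pixels
#' (canonical ordering, see [pixel_centers()]).
#'
#' @param delta named coefficients \eqn{\delta_k} (names = layer names).
#' @param raster a [cov_raster()].
#' @param space a [state_space()] on the same raster.
#' @return numeric vector summing to 1 over masked-in pixels.
#' @export
rsf_limiting_distribution <- function(delta, raster, space) {
  stopifnot(inherits(raster, "cov_raster"), inherits(space, "state_space"))
  npix <- sum(raster$mask)
  if (npix == 0L) stop("state space has no masked-in pixels")
  lp <- numeric(npix)
  for (k in names(delta)) {
    lp <- lp + delta[[k]] * .layer_values_masked(raster, k)
  }
  w <- exp(lp - max(lp))
  w / sum(w)
}
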