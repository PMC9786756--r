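#' Telemetry measurement-error spec
#'
#' Observed telemetry locations are modeled as the true location plus
#' bivariate Gaussian measurement error, \eqn{u_t | \mu_t \sim N(\mu_t,
#' \Sigma_u)}. With \eqn{\Sigma_u = 0} a location is observed without error
#' (`u = mu`). Telemetry times are restricted to the integer movement-step
#' grid.
#'
#' @param Sigma_u 2x2 symmetric positive-semidefinite covariance, or a
#'   scalar variance \eqn{\sigma_u^2} (isotropic).
#' @param times integer observation times (subset of `1..T`); `NULL` means
#'   every occasion.
#' @return an object of class `telemetry_spec`.
#' @export
telemetry_spec <- function(Sigma_u, times = NULL) {
  if (!is.matrix(Sigma_u)) Sigma_u <- diag(2) * Sigma_u
  stopifnot(identical(dim(Sigma_u), c(2L, 2L)),
            max(abs(Sigma_u - t(Sigma_u))) < 1e-12)
  ev <- eigen((Sigma_u + t(Sigma_u)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-12) stop("Sigma_u must be positive-semidefinite")
  structure(list(Sigma_u = Sigma_u, times = times), class = "telemetry_spec")
}

#' Simulate telemetry observations of one trajectory
#'
#' @param traj a `trajectory` (from [simulate_path()]).
#' @param spec a [telemetry_spec()].
#' @param seed optional integer seed (local to this call).
#' @return data frame `individual, t, x, y` of noisy locations.
#' @export
simulate_telemetry <- function(traj, spec, seed = NULL) {
  stopifnot(inherits(spec, "telemetry_spec"))
  if (!is.null(seed)) set.seed(seed)
  times <- spec$times
  if (is.null(times)) times <- traj$t
  if (!all(times %in% traj$t)) stop("telemetry times outside trajectory times")
  idx <- match(times, traj$t)
  n <- length(idx)
  mu <- cbind(traj$x[idx], traj$y[idx])
  ev <- eigen((spec$Sigma_u + t(spec$Sigma_u)) / 2, symmetric = TRUE)
  A <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 2)
  err <- matrix(stats::rnorm(2 * n), n, 2) %*% t(A)
  data.frame(individual = rep(attr(traj, "individual") %||% NA_integer_, n),
             t = times, x = mu[, 1] + err[, 1], y = mu[, 2] + err[, 2])
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Configuration for the end-to-end SCR simulator
#'
#' Bundles the landscape, population, movement, detection, and sampling
#' choices consumed by [simulate_scr_dataset()].
#'
#' @param raster a [cov_raster()] (landscape and mask).
#' @param traps a [trap_array()].
#' @param T_occasions number of sampling occasions.
#' @param det a [gauss_det()] detection model (applied to the
#'   expected-location process).
#' @param population a [pp_spec] for abundance.
#' @param movement `NULL` for classic static activity centers; a single
#'   [move_model] applied to everyone; or `list(resident = , transient = )`
#'   of class-specific kernels used with the mixture weight `phi`.
#' @param phi resident mixture weight (probability an individual is a
#'   resident).
#' @param delta optional named RSF coefficients for the resident
#'   initial-location density (defaults to the resident kernel's `delta`
#'   when it is a potential/Langevin kernel).
#' @param boundary_policy boundary handling for simulated paths (default
#'   `"reject_resample"`, i.e. truncation to `M`).
#' @param telemetry optional [telemetry_spec()]; tagged individuals are a
#'   uniform random subset of the population of size `n_tags`.
#' @param n_tags number of telemetry-tagged individuals.
#' @return a `scr_sim_config` list.
#' @export
scr_sim_config <- function(raster, traps, T_occasions, det, population,
                           movement = NULL, phi = 1, delta = NULL,
                           boundary_policy = "reject_resample",
                           telemetry = NULL, n_tags = 0L) {
  stopifnot(inherits(raster, "cov_raster"), inherits(traps, "trap_array"),
            T_occasions >= 1, inherits(det, "det_model"),
            inherits(population, "pp_spec"))
  if (!is.null(movement) && !inherits(movement, "move_model")) {
    stopifnot(is.list(movement), all(c("resident", "transient") %in% names(movement)))
  }
  if (is.null(delta) && is.list(movement) &&
      inherits(movement$resident, "move_model") &&
      movement$resident$kind %in% c("potential", "rr_langevin")) {
    delta <- movement$resident$delta
  }
  structure(list(raster = raster, space = state_space(raster), traps = traps,
                 T_occasions = as.integer(T_occasions), det = det,
                 population = population, movement = movement, phi = phi,
                 delta = delta, boundary_policy = boundary_policy,
                 telemetry = telemetry, n_tags = as.integer(n_tags)),
            class = "scr_sim_config")
}

#' Simulate a complete SCR dataset
#'
#' End-to-end generator: draws the population (abundance, residency classes,
#' initial locations), simulates per-individual movement paths of the
#' expected-location process, evaluates the Gaussian encounter probability
#' tensor, draws Bernoulli detections, and keeps the individuals detected at
#' least once (all-zero histories never appear in real SCR data). The full
#' truth (N, classes, all trajectories) is retained for recovery tests, and
#' an optional telemetry stream with measurement error is attached; tagged
#' individuals share ids with the capture data.
#'
#' Randomness is fully reproducible from `seed`: per-individual path seeds
#' are pre-drawn so path simulation is order-independent.
#'
#' @param config a [scr_sim_config()].
#' @param seed integer seed.
#' @param keep_truth retain the truth block (default `TRUE`).
#' @return an object of class `scr_data`: list with binary tensor `y`
#'   (`n x J x T`), `traps`, `T_occasions`, `telemetry` (or `NULL`), and
#'   `truth`.
#' @export
simulate_scr_dataset <- function(config, seed, keep_truth = TRUE) {
  stopifnot(inherits(config, "scr_sim_config"))
  set.seed(seed)
  raster <- config$raster; space <- config$space
  T_occ <- config$T_occasions

  pop <- sample_population(config$population, raster, space,
                           phi = if (is.list(config$movement)) config$phi else 1,
                           delta = config$delta)
  N <- pop$N
  path_seeds <- if (N > 0) sample.int(.Machine$integer.max - 1L, N) else integer(0)
  det_seed <- sample.int(.Machine$integer.max - 1L, 1)
  tag_seed <- sample.int(.Machine$integer.max - 1L, 1)

  kernel_for <- function(class_i) {
    if (is.null(config$movement)) return(NULL)
    if (inherits(config$movement, "move_model")) return(config$movement)
    if (class_i == 1L) config$movement$resident else config$movement$transient
  }

  pos <- array(NA_real_, c(max(N, 0L), T_occ, 2))
  states <- vector("list", N)
  for (i in seq_len(N)) {
    km <- kernel_for(pop$classes[i])
    if (is.null(km)) {            # static activity centers
      pos[i, , 1] <- pop$points[i, 1]
      pos[i, , 2] <- pop$points[i, 2]
    } else {
      tr <- simulate_path(km, pop$points[i, ], T_occ, seed = path_seeds[i],
                          space = space, boundary_policy = config$boundary_policy)
      pos[i, , 1] <- tr$x
      pos[i, , 2] <- tr$y
      if (!is.null(tr$state)) states[[i]] <- tr$state
    }
  }

  set.seed(det_seed)
  y_full <- array(0L, c(max(N, 0L), config$traps$J, T_occ))
  if (N > 0) {
    p <- encounter_prob_tensor(config$traps, pos, config$det)
    y_full <- array(as.integer(stats::runif(length(p)) < p), dim = dim(p))
  }
  detected <- if (N > 0) which(apply(y_full, 1, max) > 0) else integer(0)
  if (length(detected) == 0L) {
    warning("no individuals detected; returning an empty encounter history")
  }
  y <- y_full[detected, , , drop = FALSE]
  dimnames(y) <- list(individual = detected, trap = config$traps$ids,
                      occasion = seq_len(T_occ))

  telem <- NULL
  if (!is.null(config$telemetry) && config$n_tags > 0 && N > 0) {
    set.seed(tag_seed)
    tagged <- sort(sample.int(N, min(config$n_tags, N)))
    tel_seeds <- sample.int(.Machine$integer.max - 1L, length(tagged))
    rows <- vector("list", length(tagged))
    for (k in seq_along(tagged)) {
      i <- tagged[k]
      tr <- .new_trajectory(pos[i, , , drop = TRUE], individual = i)
      rows[[k]] <- simulate_telemetry(tr, config$telemetry, seed = tel_seeds[k])
    }
    telem <- do.call(rbind, rows)
  }

  truth <- NULL
  if (keep_truth) {
    truth <- list(N = N, classes = pop$classes, init = pop$points,
                  paths = pos, states = states, detected = detected)
  }
  structure(list(y = y, traps = config$traps, T_occasions = T_occ,
                 det_kind = config$det$kind, telemetry = telem, truth = truth,
                 seed = seed),
            class = "scr_data")
}

#' @export
print.scr_data <- function(x, ...) {
  s <- summarize_dataset(x)
  cat(sprintf("scr_data: n = %d individuals, J = %d traps, T = %d occasions\n",
              s$n, x$traps$J, x$T_occasions))
  cat(sprintf("  detections = %d, spatial recaptures = %d individuals\n",
              s$total_detections, s$spatial_recaptures))
  invisible(x)
}

#' Summary counts of an SCR dataset
#'
#' Reports the number of detected individuals `n`, detections per
#' individual, and the number of individuals detected at two or more
#' distinct traps ("spatial recaptures", the information source for the
#' detection scale).
#'
#' @param ds an `scr_data`.
#' @return list with `n`, `total_detections`, `detections_per_individual`,
#'   `spatial_recaptures`.
#' @export
summarize_dataset <- function(ds) {
  stopifnot(inherits(ds, "scr_data"))
  n <- dim(ds$y)[1]
  per_ind <- if (n > 0) apply(ds$y, 1, sum) else integer(0)
  sr <- if (n > 0) sum(apply(ds$y, 1, function(m) sum(rowSums(matrix(m, dim(ds$y)[2])) > 0) >= 2)) else 0L
  list(n = n, total_detections = sum(ds$y),
       detections_per_individual = per_ind,
       spatial_recaptures = as.integer(sr))
}
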