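#' Trap (detector) arrays and detection models
#'
#' `trap_array()` holds `J` uniquely-identified detector locations.
#' `gauss_det()` is the half-normal (Gaussian-kernel) detection model
#' \eqn{p = p_0 \exp\{-d^2 / (2\sigma_{det}^2)\}} applied to the distance `d`
#' between a trap and an individual's (expected) location.
#' `hazard_det()` is the integrated-hazard detection model for continuous
#' paths: over one occasion the detection probability is
#' \eqn{p = 1 - \exp\{-\int_{t-1}^{t} h(x_j, \mu(\tau)) d\tau\}} with
#' log-hazard \eqn{\log h = \beta_0 + \beta_1 \|x_j - \mu(\tau)\|}.
#'
#' @param x data frame with columns `trap`, `x`, `y`, or a numeric matrix of
#'   coordinates (ids are then 1..J).
#' @param p0 baseline detection probability at distance zero, in `[0, 1]`.
#' @param sigma_det spatial scale of detection (> 0).
#' @param h_beta0 log baseline instantaneous detection rate at distance zero.
#' @param h_beta1 distance coefficient of the log-hazard (typically < 0).
#' @param n_substeps default number of midpoint-quadrature substeps `L`.
#' @name detection
NULL

#' @rdname detection
#' @export
trap_array <- function(x) {
  if (is.matrix(x)) {
    x <- data.frame(trap = seq_len(nrow(x)), x = x[, 1], y = x[, 2])
  }
  stopifnot(is.data.frame(x), all(c("trap", "x", "y") %in% names(x)),
            nrow(x) >= 1)
  if (anyDuplicated(x$trap)) stop("trap ids must be unique")
  if (!all(is.finite(x$x)) || !all(is.finite(x$y))) {
    stop("trap coordinates must be finite")
  }
  structure(list(ids = x$trap, xy = cbind(x = x$x, y = x$y), J = nrow(x)),
            class = "trap_array")
}

#' @export
print.trap_array <- function(x, ...) {
  cat(sprintf("trap_array: J = %d detectors\n", x$J))
  invisible(x)
}

#' A regular grid of traps
#'
#' @param nx,ny traps per side.
#' @param spacing distance between adjacent traps.
#' @param origin location of the first (lower-left) trap.
#' @return a [trap_array()].
#' @export
trap_grid <- function(nx, ny = nx, spacing, origin = c(0, 0)) {
  xs <- origin[1] + (seq_len(nx) - 1) * spacing
  ys <- origin[2] + (seq_len(ny) - 1) * spacing
  trap_array(cbind(rep(xs, times = ny), rep(ys, each = nx)))
}

#' @rdname detection
#' @export
gauss_det <- function(p0, sigma_det) {
  stopifnot(p0 >= 0, p0 <= 1, sigma_det > 0)
  structure(list(kind = "gauss", p0 = p0, sigma_det = sigma_det),
            class = "det_model")
}

#' @rdname detection
#' @export
hazard_det <- function(h_beta0, h_beta1, n_substeps = 10L) {
  stopifnot(is.finite(h_beta0), is.finite(h_beta1),
            n_substeps >= 1, n_substeps == round(n_substeps))
  structure(list(kind = "hazard", h_beta0 = h_beta0, h_beta1 = h_beta1,
                 n_substeps = as.integer(n_substeps)), class = "det_model")
}

#' Gaussian-kernel detection probability at a distance
#'
#' \eqn{p_0 \exp\{-d^2/(2\sigma_{det}^2)\}}; vectorized over `distance`.
#'
#' @param params a [gauss_det()].
#' @param distance nonnegative Euclidean distance(s).
#' @return probability in `[0, p0]`.
#' @export
p_gauss <- function(params, distance) {
  stopifnot(params$kind == "gauss")
  if (any(distance < 0)) stop("distance must be nonnegative")
  params$p0 * exp(-distance^2 / (2 * params$sigma_det^2))
}

#' Integrated-hazard detection probability over a path segment
#'
#' The unknown within-occasion path is approximated piecewise-linearly
#' between the segment endpoints; the hazard integral over the unit-length
#' occasion uses the midpoint rule on `L` substeps, and the probability is
#' \eqn{1 - \exp(-\int h)}. For a stationary animal (equal endpoints) the
#' integrand is constant and the result is exact for any `L`.
#'
#' @param params a [hazard_det()].
#' @param trap length-2 trap location.
#' @param seg_from,seg_to segment endpoints \eqn{\mu_{t-1}, \mu_t}.
#' @param L number of substeps (defaults to `params$n_substeps`).
#' @return probability in `[0, 1)`.
#' @export
p_hazard_interval <- function(params, trap, seg_from, seg_to,
                              L = params$n_substeps) {
  stopifnot(params$kind == "hazard")
  if (L < 1 || L != round(L)) stop("L must be a positive integer")
  if (!all(is.finite(c(seg_from, seg_to)))) stop("segment endpoints must be finite")
  tau <- (seq_len(L) - 0.5) / L
  px <- seg_from[1] + tau * (seg_to[1] - seg_from[1])
  py <- seg_from[2] + tau * (seg_to[2] - seg_from[2])
  d <- sqrt((px - trap[1])^2 + (py - trap[2])^2)
  integral <- mean(exp(params$h_beta0 + params$h_beta1 * d))  # Delta t = 1
  -expm1(-integral)
}

#' Encounter probability tensor
#'
#' Applies the detection model elementwise over individuals, traps, and
#' occasions. For the Gaussian model, occasion `t` uses the position at time
#' `t` of each trajectory (length `T`, giving `T` occasions). For the hazard
#' model, occasion `t` covers the segment from time `t` to `t + 1`, giving
#' `T - 1` occasions.
#'
#' @param traps a [trap_array()].
#' @param positions list of trajectories (equal length `T`), or an
#'   `n x T x 2` array of positions.
#' @param det a [gauss_det()] or [hazard_det()].
#' @return array `n x J x occasions` of probabilities, with trap ids on the
#'   second dimnames.
#' @export
encounter_prob_tensor <- function(traps, positions, det) {
  stopifnot(inherits(traps, "trap_array"), inherits(det, "det_model"))
  pos <- .as_pos_array(positions)
  n <- dim(pos)[1]; T_steps <- dim(pos)[2]; J <- traps$J
  tx <- traps$xy[, 1]; ty <- traps$xy[, 2]
  if (det$kind == "gauss") {
    out <- array(NA_real_, c(n, J, T_steps))
    for (t in seq_len(T_steps)) {
      dx <- outer(pos[, t, 1], tx, "-")
      dy <- outer(pos[, t, 2], ty, "-")
      out[, , t] <- det$p0 * exp(-(dx^2 + dy^2) / (2 * det$sigma_det^2))
    }
  } else {
    if (T_steps < 2) stop("hazard detection needs trajectories of length >= 2")
    out <- array(NA_real_, c(n, J, T_steps - 1))
    for (i in seq_len(n)) {
      for (t in seq_len(T_steps - 1)) {
        for (j in seq_len(J)) {
          out[i, j, t] <- p_hazard_interval(det, traps$xy[j, ],
                                            pos[i, t, ], pos[i, t + 1, ])
        }
      }
    }
  }
  dimnames(out) <- list(NULL, traps$ids, NULL)
  out
}

# coerce list-of-trajectories / array to n x T x 2 positions array
.as_pos_array <- function(positions) {
  if (is.array(positions) && length(dim(positions)) == 3L) return(positions)
  if (inherits(positions, "trajectory")) positions <- list(positions)
  stopifnot(is.list(positions), length(positions) >= 1)
  Ts <- vapply(positions, nrow, integer(1))
  if (length(unique(Ts)) != 1L) stop("all trajectories must share one length T")
  n <- length(positions)
  pos <- array(NA_real_, c(n, Ts[1], 2))
  for (i in seq_len(n)) {
    pos[i, , 1] <- positions[[i]]$x
    pos[i, , 2] <- positions[[i]]$y
  }
  pos
}
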