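#' Discretize the state space into HMM pixel states
#'
#' Overlays a regular pixel grid (cell size `cell`, possibly coarser or finer
#' than the covariate raster) on the raster extent; a grid pixel belongs to
#' the discretized state space iff its center lies in a masked-in raster
#' pixel. Each retained pixel becomes one state of the hidden Markov model
#' used to marginalize latent trajectories.
#'
#' @param space a [state_space()].
#' @param cell pixel size of the discretization (default: the raster's own
#'   cell size).
#' @return an object of class `scr_grid`: pixel `centers` (canonical
#'   ordering: x fastest, bottom row first), `cell`, grid dimensions, index
#'   matrix `idx` (0 for excluded pixels), total `area`, and a reference to
#'   the underlying raster.
#' @export
scr_grid <- function(space, cell = NULL) {
  stopifnot(inherits(space, "state_space"))
  r <- space$raster
  if (is.null(cell)) cell <- r$cell_size
  stopifnot(cell > 0)
  nx <- max(1L, round(r$n_cols * r$cell_size / cell))
  ny <- max(1L, round(r$n_rows * r$cell_size / cell))
  xs <- r$origin[1] + (seq_len(nx) - 0.5) * cell
  ys <- r$origin[2] + (seq_len(ny) - 0.5) * cell
  cx <- rep(xs, times = ny)
  cy <- rep(ys, each = nx)
  inside <- .contains_many(space, cbind(cx, cy))
  if (!any(inside)) stop("discretization contains no pixels inside M")
  ord <- which(inside)
  idx_vec <- integer(nx * ny)
  idx_vec[ord] <- seq_along(ord)
  idx <- matrix(idx_vec, ny, nx, byrow = TRUE)
  structure(list(centers = cbind(x = cx[inside], y = cy[inside]),
                 cell = cell, nx = nx, ny = ny,
                 origin = r$origin, idx = idx,
                 npix = length(ord), area = length(ord) * cell^2,
                 raster = r),
            class = "scr_grid")
}

#' @export
print.scr_grid <- function(x, ...) {
  cat(sprintf("scr_grid: %d states (cell %g, %d x %d lattice), area %g\n",
              x$npix, x$cell, x$nx, x$ny, x$area))
  invisible(x)
}

#' Initial pixel distribution
#'
#' @param grid an [scr_grid()].
#' @param type `"uniform"`, `"rsf"` (resource-selection surface with
#'   coefficients `delta`, evaluated at grid-pixel centers), or
#'   `"brw_limit"` (biased-random-walk limiting normal `N(a, (1 - (1 -
#'   rho)^2)^{-1} Sigma)` evaluated at pixel centers and renormalized).
#' @param delta named RSF coefficients (`type = "rsf"`).
#' @param rho,a,sigma2 BRW parameters (`type = "brw_limit"`).
#' @return probability vector over grid pixels summing to 1.
#' @export
initial_distribution <- function(grid, type = c("uniform", "rsf", "brw_limit"),
                                 delta = NULL, rho = NULL, a = NULL,
                                 sigma2 = NULL) {
  type <- match.arg(type)
  if (type == "uniform") return(rep(1 / grid$npix, grid$npix))
  if (type == "rsf") {
    stopifnot(!is.null(delta))
    lp <- numeric(grid$npix)
    for (k in names(delta)) {
      lp <- lp + delta[[k]] * vapply(seq_len(grid$npix), function(i) {
        covariate_at(grid$raster, grid$centers[i, ], k)
      }, numeric(1))
    }
    w <- exp(lp - max(lp))
    return(w / sum(w))
  }
  S <- limiting_covariance_brw(rho, sigma2)
  w <- .dmvnorm2_many(grid$centers, a, S)
  w / sum(w)
}

# vectorized bivariate normal density of rows of X about `mean`
.dmvnorm2_many <- function(X, mean, S) {
  dx <- X[, 1] - mean[1]; dy <- X[, 2] - mean[2]
  det_S <- S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]
  if (det_S <= 0) stop("singular covariance")
  q <- (dx^2 * S[2, 2] - 2 * dx * dy * S[1, 2] + dy^2 * S[1, 1]) / det_S
  exp(-log(2 * pi) - 0.5 * log(det_S) - 0.5 * q)
}

#' Sparse pixel-to-pixel movement transition matrix
#'
#' Builds the row-stochastic HMM transition matrix for a position-Markov
#' movement kernel: `P[i, j]` is proportional to the kernel's normal density
#' `N(center_j; mu*(center_i), Sigma)` for pixels `j` within a
#' `(2r+1) x (2r+1)` pixel neighborhood of `i`, and rows are renormalized
#' (the truncation/mask form of boundary handling, which also zeroes
#' mask-excluded pixels). The neighborhood radius defaults to
#' `ceiling(4 sigma / cell)`; a warning is raised when the neighborhood would
#' capture less than `1 - 1e-6` of the untruncated kernel mass.
#'
#' CRW-family kernels are not position-Markov (they need the previous pixel
#' as well) and are rejected; fit transients with a larger-dispersion simple
#' random walk instead.
#'
#' @param model a position-Markov [move_model] (`rw`, `brw`,
#'   `potential`/Langevin, `rr_langevin`), or `NULL` for static centers
#'   (identity transitions).
#' @param grid an [scr_grid()].
#' @param r neighborhood radius in pixels (`NULL` = automatic).
#' @param pi1 initial pixel distribution (default uniform over `M`).
#' @return an object of class `transition_model`: sparse `P`
#'   (`dgCMatrix`), `pi1`, and the radius used.
#' @export
build_transition_matrix <- function(model, grid, r = NULL, pi1 = NULL) {
  stopifnot(inherits(grid, "scr_grid"))
  npix <- grid$npix
  if (is.null(pi1)) pi1 <- rep(1 / npix, npix)
  stopifnot(length(pi1) == npix, abs(sum(pi1) - 1) < 1e-8)

  if (is.null(model)) {  # static activity centers
    P <- Matrix::Diagonal(npix)
    return(structure(list(P = P, pi1 = pi1, r = 0L), class = "transition_model"))
  }
  stopifnot(inherits(model, "move_model"))
  if (model$kind %in% c("crw", "bcrw", "switch")) {
    stop("kernel '", model$kind, "' is not Markov in position; ",
         "the pixel HMM supports rw, brw, potential/Langevin kernels")
  }
  S <- model$Sigma
  sig <- sqrt(max(diag(S)))
  if (sig == 0) {  # degenerate kernel: stay put
    P <- Matrix::Diagonal(npix)
    return(structure(list(P = P, pi1 = pi1, r = 0L), class = "transition_model"))
  }
  if (is.null(r)) r <- max(1L, ceiling(4 * sig / grid$cell))
  r <- as.integer(r)

  ctr <- grid$centers
  mu_star <- switch(model$kind,
    rw = ctr,
    brw = ctr + model$rho * (matrix(model$a, npix, 2, byrow = TRUE) - ctr),
    potential = ,
    rr_langevin = {
      drift <- t(vapply(seq_len(npix), function(i) {
        .potential_drift(model, ctr[i, ], grid$raster)
      }, numeric(2)))
      out <- ctr + drift
      if (model$kind == "rr_langevin") {
        out <- out + model$rho * (matrix(model$a, npix, 2, byrow = TRUE) - ctr)
      }
      out
    },
    stop("unsupported kernel for the pixel HMM: ", model$kind))

  # neighborhood-coverage diagnostic (isotropic bound, worst-case drift)
  shift <- sqrt(max(rowSums((mu_star - ctr)^2)))
  half <- (r + 0.5) * grid$cell
  cov1 <- stats::pnorm((half - shift) / sig) - stats::pnorm((-half - shift) / sig)
  if (cov1^2 < 1 - 1e-6) {
    warning(sprintf(
      "neighborhood radius %d captures ~%.8f of kernel mass (< 1 - 1e-6)",
      r, cov1^2))
  }

  det_S <- S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]
  ij <- .grid_ij(grid)
  offs <- expand.grid(dx = -r:r, dy = -r:r)
  tri_i <- vector("list", nrow(offs))
  tri_j <- vector("list", nrow(offs))
  tri_x <- vector("list", nrow(offs))
  for (o in seq_len(nrow(offs))) {
    dx <- offs$dx[o]; dy <- offs$dy[o]
    jx <- ij$ix + dx; jy <- ij$iy + dy
    ok <- jx >= 1 & jx <= grid$nx & jy >= 1 & jy <= grid$ny
    jidx <- integer(npix)
    jidx[ok] <- grid$idx[cbind(jy[ok], jx[ok])]
    ok <- ok & jidx > 0
    if (!any(ok)) next
    i_ok <- which(ok)
    ex <- ctr[i_ok, 1] + dx * grid$cell - mu_star[i_ok, 1]
    ey <- ctr[i_ok, 2] + dy * grid$cell - mu_star[i_ok, 2]
    q <- (ex^2 * S[2, 2] - 2 * ex * ey * S[1, 2] + ey^2 * S[1, 1]) / det_S
    tri_i[[o]] <- i_ok
    tri_j[[o]] <- jidx[i_ok]
    tri_x[[o]] <- exp(-0.5 * q)
  }
  P <- Matrix::sparseMatrix(i = unlist(tri_i), j = unlist(tri_j),
                            x = unlist(tri_x), dims = c(npix, npix))
  rs <- Matrix::rowSums(P)
  if (any(rs == 0)) stop("a pixel has no admissible transitions; increase r")
  P <- Matrix::Diagonal(x = 1 / rs) %*% P
  structure(list(P = methods::as(P, "CsparseMatrix"), pi1 = pi1, r = r),
            class = "transition_model")
}

# lattice coordinates (ix, iy) of each retained pixel (internal)
.grid_ij <- function(grid) {
  pos <- which(t(grid$idx) > 0)  # traverse x fastest to match canonical order
  ord <- order(t(grid$idx)[pos])
  pos <- pos[ord]
  ix <- ((pos - 1L) %% grid$nx) + 1L
  iy <- ((pos - 1L) %/% grid$nx) + 1L
  list(ix = ix, iy = iy)
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf("transition_model: %d states, %d nonzeros, neighborhood r = %d\n",
              nrow(x$P), length(x$P@x), x$r))
  invisible(x)
}

# J x npix Gaussian detection probability matrix (internal). "center"
# evaluates the kernel at pixel centers; "integrated" averages it over the
# pixel, which is separable and closed-form for the Gaussian kernel:
# (1/h) int exp(-u^2 / 2 sigma^2) du = (sigma sqrt(2 pi) / h) *
# [pnorm((d + h/2)/sigma) - pnorm((d - h/2)/sigma)] per axis.
.pdet_matrix <- function(traps, det, grid, emission = c("center", "integrated")) {
  stopifnot(det$kind == "gauss")
  emission <- match.arg(emission)
  dx <- outer(traps$xy[, 1], grid$centers[, 1], "-")
  dy <- outer(traps$xy[, 2], grid$centers[, 2], "-")
  if (emission == "center") {
    return(det$p0 * exp(-(dx^2 + dy^2) / (2 * det$sigma_det^2)))
  }
  h <- grid$cell
  s <- det$sigma_det
  fac <- s * sqrt(2 * pi) / h
  ax <- fac * (stats::pnorm((dx + h / 2) / s) - stats::pnorm((dx - h / 2) / s))
  ay <- fac * (stats::pnorm((dy + h / 2) / s) - stats::pnorm((dy - h / 2) / s))
  pmin(det$p0 * ax * ay, 1)
}

#' Per-pixel emission likelihood of one occasion's detections
#'
#' For a binary detection vector \eqn{y_{\cdot t}} across the `J` traps, the
#' emission probability of pixel `z` is \eqn{e_t(z) = \prod_j
#' p_{jz}^{y_{jt}} (1 - p_{jz})^{1 - y_{jt}}} with `p_jz` the Gaussian
#' detection probability at the pixel center.
#'
#' @param y_slice binary length-`J` vector.
#' @param traps a [trap_array()].
#' @param det a [gauss_det()].
#' @param grid an [scr_grid()].
#' @return vector of emission probabilities in `(0, 1]` over pixels.
#' @export
emission_vector <- function(y_slice, traps, det, grid) {
  stopifnot(length(y_slice) == traps$J)
  pd <- .pdet_matrix(traps, det, grid)
  lg <- log1p(-pd)
  hit <- y_slice == 1
  if (any(hit)) {
    lg[hit, ] <- log(pmax(pd[hit, , drop = FALSE], .Machine$double.xmin))
  }
  exp(colSums(lg))
}

#' Scaled forward filter over pixel states
#'
#' Underflow-safe forward recursion \eqn{\alpha_t = (\alpha_{t-1} P) \circ
#' e_t}, \eqn{\alpha_1 = \pi_1 \circ e_1}, accumulating per-step log scaling
#' constants; exact marginalization of the discrete pixel trajectory. Data
#' that are impossible under the model give `-Inf` (returned, not raised).
#'
#' @param trans a [build_transition_matrix()] result.
#' @param emissions `npix x T` matrix of per-occasion emission vectors.
#' @return log marginal probability of the emission sequence.
#' @export
forward_loglik <- function(trans, emissions) {
  stopifnot(inherits(trans, "transition_model"))
  emissions <- as.matrix(emissions)
  T_occ <- ncol(emissions)
  alpha <- trans$pi1 * emissions[, 1]
  total <- sum(alpha)
  if (total <= 0) return(-Inf)
  ll <- log(total)
  alpha <- alpha / total
  if (T_occ > 1) {
    for (t in 2:T_occ) {
      alpha <- as.numeric(Matrix::crossprod(trans$P, alpha)) * emissions[, t]
      total <- sum(alpha)
      if (total <= 0) return(-Inf)
      ll <- ll + log(total)
      alpha <- alpha / total
    }
  }
  ll
}

#' Overall detection probability p*
#'
#' The probability that an individual is detected at least once during the
#' study: one minus the marginal probability of the all-zero encounter
#' history, computed with the forward filter under the movement transition
#' model and initial distribution.
#'
#' @param trans a [build_transition_matrix()] result.
#' @param traps,det,grid as in [emission_vector()].
#' @param T_occ number of occasions.
#' @param emission `"center"` (kernel at pixel centers) or `"integrated"`
#'   (kernel averaged over each pixel).
#' @return probability in `[0, 1]`.
#' @export
pstar <- function(trans, traps, det, grid, T_occ, emission = "center") {
  pd <- .pdet_matrix(traps, det, grid, emission)
  e0 <- exp(colSums(log(1 - pd)))
  ll0 <- forward_loglik(trans, matrix(e0, grid$npix, T_occ))
  1 - exp(ll0)
}

#' Model structure for the SCR likelihood
#'
#' Declares which movement-integrated SCR model the likelihood and fitting
#' engine assemble:
#'
#' * `"static"`: classic SCR with static activity centers (uniform over M).
#' * `"rw"`: dynamic expected locations following a simple random walk
#'   (the transient model), uniform initial distribution.
#' * `"mixture"`: resident/transient two-class mixture with weight `phi`:
#'   residents follow the Langevin RSF kernel (coefficients `delta`,
#'   dispersion `sigma_1`) with RSF initial distribution; transients follow
#'   a simple random walk of larger dispersion `sigma_2` with uniform
#'   initial distribution.
#'
#' When `Sigma_u` is supplied, telemetry observations of detected tagged
#' individuals contribute occasion emission factors: the marginal density of
#' `u` at the pixel center under `N(center, sigma_det^2 I + Sigma_u)`
#' (integrating the two-stage telemetry specification over the instantaneous
#' location).
#'
#' @param type model type.
#' @param delta named RSF coefficient vector: fixed values, or a template of
#'   starting values when `estimate_delta = TRUE` (mixture only).
#' @param estimate_delta treat `delta` as free parameters.
#' @param Sigma_u known telemetry measurement-error covariance (2x2 or
#'   scalar variance); `NULL` disables the telemetry terms.
#' @param r fixed neighborhood radius for transition matrices (`NULL` =
#'   automatic from each evaluation's dispersion; fixing it keeps the
#'   likelihood surface continuous during optimization).
#' @param emission `"center"` evaluates detection probabilities at pixel
#'   centers; `"integrated"` averages the Gaussian kernel over each pixel
#'   (closed form), which removes most of the detection-scale
#'   discretization bias on coarse grids.
#' @return an object of class `scr_model`.
#' @export
scr_model <- function(type = c("static", "rw", "mixture"), delta = NULL,
                      estimate_delta = FALSE, Sigma_u = NULL, r = NULL,
                      emission = c("center", "integrated")) {
  type <- match.arg(type)
  emission <- match.arg(emission)
  if (type == "mixture" && is.null(delta)) {
    stop("mixture model requires RSF coefficients 'delta'")
  }
  if (!is.null(Sigma_u) && !is.matrix(Sigma_u)) Sigma_u <- diag(2) * Sigma_u
  structure(list(type = type, delta = delta,
                 estimate_delta = isTRUE(estimate_delta),
                 Sigma_u = Sigma_u, r = r, emission = emission),
            class = "scr_model")
}

# per-individual trap-by-occasion detection index list (internal)
.detection_index <- function(y) {
  n <- dim(y)[1]
  lapply(seq_len(n), function(i) {
    m <- matrix(y[i, , ], dim(y)[2], dim(y)[3])
    which(m == 1, arr.ind = TRUE)  # cols: trap, occasion
  })
}

# npix x T log-emission matrix for one individual (internal)
.log_emissions_ind <- function(det_idx_i, base_log, Lcontrib, T_occ,
                               telem_i = NULL, tel_dens = NULL) {
  npix <- length(base_log)
  logE <- matrix(base_log, npix, T_occ)
  if (nrow(det_idx_i) > 0) {
    for (k in seq_len(nrow(det_idx_i))) {
      j <- det_idx_i[k, 1]; t <- det_idx_i[k, 2]
      logE[, t] <- logE[, t] + Lcontrib[j, ]
    }
  }
  if (!is.null(telem_i) && nrow(telem_i) > 0) {
    for (k in seq_len(nrow(telem_i))) {
      logE[, telem_i$t[k]] <- logE[, telem_i$t[k]] + tel_dens[[k]]
    }
  }
  logE
}

#' Semi-complete-data log-likelihood of an SCR dataset
#'
#' Assembles \deqn{\log L = n \log \Lambda - \Lambda p^* - \log n! +
#' \sum_{i=1}^{n} \log [y_i],} where \eqn{\Lambda = D \|M\|} is the expected
#' abundance under a homogeneous Poisson point process, \eqn{p^*} is the
#' overall detection probability, and \eqn{[y_i]} is the forward-filter
#' marginal probability of individual `i`'s encounter history. Under the
#' mixture model \eqn{[y_i] = \phi [y_i | \mathrm{res}] + (1 - \phi) [y_i |
#' \mathrm{tra}]} with class-specific transitions and initial distributions,
#' and \eqn{p^*} is mixed the same way.
#'
#' @param theta named list of natural-scale parameters: `dens`, `p0`,
#'   `sigma_det`, plus `sigma_move` (`rw`), or `sigma_1`, `sigma_2`, `phi`
#'   and optionally `delta` (`mixture`).
#' @param data an `scr_data` (or any list with `y`, `traps`,
#'   `T_occasions`, optionally `telemetry`).
#' @param grid an [scr_grid()].
#' @param model an [scr_model()].
#' @return scalar log-likelihood.
#' @export
scr_loglik <- function(theta, data, grid, model) {
  stopifnot(inherits(model, "scr_model"))
  y <- data$y
  n <- dim(y)[1]
  T_occ <- data$T_occasions
  det <- gauss_det(theta$p0, theta$sigma_det)
  pd <- .pdet_matrix(data$traps, det, grid, model$emission %||% "center")
  base_log <- colSums(log1p(-pd))
  Lambda <- theta$dens * grid$area

  tel_by_ind <- .telemetry_emission_terms(data, grid, model, theta)

  if (model$type == "static") {
    pi1 <- rep(1 / grid$npix, grid$npix)
    pstar_val <- 1 - sum(pi1 * exp(T_occ * base_log))
    sum_ll <- 0
    if (n > 0) {
      Lcontrib <- log(pd) - log1p(-pd)
      cnt <- apply(y, c(1, 2), sum)                  # n x J detection counts
      lp <- cnt %*% Lcontrib                         # n x npix
      lp <- sweep(lp, 2, T_occ * base_log, "+")
      # telemetry factors are per-occasion; fold into the static product
      for (i in which(!vapply(tel_by_ind, function(e) is.null(e$dens),
                              logical(1)))) {
        lp[i, ] <- lp[i, ] + Reduce(`+`, tel_by_ind[[i]]$dens)
      }
      mx <- apply(lp, 1, max)
      sum_ll <- sum(mx + log(as.numeric(exp(lp - mx) %*% pi1)))
    }
    return(n * log(Lambda) - Lambda * pstar_val - lfactorial(n) + sum_ll)
  }

  Lcontrib <- log(pd) - log1p(-pd)
  det_idx <- if (n > 0) .detection_index(y) else list()

  if (model$type == "rw") {
    trans <- build_transition_matrix(move_rw(theta$sigma_move^2), grid,
                                     r = model$r)
    pstar_val <- pstar(trans, data$traps, det, grid, T_occ,
                       emission = model$emission %||% "center")
    ll_i <- .forward_all(trans, det_idx, base_log, Lcontrib, T_occ, tel_by_ind, n)
    return(n * log(Lambda) - Lambda * pstar_val - lfactorial(n) + sum(ll_i))
  }

  # mixture: resident Langevin RSF + transient simple RW
  delta <- theta$delta %||% model$delta
  pi_res <- initial_distribution(grid, "rsf", delta = delta)
  trans_res <- build_transition_matrix(
    move_langevin(delta, sigma2 = theta$sigma_1^2), grid, r = model$r,
    pi1 = pi_res)
  trans_tra <- build_transition_matrix(
    move_rw(theta$sigma_2^2), grid, r = model$r)
  phi <- theta$phi
  em <- model$emission %||% "center"
  pstar_val <- phi * pstar(trans_res, data$traps, det, grid, T_occ, em) +
    (1 - phi) * pstar(trans_tra, data$traps, det, grid, T_occ, em)
  ll_res <- .forward_all(trans_res, det_idx, base_log, Lcontrib, T_occ,
                         tel_by_ind, n)
  ll_tra <- .forward_all(trans_tra, det_idx, base_log, Lcontrib, T_occ,
                         tel_by_ind, n)
  sum_ll <- 0
  if (n > 0) {
    m <- pmax(ll_res, ll_tra)
    both_inf <- !is.finite(m)
    lmix <- ifelse(both_inf, -Inf,
                   m + log(phi * exp(ll_res - m) + (1 - phi) * exp(ll_tra - m)))
    sum_ll <- sum(lmix)
  }
  n * log(Lambda) - Lambda * pstar_val - lfactorial(n) + sum_ll
}

# forward filter of every individual under one transition model (internal)
.forward_all <- function(trans, det_idx, base_log, Lcontrib, T_occ,
                         tel_by_ind, n) {
  ll_i <- numeric(n)
  for (i in seq_len(n)) {
    ti <- tel_by_ind[[i]]
    logE <- .log_emissions_ind(det_idx[[i]], base_log, Lcontrib, T_occ,
                               telem_i = ti$tab, tel_dens = ti$dens)
    cmax <- apply(logE, 2, max)
    ll_i[i] <- forward_loglik(trans, exp(sweep(logE, 2, cmax))) + sum(cmax)
  }
  ll_i
}

# telemetry emission log-density terms per detected individual (internal);
# marginal of u at pixel centers under N(center, sigma_det^2 I + Sigma_u)
.telemetry_emission_terms <- function(data, grid, model, theta) {
  n <- dim(data$y)[1]
  empty <- list(tab = NULL, dens = NULL)
  out <- rep(list(empty), max(n, 1L))
  if (is.null(model$Sigma_u) || is.null(data$telemetry) || n == 0) return(out)
  ids <- as.integer(dimnames(data$y)$individual)
  S <- model$Sigma_u + diag(2) * theta$sigma_det^2
  for (i in seq_len(n)) {
    tab <- data$telemetry[data$telemetry$individual == ids[i] &
                            data$telemetry$t <= data$T_occasions, , drop = FALSE]
    if (nrow(tab) == 0) next
    dens <- lapply(seq_len(nrow(tab)), function(k) {
      log(.dmvnorm2_many(grid$centers, c(tab$x[k], tab$y[k]), S))
    })
    out[[i]] <- list(tab = tab, dens = dens)
  }
  out
}
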