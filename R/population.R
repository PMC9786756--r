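#' Point-process models for abundance and locations
#'
#' `poisson_pp()` specifies a (possibly inhomogeneous) Poisson point process
#' for abundance and locations: the intensity at location \eqn{s} is
#' \eqn{\lambda_0 \exp\{\sum_k \beta_k c_k(s)\}} with baseline
#' \eqn{\lambda_0 = e^{\beta_0}}, so that
#' \eqn{N \sim \mathrm{Poisson}(\lambda_0 \int_M \lambda(s) ds)}; with no
#' covariates this is the homogeneous model \eqn{N \sim
#' \mathrm{Poisson}(\lambda \|M\|)}, \eqn{E[N] = \lambda\|M\|}.
#'
#' `binomial_pp()` specifies the data-augmentation style binomial model
#' \eqn{N \sim \mathrm{Binomial}(M_{aug}, \psi)}, \eqn{E[N] = \psi M_{aug}};
#' locations are uniform over the state space.
#'
#' `fixed_n_pp()` pins abundance to a known `N` (convenient for Monte Carlo
#' checks); locations are uniform unless `beta` is supplied.
#'
#' @param beta0 log baseline intensity.
#' @param beta optional named numeric vector of covariate coefficients
#'   \eqn{\beta_k} (names = raster layer names); empty/`NULL` means
#'   homogeneous.
#' @param M_aug augmentation size (integer).
#' @param psi inclusion probability in `[0, 1]`.
#' @param N fixed abundance.
#' @return an object of class `pp_spec`.
#' @name pp_spec
NULL

#' @rdname pp_spec
#' @export
poisson_pp <- function(beta0 = 0, beta = NULL) {
  stopifnot(is.finite(beta0))
  if (!is.null(beta) && length(beta)) {
    stopifnot(is.numeric(beta), all(is.finite(beta)), !is.null(names(beta)))
  } else beta <- NULL
  structure(list(family = "poisson", beta0 = beta0, beta = beta,
                 homogeneous = is.null(beta)), class = "pp_spec")
}

#' @rdname pp_spec
#' @export
binomial_pp <- function(M_aug, psi) {
  stopifnot(M_aug >= 1, psi >= 0, psi <= 1)
  structure(list(family = "binomial", M_aug = as.integer(M_aug), psi = psi,
                 beta = NULL, homogeneous = TRUE), class = "pp_spec")
}

#' @rdname pp_spec
#' @export
fixed_n_pp <- function(N, beta = NULL) {
  stopifnot(N >= 0)
  if (!is.null(beta) && !length(beta)) beta <- NULL
  structure(list(family = "fixed", N = as.integer(N), beta = beta,
                 homogeneous = is.null(beta)), class = "pp_spec")
}

#' Relative intensity surface of a point-process spec
#'
#' Evaluates \eqn{\lambda(s) = \exp\{\sum_k \beta_k c_k(s)\}} at masked-in
#' pixel centers (the baseline \eqn{\lambda_0 = e^{\beta_0}} is applied
#' separately in [expected_abundance()]). With no covariates the surface is
#' identically 1.
#'
#' @param spec a [pp_spec].
#' @param raster a [cov_raster()].
#' @param space a [state_space()].
#' @return strictly positive vector over masked-in pixels (canonical order).
#' @export
intensity_surface <- function(spec, raster, space) {
  stopifnot(inherits(spec, "pp_spec"))
  npix <- sum(raster$mask)
  if (is.null(spec$beta)) return(rep(1, npix))
  lp <- numeric(npix)
  for (k in names(spec$beta)) {
    lp <- lp + spec$beta[[k]] * .layer_values_masked(raster, k)
  }
  if (any(!is.finite(lp))) stop("non-finite covariate in intensity surface")
  exp(lp)
}

#' Expected abundance under a point-process spec
#'
#' Homogeneous Poisson: \eqn{E[N] = e^{\beta_0}\|M\|}; inhomogeneous:
#' \eqn{e^{\beta_0} \int_M \exp\{\sum_k \beta_k c_k(s)\}\,ds} by
#' pixel-midpoint quadrature; binomial: \eqn{\psi M_{aug}}.
#'
#' @inheritParams intensity_surface
#' @return scalar expected abundance.
#' @export
expected_abundance <- function(spec, raster, space) {
  stopifnot(inherits(spec, "pp_spec"))
  switch(spec$family,
    poisson = exp(spec$beta0) *
      sum(intensity_surface(spec, raster, space)) * raster$cell_size^2,
    binomial = spec$psi * spec$M_aug,
    fixed = spec$N,
    stop("unknown point-process family"))
}

#' Draw abundance N
#'
#' @inheritParams intensity_surface
#' @param seed optional integer seed (local to this call).
#' @return integer abundance.
#' @export
sample_abundance <- function(spec, raster, space, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  switch(spec$family,
    poisson = stats::rpois(1, expected_abundance(spec, raster, space)),
    binomial = stats::rbinom(1, spec$M_aug, spec$psi),
    fixed = spec$N)
}

# sample n points from per-pixel weights + uniform jitter within the pixel
.sample_points_pixelwise <- function(weights, raster, n) {
  ctr <- pixel_centers(raster)
  if (n == 0L) return(ctr[0, , drop = FALSE])
  idx <- sample.int(nrow(ctr), n, replace = TRUE, prob = weights)
  h <- raster$cell_size
  jit <- matrix(stats::runif(2 * n, -h / 2, h / 2), n, 2)
  ctr[idx, , drop = FALSE] + jit
}

#' Draw N locations from a point-process spec
#'
#' A pixel is chosen with probability proportional to its intensity times the
#' cell area, then the position is uniform within the pixel (so that
#' continuous-space detection distances are well defined); the homogeneous
#' case is uniform over `M`.
#'
#' @inheritParams sample_abundance
#' @param N number of points (`>= 0`).
#' @return `N x 2` matrix of planar points, all inside `M`.
#' @export
sample_locations <- function(spec, raster, space, N, seed = NULL) {
  stopifnot(N >= 0)
  if (!is.null(seed)) set.seed(seed)
  w <- intensity_surface(spec, raster, space)
  .sample_points_pixelwise(w / sum(w), raster, N)
}

#' Per-pixel density of initial locations by residency class
#'
#' Residents start from the resource-selection (Langevin limiting) surface
#' \eqn{\pi(s)}; transients start uniformly over `M`. Both return a
#' probability vector over masked-in pixels.
#'
#' @param label `"resident"` or `"transient"`.
#' @param delta named RSF coefficients (resident branch).
#' @param raster a [cov_raster()].
#' @param space a [state_space()].
#' @return per-pixel probability vector summing to 1.
#' @export
initial_location_density <- function(label = c("resident", "transient"),
                                     delta = NULL, raster, space) {
  label <- match.arg(label)
  npix <- sum(raster$mask)
  if (label == "transient") return(rep(1 / npix, npix))
  if (is.null(delta)) stop("resident branch requires delta coefficients")
  rsf_limiting_distribution(delta, raster, space)
}

#' Realize a population: abundance, classes, initial locations
#'
#' Draws \eqn{N} from the abundance spec, assigns each individual a
#' residency class (resident with probability `phi`), and draws its initial
#' location from the class-appropriate density: residents from the RSF
#' surface (when `delta` is given, else the abundance spec's intensity),
#' transients uniform over `M`.
#'
#' @param spec a [pp_spec] for abundance.
#' @param raster,space landscape objects.
#' @param phi resident mixture weight in `[0, 1]`; `phi = 1` (default) makes
#'   everyone a resident.
#' @param delta optional named RSF coefficients for the resident initial
#'   density.
#' @param seed optional integer seed (local to this call).
#' @return a `population` object: list with `N`, `points` (N x 2), `classes`
#'   (1 = resident, 2 = transient) and `phi`.
#' @export
sample_population <- function(spec, raster, space, phi = 1, delta = NULL,
                              seed = NULL) {
  stopifnot(phi >= 0, phi <= 1)
  if (!is.null(seed)) set.seed(seed)
  N <- sample_abundance(spec, raster, space)
  classes <- 1L + (stats::runif(N) > phi)
  npix <- sum(raster$mask)
  dens_res <- if (!is.null(delta)) {
    initial_location_density("resident", delta, raster, space)
  } else {
    w <- intensity_surface(spec, raster, space)
    w / sum(w)
  }
  dens_tra <- rep(1 / npix, npix)
  pts <- matrix(NA_real_, N, 2)
  if (any(classes == 1L)) {
    pts[classes == 1L, ] <- .sample_points_pixelwise(dens_res, raster,
                                                     sum(classes == 1L))
  }
  if (any(classes == 2L)) {
    pts[classes == 2L, ] <- .sample_points_pixelwise(dens_tra, raster,
                                                     sum(classes == 2L))
  }
  colnames(pts) <- c("x", "y")
  structure(list(N = N, points = pts, classes = classes, phi = phi),
            class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf("population: N = %d (%d residents, %d transients)\n",
              x$N, sum(x$classes == 1L), sum(x$classes == 2L)))
  invisible(x)
}
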