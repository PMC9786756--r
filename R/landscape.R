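#' Gridded habitat covariates over the state space
#'
#' A `cov_raster` stores one or more habitat covariate layers \eqn{c_k(s)} on
#' a common regular grid, together with a pixel mask defining the state space
#' \eqn{M}. Coordinates are continuous planar (projected) units with x east
#' and y north; pixel (1,1) sits at the lower-left corner, and internal value
#' matrices are indexed `[row = y from bottom, col = x]`.
#'
#' @param layers named list of numeric matrices (all the same dimension),
#'   one per covariate; values are attached to pixel centers.
#' @param origin numeric length-2, planar coordinates of the lower-left
#'   *corner* of the grid.
#' @param cell_size positive pixel edge length.
#' @param mask logical matrix of the same dimension as the layers; `TRUE`
#'   pixels belong to the state space. Default: all pixels in.
#'
#' @return an object of class `cov_raster`.
#' @seealso [state_space()], [covariate_at()], [gradient_at()], [read_asc()]
#' @export
cov_raster <- function(layers, origin = c(0, 0), cell_size = 1, mask = NULL) {
  if (!is.list(layers) || length(layers) == 0L || is.null(names(layers)) ||
      any(!nzchar(names(layers)))) {
    stop("'layers' must be a non-empty named list of matrices")
  }
  layers <- lapply(layers, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  dims <- vapply(layers, dim, integer(2))
  if (!all(dims[1, ] == dims[1, 1]) || !all(dims[2, ] == dims[2, 1])) {
    stop("all layers must share one grid")
  }
  if (!all(vapply(layers, function(m) all(is.finite(m)), logical(1)))) {
    stop("layer values must be finite")
  }
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0) {
    stop("cell_size must be a positive scalar")
  }
  nr <- dims[1, 1]; nc <- dims[2, 1]
  if (is.null(mask)) {
    mask <- matrix(TRUE, nr, nc)
  } else {
    mask <- as.matrix(mask)
    if (!all(dim(mask) == c(nr, nc))) stop("mask dimension mismatch")
    mask <- !is.na(mask) & mask
  }
  if (!any(mask)) stop("mask must contain at least one pixel inside M")
  structure(
    list(origin = as.numeric(origin), cell_size = as.numeric(cell_size),
         n_rows = nr, n_cols = nc, layers = layers, mask = mask),
    class = "cov_raster"
  )
}

#' @export
print.cov_raster <- function(x, ...) {
  cat(sprintf("cov_raster: %d x %d pixels, cell %g, layers: %s (%d/%d in mask)\n",
              x$n_rows, x$n_cols, x$cell_size,
              paste(names(x$layers), collapse = ", "),
              sum(x$mask), length(x$mask)))
  invisible(x)
}

#' The state space M
#'
#' Wraps a [cov_raster()] mask as the state space \eqn{M} over which
#' individuals (or their activity/attraction centers) live. Its area
#' \eqn{\|M\|} is exactly the number of masked-in pixels times the cell area;
#' pixels are wholly in or out (no partial pixels).
#'
#' @param raster a [cov_raster()].
#' @return an object of class `state_space`.
#' @export
state_space <- function(raster) {
  stopifnot(inherits(raster, "cov_raster"))
  structure(list(raster = raster), class = "state_space")
}

#' @export
print.state_space <- function(x, ...) {
  cat(sprintf("state_space: area %g (%d pixels of %g x %g)\n",
              sp_area(x), sum(x$raster$mask),
              x$raster$cell_size, x$raster$cell_size))
  invisible(x)
}

#' Area of the state space
#'
#' @param space a [state_space()].
#' @return `sum(mask) * cell_size^2`, exactly.
#' @export
sp_area <- function(space) {
  stopifnot(inherits(space, "state_space"))
  r <- space$raster
  sum(r$mask) * r$cell_size^2
}

# continuous coords -> fractional center-lattice coords (0-based), clamped to
# the center lattice; errors outside the raster extent
.raster_frac_index <- function(raster, location) {
  x <- location[1]; y <- location[2]
  h <- raster$cell_size
  ex <- raster$origin[1] + c(0, raster$n_cols * h)
  ey <- raster$origin[2] + c(0, raster$n_rows * h)
  if (is.na(x) || is.na(y) || x < ex[1] || x > ex[2] || y < ey[1] || y > ey[2]) {
    stop("location outside raster extent")
  }
  gx <- (x - raster$origin[1]) / h - 0.5
  gy <- (y - raster$origin[2]) / h - 0.5
  list(gx = min(max(gx, 0), raster$n_cols - 1),
       gy = min(max(gy, 0), raster$n_rows - 1),
       clamped_x = gx < 0 || gx > raster$n_cols - 1,
       clamped_y = gy < 0 || gy > raster$n_rows - 1)
}

.raster_layer <- function(raster, k) {
  if (!k %in% names(raster$layers)) stop("unknown layer: ", k)
  raster$layers[[k]]
}

#' Evaluate a covariate layer at a continuous location
#'
#' Bilinear interpolation of the four surrounding pixel-center values; at a
#' pixel center the stored value is returned exactly. Between the raster
#' extent and the outer ring of pixel centers, values are clamped to the
#' nearest-edge cells so covariates are defined on the whole extent.
#'
#' @param raster a [cov_raster()].
#' @param location numeric length-2 planar point.
#' @param k layer name.
#' @return scalar covariate value.
#' @export
covariate_at <- function(raster, location, k) {
  m <- .raster_layer(raster, k)
  fi <- .raster_frac_index(raster, location)
  j0 <- floor(fi$gx); i0 <- floor(fi$gy)
  j0 <- min(j0, raster$n_cols - 2 + (raster$n_cols == 1))
  i0 <- min(i0, raster$n_rows - 2 + (raster$n_rows == 1))
  tx <- fi$gx - j0; ty <- fi$gy - i0
  if (raster$n_cols == 1) { j1 <- j0 } else { j1 <- j0 + 1 }
  if (raster$n_rows == 1) { i1 <- i0 } else { i1 <- i0 + 1 }
  c00 <- m[i0 + 1, j0 + 1]; c10 <- m[i0 + 1, j1 + 1]
  c01 <- m[i1 + 1, j0 + 1]; c11 <- m[i1 + 1, j1 + 1]
  (1 - ty) * ((1 - tx) * c00 + tx * c10) + ty * ((1 - tx) * c01 + tx * c11)
}

#' Gradient of a covariate layer at a continuous location
#'
#' Analytic partial derivatives of the piecewise-bilinear surface defined by
#' the pixel-center values; continuous within cells, with accepted
#' discontinuities at cell boundaries. In clamped edge regions the gradient
#' component along the clamped direction is zero.
#'
#' @inheritParams covariate_at
#' @return numeric length-2 gradient `(d/dx, d/dy)`, pointing toward
#'   increasing covariate values.
#' @export
gradient_at <- function(raster, location, k) {
  m <- .raster_layer(raster, k)
  fi <- .raster_frac_index(raster, location)
  h <- raster$cell_size
  j0 <- floor(fi$gx); i0 <- floor(fi$gy)
  j0 <- min(j0, raster$n_cols - 2 + (raster$n_cols == 1))
  i0 <- min(i0, raster$n_rows - 2 + (raster$n_rows == 1))
  tx <- fi$gx - j0; ty <- fi$gy - i0
  if (raster$n_cols == 1) { j1 <- j0 } else { j1 <- j0 + 1 }
  if (raster$n_rows == 1) { i1 <- i0 } else { i1 <- i0 + 1 }
  c00 <- m[i0 + 1, j0 + 1]; c10 <- m[i0 + 1, j1 + 1]
  c01 <- m[i1 + 1, j0 + 1]; c11 <- m[i1 + 1, j1 + 1]
  gx <- ((1 - ty) * (c10 - c00) + ty * (c11 - c01)) / h
  gy <- ((1 - tx) * (c01 - c00) + tx * (c11 - c10)) / h
  if (fi$clamped_x || raster$n_cols == 1) gx <- 0
  if (fi$clamped_y || raster$n_rows == 1) gy <- 0
  c(gx, gy)
}

#' Is a location inside the state space?
#'
#' `TRUE` iff the pixel containing the location is masked in; points outside
#' the raster extent are `FALSE` (no error).
#'
#' @param space a [state_space()].
#' @param location numeric length-2 planar point.
#' @return logical scalar.
#' @export
sp_contains <- function(space, location) {
  r <- space$raster
  h <- r$cell_size
  jx <- floor((location[1] - r$origin[1]) / h) + 1
  iy <- floor((location[2] - r$origin[2]) / h) + 1
  # points exactly on the upper/right extent edge belong to the last pixel
  if (jx == r$n_cols + 1 && location[1] == r$origin[1] + r$n_cols * h) jx <- r$n_cols
  if (iy == r$n_rows + 1 && location[2] == r$origin[2] + r$n_rows * h) iy <- r$n_rows
  if (is.na(jx) || is.na(iy) || jx < 1 || jx > r$n_cols || iy < 1 || iy > r$n_rows) {
    return(FALSE)
  }
  isTRUE(r$mask[iy, jx])
}

# vectorized mask test on an n x 2 matrix of points (internal, simulation hot path)
.contains_many <- function(space, xy) {
  r <- space$raster
  h <- r$cell_size
  jx <- floor((xy[, 1] - r$origin[1]) / h) + 1
  iy <- floor((xy[, 2] - r$origin[2]) / h) + 1
  ok <- !is.na(jx) & !is.na(iy) & jx >= 1 & jx <= r$n_cols & iy >= 1 & iy <= r$n_rows
  out <- logical(nrow(xy))
  out[ok] <- r$mask[cbind(iy[ok], jx[ok])]
  out
}

#' Pixel-center coordinates of a raster
#'
#' @param raster a [cov_raster()].
#' @param masked_only return only centers of masked-in pixels (default).
#' @return matrix with columns `x`, `y`; pixels are ordered x-fastest,
#'   bottom row first (the canonical pixel ordering used throughout).
#' @export
pixel_centers <- function(raster, masked_only = TRUE) {
  h <- raster$cell_size
  xs <- raster$origin[1] + (seq_len(raster$n_cols) - 0.5) * h
  ys <- raster$origin[2] + (seq_len(raster$n_rows) - 0.5) * h
  cx <- rep(xs, times = raster$n_rows)
  cy <- rep(ys, each = raster$n_cols)
  keep <- if (masked_only) as.vector(t(raster$mask)) else rep(TRUE, length(cx))
  cbind(x = cx[keep], y = cy[keep])
}

# covariate values at masked-in pixel centers, canonical ordering (internal)
.layer_values_masked <- function(raster, k) {
  m <- .raster_layer(raster, k)
  as.vector(t(m))[as.vector(t(raster$mask))]
}
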