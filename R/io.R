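#' Read an ESRI ASCII grid covariate layer
#'
#' Parses the standard six-line header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `NODATA_value`) followed by `nrows` rows of
#' values listed top-down (the reader flips them into the package's
#' bottom-up orientation). `NODATA` pixels define the mask; their layer
#' values are filled by nearest-valid-neighbor averaging so that bilinear
#' interpolation stays defined near the mask boundary.
#'
#' @param paths named character vector of `.asc` file paths, one per layer.
#' @return a [cov_raster()] whose mask is the intersection of the layers'
#'   data-valid pixels.
#' @export
read_asc <- function(paths) {
  stopifnot(length(paths) >= 1, !is.null(names(paths)))
  hdr <- NULL
  layers <- list()
  mask <- NULL
  for (k in names(paths)) {
    lines <- readLines(paths[[k]])
    hk <- list()
    for (i in 1:6) {
      parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      hk[[tolower(parts[1])]] <- as.numeric(parts[2])
    }
    vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
    m <- matrix(vals, nrow = hk$nrows, ncol = hk$ncols, byrow = TRUE)
    m <- m[rev(seq_len(nrow(m))), , drop = FALSE]  # top-down file -> bottom-up
    nd <- hk$nodata_value
    valid <- m != nd
    m[!valid] <- NA_real_
    if (is.null(hdr)) {
      hdr <- hk
      mask <- valid
    } else {
      if (hk$ncols != hdr$ncols || hk$nrows != hdr$nrows ||
          hk$cellsize != hdr$cellsize ||
          hk$xllcorner != hdr$xllcorner || hk$yllcorner != hdr$yllcorner) {
        stop("layer '", k, "' grid does not match the first layer")
      }
      mask <- mask & valid
    }
    layers[[k]] <- .fill_na_nearest(m)
  }
  cov_raster(layers, origin = c(hdr$xllcorner, hdr$yllcorner),
             cell_size = hdr$cellsize, mask = mask)
}

# iterative nearest-neighbor fill of NA cells (internal)
.fill_na_nearest <- function(m) {
  while (anyNA(m)) {
    na_idx <- which(is.na(m), arr.ind = TRUE)
    filled <- m
    for (r in seq_len(nrow(na_idx))) {
      i <- na_idx[r, 1]; j <- na_idx[r, 2]
      nb <- c(if (i > 1) m[i - 1, j], if (i < nrow(m)) m[i + 1, j],
              if (j > 1) m[i, j - 1], if (j < ncol(m)) m[i, j + 1])
      nb <- nb[!is.na(nb)]
      if (length(nb)) filled[i, j] <- mean(nb)
    }
    if (identical(filled, m)) stop("cannot fill an all-NODATA layer")
    m <- filled
  }
  m
}

#' Write one raster layer as an ESRI ASCII grid
#'
#' @param raster a [cov_raster()].
#' @param k layer name.
#' @param path output file; masked-out pixels are written as the
#'   `NODATA_value` (-9999).
#' @export
write_asc <- function(raster, k, path) {
  m <- .raster_layer(raster, k)
  m[!raster$mask] <- -9999
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]  # bottom-up -> top-down
  hdr <- c(sprintf("ncols %d", raster$n_cols),
           sprintf("nrows %d", raster$n_rows),
           sprintf("xllcorner %.10g", raster$origin[1]),
           sprintf("yllcorner %.10g", raster$origin[2]),
           sprintf("cellsize %.10g", raster$cell_size),
           "NODATA_value -9999")
  body <- apply(m, 1, function(rw) paste(format(rw, trim = TRUE), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a trap layout CSV
#'
#' Expects columns `trap`, `x`, `y`.
#' @param path CSV file.
#' @return a [trap_array()].
#' @export
read_traps <- function(path) {
  trap_array(utils::read.csv(path))
}

#' @rdname read_traps
#' @param traps a [trap_array()] to write.
#' @export
write_traps <- function(traps, path) {
  utils::write.csv(data.frame(trap = traps$ids, x = traps$xy[, 1],
                              y = traps$xy[, 2]),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read long-format spatial encounter histories
#'
#' Expects a CSV with header `session,individual,occasion,trap` and one row
#' per detection; occasions are 1-based in the file. Duplicate
#' `(individual, occasion, trap)` rows collapse to a single 1 (the Bernoulli
#' observation model). Unknown trap ids and occasions outside `1..T` are
#' errors. An empty detail table yields an `n = 0` tensor.
#'
#' @param path CSV file.
#' @param traps a [trap_array()] defining valid trap ids.
#' @param T_occasions total number of occasions.
#' @return binary array `n x J x T` with individual ids on the first
#'   dimnames.
#' @export
read_captures <- function(path, traps, T_occasions) {
  df <- utils::read.csv(path)
  stopifnot(all(c("session", "individual", "occasion", "trap") %in% names(df)))
  if (nrow(df) == 0) {
    return(array(0L, c(0, traps$J, T_occasions),
                 dimnames = list(individual = NULL, trap = traps$ids,
                                 occasion = seq_len(T_occasions))))
  }
  jm <- match(df$trap, traps$ids)
  if (anyNA(jm)) stop("unknown trap id: ", df$trap[which(is.na(jm))[1]])
  if (any(df$occasion < 1 | df$occasion > T_occasions)) {
    stop("occasion outside 1..T")
  }
  ids <- sort(unique(df$individual))
  y <- array(0L, c(length(ids), traps$J, T_occasions),
             dimnames = list(individual = ids, trap = traps$ids,
                             occasion = seq_len(T_occasions)))
  y[cbind(match(df$individual, ids), jm, df$occasion)] <- 1L
  y
}

#' Write the capture, trap, telemetry, and truth files of a dataset
#'
#' Captures go to long format `session,individual,occasion,trap` (1-based
#' occasions); telemetry to `individual,t,x,y`; truth (when present) to
#' `individual,class,x,y` initial locations. A JSON run manifest records the
#' seed and package version for reproducibility.
#'
#' @param ds an `scr_data`.
#' @param dir output directory (created if needed).
#' @param session session label for the captures file.
#' @return the directory, invisibly.
#' @export
write_scr_dataset <- function(ds, dir, session = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  det <- which(ds$y == 1, arr.ind = TRUE)
  ids <- dimnames(ds$y)$individual
  cap <- data.frame(session = session,
                    individual = as.integer(ids[det[, 1]]),
                    occasion = det[, 3],
                    trap = ds$traps$ids[det[, 2]])
  cap <- cap[order(cap$individual, cap$occasion, cap$trap), ]
  utils::write.csv(cap, file.path(dir, "captures.csv"), row.names = FALSE)
  write_traps(ds$traps, file.path(dir, "traps.csv"))
  if (!is.null(ds$telemetry)) {
    utils::write.csv(ds$telemetry, file.path(dir, "telemetry.csv"),
                     row.names = FALSE)
  }
  if (!is.null(ds$truth)) {
    tr <- data.frame(individual = seq_len(ds$truth$N),
                     class = ds$truth$classes,
                     x = ds$truth$init[, 1], y = ds$truth$init[, 2])
    utils::write.csv(tr, file.path(dir, "truth.csv"), row.names = FALSE)
  }
  manifest <- list(seed = ds$seed, T_occasions = ds$T_occasions,
                   n = dim(ds$y)[1], J = ds$traps$J,
                   package_version = as.character(utils::packageVersion("scrmove")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a dataset written by [write_scr_dataset()]
#'
#' @param dir directory with `captures.csv`, `traps.csv`, optionally
#'   `telemetry.csv`, and `manifest.json`.
#' @return an `scr_data` (without a truth block).
#' @export
read_scr_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  traps <- read_traps(file.path(dir, "traps.csv"))
  T_occ <- manifest$T_occasions
  y <- read_captures(file.path(dir, "captures.csv"), traps, T_occ)
  tel_path <- file.path(dir, "telemetry.csv")
  telem <- if (file.exists(tel_path)) utils::read.csv(tel_path) else NULL
  structure(list(y = y, traps = traps, T_occasions = T_occ,
                 det_kind = "gauss", telemetry = telem, truth = NULL,
                 seed = manifest$seed),
            class = "scr_data")
}

#' Write a trajectory CSV (`individual,t,x,y[,state]`)
#'
#' @param traj a `trajectory`.
#' @param path CSV file.
#' @export
write_trajectory <- function(traj, path) {
  df <- data.frame(individual = attr(traj, "individual") %||% NA_integer_,
                   traj)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path)
  pos <- cbind(df$x, df$y)
  .new_trajectory(pos, states = df$state, individual = df$individual[1])
}

#' Read a YAML run configuration
#'
#' Validates the block structure of a run configuration file (landscape,
#' population, movement, detection, sampling, inference, seed) and rejects
#' unknown top-level keys. Values are returned as a named list for the
#' caller to assemble into [scr_sim_config()] / [scr_model()] objects.
#'
#' @param path YAML file.
#' @return named list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("landscape", "population", "movement", "detection",
               "sampling", "inference", "seed")
  extra <- setdiff(names(cfg), allowed)
  if (length(extra)) stop("unknown config keys: ", paste(extra, collapse = ", "))
  required <- c("detection", "sampling", "seed")
  missing <- setdiff(required, names(cfg))
  if (length(missing)) stop("missing config blocks: ",
                            paste(missing, collapse = ", "))
  cfg
}
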