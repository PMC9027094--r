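#' Render a simulation into a synthetic confocal z-stack movie
#'
#' Emulates spinning-disk acquisition of the simulated cells: each polarity
#' site becomes an anisotropic 3D Gaussian spot of integrated intensity
#' `spot_intensity` at its true position plus the cumulative stage drift;
#' fiducial beads are rendered as brighter Gaussians subject to the same
#' drift; a constant background is added and, optionally, Poisson shot noise
#' plus Gaussian read noise. The voxel grid covers the arena bounding box
#' plus `margin`, automatically extended by the total drift excursion so
#' drifting objects stay in the field of view; the axial extent is `n_z`
#' planes of `z_step` centered on the arena.
#'
#' Voxel `(i, j, k)` (1-based) has its center at
#' `origin + ((i, j, k) - 0.5) * (dx, dy, dz)`.
#'
#' @param truth a [simulate_walks()] result.
#' @param config a [sim_config()]; defaults to the one stored in `truth`.
#' @param margin spatial margin around the arena bounding box (um).
#' @return An object of class `"movie"`: list with `frames` (list of 3D
#'   arrays indexed `[x, y, z]`, one per timepoint) and `meta` (voxel sizes,
#'   origin, dimensions, frame interval, bead positions, cell geometry,
#'   background, and any out-of-field truncations).
#' @export
render_movie <- function(truth, config = truth$config, margin = 1.0) {
  stopifnot(inherits(truth, "ground_truth"))
  restore <- preserve_rng()
  on.exit(restore())

  arena <- truth$arena
  n_frames <- config$n_frames
  dx <- config$pixel_size_xy; dz <- config$z_step

  drift_tot <- (n_frames - 1) * config$drift_velocity
  lo <- c(min(arena$x - arena$radius), min(arena$y - arena$radius)) -
    margin + pmin(drift_tot[1:2], 0)
  hi <- c(max(arena$x + arena$radius), max(arena$y + arena$radius)) +
    margin + pmax(drift_tot[1:2], 0)
  nz <- config$n_z
  zmid <- (min(arena$z - arena$radius) + max(arena$z + arena$radius)) / 2 +
    (min(drift_tot[3], 0) + max(drift_tot[3], 0)) / 2

  beads <- config$bead_positions
  if (is.null(beads)) {
    # bead lane in the lower-left corner, clear of every cell's tracking ROI
    beads <- matrix(c(min(arena$x - arena$radius) - margin - 0.85 +
                        min(drift_tot[1], 0),
                      min(arena$y - arena$radius) - margin - 0.85 +
                        min(drift_tot[2], 0),
                      zmid), nrow = 1)
    lo <- lo - 1.7
  } else {
    beads <- matrix(as.numeric(unlist(beads)), ncol = 3, byrow = TRUE)
  }

  nx <- ceiling((hi[1] - lo[1]) / dx)
  ny <- ceiling((hi[2] - lo[2]) / dx)
  origin <- c(lo[1], lo[2], zmid - nz * dz / 2)
  voxel <- c(dx, dx, dz)
  dims <- c(nx, ny, nz)

  pos <- truth$positions
  set.seed((config$seed %% 1000000L) + 777L)  # noise substream
  frames <- vector("list", n_frames)
  truncated <- list()
  for (t in seq_len(n_frames)) {
    A <- array(config$background, dim = dims)
    cum_drift <- (t - 1) * config$drift_velocity
    pt <- pos[pos$frame == t, ]
    for (r in seq_len(nrow(pt))) {
      p <- c(pt$x_um[r], pt$y_um[r], pt$z_um[r]) + cum_drift
      if (!point_in_fov(p, origin, voxel, dims)) {
        warning(sprintf("cell %s out of field of view at frame %d",
                        pt$cell_id[r], t))
        truncated[[length(truncated) + 1]] <-
          data.frame(frame = t, cell_id = pt$cell_id[r])
        next
      }
      A <- add_spot(A, origin, voxel, p, config$spot_sigma_xy,
                    config$spot_sigma_z, config$spot_intensity)
    }
    for (b in seq_len(nrow(beads))) {
      A <- add_spot(A, origin, voxel, beads[b, ] + cum_drift,
                    config$spot_sigma_xy, config$spot_sigma_z,
                    config$bead_intensity)
    }
    if (config$noise_model == "poisson") {
      A[] <- stats::rpois(length(A), pmax(A, 0)) +
        stats::rnorm(length(A), 0, config$read_noise_sd)
      A[A < 0] <- 0
    }
    frames[[t]] <- A
  }

  meta <- list(voxel = voxel, origin = origin, dim = dims,
               n_frames = n_frames, frame_interval = config$frame_interval,
               bead_positions = beads,
               background = config$background,
               cells = data.frame(cell_id = arena$cell_id,
                                  mating_type = arena$mating_type,
                                  x = arena$x, y = arena$y, z = arena$z,
                                  radius = arena$radius),
               truncated = if (length(truncated)) do.call(rbind, truncated)
               else NULL)
  structure(list(frames = frames, meta = meta), class = "movie")
}

point_in_fov <- function(p, origin, voxel, dims) {
  all(p >= origin) && all(p <= origin + dims * voxel)
}

# Add a separable anisotropic Gaussian of integrated intensity `total` at
# position p (um), evaluated over a +/- 4 sigma voxel window.
add_spot <- function(A, origin, voxel, p, sigma_xy, sigma_z, total) {
  dims <- dim(A)
  sig <- c(sigma_xy, sigma_xy, sigma_z)
  idx <- vector("list", 3)
  dens <- vector("list", 3)
  for (ax in 1:3) {
    i0 <- max(1L, floor((p[ax] - 4 * sig[ax] - origin[ax]) / voxel[ax]) + 1L)
    i1 <- min(dims[ax],
              ceiling((p[ax] + 4 * sig[ax] - origin[ax]) / voxel[ax]))
    if (i0 > i1) return(A)
    ii <- i0:i1
    centers <- origin[ax] + (ii - 0.5) * voxel[ax]
    idx[[ax]] <- ii
    dens[[ax]] <- stats::dnorm(centers, p[ax], sig[ax]) * voxel[ax]
  }
  blob <- total * outer(outer(dens[[1]], dens[[2]]), dens[[3]])
  A[idx[[1]], idx[[2]], idx[[3]]] <-
    A[idx[[1]], idx[[2]], idx[[3]]] + blob
  A
}

#' @export
print.movie <- function(x, ...) {
  d <- x$meta$dim
  cat(sprintf("<movie> %d frames of %d x %d x %d voxels (%.2f x %.2f x %.2f um)\n",
              x$meta$n_frames, d[1], d[2], d[3],
              x$meta$voxel[1], x$meta$voxel[2], x$meta$voxel[3]))
  invisible(x)
}

#' Write / read a movie as multi-page TIFF plus a YAML sidecar
#'
#' One 16-bit multi-page TIFF per timepoint (`frame_001.tif`, ...; one page
#' per z-plane) plus `meta.yaml` holding voxel sizes, origin, intensity
#' scale, frame interval, bead positions and cell geometry.
#'
#' @param movie a `"movie"` object.
#' @param dir output directory (created if needed).
#' @return `write_movie()` invisibly returns `dir`; `read_movie()` returns
#'   the reconstructed `"movie"` (intensities quantized to 16 bits).
#' @export
write_movie <- function(movie, dir) {
  stopifnot(inherits(movie, "movie"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scale <- max(1, vapply(movie$frames, max, numeric(1))) * 1.05
  for (t in seq_along(movie$frames)) {
    A <- pmin(pmax(movie$frames[[t]], 0), scale)
    pages <- lapply(seq_len(dim(A)[3]), function(k) t(A[, , k]) / scale)
    tiff::writeTIFF(pages, file.path(dir, sprintf("frame_%03d.tif", t)),
                    bits.per.sample = 16L)
  }
  m <- movie$meta
  yaml::write_yaml(list(
    voxel = as.numeric(m$voxel), origin = as.numeric(m$origin),
    dim = as.integer(m$dim), n_frames = m$n_frames,
    frame_interval = m$frame_interval,
    intensity_scale = scale,
    background = m$background,
    bead_positions = lapply(seq_len(nrow(m$bead_positions)),
                            function(i) as.numeric(m$bead_positions[i, ])),
    cells = lapply(seq_len(nrow(m$cells)), function(i) as.list(m$cells[i, ]))
  ), file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' @rdname write_movie
#' @export
read_movie <- function(dir) {
  m <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  dims <- as.integer(m$dim)
  frames <- vector("list", m$n_frames)
  for (t in seq_len(m$n_frames)) {
    pages <- tiff::readTIFF(file.path(dir, sprintf("frame_%03d.tif", t)),
                            all = TRUE)
    A <- array(0, dim = dims)
    for (k in seq_len(dims[3])) A[, , k] <- t(pages[[k]]) * m$intensity_scale
    frames[[t]] <- A
  }
  cells <- do.call(rbind, lapply(m$cells, as.data.frame))
  beads <- do.call(rbind, lapply(m$bead_positions, rbind))
  meta <- list(voxel = as.numeric(m$voxel), origin = as.numeric(m$origin),
               dim = dims, n_frames = m$n_frames,
               frame_interval = m$frame_interval,
               bead_positions = beads, background = m$background,
               cells = cells, truncated = NULL)
  structure(list(frames = frames, meta = meta), class = "movie")
}
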