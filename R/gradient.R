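#' Point-source pheromone emitter
#'
#' Models a polarity site as a continuous point source of pheromone. At steady
#' state, free diffusion from a point source yields a concentration field that
#' decays inversely with distance, `c(r) = S / (4 pi D r)`. Degradation and
#' advection are deliberately omitted: for a peptide as small as alpha-factor
#' (D on the order of 150-300 um^2/s) diffusional escape is far faster than
#' any plausible extracellular proteolysis.
#'
#' @param position numeric length-3, source location in microns.
#' @param S source strength, molecules emitted per second (> 0).
#' @param D diffusion constant, um^2 per second (> 0).
#' @return An object of class `"point_source"`.
#' @examples
#' src <- point_source(c(0, 0, 0), S = 1000, D = 150)
#' concentration(src, c(1, 0, 0))
#' @export
point_source <- function(position, S, D) {
  position <- as.numeric(position)
  if (length(position) != 3 || anyNA(position)) {
    stop("`position` must be a numeric 3-vector")
  }
  if (!is.numeric(S) || length(S) != 1 || S <= 0) stop("`S` must be > 0")
  if (!is.numeric(D) || length(D) != 1 || D <= 0) stop("`D` must be > 0")
  structure(list(position = position, S = S, D = D), class = "point_source")
}

#' @export
print.point_source <- function(x, ...) {
  cat(sprintf(
    "<point_source> at (%.3g, %.3g, %.3g) um, S = %.3g /s, D = %.3g um^2/s\n",
    x$position[1], x$position[2], x$position[3], x$S, x$D))
  invisible(x)
}

#' Steady-state concentration of a point-source gradient
#'
#' Evaluates `c(r) = S / (4 pi D r)` at one or more query points.
#'
#' @param source a [point_source()].
#' @param point numeric 3-vector, or a matrix with one point per row.
#' @param tol distances below `tol` (microns) are treated as singular.
#' @return A data.frame with columns `r` (distance from the source, um) and
#'   `c` (concentration, molecules per um^3), one row per query point.
#' @export
concentration <- function(source, point, tol = 1e-9) {
  stopifnot(inherits(source, "point_source"))
  pts <- if (is.matrix(point)) point else matrix(as.numeric(point), nrow = 1)
  if (ncol(pts) != 3) stop("`point` must have 3 coordinates")
  d <- sweep(pts, 2, source$position)
  r <- sqrt(rowSums(d * d))
  if (any(r < tol)) stop("concentration is singular at the source (r = 0)")
  data.frame(r = r, c = source$S / (4 * pi * source$D * r))
}

# Gradient of the concentration field at a point; points toward the source
# with magnitude S / (4 pi D r^2). Internal: the simulator sums these over
# partners before projecting onto the cell surface.
concentration_gradient <- function(source, point, tol = 1e-9) {
  d <- source$position - as.numeric(point)
  r <- v_norm(d)
  if (r < tol) stop("concentration gradient is singular at the source")
  (source$S / (4 * pi * source$D * r^2)) * (d / r)
}

#' Tangential bias direction induced by a pheromone source
#'
#' Projects the direction from a polarity site toward a pheromone source onto
#' the tangent plane of the receiving cell at the site, giving the direction
#' along the cortex in which the concentration increases fastest. This is the
#' directional input that biases the simulated polarity-site walk toward the
#' mating partner.
#'
#' @param source a [point_source()] or a numeric 3-vector source position.
#' @param cell_center numeric 3-vector, center of the receiving cell (um).
#' @param site_pos numeric 3-vector on the receiving cell's surface (um).
#' @param radius cell radius; defaults to `|site_pos - cell_center|`.
#' @param tol relative tolerance below which the tangential projection is
#'   declared zero (source radially aligned with the site).
#' @param on_sphere_tol relative tolerance for the on-sphere check.
#' @return A unit 3-vector tangent to the sphere at `site_pos`, or the zero
#'   vector when the source is radially aligned.
#' @export
bias_direction <- function(source, cell_center, site_pos, radius = NULL,
                           tol = 1e-9, on_sphere_tol = 1e-6) {
  src <- if (inherits(source, "point_source")) source$position else
    as.numeric(source)
  cell_center <- as.numeric(cell_center)
  site_pos <- as.numeric(site_pos)
  rad_vec <- site_pos - cell_center
  r_site <- v_norm(rad_vec)
  if (is.null(radius)) radius <- r_site
  if (abs(r_site - radius) > on_sphere_tol * radius) {
    stop("`site_pos` does not lie on the cell sphere (beyond tolerance)")
  }
  if (v_norm(src - cell_center) < radius * (1 - on_sphere_tol)) {
    stop("source lies inside the receiving cell")
  }
  n_hat <- rad_vec / r_site
  v <- src - site_pos
  t_vec <- project_tangent(v, n_hat)
  if (v_norm(t_vec) < tol * max(v_norm(v), 1)) return(c(0, 0, 0))
  t_vec / v_norm(t_vec)
}
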