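# Internal 3-vector helpers. All coordinates are microns.

v_norm <- function(v) sqrt(sum(v * v))

v_unit <- function(v, tol = 1e-12) {
  n <- v_norm(v)
  if (n < tol) stop("cannot normalize a (near-)zero vector")
  v / n
}

v_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# component of v orthogonal to the unit vector n_hat
project_tangent <- function(v, n_hat) v - sum(v * n_hat) * n_hat

# uniform random direction on the unit sphere
runif_sphere <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- v_norm(v)
    if (n > 1e-6) return(v / n)
  }
}

# uniform random unit vector in the tangent plane with normal n_hat
runif_tangent <- function(n_hat) {
  repeat {
    t <- project_tangent(stats::rnorm(3), n_hat)
    n <- v_norm(t)
    if (n > 1e-6) return(t / n)
  }
}

# Exponential-map step on a sphere: move from p along the great circle with
# initial tangent direction dir_hat by arclength arc. Exact on-sphere motion.
sphere_step <- function(p, center, radius, dir_hat, arc) {
  u <- (p - center) / radius
  t_hat <- v_unit(project_tangent(dir_hat, u))
  a <- arc / radius
  center + radius * (cos(a) * u + sin(a) * t_hat)
}

#' Rotation matrix about an axis
#'
#' Rodrigues rotation matrix; exported because rotation invariance of the
#' direction statistic is one of the package's testable contracts.
#'
#' @param axis numeric length-3 rotation axis (need not be unit length).
#' @param angle rotation angle in radians.
#' @return a 3x3 rotation matrix.
#' @export
rotation_matrix <- function(axis, angle) {
  a <- v_unit(axis)
  K <- matrix(c(0, a[3], -a[2],
                -a[3], 0, a[1],
                a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# save/restore the caller's RNG state around seeded internals
preserve_rng <- function() {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}
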