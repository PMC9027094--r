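# Independent brute-force oracles used to validate the package's geometry
# and statistics, plus small fixture builders. The oracles deliberately use
# different formulations than the implementation.

# tangential projection via the explicit projection matrix (I - n n^T)
oracle_tangent_projection <- function(v, n_hat) {
  P <- diag(3) - n_hat %*% t(n_hat)
  as.numeric(P %*% v)
}

# step angle via rotation into 2D plane coordinates: build an orthonormal
# basis of the plane, express both directions in it, take atan2 angles.
oracle_step_angle <- function(normal, optimal, step_inplane) {
  e1 <- optimal / sqrt(sum(optimal^2))
  e2 <- c(normal[2] * e1[3] - normal[3] * e1[2],
          normal[3] * e1[1] - normal[1] * e1[3],
          normal[1] * e1[2] - normal[2] * e1[1])
  e2 <- e2 / sqrt(sum(e2^2))
  u <- c(sum(step_inplane * e1), sum(step_inplane * e2))
  ang <- atan2(u[2], u[1]) * 180 / pi
  abs(((ang + 180) %% 360) - 180)
}

# two-sample KS D by direct ECDF comparison at pooled unique points
oracle_ks_D <- function(x, y) {
  v <- sort(unique(c(x, y)))
  max(abs(vapply(v, function(q) mean(x <= q) - mean(y <= q), numeric(1))))
}

# exact p by explicit enumeration of every split of the pooled sample
oracle_ks_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  d_obs <- oracle_ks_D(x, y)
  splits <- utils::combn(length(pooled), n1)
  d_all <- apply(splits, 2, function(ix) {
    oracle_ks_D(pooled[ix], pooled[-ix])
  })
  mean(d_all >= d_obs - 1e-12)
}

# partner counting by direct O(n^2) pairwise distances
oracle_partner_count <- function(cells, cell_id, eps = 0.05) {
  i <- which(cells$cell_id == cell_id)
  cnt <- 0
  for (j in seq_len(nrow(cells))) {
    if (j == i) next
    if (cells$mating_type[j] == cells$mating_type[i]) next
    d <- sqrt((cells$x[i] - cells$x[j])^2 + (cells$y[i] - cells$y[j])^2 +
                (cells$z[i] - cells$z[j])^2)
    if (d <= cells$radius[i] + cells$radius[j] + eps) cnt <- cnt + 1
  }
  cnt
}

# maximal below-threshold runs by linear scan
oracle_runs <- function(below) {
  out <- NULL
  i <- 1
  n <- length(below)
  while (i <= n) {
    if (below[i]) {
      j <- i
      while (j < n && below[j + 1]) j <- j + 1
      out <- rbind(out, c(start = i, end = j))
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  out
}

# uniform random unit vector / random point on a sphere
rand_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# small, fast simulation config for tests
tiny_config <- function(n_frames = 20, seed = 99, ...) {
  sim_config(n_frames = n_frames, seed = seed, ...)
}

# voxel diagonal of a config, in microns
voxel_diag <- function(cfg) {
  sqrt(2 * cfg$pixel_size_xy^2 + cfg$z_step^2)
}

# tracking round-trip helper: simulate, render, track, truncate at overlap,
# and return per-frame centroid errors against ground truth
roundtrip_errors <- function(cfg, ar = arena_pair()) {
  gt <- simulate_walks(cfg, ar)
  mv <- render_movie(gt, cfg)
  tr <- track_movie(mv)
  cut <- track_until_overlap(tr$tracks[["1"]], tr$tracks[["2"]])
  errs <- numeric(0)
  n_kept <- 0
  for (cid in 1:2) {
    t <- if (cid == 1) cut$a else cut$b
    t <- t[!t$excluded, ]
    n_kept <- n_kept + nrow(t)
    p <- gt$positions[gt$positions$cell_id == cid, ]
    for (f in t$frame) {
      row <- t[t$frame == f, ]
      truth <- as.numeric(p[p$frame == f, c("x_um", "y_um", "z_um")])
      errs <- c(errs, sqrt(sum((c(row$x_um, row$y_um, row$z_um) -
                                  truth)^2)))
    }
  }
  list(errors = errs, n_kept = n_kept)
}
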