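#' Simulate biased polarity-site walks on touching spherical cells
#'
#' Ground-truth generator. Each cell carries one polarity site that performs a
#' persistent random walk on the cell surface. The tangential direction of
#' each step is the renormalized mixture
#'
#'   `persistence * previous direction + kappa * gradient direction +
#'    (1 - persistence) * isotropic noise`
#'
#' where the gradient direction is the tangential projection of the summed
#' steady-state point-source gradients emitted by the polarity sites of all
#' touching opposite-type partners (see [bias_direction()]); the bias term is
#' silently zero for cells that are not sensing, have `kappa = 0`, or have no
#' touching partner. Step arclengths are folded-normal draws and motion along
#' the sphere uses the exponential map (exact on-sphere great-circle steps).
#' If commitment is enabled and the sites of a mutually-sensing pair approach
#' within `commitment_distance`, both sites stop moving for the remainder of
#' the movie ("commit"); otherwise close approaches end with the sites moving
#' apart again ("kiss-and-run").
#'
#' Randomness: each cell draws from its own substream derived
#' deterministically from `config$seed`, so adding a cell to an arena leaves
#' the random draws of the other cells unchanged. The caller's RNG state is
#' preserved.
#'
#' @param config a [sim_config()].
#' @param arena an [arena()].
#' @return An object of class `"ground_truth"`: a list with elements
#'   `positions` (data.frame `frame, cell_id, x_um, y_um, z_um`; true on-sphere
#'   site positions, drift-free), `drift` (cumulative stage drift per frame),
#'   `pairs` (touching opposite-type pairs), `distances` (per-pair per-frame
#'   inter-site distances), `events` (true encounter intervals with outcome),
#'   `stopped` (per-cell commitment frame or `NA`), `arena`, and `config`.
#' @export
simulate_walks <- function(config, arena) {
  stopifnot(inherits(config, "sim_config"), inherits(arena, "arena"))
  restore <- preserve_rng()
  on.exit(restore())

  n_cells <- nrow(arena)
  n_frames <- config$n_frames
  ids <- arena$cell_id
  centers <- as.matrix(arena[, c("x", "y", "z")])
  radii <- arena$radius
  sensing <- arena$sensing
  pairs <- touching_pairs(arena, config$contact_eps)

  # partner indices (opposite type, touching) per cell
  partner_idx <- lapply(seq_len(n_cells), function(i) {
    id <- ids[i]
    p <- c(pairs$id_b[pairs$id_a == id], pairs$id_a[pairs$id_b == id])
    match(p, ids)
  })

  # Deterministic per-cell substream seeds drawn sequentially from the
  # master stream: the i-th draw does not depend on n_cells, so adding a
  # cell leaves the other cells' substreams (hence trajectories, absent
  # coupling through the bias) unchanged. Drawing the seeds — rather than
  # deriving them arithmetically — avoids correlated generator states from
  # related seeds.
  set.seed(config$seed)
  cell_seeds <- sample.int(.Machine$integer.max - 1L, n_cells)
  streams <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    set.seed(cell_seeds[i])
    streams[[i]] <- get(".Random.seed", envir = globalenv())
  }
  with_stream <- function(i, expr) {
    assign(".Random.seed", streams[[i]], envir = globalenv())
    out <- expr
    streams[[i]] <<- get(".Random.seed", envir = globalenv())
    out
  }

  # initial site positions: uniform on each sphere
  P <- matrix(0, n_cells, 3)
  for (i in seq_len(n_cells)) {
    P[i, ] <- centers[i, ] + radii[i] * with_stream(i, runif_sphere())
  }
  prev_dir <- matrix(0, n_cells, 3)
  stopped <- rep(FALSE, n_cells)
  stop_frame <- rep(NA_integer_, n_cells)

  pos <- array(NA_real_, c(n_frames, n_cells, 3))
  pos[1, , ] <- P

  check_commitment <- function(P, frame) {
    for (r in seq_len(nrow(pairs))) {
      i <- match(pairs$id_a[r], ids); j <- match(pairs$id_b[r], ids)
      if (!sensing[i] || !sensing[j]) next  # commitment needs mutual signaling
      if (stopped[i] && stopped[j]) next
      d <- sqrt(sum((P[i, ] - P[j, ])^2))
      if (d < config$commitment_distance) {
        stopped[c(i, j)] <<- TRUE
        stop_frame[c(i, j)] <<- ifelse(is.na(stop_frame[c(i, j)]), frame,
                                       stop_frame[c(i, j)])
      }
    }
  }
  if (config$commitment_enabled) check_commitment(P, 1L)

  for (t in seq_len(n_frames - 1)) {
    newP <- P
    for (i in seq_len(n_cells)) {
      if (stopped[i]) next
      n_hat <- (P[i, ] - centers[i, ]) / radii[i]
      xi <- with_stream(i, runif_tangent(n_hat))
      L <- with_stream(i, abs(stats::rnorm(1, config$step_length_mean,
                                           config$step_length_sd)))
      bias <- c(0, 0, 0)
      if (sensing[i] && config$kappa > 0 && length(partner_idx[[i]])) {
        g <- c(0, 0, 0)
        for (j in partner_idx[[i]]) {
          d <- P[j, ] - P[i, ]
          r <- v_norm(d)
          if (r < 1e-6) next  # sites coincident: gradient direction undefined
          src <- point_source(P[j, ], config$gradient_S, config$gradient_D)
          g <- g + concentration_gradient(src, P[i, ])
        }
        gt <- project_tangent(g, n_hat)
        if (v_norm(gt) > 1e-12) bias <- gt / v_norm(gt)
      }
      prev_t <- project_tangent(prev_dir[i, ], n_hat)
      if (v_norm(prev_t) > 1e-9) prev_t <- prev_t / v_norm(prev_t)
      d_mix <- config$persistence * prev_t + config$kappa * bias +
        (1 - config$persistence) * xi
      d_mix <- project_tangent(d_mix, n_hat)
      if (v_norm(d_mix) < 1e-9) d_mix <- xi
      dir_hat <- d_mix / v_norm(d_mix)
      arc <- min(L, 0.9 * pi * radii[i])
      newP[i, ] <- sphere_step(P[i, ], centers[i, ], radii[i], dir_hat, arc)
      prev_dir[i, ] <- dir_hat
    }
    P <- newP
    if (config$commitment_enabled) check_commitment(P, t + 1L)
    pos[t + 1, , ] <- P
  }

  positions <- data.frame(
    frame = rep(seq_len(n_frames), times = n_cells),
    cell_id = rep(ids, each = n_frames),
    x_um = as.vector(pos[, , 1]),
    y_um = as.vector(pos[, , 2]),
    z_um = as.vector(pos[, , 3]))

  drift <- data.frame(
    frame = seq_len(n_frames),
    dx_um = (seq_len(n_frames) - 1) * config$drift_velocity[1],
    dy_um = (seq_len(n_frames) - 1) * config$drift_velocity[2],
    dz_um = (seq_len(n_frames) - 1) * config$drift_velocity[3])

  distances <- truth_distances(pos, ids, pairs, n_frames)
  events <- truth_events(distances, pairs, stopped, ids, config)

  structure(list(positions = positions, drift = drift, pairs = pairs,
                 distances = distances, events = events,
                 stopped = data.frame(cell_id = ids,
                                      stop_frame = stop_frame),
                 arena = arena, config = config),
            class = "ground_truth")
}

truth_distances <- function(pos, ids, pairs, n_frames) {
  if (!nrow(pairs)) {
    return(data.frame(frame = integer(), id_a = integer(), id_b = integer(),
                      dist_um = numeric()))
  }
  out <- vector("list", nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    i <- match(pairs$id_a[r], ids); j <- match(pairs$id_b[r], ids)
    d <- sqrt(rowSums((pos[, i, , drop = TRUE] -
                         pos[, j, , drop = TRUE])^2))
    out[[r]] <- data.frame(frame = seq_len(n_frames),
                           id_a = pairs$id_a[r], id_b = pairs$id_b[r],
                           dist_um = d)
  }
  do.call(rbind, out)
}

# True encounter intervals from the ground-truth distance series: maximal runs
# below encounter_distance; a run that ends with both cells committed and
# reaches the movie end is labeled "commitment".
truth_events <- function(distances, pairs, stopped, ids, config) {
  ev <- list()
  n_frames <- config$n_frames
  for (r in seq_len(nrow(pairs))) {
    dd <- distances[distances$id_a == pairs$id_a[r] &
                      distances$id_b == pairs$id_b[r], ]
    below <- dd$dist_um < config$encounter_distance
    rl <- rle(below)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1
    for (k in seq_along(rl$values)) {
      if (!rl$values[k]) next
      i <- match(pairs$id_a[r], ids); j <- match(pairs$id_b[r], ids)
      outcome <- if (starts[k] == n_frames) {
        "censored"
      } else if (ends[k] == n_frames && stopped[i] && stopped[j]) {
        "commitment"
      } else {
        "kiss-and-run"
      }
      ev[[length(ev) + 1]] <- data.frame(
        id_a = pairs$id_a[r], id_b = pairs$id_b[r],
        start_frame = starts[k], end_frame = ends[k],
        min_dist_um = min(dd$dist_um[starts[k]:ends[k]]),
        time_to_encounter_min = (starts[k] - 1) * config$frame_interval,
        outcome = outcome)
    }
  }
  if (!length(ev)) {
    return(data.frame(id_a = integer(), id_b = integer(),
                      start_frame = integer(), end_frame = integer(),
                      min_dist_um = numeric(),
                      time_to_encounter_min = numeric(),
                      outcome = character()))
  }
  do.call(rbind, ev)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d cells x %d frames, %d touching pair(s), %d encounter event(s)\n",
              nrow(x$arena), x$config$n_frames, nrow(x$pairs),
              nrow(x$events)))
  invisible(x)
}

#' Ground-truth positions as a track table
#'
#' Converts a [simulate_walks()] result into the track format consumed by the
#' direction analysis (all frames retained, no exclusions), so that the same
#' statistics can be computed on truth and on tracked renders.
#'
#' @param truth a `"ground_truth"` object.
#' @return data.frame `frame, cell_id, x_um, y_um, z_um, excluded, reason`.
#' @export
truth_tracks <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  tr <- truth$positions
  tr$intensity <- NA_real_
  tr$excluded <- FALSE
  tr$reason <- NA_character_
  tr
}

#' Tangent-plane step angles computed on ground truth
#'
#' Convenience wrapper: runs [compute_step_angles()] on the true site
#' positions of a simulation, using the simulated arena's touching pairs and
#' cell centers.
#'
#' @param truth a `"ground_truth"` object.
#' @param ... passed to [compute_step_angles()] (e.g. `gate_um`,
#'   `truncate_at_encounter`).
#' @return The step-angle table (see [compute_step_angles()]) with an added
#'   `mating_type` column.
#' @export
truth_step_angles <- function(truth, ...) {
  stopifnot(inherits(truth, "ground_truth"))
  centers <- data.frame(cell_id = truth$arena$cell_id,
                        x = truth$arena$x, y = truth$arena$y,
                        z = truth$arena$z)
  ang <- compute_step_angles(truth_tracks(truth), truth$pairs, centers,
                             encounter_um = truth$config$encounter_distance,
                             ...)
  ang$mating_type <- truth$arena$mating_type[match(ang$cell_id,
                                                   truth$arena$cell_id)]
  ang
}

#' Write ground truth to plain-text files
#'
#' Positions go to `<stem>_positions.csv` (`frame, cell_id, x_um, y_um,
#' z_um`), encounter events to `<stem>_events.json`.
#'
#' @param truth a `"ground_truth"` object.
#' @param stem output path stem.
#' @return Invisibly, the two file paths.
#' @export
write_ground_truth <- function(truth, stem) {
  stopifnot(inherits(truth, "ground_truth"))
  pos_path <- paste0(stem, "_positions.csv")
  ev_path <- paste0(stem, "_events.json")
  utils::write.csv(truth$positions, pos_path, row.names = FALSE)
  jsonlite::write_json(truth$events, ev_path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(c(positions = pos_path, events = ev_path))
}
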