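#' Fit a tangent plane from three consecutive site positions
#'
#' The polarity site can only move along the cell cortex, so direction is
#' measured in a plane roughly tangential to the cell surface: the plane
#' through the current position and its two surrounding positions. The
#' normal is the unit cross product of `(p_cur - p_prev)` and
#' `(p_next - p_prev)`, oriented outward when the cell center is known. A
#' collinear triplet falls back to the outward radial direction at `p_cur`
#' (flagged); coincident points are degenerate and return `NULL` (the step is
#' skipped by the caller).
#'
#' @param p_prev,p_cur,p_next numeric 3-vectors (um) at consecutive retained
#'   frames.
#' @param cell_center optional cell center for outward orientation and for
#'   the collinear fallback.
#' @param tol degeneracy tolerance.
#' @return list `anchor`, `normal` (unit), `fallback` (logical), or `NULL`
#'   for a degenerate (coincident-point) triplet.
#' @export
fit_tangent_plane <- function(p_prev, p_cur, p_next, cell_center = NULL,
                              tol = 1e-9) {
  p_prev <- as.numeric(p_prev); p_cur <- as.numeric(p_cur)
  p_next <- as.numeric(p_next)
  u <- p_cur - p_prev
  w <- p_next - p_prev
  scale <- max(v_norm(u), v_norm(w))
  if (scale < tol) return(NULL)  # coincident points
  n <- v_cross(u, w)
  fallback <- FALSE
  if (v_norm(n) < tol * scale^2) {
    if (is.null(cell_center)) return(NULL)
    r <- p_cur - as.numeric(cell_center)
    if (v_norm(r) < tol) return(NULL)
    n <- r
    fallback <- TRUE
  }
  n <- n / v_norm(n)
  if (!is.null(cell_center) &&
      sum(n * (p_cur - as.numeric(cell_center))) < 0) {
    n <- -n
  }
  list(anchor = p_cur, normal = n, fallback = fallback)
}

#' Optimal movement direction toward the projected partner site
#'
#' Orthogonally projects the partner's polarity site onto the tangent plane;
#' the unit vector from the plane's anchor (the current site position) to
#' that projection is the optimal direction of movement.
#'
#' @param plane a [fit_tangent_plane()] result.
#' @param partner_site numeric 3-vector (um).
#' @param tol if the projected partner lies within `tol` of the anchor
#'   (partner directly along the normal) the direction is undefined and
#'   `NULL` is returned.
#' @return Unit 3-vector in the plane, or `NULL`.
#' @export
optimal_direction <- function(plane, partner_site, tol = 1e-9) {
  s <- as.numeric(partner_site)
  n <- plane$normal
  q <- s - sum((s - plane$anchor) * n) * n
  d <- q - plane$anchor
  if (v_norm(d) < tol) return(NULL)
  d / v_norm(d)
}

#' Angle between the actual step and the optimal direction
#'
#' The actual step `p_next - p_cur` is projected into the tangent plane
#' (default; set `project_step = FALSE` to measure the raw 3D step against
#' the in-plane optimal direction) and theta is the angle between the two
#' directions, in degrees in `[0, 180]`.
#'
#' @param plane a [fit_tangent_plane()] result.
#' @param optimal unit vector from [optimal_direction()].
#' @param p_cur,p_next site positions bounding the step (um).
#' @param project_step project the actual step into the plane first?
#' @param tol zero-length step tolerance (um).
#' @return list `theta_deg`, `step_um` (3D step length), or `NULL` when the
#'   (in-plane) step is of negligible length.
#' @export
step_angle <- function(plane, optimal, p_cur, p_next, project_step = TRUE,
                       tol = 1e-9) {
  step <- as.numeric(p_next) - as.numeric(p_cur)
  s <- if (project_step) project_tangent(step, plane$normal) else step
  if (v_norm(s) < tol) return(NULL)
  cosang <- sum(s / v_norm(s) * optimal)
  list(theta_deg = acos(min(1, max(-1, cosang))) * 180 / pi,
       step_um = v_norm(step))
}

#' Tangent-plane step angles for tracked cell pairs
#'
#' For every retained step of every cell in `pairs`, fits the tangent plane
#' from the nearest retained frames before and after the current frame,
#' projects the partner's site (taken at the current frame, or the nearest
#' retained frame within `partner_frame_slack`), and computes the angle
#' theta between the optimal direction and the actual movement. Steps at or
#' after the pair's first encounter (inter-site distance below
#' `encounter_um`) are dropped when `truncate_at_encounter` is `TRUE`,
#' since direction toward the partner is no longer defined once the sites
#' have met.
#'
#' @param tracks data.frame with columns `frame, cell_id, x_um, y_um, z_um`
#'   and optionally `excluded` (from [assemble_track()]); or a list of such
#'   data.frames.
#' @param pairs data.frame `id_a, id_b` of partner cells.
#' @param centers optional data.frame `cell_id, x, y, z` of cell centers
#'   (used to orient tangent planes and for the collinear fallback).
#' @param encounter_um encounter distance for truncation (um).
#' @param truncate_at_encounter drop steps from the first encounter on?
#' @param project_step see [step_angle()].
#' @param partner_frame_slack how far (frames) to look for a retained
#'   partner frame when the partner is excluded at the current frame.
#' @param gate_um inter-site distance gate applied to the result via
#'   [gate_by_distance()]; `Inf` keeps every step.
#' @return data.frame `t0, cell_id, partner_id, theta_deg, dist_um` (3D
#'   inter-site distance at the step start), `step_um, dt_frames`.
#' @export
compute_step_angles <- function(tracks, pairs, centers = NULL,
                                encounter_um = 1,
                                truncate_at_encounter = TRUE,
                                project_step = TRUE,
                                partner_frame_slack = 1,
                                gate_um = Inf) {
  if (is.list(tracks) && !is.data.frame(tracks)) {
    tracks <- do.call(rbind, tracks)
  }
  if (!"excluded" %in% names(tracks)) tracks$excluded <- FALSE
  kept <- tracks[!tracks$excluded & !is.na(tracks$x_um), ]

  # per-cell frame vectors and position matrices for fast lookup
  cell_ids <- unique(kept$cell_id)
  frames_of <- list()
  pos_of <- list()
  for (cid in cell_ids) {
    sub <- kept[kept$cell_id == cid, ]
    o <- order(sub$frame)
    frames_of[[as.character(cid)]] <- sub$frame[o]
    pos_of[[as.character(cid)]] <-
      as.matrix(sub[o, c("x_um", "y_um", "z_um")])
  }
  get_pos <- function(cell, frame) {
    key <- as.character(cell)
    i <- match(frame, frames_of[[key]])
    if (is.na(i)) return(NULL)
    pos_of[[key]][i, ]
  }
  center_of <- function(cell) {
    if (is.null(centers)) return(NULL)
    i <- match(cell, centers$cell_id)
    if (is.na(i)) return(NULL)
    as.numeric(centers[i, c("x", "y", "z")])
  }

  out <- list()
  for (r in seq_len(nrow(pairs))) {
    duo <- c(pairs$id_a[r], pairs$id_b[r])
    fa <- frames_of[[as.character(duo[1])]]
    fb <- frames_of[[as.character(duo[2])]]
    if (is.null(fa) || is.null(fb)) next
    # first encounter frame of the pair (on frames where both are retained)
    common <- sort(intersect(fa, fb))
    enc_frame <- Inf
    if (truncate_at_encounter && length(common)) {
      pa <- pos_of[[as.character(duo[1])]][match(common, fa), , drop = FALSE]
      pb <- pos_of[[as.character(duo[2])]][match(common, fb), , drop = FALSE]
      d <- sqrt(rowSums((pa - pb)^2))
      hit <- which(d < encounter_um)
      if (length(hit)) enc_frame <- common[hit[1]]
    }
    for (s in 1:2) {
      cell <- duo[s]; partner <- duo[3 - s]
      frames <- frames_of[[as.character(cell)]]
      if (length(frames) < 3) next
      pf <- frames_of[[as.character(partner)]]
      ctr <- center_of(cell)
      for (k in 2:(length(frames) - 1)) {
        t0 <- frames[k]
        if (t0 >= enc_frame) next
        # partner position at t0 or nearest retained frame within slack
        cand <- pf[abs(pf - t0) <= partner_frame_slack]
        if (!length(cand)) next
        tp <- cand[which.min(abs(cand - t0))]
        p_prev <- get_pos(cell, frames[k - 1])
        p_cur <- get_pos(cell, t0)
        p_next <- get_pos(cell, frames[k + 1])
        partner_pos <- get_pos(partner, tp)
        plane <- fit_tangent_plane(p_prev, p_cur, p_next, ctr)
        if (is.null(plane)) next
        opt <- optimal_direction(plane, partner_pos)
        if (is.null(opt)) next
        sa <- step_angle(plane, opt, p_cur, p_next,
                         project_step = project_step)
        if (is.null(sa)) next
        out[[length(out) + 1]] <- c(
          t0, cell, partner, sa$theta_deg,
          sqrt(sum((p_cur - partner_pos)^2)), sa$step_um,
          frames[k + 1] - t0)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(t0 = integer(), cell_id = integer(),
                      partner_id = integer(), theta_deg = numeric(),
                      dist_um = numeric(), step_um = numeric(),
                      dt_frames = integer()))
  }
  m <- do.call(rbind, out)
  res <- data.frame(t0 = as.integer(m[, 1]), cell_id = m[, 2],
                    partner_id = m[, 3], theta_deg = m[, 4],
                    dist_um = m[, 5], step_um = m[, 6],
                    dt_frames = as.integer(m[, 7]))
  gate_by_distance(res, gate_um)
}

#' Gate step angles by inter-site distance
#'
#' Directional bias is distance dependent: guidance is strong only when the
#' partner sites are close. This retains steps whose inter-site distance at
#' the step start is at most `max_distance` (default 4 um).
#'
#' @param samples step-angle table from [compute_step_angles()].
#' @param max_distance gate in microns.
#' @return The gated subset.
#' @export
gate_by_distance <- function(samples, max_distance = 4) {
  samples[samples$dist_um <= max_distance, , drop = FALSE]
}

#' ECDF and polar-histogram summaries of step angles
#'
#' @param samples numeric vector of angles in degrees, or a step-angle table
#'   with a `theta_deg` column.
#' @param bin_width polar-histogram bin width in degrees (default 15; bins
#'   `[0,15), ..., [165,180]`).
#' @return list `ecdf` (an [ecdf_table()]), `polar` (data.frame
#'   `bin_start, bin_end, count`; counts sum to `n`), `n`.
#' @export
angle_summaries <- function(samples, bin_width = 15) {
  theta <- if (is.data.frame(samples)) samples$theta_deg else
    as.numeric(samples)
  if (!length(theta)) stop("no angle samples")
  if (any(theta < 0 | theta > 180)) stop("angles must lie in [0, 180]")
  n_bins <- ceiling(180 / bin_width)
  bin <- pmin(floor(theta / bin_width) + 1L, n_bins)
  polar <- data.frame(bin_start = (seq_len(n_bins) - 1) * bin_width,
                      bin_end = pmin(seq_len(n_bins) * bin_width, 180),
                      count = tabulate(bin, n_bins))
  list(ecdf = ecdf_table(theta), polar = polar, n = length(theta))
}
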