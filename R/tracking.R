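#' Detect polarity-site candidates in a voxel stack by thresholding
#'
#' Implements the thresholding step of the tracking pipeline: voxels at or
#' above a threshold are grouped into 26-connected 3D components; each
#' component with at least `min_voxels` voxels yields an intensity-weighted
#' 3D centroid in physical microns. Candidates are returned sorted by total
#' intensity. The default threshold is a fraction of the region's maximum
#' intensity; Otsu's method is available as an alternative policy.
#'
#' @param stack 3D numeric array indexed `[x, y, z]`.
#' @param voxel numeric length-3 voxel sizes `(dx, dy, dz)` in microns.
#' @param origin numeric length-3 position (um) of the corner of voxel
#'   `(1, 1, 1)`; its center is at `origin + 0.5 * voxel`.
#' @param roi optional list with integer index ranges `x = c(i0, i1)`,
#'   `y = ...`, `z = ...` restricting the search; `NULL` searches the whole
#'   stack. An empty ROI is an error; an all-zero region returns no
#'   candidates.
#' @param threshold_policy `"max_fraction"` (threshold =
#'   `threshold_frac * max(roi)`) or `"otsu"`.
#' @param threshold_frac fraction of the ROI maximum (default 0.5).
#' @param min_voxels minimum component size (default 2, rejects hot pixels).
#' @param min_signal candidates are only reported when the ROI maximum
#'   exceeds this absolute intensity (0 disables the gate).
#' @return data.frame `x_um, y_um, z_um, intensity, n_voxels`, one row per
#'   candidate, ordered by decreasing intensity.
#' @export
detect_sites <- function(stack, voxel, origin, roi = NULL,
                         threshold_policy = c("max_fraction", "otsu"),
                         threshold_frac = 0.5, min_voxels = 2,
                         min_signal = 0) {
  threshold_policy <- match.arg(threshold_policy)
  dims <- dim(stack)
  if (is.null(roi)) {
    roi <- list(x = c(1L, dims[1]), y = c(1L, dims[2]), z = c(1L, dims[3]))
  }
  for (ax in c("x", "y", "z")) {
    if (roi[[ax]][1] > roi[[ax]][2]) stop("empty roi")
  }
  rx <- roi$x[1]:roi$x[2]; ry <- roi$y[1]:roi$y[2]; rz <- roi$z[1]:roi$z[2]
  sub <- stack[rx, ry, rz, drop = FALSE]
  empty <- data.frame(x_um = numeric(), y_um = numeric(), z_um = numeric(),
                      intensity = numeric(), n_voxels = integer())
  mx <- max(sub)
  if (mx <= 0 || mx < min_signal) return(empty)
  thr <- switch(threshold_policy,
                max_fraction = threshold_frac * mx,
                otsu = otsu_threshold(sub))
  mask <- sub >= thr
  lab <- label_components_3d(mask)
  if (lab$n == 0) return(empty)
  off <- c(roi$x[1], roi$y[1], roi$z[1]) - 1L
  out <- list()
  for (k in seq_len(lab$n)) {
    vox <- which(lab$labels == k)
    if (length(vox) < min_voxels) next
    co <- arrayInd(vox, dim(sub))
    w <- sub[vox]
    cent_idx <- colSums(co * w) / sum(w) + off  # fractional 1-based index
    out[[length(out) + 1]] <- data.frame(
      x_um = origin[1] + (cent_idx[1] - 0.5) * voxel[1],
      y_um = origin[2] + (cent_idx[2] - 0.5) * voxel[2],
      z_um = origin[3] + (cent_idx[3] - 0.5) * voxel[3],
      intensity = sum(w), n_voxels = length(vox))
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[order(-res$intensity), , drop = FALSE]
}

# Label TRUE voxels of a 3D logical array into 26-connected components.
label_components_3d <- function(mask) {
  dims <- dim(mask)
  labels <- array(0L, dims)
  nbr <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  nbr <- nbr[rowSums(abs(nbr)) > 0, , drop = FALSE]
  todo <- which(mask)
  n <- 0L
  for (v in todo) {
    if (labels[v] != 0L) next
    n <- n + 1L
    queue <- v
    labels[v] <- n
    while (length(queue)) {
      w <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      co <- arrayInd(w, dims)
      cand <- sweep(nbr, 2, as.integer(co), `+`)
      ok <- cand[, 1] >= 1 & cand[, 1] <= dims[1] &
        cand[, 2] >= 1 & cand[, 2] <= dims[2] &
        cand[, 3] >= 1 & cand[, 3] <= dims[3]
      cand <- cand[ok, , drop = FALSE]
      lin <- cand[, 1] + dims[1] * (cand[, 2] - 1) +
        dims[1] * dims[2] * (cand[, 3] - 1)
      lin <- lin[mask[lin] & labels[lin] == 0L]
      labels[lin] <- n
      queue <- c(queue, lin)
    }
  }
  list(labels = labels, n = n)
}

#' Otsu threshold of an intensity array
#'
#' Classical between-class-variance maximization over a 256-bin histogram.
#'
#' @param x numeric array or vector.
#' @param n_bins number of histogram bins.
#' @return The threshold intensity.
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  v <- as.numeric(x)
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (br[-1] + br[-length(br)]) / 2
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

#' Drift-correct detected centroids with a fiducial bead
#'
#' Subtracts the bead displacement relative to a reference frame from every
#' centroid: `corrected = raw - (bead(frame) - bead(reference))`. Frames with
#' no bead centroid are flagged uncorrectable (`excluded`, reason
#' `"no-bead"`).
#'
#' @param track data.frame with `frame, x_um, y_um, z_um` (raw centroids) and
#'   optional `excluded`/`reason` columns from [assemble_track()].
#' @param bead data.frame `frame, x_um, y_um, z_um` of bead centroids.
#' @param ref_frame reference frame index (default: first frame with a bead).
#' @return The track with `x_um, y_um, z_um` drift-corrected and the raw
#'   coordinates preserved as `x_raw_um, y_raw_um, z_raw_um`.
#' @export
correct_drift <- function(track, bead, ref_frame = NULL) {
  bead <- bead[stats::complete.cases(bead[, c("x_um", "y_um", "z_um")]), ]
  if (is.null(ref_frame)) ref_frame <- min(bead$frame)
  ref <- bead[bead$frame == ref_frame, c("x_um", "y_um", "z_um")]
  if (nrow(ref) != 1) stop("no bead centroid at the reference frame")
  track$x_raw_um <- track$x_um
  track$y_raw_um <- track$y_um
  track$z_raw_um <- track$z_um
  if (!"excluded" %in% names(track)) track$excluded <- FALSE
  if (!"reason" %in% names(track)) track$reason <- NA_character_
  m <- match(track$frame, bead$frame)
  no_bead <- is.na(m) & !track$excluded
  track$excluded[no_bead] <- TRUE
  track$reason[no_bead] <- "no-bead"
  ok <- !is.na(m)
  track$x_um[ok] <- track$x_raw_um[ok] - (bead$x_um[m[ok]] - ref$x_um)
  track$y_um[ok] <- track$y_raw_um[ok] - (bead$y_um[m[ok]] - ref$y_um)
  track$z_um[ok] <- track$z_raw_um[ok] - (bead$z_um[m[ok]] - ref$z_um)
  track$x_um[!ok] <- NA_real_
  track$y_um[!ok] <- NA_real_
  track$z_um[!ok] <- NA_real_
  track
}

#' Assemble per-frame candidates into a single-cell track
#'
#' Frames with exactly one candidate contribute a centroid; frames with none
#' or with several are recorded as excluded (reasons `"none-detected"` /
#' `"multiple-detected"`). No interpolation across gaps.
#'
#' @param candidates named list, one element per frame (names = frame
#'   indices), each a candidate data.frame from [detect_sites()].
#' @param cell_id id stored in the track.
#' @return data.frame `frame, cell_id, x_um, y_um, z_um, intensity,
#'   n_voxels, excluded, reason` with one row per frame, frames increasing.
#' @export
assemble_track <- function(candidates, cell_id = NA_integer_) {
  frames <- as.integer(names(candidates))
  o <- order(frames)
  frames <- frames[o]
  candidates <- candidates[o]
  rows <- lapply(seq_along(frames), function(i) {
    cand <- candidates[[i]]
    if (nrow(cand) == 1) {
      data.frame(frame = frames[i], cell_id = cell_id,
                 x_um = cand$x_um, y_um = cand$y_um, z_um = cand$z_um,
                 intensity = cand$intensity, n_voxels = cand$n_voxels,
                 excluded = FALSE, reason = NA_character_)
    } else {
      data.frame(frame = frames[i], cell_id = cell_id,
                 x_um = NA_real_, y_um = NA_real_, z_um = NA_real_,
                 intensity = NA_real_, n_voxels = NA_integer_,
                 excluded = TRUE,
                 reason = if (nrow(cand) == 0) "none-detected"
                 else "multiple-detected")
    }
  })
  do.call(rbind, rows)
}

#' Truncate a pair of tracks when the partners' signals overlap
#'
#' Both tracks are cut at the first frame where the drift-corrected centroid
#' distance drops below `merge_dist` (sub-resolution: the two thresholded
#' components can no longer be separated), mirroring the rule of tracking
#' sites only until their signals overlap. Without overlap the tracks are
#' returned unchanged.
#'
#' @param track_a,track_b tracks from [assemble_track()] /
#'   [correct_drift()].
#' @param merge_dist centroid merge distance in microns (default 0.5).
#' @return list `a`, `b` (tracks truncated to frames before the overlap) and
#'   `cut_frame` (`NA` when no overlap occurred).
#' @export
track_until_overlap <- function(track_a, track_b, merge_dist = 0.5) {
  ka <- track_a[!track_a$excluded, ]
  kb <- track_b[!track_b$excluded, ]
  common <- intersect(ka$frame, kb$frame)
  cut <- NA_integer_
  for (f in sort(common)) {
    pa <- ka[ka$frame == f, c("x_um", "y_um", "z_um")]
    pb <- kb[kb$frame == f, c("x_um", "y_um", "z_um")]
    if (sqrt(sum((pa - pb)^2)) < merge_dist) {
      cut <- f
      break
    }
  }
  if (is.na(cut)) {
    return(list(a = track_a, b = track_b, cut_frame = NA_integer_))
  }
  list(a = track_a[track_a$frame < cut, ],
       b = track_b[track_b$frame < cut, ],
       cut_frame = cut)
}

#' Track a rendered movie end to end
#'
#' Full tracking pipeline for a synthetic (or equivalently formatted) movie:
#' (1) the fiducial bead is followed frame to frame from its nominal position
#' (brightest component in a small search box around the previous centroid);
#' (2) for each cell, a box ROI around the cell (shifted every frame by the
#' measured bead displacement so the ROI follows stage drift) is thresholded
#' with [detect_sites()]; (3) per-frame candidates are assembled with the
#' exclusion rules of [assemble_track()] and drift-corrected against the
#' bead.
#'
#' @param movie a `"movie"` from [render_movie()] or [read_movie()].
#' @param threshold_frac,threshold_policy,min_voxels see [detect_sites()].
#' @param roi_margin half-width added to the cell radius for the ROI box
#'   (um).
#' @param bead_search_um half-width of the bead search box (um).
#' @param min_signal absolute intensity gate for site candidates; defaults
#'   to 1.5x the rendered background.
#' @param ref_frame drift reference frame.
#' @return list with `tracks` (named list of drift-corrected per-cell
#'   tracks) and `bead` (per-frame bead centroids).
#' @export
track_movie <- function(movie, threshold_frac = 0.5,
                        threshold_policy = "max_fraction", min_voxels = 2,
                        roi_margin = 0.75, bead_search_um = 0.75,
                        min_signal = NULL, ref_frame = 1L) {
  stopifnot(inherits(movie, "movie"))
  meta <- movie$meta
  if (is.null(min_signal)) min_signal <- 1.5 * meta$background
  voxel <- meta$voxel; origin <- meta$origin; dims <- meta$dim

  box_roi <- function(center, half) {
    lo <- pmax(1L, floor((center - half - origin) / voxel) + 1L)
    hi <- pmin(dims, ceiling((center + half - origin) / voxel))
    list(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]), z = c(lo[3], hi[3]))
  }

  # --- bead tracking (brightest candidate near the previous position)
  bead0 <- as.numeric(meta$bead_positions[1, ])
  bead_rows <- vector("list", meta$n_frames)
  prev <- bead0
  for (t in seq_len(meta$n_frames)) {
    roi <- box_roi(prev, rep(bead_search_um + 3 * voxel[1], 3))
    cand <- detect_sites(movie$frames[[t]], voxel, origin, roi,
                         threshold_policy = "max_fraction",
                         threshold_frac = threshold_frac,
                         min_voxels = min_voxels, min_signal = min_signal)
    if (nrow(cand) >= 1) {
      prev <- c(cand$x_um[1], cand$y_um[1], cand$z_um[1])
      bead_rows[[t]] <- data.frame(frame = t, x_um = prev[1],
                                   y_um = prev[2], z_um = prev[3])
    } else {
      bead_rows[[t]] <- data.frame(frame = t, x_um = NA_real_,
                                   y_um = NA_real_, z_um = NA_real_)
    }
  }
  bead <- do.call(rbind, bead_rows)
  bead_ok <- bead[stats::complete.cases(bead), ]
  ref <- bead_ok[bead_ok$frame == ref_frame, ]
  if (nrow(ref) != 1) stop("bead not detected at the reference frame")

  # --- per-cell tracking with drift-following ROIs
  tracks <- list()
  for (ci in seq_len(nrow(meta$cells))) {
    cell <- meta$cells[ci, ]
    center <- c(cell$x, cell$y, cell$z)
    half <- rep(cell$radius + roi_margin, 3)
    cands <- list()
    for (t in seq_len(meta$n_frames)) {
      b <- bead[bead$frame == t, ]
      shift <- if (stats::complete.cases(b)) {
        c(b$x_um - ref$x_um, b$y_um - ref$y_um, b$z_um - ref$z_um)
      } else c(0, 0, 0)
      roi <- box_roi(center + shift, half)
      cands[[as.character(t)]] <-
        detect_sites(movie$frames[[t]], voxel, origin, roi,
                     threshold_policy = threshold_policy,
                     threshold_frac = threshold_frac,
                     min_voxels = min_voxels, min_signal = min_signal)
    }
    tr <- assemble_track(cands, cell_id = cell$cell_id)
    tracks[[as.character(cell$cell_id)]] <-
      correct_drift(tr, bead, ref_frame = ref_frame)
  }
  list(tracks = tracks, bead = bead)
}

#' Read / write track tables as CSV
#'
#' @param tracks a single track data.frame or a list of them.
#' @param path CSV path.
#' @return `read_tracks()` returns one data.frame (all cells);
#'   `write_tracks()` invisibly returns `path`.
#' @export
write_tracks <- function(tracks, path) {
  if (is.data.frame(tracks)) tracks <- list(tracks)
  df <- do.call(rbind, tracks)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
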