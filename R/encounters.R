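#' Maximum-intensity projection of a z-stack
#'
#' @param stack 3D array indexed `[x, y, z]`.
#' @return 2D matrix of per-pixel maxima over z.
#' @export
max_project <- function(stack) {
  if (length(dim(stack)) != 3) stop("`stack` must be a 3D array")
  apply(stack, c(1, 2), max)
}

#' Averaged line scan across an image
#'
#' Samples intensity along the segment from `p0` to `p1` at pixel pitch,
#' averaging `width_px` parallel samples perpendicular to the line (bilinear
#' interpolation), the digital equivalent of drawing a 10-pixel-wide line
#' across two polarity sites.
#'
#' @param image 2D matrix indexed `[x, y]`.
#' @param p0,p1 segment endpoints in microns (xy).
#' @param width_px averaging width in pixels (>= 1).
#' @param pixel_size pixel size in microns.
#' @param origin xy position (um) of the corner of pixel `(1, 1)`.
#' @return data.frame `pos_um` (distance along the line from `p0`) and
#'   `intensity` (width-averaged).
#' @export
line_scan <- function(image, p0, p1, width_px = 10, pixel_size,
                      origin = c(0, 0)) {
  p0 <- as.numeric(p0); p1 <- as.numeric(p1)
  L <- sqrt(sum((p1 - p0)^2))
  if (L < pixel_size * 1e-6) stop("line endpoints coincide")
  if (width_px < 1) stop("`width_px` must be >= 1")
  u <- (p1 - p0) / L                       # along the line
  v <- c(-u[2], u[1])                      # perpendicular
  n_samp <- max(2L, floor(L / pixel_size) + 1L)
  pos <- seq(0, L, length.out = n_samp)
  offs <- (seq_len(width_px) - (width_px + 1) / 2) * pixel_size
  vals <- vapply(pos, function(s) {
    pts_x <- p0[1] + s * u[1] + offs * v[1]
    pts_y <- p0[2] + s * u[2] + offs * v[2]
    mean(bilinear_sample(image, pts_x, pts_y, pixel_size, origin))
  }, numeric(1))
  data.frame(pos_um = pos, intensity = vals)
}

# Bilinear interpolation of a [x, y] image at physical coordinates;
# coordinates are clamped to the image.
bilinear_sample <- function(image, x_um, y_um, pixel_size, origin) {
  nx <- nrow(image); ny <- ncol(image)
  u <- pmin(pmax((x_um - origin[1]) / pixel_size + 0.5, 1), nx)
  v <- pmin(pmax((y_um - origin[2]) / pixel_size + 0.5, 1), ny)
  i0 <- pmin(floor(u), nx - 1L); j0 <- pmin(floor(v), ny - 1L)
  fu <- u - i0; fv <- v - j0
  image[cbind(i0, j0)] * (1 - fu) * (1 - fv) +
    image[cbind(i0 + 1, j0)] * fu * (1 - fv) +
    image[cbind(i0, j0 + 1)] * (1 - fu) * fv +
    image[cbind(i0 + 1, j0 + 1)] * fu * fv
}

# topographic prominence of each local maximum of a profile
peak_prominences <- function(y) {
  n <- length(y)
  is_peak <- integer(0)
  if (n >= 2) {
    for (i in seq_len(n)) {
      ok <- if (i == 1) {
        y[1] > y[2]
      } else if (i == n) {
        y[n] > y[n - 1]
      } else {
        y[i] > y[i - 1] && y[i] >= y[i + 1]
      }
      if (ok) is_peak <- c(is_peak, i)
    }
  }
  prom <- vapply(is_peak, function(i) {
    # lowest point between the peak and the nearest higher ground on each
    # side (whole side if nothing higher); prominence = height - higher base
    base_l <- min(y[seq_len(i)])
    for (j in rev(seq_len(i - 1))) {
      if (y[j] > y[i]) {
        base_l <- min(y[j:i])
        break
      }
    }
    base_r <- min(y[i:n])
    if (i < n) {
      for (j in (i + 1):n) {
        if (y[j] > y[i]) {
          base_r <- min(y[i:j])
          break
        }
      }
    }
    y[i] - max(base_l, base_r)
  }, numeric(1))
  data.frame(index = is_peak, height = y[is_peak], prominence = prom)
}

#' Distance between the two most prominent peaks of a line profile
#'
#' Each polarity site appears as an intensity peak along the line scan; an
#' encounter is scored from the distance between the two peaks. Peaks are
#' local maxima with topographic prominence of at least `prominence_frac`
#' of the profile's dynamic range. When only one qualifying peak remains the
#' two sites are unresolvable ("merged") and the distance is 0.
#'
#' @param profile data.frame from [line_scan()].
#' @param prominence_frac minimum prominence as a fraction of
#'   `max - min` of the profile (default 0.2).
#' @return list `distance_um`, `merged` (logical), `n_peaks`, `peaks`
#'   (data.frame of qualifying peaks). With no qualifying peak at all,
#'   `distance_um` is `NA` (the frame cannot be scored).
#' @export
peak_distance <- function(profile, prominence_frac = 0.2) {
  y <- profile$intensity
  rng <- max(y) - min(y)
  pk <- peak_prominences(y)
  pk <- pk[pk$prominence >= prominence_frac * rng & rng > 0, , drop = FALSE]
  if (nrow(pk) == 0) {
    return(list(distance_um = NA_real_, merged = FALSE, n_peaks = 0L,
                peaks = pk))
  }
  if (nrow(pk) == 1) {
    return(list(distance_um = 0, merged = TRUE, n_peaks = 1L, peaks = pk))
  }
  top2 <- pk[order(-pk$prominence)[1:2], ]
  list(distance_um = abs(diff(profile$pos_um[top2$index])),
       merged = FALSE, n_peaks = nrow(pk), peaks = pk)
}

#' Detect polarity-site encounters from an inter-site distance series
#'
#' An encounter is a maximal run of consecutive frames in which the
#' inter-site distance is below `threshold` (1 um); runs separated by at
#' least one frame at or above threshold are distinct events. The time to
#' encounter is measured from the start of the movie (mixing), with frame
#' `f` acquired at `(f - 1) * frame_interval` minutes.
#'
#' @param distances data.frame with columns `frame` and `dist_um` (may
#'   contain `NA` for unscorable frames, which break runs).
#' @param threshold encounter distance in microns (default 1).
#' @param frame_interval minutes per frame.
#' @return data.frame `start_frame, end_frame, min_dist_um,
#'   time_to_encounter_min`, one row per event (zero rows when none).
#' @export
detect_encounters <- function(distances, threshold = 1, frame_interval = 2) {
  o <- order(distances$frame)
  fr <- distances$frame[o]
  d <- distances$dist_um[o]
  below <- !is.na(d) & d < threshold
  rl <- rle(below)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1
  keep <- which(rl$values)
  if (!length(keep)) {
    return(data.frame(start_frame = integer(), end_frame = integer(),
                      min_dist_um = numeric(),
                      time_to_encounter_min = numeric()))
  }
  do.call(rbind, lapply(keep, function(k) {
    idx <- starts[k]:ends[k]
    data.frame(start_frame = fr[starts[k]], end_frame = fr[ends[k]],
               min_dist_um = min(d[idx]),
               time_to_encounter_min = (fr[starts[k]] - 1) * frame_interval)
  }))
}

#' Classify an encounter as commitment or kiss-and-run
#'
#' Commitment means both polarity sites stabilize facing each other: the
#' pair stays below the encounter threshold for at least `K` consecutive
#' frames (default 5, i.e. 10 min at 2 min/frame) or through the final
#' frame of the movie. Otherwise one or both sites moved on: kiss-and-run.
#' An event starting on the last frame cannot be classified (censored).
#'
#' @param event one row of a [detect_encounters()] table.
#' @param n_frames total frames in the movie.
#' @param K commitment persistence in frames.
#' @return `"commitment"`, `"kiss-and-run"` or `"censored"`.
#' @export
classify_outcome <- function(event, n_frames, K = 5) {
  if (event$start_frame >= n_frames) return("censored")
  len <- event$end_frame - event$start_frame + 1
  if (len >= K || event$end_frame >= n_frames) return("commitment")
  "kiss-and-run"
}

#' Stratify encounter times by the number of touching partners
#'
#' Groups first-encounter times by how many potential partners each cell
#' touches (strata `"1"`, `"2"`, `">2"`, mirroring sparse vs crowded mating
#' mixes). Cells whose pairs never encounter contribute right-censored
#' observations at the movie end. The outcome of each cell's first event is
#' tallied into per-stratum commitment / kiss-and-run fractions.
#'
#' @param events data.frame with `id_a, id_b, start_frame, end_frame,
#'   outcome` (e.g. the `events` element of a [simulate_walks()] result, or
#'   built from [detect_encounters()] + [classify_outcome()]).
#' @param arena the [arena()] the events came from.
#' @param n_frames,frame_interval movie length and interval (min).
#' @param eps contact slack for partner counting (um).
#' @return list `times` (data.frame `cell_id, stratum, time_min, censored,
#'   outcome`) and `outcome_fractions` (per-stratum fractions over
#'   non-censored first events).
#' @export
stratify_times <- function(events, arena, n_frames, frame_interval = 2,
                           eps = 0.05) {
  pairs <- touching_pairs(arena, eps)
  cells <- unique(c(pairs$id_a, pairs$id_b))
  rows <- lapply(cells, function(cid) {
    np <- count_touching_partners(arena, cid, eps)
    stratum <- if (np <= 1) "1" else if (np == 2) "2" else ">2"
    ev <- events[events$id_a == cid | events$id_b == cid, , drop = FALSE]
    if (nrow(ev) == 0) {
      data.frame(cell_id = cid, stratum = stratum,
                 time_min = (n_frames - 1) * frame_interval,
                 censored = TRUE, outcome = NA_character_)
    } else {
      first <- ev[which.min(ev$start_frame), ]
      data.frame(cell_id = cid, stratum = stratum,
                 time_min = (first$start_frame - 1) * frame_interval,
                 censored = FALSE, outcome = first$outcome)
    }
  })
  times <- do.call(rbind, rows)
  strata <- unique(times$stratum)
  fractions <- do.call(rbind, lapply(strata, function(s) {
    oc <- times$outcome[times$stratum == s & !times$censored]
    n <- length(oc)
    data.frame(stratum = s, n_events = n,
               commitment = if (n) mean(oc == "commitment") else NA_real_,
               kiss_and_run = if (n) mean(oc == "kiss-and-run") else
                 NA_real_)
  }))
  list(times = times, outcome_fractions = fractions)
}
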