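#' Arena of touching spherical cells
#'
#' An arena is a data.frame (class `"arena"`) with one row per cell and
#' columns `cell_id`, `mating_type` (`"a"` or `"alpha"`), `x`, `y`, `z`
#' (center, um), `radius` (um), `sensing` (can this cell perceive the
#' partner's pheromone? `FALSE` emulates receptorless, *gpa1*-delta or
#' *cdc24-m1* cells) and `genotype` (free-text label). Cells may touch but
#' must not interpenetrate beyond `overlap_tol`.
#'
#' @param cells data.frame with the columns above (`genotype` optional).
#' @param overlap_tol maximum allowed overlap between two spheres (um).
#' @return The validated arena.
#' @seealso [arena_pair()], [arena_star()], [arena_chain()]
#' @export
arena <- function(cells, overlap_tol = 0.01) {
  need <- c("cell_id", "mating_type", "x", "y", "z", "radius", "sensing")
  if (!all(need %in% names(cells))) {
    stop("arena cells need columns: ", paste(need, collapse = ", "))
  }
  if (!"genotype" %in% names(cells)) cells$genotype <- "WT"
  cells <- as.data.frame(cells)
  if (anyDuplicated(cells$cell_id)) stop("duplicate cell_id in arena")
  if (!all(cells$mating_type %in% c("a", "alpha"))) {
    stop("mating_type must be \"a\" or \"alpha\"")
  }
  if (any(cells$radius <= 0)) stop("cell radii must be > 0")
  n <- nrow(cells)
  if (n > 1) {
    ctr <- as.matrix(cells[, c("x", "y", "z")])
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d <- sqrt(sum((ctr[i, ] - ctr[j, ])^2))
        if (d < cells$radius[i] + cells$radius[j] - overlap_tol) {
          stop(sprintf("cells %s and %s overlap beyond tolerance",
                       cells$cell_id[i], cells$cell_id[j]))
        }
      }
    }
  }
  structure(cells, class = c("arena", "data.frame"),
            overlap_tol = overlap_tol)
}

#' Isolated pair of touching cells of opposite mating type
#'
#' The canonical sparse-conditions geometry: one MATa and one MATalpha cell in
#' contact, each with exactly one potential partner.
#'
#' @param radius cell radius in microns (default 2.5).
#' @param sensing_a,sensing_alpha can the MATa / MATalpha cell sense its
#'   partner's pheromone? Setting one to `FALSE` gives the unilateral
#'   (receptorless-mix) scenario, both `FALSE` the fully signaling-dead mix.
#' @param genotype_a,genotype_alpha genotype labels.
#' @return An [arena()] with two cells centered at the origin and `(2*radius,
#'   0, 0)`.
#' @export
arena_pair <- function(radius = 2.5, sensing_a = TRUE, sensing_alpha = TRUE,
                       genotype_a = "WT", genotype_alpha = "WT") {
  arena(data.frame(
    cell_id = c(1L, 2L),
    mating_type = c("a", "alpha"),
    x = c(0, 2 * radius), y = 0, z = 0,
    radius = radius,
    sensing = c(sensing_a, sensing_alpha),
    genotype = c(genotype_a, genotype_alpha)))
}

#' Star arena: one focal cell touching several opposite-type partners
#'
#' Emulates crowded mating mixes in which a cell touches more than one
#' potential partner: `n_partners` opposite-type cells are arranged in the
#' xy-plane around a focal cell, all touching it.
#'
#' @param n_partners number of touching partners (1..6).
#' @param radius cell radius (um).
#' @param focal_type mating type of the central cell.
#' @param sensing are all cells able to sense pheromone?
#' @return An [arena()]; the focal cell has `cell_id` 1.
#' @export
arena_star <- function(n_partners, radius = 2.5, focal_type = "a",
                       sensing = TRUE) {
  stopifnot(n_partners >= 1, n_partners <= 6)
  other <- if (focal_type == "a") "alpha" else "a"
  ang <- 2 * pi * (seq_len(n_partners) - 1) / max(n_partners, 1)
  arena(data.frame(
    cell_id = seq_len(n_partners + 1),
    mating_type = c(focal_type, rep(other, n_partners)),
    x = c(0, 2 * radius * cos(ang)),
    y = c(0, 2 * radius * sin(ang)),
    z = 0,
    radius = radius,
    sensing = sensing,
    genotype = "WT"))
}

#' Chain arena: cells in a row, consecutive cells touching
#'
#' @param types character vector of mating types along the chain.
#' @param radius cell radius (um).
#' @param sensing logical, recycled along the chain.
#' @return An [arena()].
#' @export
arena_chain <- function(types, radius = 2.5, sensing = TRUE) {
  n <- length(types)
  arena(data.frame(
    cell_id = seq_len(n),
    mating_type = types,
    x = 2 * radius * (seq_len(n) - 1), y = 0, z = 0,
    radius = radius,
    sensing = rep_len(sensing, n),
    genotype = "WT"))
}

#' Number of touching potential mating partners
#'
#' A potential partner is a cell of opposite mating type whose center lies
#' within `r1 + r2 + eps` of the focal cell's center.
#'
#' @param arena an [arena()].
#' @param cell_id focal cell id.
#' @param eps contact slack in microns.
#' @return Integer partner count.
#' @export
count_touching_partners <- function(arena, cell_id, eps = 0.05) {
  i <- match(cell_id, arena$cell_id)
  if (is.na(i)) stop("unknown cell_id: ", cell_id)
  ctr <- as.matrix(arena[, c("x", "y", "z")])
  d <- sqrt(colSums((t(ctr) - ctr[i, ])^2))
  opp <- arena$mating_type != arena$mating_type[i]
  sum(opp & d <= arena$radius + arena$radius[i] + eps & seq_along(d) != i)
}

#' Touching opposite-mating-type pairs in an arena
#'
#' @inheritParams count_touching_partners
#' @return data.frame with columns `id_a` (the MATa cell) and `id_b` (the
#'   MATalpha cell), one row per touching opposite-type pair.
#' @export
touching_pairs <- function(arena, eps = 0.05) {
  ctr <- as.matrix(arena[, c("x", "y", "z")])
  out <- list()
  n <- nrow(arena)
  for (i in seq_len(n)) {
    if (arena$mating_type[i] != "a") next
    for (j in seq_len(n)) {
      if (arena$mating_type[j] != "alpha") next
      d <- sqrt(sum((ctr[i, ] - ctr[j, ])^2))
      if (d <= arena$radius[i] + arena$radius[j] + eps) {
        out[[length(out) + 1]] <- data.frame(id_a = arena$cell_id[i],
                                             id_b = arena$cell_id[j])
      }
    }
  }
  if (!length(out)) {
    return(data.frame(id_a = integer(), id_b = integer()))
  }
  do.call(rbind, out)
}
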