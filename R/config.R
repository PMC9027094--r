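#' Simulation and rendering configuration
#'
#' Bundles every knob of the simulator, renderer and analysis defaults into a
#' validated list of class `"sim_config"`. The imaging geometry defaults
#' (2 min frame interval, 15 z-planes of 0.48 um) match standard spinning-disk
#' acquisition of mating yeast; the motion-model defaults are illustrative
#' (real polarity-patch step lengths and persistence are not quantified in
#' the literature) and are meant to be recovered from data, not asserted.
#'
#' @param cell_radius cell radius in microns.
#' @param n_frames number of timepoints.
#' @param frame_interval minutes between frames.
#' @param step_length_mean,step_length_sd folded-normal parameters of the
#'   per-frame arclength moved by a polarity site (um per frame).
#' @param persistence weight in `[0, 1]` on the previous step direction.
#' @param kappa bias weight (>= 0) on the pheromone-gradient direction;
#'   `kappa = 0` emulates cells that cannot decode the gradient
#'   (receptorless, *gpa1*-delta, *cdc24-m1*).
#' @param commitment_enabled if `TRUE`, both sites stop moving permanently
#'   ("commit") once a mutually-sensing pair comes within
#'   `commitment_distance`.
#' @param commitment_distance commitment trigger distance (um).
#' @param encounter_distance encounter-scoring distance (um, default 1).
#' @param drift_velocity stage drift per frame, 3-vector (um/frame).
#' @param pixel_size_xy lateral voxel size (um, default 0.16 for a 100x/1.4
#'   objective class sampling).
#' @param z_step axial step (um, default 0.48).
#' @param n_z number of z-planes (default 15).
#' @param spot_sigma_xy,spot_sigma_z Gaussian spot widths (um) used to render
#'   a polarity site.
#' @param spot_intensity integrated counts per rendered polarity site.
#' @param bead_intensity integrated counts per fiducial bead (brighter).
#' @param bead_positions optional list/matrix of bead positions (um); when
#'   `NULL` the renderer places one bead in a free corner of the field.
#' @param background constant background counts per voxel.
#' @param noise_model `"none"` or `"poisson"` (Poisson shot noise plus
#'   Gaussian read noise of sd `read_noise_sd`).
#' @param read_noise_sd read-noise standard deviation (counts).
#' @param gradient_S,gradient_D point-source strength (molecules/s) and
#'   diffusion constant (um^2/s) of the pheromone gradient model. Only the
#'   *direction* of the gradient enters the walk; its magnitude is absorbed
#'   into `kappa`.
#' @param contact_eps slack for the touching-partner test (um).
#' @param seed integer RNG seed; per-cell substreams are derived from it so
#'   that adding a cell does not perturb the other cells' random draws.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(cell_radius = 2.5,
                       n_frames = 60,
                       frame_interval = 2,
                       step_length_mean = 0.5,
                       step_length_sd = 0.25,
                       persistence = 0.3,
                       kappa = 1,
                       commitment_enabled = TRUE,
                       commitment_distance = 1.0,
                       encounter_distance = 1.0,
                       drift_velocity = c(0, 0, 0),
                       pixel_size_xy = 0.16,
                       z_step = 0.48,
                       n_z = 15,
                       spot_sigma_xy = 0.25,
                       spot_sigma_z = 0.5,
                       spot_intensity = 2000,
                       bead_intensity = 8000,
                       bead_positions = NULL,
                       background = 10,
                       noise_model = c("none", "poisson"),
                       read_noise_sd = 2,
                       gradient_S = 1000,
                       gradient_D = 150,
                       contact_eps = 0.05,
                       seed = 1L) {
  noise_model <- match.arg(noise_model)
  cfg <- list(
    cell_radius = cell_radius, n_frames = as.integer(n_frames),
    frame_interval = frame_interval,
    step_length_mean = step_length_mean, step_length_sd = step_length_sd,
    persistence = persistence, kappa = kappa,
    commitment_enabled = isTRUE(commitment_enabled),
    commitment_distance = commitment_distance,
    encounter_distance = encounter_distance,
    drift_velocity = as.numeric(drift_velocity),
    pixel_size_xy = pixel_size_xy, z_step = z_step, n_z = as.integer(n_z),
    spot_sigma_xy = spot_sigma_xy, spot_sigma_z = spot_sigma_z,
    spot_intensity = spot_intensity, bead_intensity = bead_intensity,
    bead_positions = bead_positions,
    background = background, noise_model = noise_model,
    read_noise_sd = read_noise_sd,
    gradient_S = gradient_S, gradient_D = gradient_D,
    contact_eps = contact_eps, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  pos <- c("cell_radius", "frame_interval", "pixel_size_xy", "z_step",
           "spot_sigma_xy", "spot_sigma_z", "commitment_distance",
           "encounter_distance")
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0) stop("`", f, "` must be > 0")
  }
  if (cfg$n_frames < 2) stop("`n_frames` must be >= 2")
  if (cfg$n_z < 1) stop("`n_z` must be >= 1")
  if (cfg$step_length_mean < 0 || cfg$step_length_sd < 0) {
    stop("step-length parameters must be >= 0")
  }
  if (cfg$persistence < 0 || cfg$persistence > 1) {
    stop("`persistence` must be in [0, 1]")
  }
  if (cfg$kappa < 0) stop("`kappa` must be >= 0")
  if (length(cfg$drift_velocity) != 3) {
    stop("`drift_velocity` must be a 3-vector")
  }
  if (cfg$gradient_S <= 0 || cfg$gradient_D <= 0) {
    stop("gradient parameters must be > 0")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  cells: radius %.2f um; %d frames x %g min\n",
              x$cell_radius, x$n_frames, x$frame_interval))
  cat(sprintf("  walk: step %.2f +/- %.2f um, persistence %.2f, kappa %.2f\n",
              x$step_length_mean, x$step_length_sd, x$persistence, x$kappa))
  cat(sprintf("  commitment: %s (< %.2f um); encounter < %.2f um\n",
              if (x$commitment_enabled) "on" else "off",
              x$commitment_distance, x$encounter_distance))
  cat(sprintf("  voxels: %.2f x %.2f x %.2f um, %d z-planes; noise %s\n",
              x$pixel_size_xy, x$pixel_size_xy, x$z_step, x$n_z,
              x$noise_model))
  cat(sprintf("  gradient: S %.3g /s, D %.3g um^2/s; seed %d\n",
              x$gradient_S, x$gradient_D, x$seed))
  invisible(x)
}

# derive an updated copy of a config; revalidates
update_config <- function(config, ...) {
  cfg <- modifyList(unclass(config), list(...))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' Read / write a simulation configuration as YAML
#'
#' @param path file path.
#' @return `read_sim_config()` returns a [sim_config()];
#'   `write_sim_config()` invisibly returns `path`.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$drift_velocity)) {
    vals$drift_velocity <- as.numeric(vals$drift_velocity)
  }
  do.call(sim_config, vals)
}

#' @param config a [sim_config()].
#' @rdname read_sim_config
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  vals <- unclass(config)
  vals$bead_positions <- if (is.null(vals$bead_positions)) NULL else
    lapply(seq_len(nrow(as.matrix(vals$bead_positions))),
           function(i) as.numeric(as.matrix(vals$bead_positions)[i, ]))
  yaml::write_yaml(vals, path)
  invisible(path)
}
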