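#' Calibration curve mapping bias strength kappa to mean cos(theta)
#'
#' The gradient-bias weight kappa has no direct experimental counterpart, so
#' it is recovered from data by inverting a simulation calibration curve:
#' for each kappa on a grid, isolated bilateral pairs are simulated (same
#' walk parameters, commitment off so the walk never freezes) and the mean
#' of `cos(theta)` over all steps is recorded. Mean cos(theta) is 0 for an
#' unbiased walk and approaches 1 as the bias dominates, and increases
#' monotonically with kappa.
#'
#' @param kappas grid of bias weights.
#' @param n_steps target number of step-angle samples per grid point.
#' @param config base [sim_config()]; `kappa`, `seed`, `n_frames` and
#'   `commitment_enabled` are overridden internally.
#' @param n_frames frames per simulated pair (controls how many independent
#'   pairs are pooled per grid point).
#' @param seed calibration RNG seed.
#' @return An object of class `"kappa_calibration"`: list `table`
#'   (data.frame `kappa, mean_cos, n`), `fun` (monotone spline
#'   kappa -> mean cos), `range`.
#' @seealso [estimate_kappa()]
#' @export
calibrate_kappa <- function(kappas = seq(0, 4, by = 0.25), n_steps = 3000,
                            config = sim_config(), n_frames = 152,
                            seed = 424243L) {
  tab <- do.call(rbind, lapply(seq_along(kappas), function(gi) {
    k <- kappas[gi]
    cosv <- numeric(0)
    rep_i <- 0L
    while (length(cosv) < n_steps) {
      rep_i <- rep_i + 1L
      cfg <- update_config(config, kappa = k, n_frames = n_frames,
                           commitment_enabled = FALSE,
                           seed = (seed + 7717L * gi + rep_i) %%
                             .Machine$integer.max)
      gt <- simulate_walks(cfg, arena_pair(radius = config$cell_radius))
      ang <- truth_step_angles(gt, gate_um = Inf,
                               truncate_at_encounter = FALSE)
      cosv <- c(cosv, cos(ang$theta_deg * pi / 180))
      if (rep_i > 1000) stop("calibration failed to accumulate steps")
    }
    data.frame(kappa = k, mean_cos = mean(cosv[seq_len(n_steps)]),
               n = n_steps)
  }))
  # enforce monotonicity before spline inversion (MC noise can produce
  # tiny local decreases on a fine grid)
  mono <- cummax(tab$mean_cos)
  fun <- stats::splinefun(tab$kappa, mono, method = "hyman")
  structure(list(table = tab, fun = fun,
                 range = range(tab$kappa),
                 mean_cos_range = range(mono)),
            class = "kappa_calibration")
}

#' Estimate kappa from observed step angles
#'
#' Inverts a [calibrate_kappa()] curve at the observed mean `cos(theta)`.
#' Observations outside the calibrated range are clamped to the grid
#' boundary.
#'
#' @param samples numeric angles in degrees, a step-angle table with a
#'   `theta_deg` column, or a single precomputed mean cos(theta) given as
#'   `mean_cos`.
#' @param calibration a `"kappa_calibration"`.
#' @param mean_cos optional: supply the summary statistic directly.
#' @return The estimated kappa (numeric scalar).
#' @export
estimate_kappa <- function(samples = NULL, calibration, mean_cos = NULL) {
  stopifnot(inherits(calibration, "kappa_calibration"))
  if (is.null(mean_cos)) {
    theta <- if (is.data.frame(samples)) samples$theta_deg else
      as.numeric(samples)
    if (!length(theta)) stop("no angle samples")
    mean_cos <- mean(cos(theta * pi / 180))
  }
  lo <- calibration$range[1]
  hi <- calibration$range[2]
  if (mean_cos <= calibration$fun(lo)) return(lo)
  if (mean_cos >= calibration$fun(hi)) return(hi)
  stats::uniroot(function(k) calibration$fun(k) - mean_cos,
                 lower = lo, upper = hi, tol = 1e-6)$root
}

#' @export
print.kappa_calibration <- function(x, ...) {
  cat(sprintf("<kappa_calibration> %d grid points, kappa in [%g, %g], mean cos(theta) in [%.3f, %.3f]\n",
              nrow(x$table), x$range[1], x$range[2],
              x$mean_cos_range[1], x$mean_cos_range[2]))
  invisible(x)
}
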