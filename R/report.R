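#' First-encounter times for a batch of isolated pairs
#'
#' Simulates `n_pairs` independent isolated pairs under one sensing scenario
#' and returns each pair's time to first polarity-site encounter; pairs with
#' no encounter are right-censored at the movie end.
#'
#' @param config a [sim_config()].
#' @param n_pairs number of independent pairs.
#' @param sensing_a,sensing_alpha sensing flags of the two partners.
#' @param seed_base seeds used are `seed_base + 1 .. seed_base + n_pairs`.
#' @return data.frame `pair, time_min, censored, outcome`.
#' @export
pair_encounter_times <- function(config, n_pairs = 20, sensing_a = TRUE,
                                 sensing_alpha = TRUE, seed_base = 1000L) {
  ar <- arena_pair(radius = config$cell_radius, sensing_a = sensing_a,
                   sensing_alpha = sensing_alpha)
  do.call(rbind, lapply(seq_len(n_pairs), function(i) {
    cfg <- update_config(config,
                         seed = (seed_base + i) %% .Machine$integer.max)
    gt <- simulate_walks(cfg, ar)
    ev <- gt$events
    if (nrow(ev) == 0) {
      data.frame(pair = i,
                 time_min = (cfg$n_frames - 1) * cfg$frame_interval,
                 censored = TRUE, outcome = NA_character_)
    } else {
      first <- ev[which.min(ev$start_frame), ]
      data.frame(pair = i, time_min = first$time_to_encounter_min,
                 censored = FALSE, outcome = first$outcome)
    }
  }))
}

#' End-to-end synthetic study report
#'
#' Runs the package's standard in-silico experiments and gathers the
#' statistics that summarize them:
#'
#' * **Direction bias** — step angles theta from bilateral wild-type pairs,
#'   gated at 4 um, split by mating type, with a two-sample KS comparison of
#'   the MATa and MATalpha distributions (expected NS: both pheromones carry
#'   the same information in the generator).
#' * **Encounter timing by scenario** — time-to-first-encounter
#'   distributions for bilateral, the two unilateral (only one mating type
#'   sensing) and the non-sensing scenario, plus the KS comparison of the
#'   two unilateral variants.
#' * **Signaling-dead analogues** — three independent non-sensing batches
#'   (receptorless, Galpha-null and Far1-pathway-broken analogues are all
#'   kappa = 0 in the model) compared pairwise by KS.
#' * **Partner-count strata** — encounter times and commitment /
#'   kiss-and-run fractions for cells touching 1, 2 or 3 partners.
#'
#' With `out_dir` set, ECDF figures, a polar histogram and a JSON summary
#' (including the seed and a config hash) are written. No multiple-testing
#' correction is applied to the KS p-values; they are reported raw.
#'
#' @param seed integer master seed; every simulation seed derives from it.
#' @param out_dir optional output directory for figures and JSON.
#' @param config base [sim_config()].
#' @param n_pairs pairs per batch.
#' @param n_frames_angles movie length for the direction-bias experiment.
#' @param strata_reps arenas per partner-count stratum.
#' @return A list with elements `angles`, `ks_mating_types`, `scenarios`,
#'   `ks_unilateral`, `ks_dead_trio`, `strata`, `summary` (invisible).
#' @export
run_report <- function(seed = 1, out_dir = NULL, config = sim_config(),
                       n_pairs = 15, n_frames_angles = 100,
                       strata_reps = 12) {
  seed <- as.integer(seed)
  base <- function(k) (abs(seed) * 101L + k * 10007L) %% 2000000000L

  # --- direction bias, bilateral wild type
  ang <- do.call(rbind, lapply(seq_len(n_pairs), function(i) {
    cfg <- update_config(config, n_frames = n_frames_angles,
                         commitment_enabled = FALSE,
                         seed = base(1L) + i)
    truth_step_angles(simulate_walks(cfg, arena_pair(
      radius = config$cell_radius)), gate_um = Inf)
  }))
  ang <- gate_by_distance(ang, 4)
  th_a <- ang$theta_deg[ang$mating_type == "a"]
  th_al <- ang$theta_deg[ang$mating_type == "alpha"]
  ks_types <- ks_two_sample(th_a, th_al)

  # --- encounter timing by sensing scenario
  scen_flags <- list(bilateral = c(TRUE, TRUE),
                     unilateral_a = c(TRUE, FALSE),
                     unilateral_alpha = c(FALSE, TRUE),
                     no_sensing = c(FALSE, FALSE))
  scenarios <- lapply(seq_along(scen_flags), function(k) {
    fl <- scen_flags[[k]]
    pair_encounter_times(config, n_pairs, fl[1], fl[2],
                         seed_base = base(10L + k))
  })
  names(scenarios) <- names(scen_flags)
  ks_uni <- ks_two_sample(scenarios$unilateral_a$time_min,
                          scenarios$unilateral_alpha$time_min)

  # --- three signaling-dead analogues (identical generating law)
  dead <- lapply(1:3, function(k) {
    pair_encounter_times(config, n_pairs, FALSE, FALSE,
                         seed_base = base(20L + k))
  })
  names(dead) <- c("receptorless", "gpa1", "cdc24m1")
  ks_dead <- list(
    receptorless_vs_gpa1 = ks_two_sample(dead[[1]]$time_min,
                                         dead[[2]]$time_min),
    receptorless_vs_cdc24m1 = ks_two_sample(dead[[1]]$time_min,
                                            dead[[3]]$time_min),
    gpa1_vs_cdc24m1 = ks_two_sample(dead[[2]]$time_min,
                                    dead[[3]]$time_min))

  # --- partner-count strata
  strata_raw <- do.call(rbind, lapply(1:3, function(np) {
    do.call(rbind, lapply(seq_len(strata_reps), function(i) {
      cfg <- update_config(config, seed = base(30L + np) + i)
      gt <- simulate_walks(cfg, arena_star(np,
                                           radius = config$cell_radius))
      st <- stratify_times(gt$events, gt$arena, cfg$n_frames,
                           cfg$frame_interval, cfg$contact_eps)
      focal <- st$times[st$times$cell_id == 1L, ]
      focal$arena_rep <- i
      focal
    }))
  }))
  strata_frac <- do.call(rbind, lapply(unique(strata_raw$stratum),
                                       function(s) {
    oc <- strata_raw$outcome[strata_raw$stratum == s &
                               !strata_raw$censored]
    data.frame(stratum = s, n_events = length(oc),
               commitment = if (length(oc)) mean(oc == "commitment")
               else NA_real_,
               kiss_and_run = if (length(oc)) mean(oc == "kiss-and-run")
               else NA_real_)
  }))

  summary <- list(
    seed = seed,
    config_hash = rlang::hash(unclass(config)),
    n_theta_steps = nrow(ang),
    median_theta_deg = stats::median(ang$theta_deg),
    median_theta_deg_by_type = c(a = stats::median(th_a),
                                 alpha = stats::median(th_al)),
    ks_mating_types = list(D = ks_types$D, p = ks_types$p),
    median_time_min = vapply(scenarios, function(s)
      stats::median(s$time_min), numeric(1)),
    censored_pairs = vapply(scenarios, function(s) sum(s$censored),
                            numeric(1)),
    ks_unilateral = list(D = ks_uni$D, p = ks_uni$p),
    ks_dead_trio_p = vapply(ks_dead, function(k) k$p, numeric(1)),
    strata_outcomes = strata_frac)

  result <- list(angles = ang, ks_mating_types = ks_types,
                 scenarios = scenarios, ks_unilateral = ks_uni,
                 ks_dead_trio = ks_dead, strata = list(
                   times = strata_raw, outcome_fractions = strata_frac),
                 summary = summary)
  if (!is.null(out_dir)) write_report_files(result, out_dir)
  invisible(result)
}

write_report_files <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ang <- result$angles

  p1 <- ggplot2::ggplot(ang, ggplot2::aes(.data$theta_deg,
                                          color = .data$mating_type)) +
    ggplot2::stat_ecdf(linewidth = 0.8) +
    ggplot2::labs(x = expression(theta ~ "(degrees)"),
                  y = "cumulative fraction",
                  color = "mating type",
                  title = "Direction of polarity-site movement (sites within 4 µm)") +
    ggplot2::coord_cartesian(xlim = c(0, 180)) +
    ggplot2::theme_classic()
  ggplot2::ggsave(file.path(out_dir, "theta_ecdf.png"), p1,
                  width = 5, height = 4, dpi = 150)

  pol <- angle_summaries(ang)$polar
  pol$mid <- (pol$bin_start + pol$bin_end) / 2
  p2 <- ggplot2::ggplot(pol, ggplot2::aes(.data$mid, .data$count)) +
    ggplot2::geom_col(width = 15, fill = "grey40") +
    ggplot2::coord_polar(start = -pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = seq(0, 180, 45)) +
    ggplot2::labs(x = expression(theta), y = "steps",
                  title = "Polar histogram of step angles") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(file.path(out_dir, "theta_polar.png"), p2,
                  width = 4.5, height = 4.5, dpi = 150)

  times <- do.call(rbind, lapply(names(result$scenarios), function(nm) {
    s <- result$scenarios[[nm]]
    s$scenario <- nm
    s
  }))
  p3 <- ggplot2::ggplot(times, ggplot2::aes(.data$time_min,
                                            color = .data$scenario)) +
    ggplot2::stat_ecdf(linewidth = 0.8) +
    ggplot2::labs(x = "time to polarity-site encounter (min)",
                  y = "cumulative fraction", color = "scenario") +
    ggplot2::theme_classic()
  ggplot2::ggsave(file.path(out_dir, "encounter_times_ecdf.png"), p3,
                  width = 5.5, height = 4, dpi = 150)

  jsonlite::write_json(result$summary,
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(out_dir)
}
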