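test_that("tangent plane fitting handles planar, spherical and degenerate cases", {
  # three points in the z = 0 plane: normal is +/- z
  pl <- fit_tangent_plane(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  expect_equal(abs(pl$normal), c(0, 0, 1), tolerance = 1e-12)
  expect_false(pl$fallback)

  # with the cell center below, orientation is outward (+z)
  pl2 <- fit_tangent_plane(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0),
                           cell_center = c(0.5, 0.5, -3))
  expect_equal(pl2$normal, c(0, 0, 1), tolerance = 1e-12)

  # points sampled on a sphere near a pole: normal within 5 degrees of radial
  ctr <- c(1, -2, 0.5)
  R <- 2.5
  p_of <- function(th, ph) ctr + R * c(sin(th) * cos(ph), sin(th) * sin(ph),
                                       cos(th))
  pl3 <- fit_tangent_plane(p_of(0.05, 0.3), p_of(0.06, 1.8),
                           p_of(0.045, 3.6), cell_center = ctr)
  radial <- (pl3$anchor - ctr) / R
  ang <- acos(min(1, sum(pl3$normal * radial))) * 180 / pi
  expect_lt(ang, 5)

  # collinear points: radial fallback, flagged
  pl4 <- fit_tangent_plane(c(0, 0, 1), c(0, 0, 2), c(0, 0, 3),
                           cell_center = c(0, -2, 2))
  expect_true(pl4$fallback)
  expect_equal(pl4$normal, c(0, 1, 0), tolerance = 1e-12)

  # coincident points: degenerate
  expect_null(fit_tangent_plane(c(1, 1, 1), c(1, 1, 1), c(1, 1, 1)))
})

test_that("optimal direction is the in-plane unit vector to the projected partner", {
  pl <- list(anchor = c(0, 0, 0), normal = c(0, 0, 1), fallback = FALSE)
  # partner already in the plane
  expect_equal(optimal_direction(pl, c(3, 4, 0)), c(0.6, 0.8, 0))
  # partner displaced purely along the normal: undefined
  expect_null(optimal_direction(pl, c(0, 0, 7)))
  # random configurations match the explicit projection oracle
  set.seed(12)
  for (i in 1:25) {
    a <- stats::rnorm(3)
    n <- rand_unit()
    s <- stats::rnorm(3, sd = 3)
    pl <- list(anchor = a, normal = n, fallback = FALSE)
    opt <- optimal_direction(pl, s)
    q <- s - sum((s - a) * n) * n     # independent projection formula
    if (is.null(opt)) {
      expect_lt(sqrt(sum((q - a)^2)), 1e-9)
    } else {
      expect_equal(opt, (q - a) / sqrt(sum((q - a)^2)), tolerance = 1e-12)
    }
  }
})

test_that("step angles hit the defining special cases", {
  pl <- list(anchor = c(0, 0, 0), normal = c(0, 0, 1), fallback = FALSE)
  opt <- c(1, 0, 0)
  expect_equal(step_angle(pl, opt, c(0, 0, 0), c(2, 0, 0))$theta_deg, 0)
  expect_equal(step_angle(pl, opt, c(0, 0, 0), c(-2, 0, 0))$theta_deg, 180)
  expect_equal(step_angle(pl, opt, c(0, 0, 0), c(0, 3, 0))$theta_deg, 90)
  # zero-length in-plane step is skipped
  expect_null(step_angle(pl, opt, c(0, 0, 0), c(0, 0, 5)))
})

test_that("theta is invariant under global rotation and translation", {
  set.seed(13)
  for (i in 1:10) {
    ctr <- stats::rnorm(3)
    p_of <- function() ctr + 2.5 * rand_unit()
    p_prev <- p_of(); p_cur <- p_of(); p_next <- p_of(); partner <- p_of() + c(5, 0, 0)
    pl <- fit_tangent_plane(p_prev, p_cur, p_next, ctr)
    th <- step_angle(pl, optimal_direction(pl, partner), p_cur,
                     p_next)$theta_deg
    R <- rotation_matrix(rand_unit(), stats::runif(1, 0, 2 * pi))
    tr <- stats::rnorm(3, sd = 10)
    mv <- function(p) as.numeric(R %*% p) + tr
    pl2 <- fit_tangent_plane(mv(p_prev), mv(p_cur), mv(p_next), mv(ctr))
    th2 <- step_angle(pl2, optimal_direction(pl2, mv(partner)), mv(p_cur),
                      mv(p_next))$theta_deg
    expect_equal(th2, th, tolerance = 1e-8)
  }
})

test_that("no step angle is taken at or after the first encounter", {
  # two gently curved tracks that meet at frame 6 and separate again
  xs_a <- c(0, 1, 2, 3, 4, 4.8, 4, 3, 2)
  ys_a <- 0.05 * sin(1:9)  # curvature so triplets are never collinear
  xs_b <- rep(5, 9)
  ys_b <- 0.2 + 0.05 * cos(1:9)
  tracks <- rbind(
    data.frame(frame = 1:9, cell_id = 1L, x_um = xs_a, y_um = ys_a,
               z_um = 0.3),
    data.frame(frame = 1:9, cell_id = 2L, x_um = xs_b, y_um = ys_b,
               z_um = 0.05 * sin(2 * (1:9))))
  pairs <- data.frame(id_a = 1L, id_b = 2L)
  ang <- compute_step_angles(tracks, pairs, truncate_at_encounter = TRUE,
                             encounter_um = 1)
  expect_true(all(ang$t0 < 6))
  ang_all <- compute_step_angles(tracks, pairs,
                                 truncate_at_encounter = FALSE)
  expect_gt(max(ang_all$t0), 6)
})

test_that("excluded frames bridge to the nearest retained neighbors", {
  set.seed(14)
  gt <- simulate_walks(tiny_config(n_frames = 12, kappa = 0,
                                   commitment_enabled = FALSE),
                       arena_pair())
  tr <- truth_tracks(gt)
  # drop cell 1's frame 5: steps bridging it span 2 frames
  tr2 <- tr[!(tr$cell_id == 1 & tr$frame == 5), ]
  ang <- compute_step_angles(tr2, gt$pairs,
                             truncate_at_encounter = FALSE)
  a1 <- ang[ang$cell_id == 1, ]
  expect_false(5 %in% a1$t0)
  expect_true(any(a1$dt_frames == 2))
})

test_that("distance gating filters exactly by the threshold", {
  df <- data.frame(t0 = 1:6, cell_id = 1, partner_id = 2,
                   theta_deg = 10 * (1:6),
                   dist_um = c(5, 3.9, 4.0, 4.1, 0.5, 7),
                   step_um = 1, dt_frames = 1)
  expect_equal(gate_by_distance(df, 4)$t0, c(2, 3, 5))
  expect_equal(nrow(gate_by_distance(df, Inf)), 6)
  expect_equal(nrow(gate_by_distance(df[df$dist_um >= 5, ], 4)), 0)
  # brute-force linear scan
  keep <- df$dist_um <= 2.5
  expect_equal(gate_by_distance(df, 2.5)$t0, df$t0[keep])
})

test_that("angle summaries produce a valid ECDF and 15-degree polar bins", {
  s <- angle_summaries(c(0))
  expect_equal(s$polar$count[1], 1)
  expect_equal(ecdf_eval(s$ecdf, 0), 1)

  th <- c(0, 30, 30, 100, 179.5, 180)
  s2 <- angle_summaries(th)
  expect_equal(sum(s2$polar$count), length(th))
  expect_equal(s2$polar$count[s2$polar$bin_start == 30], 2)
  # the closed last bin catches 180 exactly
  expect_equal(s2$polar$count[s2$polar$bin_start == 165], 2)
  expect_error(angle_summaries(numeric(0)), "no angle")
})
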