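test_that("simulation is deterministic and stays on the sphere", {
  cfg <- tiny_config(n_frames = 40)
  ar <- arena_pair()
  gt1 <- simulate_walks(cfg, ar)
  gt2 <- simulate_walks(cfg, ar)
  expect_identical(gt1$positions, gt2$positions)
  expect_identical(gt1$events, gt2$events)

  for (cid in ar$cell_id) {
    p <- gt1$positions[gt1$positions$cell_id == cid, ]
    ctr <- as.numeric(ar[ar$cell_id == cid, c("x", "y", "z")])
    r <- sqrt(rowSums(sweep(as.matrix(p[, c("x_um", "y_um", "z_um")]),
                            2, ctr)^2))
    expect_lt(max(abs(r - 2.5)), 1e-9 * 2.5)
  }
})

test_that("an unbiased non-persistent walk is directionally isotropic", {
  # theta measured against the partner direction should be uniform on
  # [0, 180] when kappa = 0 and persistence = 0 (distributional check)
  th <- numeric(0)
  for (s in 1:8) {
    cfg <- sim_config(n_frames = 60, seed = 400 + s, kappa = 0,
                      persistence = 0, commitment_enabled = FALSE)
    gt <- simulate_walks(cfg, arena_pair())
    a <- truth_step_angles(gt, gate_um = 4, truncate_at_encounter = FALSE)
    th <- c(th, a$theta_deg)
  }
  expect_gt(length(th), 100)
  p <- suppressWarnings(stats::ks.test(th, "punif", 0, 180)$p.value)
  expect_gt(p, 0.01)
})

test_that("a dominant bias drives theta toward zero", {
  cfg <- sim_config(n_frames = 80, seed = 17, kappa = 50,
                    commitment_enabled = FALSE)
  gt <- simulate_walks(cfg, arena_pair())
  a <- truth_step_angles(gt, gate_um = Inf, truncate_at_encounter = FALSE)
  expect_lt(stats::median(a$theta_deg), 15)
})

test_that("commitment freezes both sites once they are close", {
  cfg <- sim_config(n_frames = 100, seed = 23, kappa = 2,
                    commitment_enabled = TRUE)
  gt <- simulate_walks(cfg, arena_pair())
  sf <- gt$stopped$stop_frame
  expect_true(all(!is.na(sf)))  # kappa = 2 pairs commit within 100 frames
  for (cid in 1:2) {
    p <- gt$positions[gt$positions$cell_id == cid, ]
    after <- p[p$frame >= sf[cid], c("x_um", "y_um", "z_um")]
    expect_lt(max(dist(as.matrix(after))), 1e-12)
  }
  # distance at and after the stop frame is below the commitment trigger
  d <- gt$distances
  expect_lt(d$dist_um[d$frame == max(sf)], cfg$commitment_distance)
  # the final event is labeled commitment and runs to the movie end
  last <- gt$events[nrow(gt$events), ]
  expect_equal(last$outcome, "commitment")
  expect_equal(last$end_frame, cfg$n_frames)
})

test_that("per-cell RNG substreams: adding a cell leaves others unchanged", {
  # with kappa = 0 trajectories depend only on each cell's own stream
  cfg <- tiny_config(n_frames = 30, kappa = 0, commitment_enabled = FALSE)
  two <- simulate_walks(cfg, arena_chain(c("a", "alpha")))
  three <- simulate_walks(cfg, arena_chain(c("a", "alpha", "a")))
  for (cid in 1:2) {
    expect_equal(
      two$positions[two$positions$cell_id == cid,
                    c("x_um", "y_um", "z_um")],
      three$positions[three$positions$cell_id == cid,
                      c("x_um", "y_um", "z_um")],
      ignore_attr = TRUE)
  }
})

test_that("bias with no partner present is silently zero", {
  # a lone sensing cell with kappa > 0 must walk like an unbiased one
  lone <- arena(data.frame(cell_id = 1L, mating_type = "a", x = 0, y = 0,
                           z = 0, radius = 2.5, sensing = TRUE))
  cfg <- tiny_config(kappa = 5, commitment_enabled = FALSE)
  cfg0 <- tiny_config(kappa = 0, commitment_enabled = FALSE)
  expect_identical(simulate_walks(cfg, lone)$positions,
                   simulate_walks(cfg0, lone)$positions)
})

test_that("ground truth round-trips through CSV/JSON files", {
  # kappa = 2 over 60 frames guarantees at least one encounter event
  gt <- simulate_walks(tiny_config(n_frames = 60, kappa = 2),
                       arena_pair())
  expect_gt(nrow(gt$events), 0)
  stem <- file.path(tempdir(), "gt_test")
  paths <- write_ground_truth(gt, stem)
  pos <- utils::read.csv(paths[["positions"]])
  expect_equal(nrow(pos), nrow(gt$positions))
  expect_equal(pos$x_um, gt$positions$x_um, tolerance = 1e-9)
  ev <- jsonlite::read_json(paths[["events"]], simplifyVector = TRUE)
  expect_equal(nrow(ev), nrow(gt$events))
})
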