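test_that("maximum projection behaves on trivial stacks", {
  A <- array(0, dim = c(6, 6, 1))
  A[3, 4, 1] <- 7
  expect_equal(max_project(A), A[, , 1])
  B <- array(0, dim = c(6, 6, 4))
  B[2, 2, 3] <- 9  # present in a single plane only
  expect_equal(max_project(B)[2, 2], 9)
  expect_error(max_project(matrix(0, 2, 2)), "3D")
})

test_that("line scans average across the width and locate rendered peaks", {
  px <- 0.16
  # uniform image: flat profile
  img <- matrix(3, 60, 60)
  prof <- line_scan(img, c(1, 1), c(8, 8), width_px = 10, pixel_size = px)
  expect_true(all(abs(prof$intensity - 3) < 1e-12))
  expect_true(all(diff(prof$pos_um) > 0))

  # Gaussian spot: profile max at the spot's abscissa within one pixel
  xc <- (seq_len(60) - 0.5) * px
  spot <- outer(dnorm(xc, 4.0, 0.3), dnorm(xc, 3.0, 0.3))
  prof2 <- line_scan(spot, c(1, 3.0), c(8, 3.0), width_px = 10,
                     pixel_size = px)
  expect_lt(abs(prof2$pos_um[which.max(prof2$intensity)] - (4.0 - 1)), px)

  # width 1 and width 10 agree on a symmetric spot's peak position
  prof1 <- line_scan(spot, c(1, 3.0), c(8, 3.0), width_px = 1,
                     pixel_size = px)
  expect_equal(prof1$pos_um[which.max(prof1$intensity)],
               prof2$pos_um[which.max(prof2$intensity)])

  expect_error(line_scan(img, c(1, 1), c(1, 1), pixel_size = px),
               "coincide")
})

test_that("peak distance measures two-spot separations and flags merges", {
  pos <- seq(0, 8, by = 0.1)
  two <- data.frame(pos_um = pos,
                    intensity = dnorm(pos, 2.5, 0.3) + dnorm(pos, 5.5, 0.3))
  pd <- peak_distance(two)
  expect_false(pd$merged)
  expect_equal(pd$distance_um, 3, tolerance = 0.1)

  close <- data.frame(pos_um = pos,
                      intensity = dnorm(pos, 3.6, 0.25) +
                        dnorm(pos, 4.4, 0.25))
  pdc <- peak_distance(close)
  expect_false(pdc$merged)
  expect_lt(pdc$distance_um, 1)   # 0.8 um apart: qualifies as an encounter

  merged <- data.frame(pos_um = pos, intensity = dnorm(pos, 4, 0.5))
  pdm <- peak_distance(merged)
  expect_true(pdm$merged)
  expect_equal(pdm$distance_um, 0)

  flat <- data.frame(pos_um = pos, intensity = rep(1, length(pos)))
  expect_true(is.na(peak_distance(flat)$distance_um))
})

test_that("encounters are exactly the maximal sub-threshold runs", {
  d <- data.frame(frame = 1:12,
                  dist_um = c(3, 2, 0.8, 0.9, 0.7, 1.5, 2, 0.99, 1.2,
                              0.5, 0.4, 0.3))
  ev <- detect_encounters(d, threshold = 1, frame_interval = 2)
  expect_equal(nrow(ev), 3)
  expect_equal(ev$start_frame, c(3, 8, 10))
  expect_equal(ev$end_frame, c(5, 8, 12))
  expect_equal(ev$time_to_encounter_min, c(4, 14, 18))
  expect_equal(ev$min_dist_um, c(0.7, 0.99, 0.3))
  # no sub-threshold frames: no events
  far <- data.frame(frame = 1:5, dist_um = rep(2, 5))
  expect_equal(nrow(detect_encounters(far)), 0)

  # random binary series match a linear-scan oracle
  set.seed(41)
  for (i in 1:20) {
    dd <- data.frame(frame = 1:30, dist_um = stats::runif(30, 0, 2))
    ev2 <- detect_encounters(dd)
    runs <- oracle_runs(dd$dist_um < 1)
    if (is.null(runs)) {
      expect_equal(nrow(ev2), 0)
    } else {
      expect_equal(ev2$start_frame, unname(runs[, "start"]))
      expect_equal(ev2$end_frame, unname(runs[, "end"]))
    }
  }
})

test_that("outcome classification follows the persistence rule", {
  mk <- function(s, e) data.frame(start_frame = s, end_frame = e)
  # below threshold through the movie end: commitment
  expect_equal(classify_outcome(mk(10, 60), n_frames = 60), "commitment")
  # a single-frame dip: kiss-and-run
  expect_equal(classify_outcome(mk(10, 10), n_frames = 60), "kiss-and-run")
  # K consecutive frames even if it later separates: commitment
  expect_equal(classify_outcome(mk(10, 14), n_frames = 60, K = 5),
               "commitment")
  expect_equal(classify_outcome(mk(10, 13), n_frames = 60, K = 5),
               "kiss-and-run")
  # event starting on the final frame is censored
  expect_equal(classify_outcome(mk(60, 60), n_frames = 60), "censored")
})

test_that("stratification groups by partner count and reports censoring", {
  st <- arena_star(2)
  # both pairs encounter at frame 11 (-> 20 min at 2 min/frame)
  ev <- data.frame(id_a = c(1L, 1L), id_b = c(2L, 3L),
                   start_frame = 11L, end_frame = 12L,
                   outcome = "kiss-and-run")
  out <- stratify_times(ev, st, n_frames = 30, frame_interval = 2)
  focal <- out$times[out$times$cell_id == 1, ]
  expect_equal(focal$stratum, "2")
  expect_equal(focal$time_min, 20)
  partners <- out$times[out$times$cell_id != 1, ]
  expect_true(all(partners$stratum == "1"))
  # no events at all: everything censored at the movie end
  out0 <- stratify_times(ev[0, ], st, n_frames = 30, frame_interval = 2)
  expect_true(all(out0$times$censored))
  expect_true(all(out0$times$time_min == 58))
  expect_true(all(out0$outcome_fractions$n_events == 0))
})

test_that("line-scan and centroid encounter calls agree on clean renders", {
  # two rendered spots at a known separation: the max-projection line scan
  # must report the same distance as the 3D centroid difference
  cfg <- sim_config()
  voxel <- c(cfg$pixel_size_xy, cfg$pixel_size_xy, cfg$z_step)
  for (sep in c(3, 2, 1.5)) {
    A <- array(0, dim = c(80, 50, 15))
    p1 <- c(3, 3.5, 3.6)
    p2 <- p1 + c(sep, 0, 0)
    A <- pherotrack:::add_spot(A, c(0, 0, 0), voxel, p1, 0.25, 0.5, 2000)
    A <- pherotrack:::add_spot(A, c(0, 0, 0), voxel, p2, 0.25, 0.5, 2000)
    mp <- max_project(A)
    prof <- line_scan(mp, p1[1:2] - c(1, 0), p2[1:2] + c(1, 0),
                      width_px = 10, pixel_size = cfg$pixel_size_xy)
    pd <- peak_distance(prof)
    expect_equal(pd$distance_um, sep, tolerance = 0.1)
  }
})
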