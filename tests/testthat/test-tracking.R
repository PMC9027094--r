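test_that("detect_sites finds thresholded components with weighted centroids", {
  voxel <- c(0.16, 0.16, 0.48)
  origin <- c(0, 0, 0)
  A <- array(0, dim = c(20, 20, 8))

  # single bright voxel (min_voxels = 1): centroid at that voxel's center
  A[5, 7, 3] <- 100
  cand <- detect_sites(A, voxel, origin, min_voxels = 1)
  expect_equal(nrow(cand), 1)
  expect_equal(c(cand$x_um, cand$y_um, cand$z_um),
               c((5 - 0.5) * 0.16, (7 - 0.5) * 0.16, (3 - 0.5) * 0.48))

  # two well-separated spots give two candidates, brightest first
  A[15, 15, 6] <- 80
  A[15, 16, 6] <- 80
  cand2 <- detect_sites(A, voxel, origin, min_voxels = 1)
  expect_equal(nrow(cand2), 2)
  expect_equal(cand2$intensity[1], 160)

  # all-zero stack: no candidates, not an error
  expect_equal(nrow(detect_sites(array(0, dim = c(4, 4, 2)), voxel,
                                 origin)), 0)
  # empty roi is an error
  expect_error(detect_sites(A, voxel, origin,
                            roi = list(x = c(5, 4), y = c(1, 2),
                                       z = c(1, 2))), "empty")
})

test_that("a rendered Gaussian spot is located to sub-voxel accuracy", {
  cfg <- sim_config()
  voxel <- c(cfg$pixel_size_xy, cfg$pixel_size_xy, cfg$z_step)
  origin <- c(0, 0, 0)
  A <- array(0, dim = c(40, 40, 15))
  # place the spot off voxel centers
  p <- c(3.13, 3.41, 3.77)
  A <- pherotrack:::add_spot(A, origin, voxel, p, cfg$spot_sigma_xy,
                             cfg$spot_sigma_z, 2000)
  cand <- detect_sites(A, voxel, origin)
  expect_equal(nrow(cand), 1)
  err <- abs(c(cand$x_um, cand$y_um, cand$z_um) - p)
  expect_true(all(err < 0.1 * voxel))
})

test_that("raising the threshold never grows a component", {
  set.seed(71)
  A <- array(stats::runif(16 * 16 * 6), dim = c(16, 16, 6))
  voxel <- c(0.16, 0.16, 0.48)
  sizes <- vapply(c(0.3, 0.5, 0.7, 0.9), function(f) {
    cand <- detect_sites(A, voxel, c(0, 0, 0), threshold_frac = f,
                         min_voxels = 1)
    sum(cand$n_voxels)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("drift correction cancels injected displacement exactly", {
  frames <- 1:6
  truth <- data.frame(frame = frames, x_um = 2, y_um = 3, z_um = 1)
  drift <- cbind(0.2 * (frames - 1), -0.1 * (frames - 1), 0)
  raw <- truth
  raw$x_um <- raw$x_um + drift[, 1]
  raw$y_um <- raw$y_um + drift[, 2]
  bead <- data.frame(frame = frames, x_um = 5 + drift[, 1],
                     y_um = 5 + drift[, 2], z_um = 0)
  corr <- correct_drift(raw, bead)
  expect_equal(corr$x_um, rep(2, 6))
  expect_equal(corr$y_um, rep(3, 6))
  # zero drift: corrected equals raw
  bead0 <- data.frame(frame = frames, x_um = 5, y_um = 5, z_um = 0)
  corr0 <- correct_drift(truth, bead0)
  expect_equal(corr0$x_um, corr0$x_raw_um)
  # missing bead flags the frame uncorrectable
  corr_na <- correct_drift(truth, bead0[-3, ])
  expect_true(corr_na$excluded[3])
  expect_equal(corr_na$reason[3], "no-bead")
})

test_that("track assembly applies the frame-exclusion rules", {
  one <- data.frame(x_um = 1, y_um = 2, z_um = 3, intensity = 10,
                    n_voxels = 4L)
  none <- one[0, ]
  two <- rbind(one, one)
  tr <- assemble_track(list(`1` = one, `2` = none, `3` = two, `4` = one),
                       cell_id = 7L)
  expect_equal(tr$frame, 1:4)
  expect_equal(tr$excluded, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(tr$reason[2:3], c("none-detected", "multiple-detected"))
  expect_true(all(is.na(tr$x_um[tr$excluded])))
  # all frames single-candidate: full-length track, no exclusions
  tr_ok <- assemble_track(list(`1` = one, `2` = one), cell_id = 1L)
  expect_false(any(tr_ok$excluded))
})

test_that("tracks are truncated where partner signals overlap", {
  mk <- function(xs) data.frame(frame = seq_along(xs), cell_id = 1L,
                                x_um = xs, y_um = 0, z_um = 0,
                                excluded = FALSE)
  ta <- mk(c(0, 0.5, 1.0, 1.2))
  tb <- mk(c(4, 2.0, 1.3, 1.25))
  # distances 4, 1.5, 0.3, 0.05: first merge at frame 3
  cut <- track_until_overlap(ta, tb, merge_dist = 0.5)
  expect_equal(cut$cut_frame, 3)
  expect_equal(max(cut$a$frame), 2)
  # always far apart: no truncation
  cut2 <- track_until_overlap(mk(c(0, 0, 0)), mk(c(5, 5, 5)))
  expect_true(is.na(cut2$cut_frame))
  expect_equal(nrow(cut2$a), 3)
})
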