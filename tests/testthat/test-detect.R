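test_that("a single noise-free spot is localized within half a voxel", {
  acq <- test_acq(n_frames = 1L, noise = FALSE)
  sim <- simulate_movie(schedule = NULL, motion = still_motion(), acq = acq,
                        seed = 31, nucleus_radius = 2.5)
  f <- movie_frame(sim$movie, 0, "dots")
  sp <- detect_spots(f, 0.5)
  expect_equal(nrow(sp), 1)
  tr <- sim$truth$dots[sim$truth$dots$frame == 0, ]
  err <- c(abs(sp$x - tr$x) / 0.125, abs(sp$y - tr$y) / 0.125,
           abs(sp$z - tr$z) / 0.5)
  expect_true(all(err < 0.5))
})

test_that("two spots separated by two diameters are both found", {
  acq <- test_acq(n_frames = 1L, noise = FALSE)
  init <- data.frame(id = c("a", "b"), x = c(-0.6, 0.6), y = c(0, 0),
                     z = c(0, 0), intensity = c(2000, 2000))
  sim <- simulate_movie(schedule = NULL, motion = still_motion(), acq = acq,
                        seed = 31, nucleus_radius = 2.5, initial_dots = init)
  sp <- detect_spots(movie_frame(sim$movie, 0, "dots"), 0.5)
  expect_equal(nrow(sp), 2)
})

test_that("pure-noise frames yield (almost) no detections", {
  # false-positive rate < 1 per frame at the default auto threshold
  set.seed(99)
  n_fp <- 0
  for (i in 1:5) {
    noise <- array(pmax(0, round(rnorm(48 * 48 * 14, 10, 2))),
                   c(48, 48, 14))
    attr(noise, "spacing") <- c(0.125, 0.125, 0.5)
    n_fp <- n_fp + nrow(detect_spots(noise, 0.5))
  }
  expect_lt(n_fp / 5, 1)
})

test_that("detection recall and precision reach 0.95 at SNR >= 5", {
  sim <- three_dot_movie("canonical", seed = 17, noise = TRUE, n_frames = 10L)
  spots <- detect_spots_movie(sim$movie, estimated_xy_diameter = 0.5)
  tp <- fp <- fn <- 0
  for (t in unique(sim$truth$dots$frame)) {
    m <- match_detections(spots[spots$frame == t, ],
                          sim$truth$dots[sim$truth$dots$frame == t, ],
                          tol = 0.5)
    tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
  }
  expect_gte(tp / (tp + fn), 0.95)  # recall
  expect_gte(tp / (tp + fp), 0.95)  # precision
})

test_that("integrated intensity is linear in spot amplitude", {
  acq <- test_acq(n_frames = 1L, noise = FALSE)
  mk <- function(amp) {
    init <- data.frame(id = "a", x = 0.2, y = -0.1, z = 0.15, intensity = amp)
    sim <- simulate_movie(schedule = NULL, motion = still_motion(), acq = acq,
                          seed = 13, nucleus_radius = 2.5,
                          initial_dots = init)
    detect_spots(movie_frame(sim$movie, 0, "dots"), 0.5)$intensity
  }
  i1 <- mk(3000); i2 <- mk(6000)
  expect_lt(abs(i2 / i1 - 2), 0.02)
})

test_that("the detector is translation-equivariant to whole-voxel shifts", {
  acq <- test_acq(n_frames = 1L, noise = FALSE)
  init <- data.frame(id = "a", x = -0.4, y = 0.3, z = -0.25,
                     intensity = 2000)
  sim <- simulate_movie(schedule = NULL, motion = still_motion(), acq = acq,
                        seed = 23, nucleus_radius = 2.5, initial_dots = init)
  f <- movie_frame(sim$movie, 0, "dots")
  shifted <- array(0, dim(f))
  shifted[4:48, , ] <- f[1:45, , ]   # shift +3 voxels along y
  attr(shifted, "spacing") <- attr(f, "spacing")
  s1 <- detect_spots(f, 0.5)
  s2 <- detect_spots(shifted, 0.5)
  expect_equal(s2$y - s1$y, 3 * 0.125, tolerance = 1e-6)
  expect_equal(s2$x, s1$x, tolerance = 1e-6)
  expect_equal(s2$z, s1$z, tolerance = 1e-6)
})

test_that("integrate_intensity sums region voxels and handles background", {
  vol <- array(2, c(10, 10, 6))
  attr(vol, "spacing") <- c(0.1, 0.1, 0.3)
  mask <- array(FALSE, dim(vol)); mask[3:5, 3:5, 2:3] <- TRUE
  expect_equal(integrate_intensity(vol, mask), 2 * sum(mask))
  # background-only region with local background on is ~0
  expect_equal(integrate_intensity(vol, mask, local_background = TRUE), 0)
  expect_error(integrate_intensity(vol, array(FALSE, dim(vol))), "empty")
  expect_error(integrate_intensity(vol, array(TRUE, c(2, 2, 2))),
               "dimensions")
  expect_error(integrate_intensity(vol, list(center = c(99, 0, 0),
                                             radius = 0.2)), "bounds")
})

test_that("measured child intensities after a 0.5 split agree within 5%", {
  acq <- test_acq(n_frames = 6L, frame_interval = 60, noise = FALSE,
                  ny = 64L, nx = 64L)
  sch <- simulate_decluster_schedule("canonical",
    stage_durations = c(0, 0, 120, 1e6, 1e6, 1e6, 1e6))
  sch <- sch[sch$time > 0 & sch$time <= 300, ]
  init <- data.frame(id = c("Aa", "Ab", "XY4"),
                     x = c(-1.8, 1.8, 0), y = c(1.0, -1.0, 1.6),
                     z = c(0.4, -0.4, 0), intensity = c(4, 4, 10) * 1000)
  sim <- simulate_movie(schedule = sch, motion = still_motion(), acq = acq,
                        seed = 41, nucleus_radius = 3.0, initial_dots = init,
                        split_separation = 1.0)
  sp <- detect_spots(movie_frame(sim$movie, 5, "dots"), 0.5)
  tr <- sim$truth$dots[sim$truth$dots$frame == 5, ]
  get_meas <- function(id) {
    i <- which(tr$id == id)
    d <- sqrt((sp$x - tr$x[i])^2 + (sp$y - tr$y[i])^2 + (sp$z - tr$z[i])^2)
    sp$intensity[which.min(d)]
  }
  i1 <- get_meas("Aa1"); i2 <- get_meas("Aa2")
  expect_lt(abs(i1 - i2) / max(i1, i2), 0.05)
})

test_that("degenerate inputs are handled", {
  vol <- array(5, c(12, 12, 6))
  attr(vol, "spacing") <- c(0.125, 0.125, 0.5)
  expect_equal(nrow(detect_spots(vol, 0.5)), 0)     # constant frame
  expect_error(detect_spots(vol, 0.1), "resolvable")
})
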