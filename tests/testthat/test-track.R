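test_that("a single moving dot yields one gap-free track", {
  acq <- test_acq(n_frames = 20L, frame_interval = 5, noise = TRUE)
  mot <- motion_config(mean_speed = 0.03, confinement_radius = 1)
  sim <- simulate_movie(schedule = NULL, motion = mot, acq = acq, seed = 51,
                        nucleus_radius = 2.5)
  spots <- detect_spots_movie(sim$movie, estimated_xy_diameter = 0.5)
  tr <- link_tracks(spots, max_step = 0.6)
  expect_equal(length(unique(tr$track)), 1)
  expect_equal(sort(tr$frame), 0:19)
})

test_that("linking preserves identities of well-separated dots", {
  # five confined dots at the 0.03 um/s regime, 5 s sampling, SNR >= 5
  acq <- test_acq(n_frames = 30L, frame_interval = 5, noise = TRUE,
                  ny = 64L, nx = 64L)
  mot <- motion_config(mean_speed = 0.03, confinement_radius = 0.5)
  init <- data.frame(id = paste0("d", 1:5),
                     x = c(-1.8, 1.8, 0, -1.2, 1.2),
                     y = c(-1.0, -1.0, 1.8, 1.0, 1.0),
                     z = c(0.4, -0.4, 0, -1.2, 1.2),
                     intensity = c(800, 800, 1600, 1200, 2000))
  sim <- simulate_movie(schedule = NULL, motion = mot, acq = acq, seed = 52,
                        nucleus_radius = 2.8, initial_dots = init)
  spots <- detect_spots_movie(sim$movie, estimated_xy_diameter = 0.5)
  tr <- link_tracks(spots, max_step = 0.6)
  # match each track frame to the nearest truth dot; a track is consistent
  # if it always matches the same truth id
  truth <- sim$truth$dots
  n_ok <- 0; n_tot <- 0
  for (id in unique(tr$track)) {
    t1 <- tr[tr$track == id, ]
    hits <- vapply(seq_len(nrow(t1)), function(i) {
      tf <- truth[truth$frame == t1$frame[i], ]
      d <- sqrt((tf$x - t1$x[i])^2 + (tf$y - t1$y[i])^2 +
                  (tf$z - t1$z[i])^2)
      tf$id[which.min(d)]
    }, character(1))
    n_tot <- n_tot + length(hits)
    n_ok <- n_ok + max(table(hits))
  }
  expect_gte(n_ok / n_tot, 0.95)
})

test_that("linking is invariant to spot row order within frames", {
  sim <- three_dot_movie("canonical", seed = 53, noise = TRUE, n_frames = 12L)
  spots <- detect_spots_movie(sim$movie, estimated_xy_diameter = 0.5)
  set.seed(1)
  shuffled <- spots[sample(nrow(spots)), ]
  t1 <- link_tracks(spots, max_step = 0.9)
  t2 <- link_tracks(shuffled, max_step = 0.9)
  rownames(t1) <- rownames(t2) <- NULL
  expect_equal(t1, t2)
})

test_that("empty input and empty frames are handled", {
  empty <- data.frame(frame = integer(), x = numeric(), y = numeric(),
                      z = numeric())
  expect_equal(nrow(link_tracks(empty)), 0)
  # a dot absent beyond max_gap opens a new track
  spots <- data.frame(frame = c(0, 1, 4, 5), x = c(1, 1, 1, 1),
                      y = 1, z = 1, intensity = 10)
  tr <- link_tracks(spots, max_gap = 1L, max_step = 0.5)
  expect_equal(length(unique(tr$track)), 2)
  # within the gap the track is continued
  spots2 <- data.frame(frame = c(0, 1, 3, 4), x = 1, y = 1, z = 1,
                       intensity = 10)
  tr2 <- link_tracks(spots2, max_gap = 1L, max_step = 0.5)
  expect_equal(length(unique(tr2$track)), 1)
})

test_that("injected drift is removed to within 0.1 um", {
  acq <- test_acq(n_frames = 15L, frame_interval = 60, noise = TRUE,
                  ny = 64L, nx = 64L, z_planes = 16L)
  mot <- motion_config(mean_speed = 0, drift_amplitude = 0.08)
  sim <- simulate_movie(schedule = NULL, motion = mot, acq = acq, seed = 54,
                        nucleus_radius = 2.5)
  spots <- detect_spots_movie(sim$movie, estimated_xy_diameter = 0.5)
  tr <- link_tracks(spots, max_step = 0.9)
  seg <- segment_nucleus_movie(sim$movie)
  dc <- correct_drift(tr, seg$table)
  # the dot is static in the nucleus frame: corrected positions constant
  expect_lt(max(abs(dc$tracks$x - mean(dc$tracks$x))), 0.1)
  expect_lt(max(abs(dc$tracks$y - mean(dc$tracks$y))), 0.1)
  expect_lt(max(abs(dc$tracks$z - mean(dc$tracks$z))), 0.1)
  # estimated drift tracks the injected drift
  merged <- merge(dc$drift, sim$truth$drift, by = "frame")
  expect_lt(max(abs(merged$dx.x - merged$dx.y)), 0.1)
  # frame-0 entry is zero by construction
  expect_equal(unlist(dc$drift[dc$drift$frame == 0, c("dx", "dy", "dz")]),
               c(dx = 0, dy = 0, dz = 0))
})

test_that("drift correction preserves pairwise distances", {
  tracks <- structure(data.frame(
    track = rep(1:2, each = 3), frame = rep(0:2, 2),
    x = c(0, 1, 2, 3, 4, 5), y = rep(0, 6), z = rep(0, 6),
    intensity = 1), class = c("tracks", "data.frame"))
  centroids <- data.frame(frame = 0:2, cx = c(0, 0.5, 1), cy = 0, cz = 0)
  dc <- correct_drift(tracks, centroids)
  d_before <- abs(tracks$x[1:3] - tracks$x[4:6])
  d_after <- abs(dc$tracks$x[1:3] - dc$tracks$x[4:6])
  expect_equal(d_after, d_before)
})

test_that("velocities follow the definition speed = step / interval", {
  tr <- data.frame(track = 1L, frame = 0:3, x = c(0, 0.3, 0.6, 0.6),
                   y = 0, z = 0, intensity = 1)
  v <- compute_velocities(tr, frame_interval = 10)
  expect_equal(v$speed, c(0.03, 0.03, 0))
  # halving the interval doubles the speeds
  v2 <- compute_velocities(tr, frame_interval = 5)
  expect_equal(v2$speed, 2 * v$speed)
  # static dot -> all zero; length-1 track -> empty
  expect_equal(compute_velocities(
    data.frame(track = 1L, frame = 0:2, x = 1, y = 1, z = 1), 5)$speed,
    c(0, 0))
  expect_equal(nrow(compute_velocities(
    data.frame(track = 1L, frame = 0L, x = 1, y = 1, z = 1), 5)), 0)
})

test_that("simulated 0.03 um/s mean speed is recovered within 15%", {
  acq <- test_acq(n_frames = 40L, frame_interval = 5, noise = TRUE)
  mot <- motion_config(mean_speed = 0.03, confinement_radius = 1.5)
  sim <- simulate_movie(schedule = NULL, motion = mot, acq = acq, seed = 55,
                        nucleus_radius = 2.5, dot_unit_intensity = 400)
  spots <- detect_spots_movie(sim$movie, estimated_xy_diameter = 0.5)
  tr <- link_tracks(spots, max_step = 0.6)
  seg <- segment_nucleus_movie(sim$movie)
  dc <- correct_drift(tr, seg$table)
  vs <- velocity_summary(dc$tracks, acq$frame_interval)
  expect_lt(abs(vs$mean - 0.03) / 0.03, 0.15)
})

test_that("a 0.5 split is called at the scheduled frame with its fraction", {
  acq <- acquisition_config("custom", n_frames = 12L, ny = 64L, nx = 64L,
                            z_planes = 16L, frame_interval = 300,
                            gaussian_sd = 1, poisson_scale = 1)
  mot <- motion_config(mean_speed = 0.0005, confinement_radius = 0.3)
  sch <- simulate_decluster_schedule("canonical",
    stage_durations = c(0, 0, 1200, 1e6, 1e6, 1e6, 1e6))
  sch <- sch[sch$time > 0 & sch$time < 3000, ]
  init <- data.frame(id = c("Aa", "Ab", "XY4"),
                     x = c(-1.6, 1.6, 0), y = c(0.9, -0.9, 1.4),
                     z = c(0.4, -0.4, 0), intensity = c(4, 4, 10) * 400)
  sim <- simulate_movie(schedule = sch, motion = mot, acq = acq, seed = 56,
                        nucleus_radius = 3.2, initial_dots = init)
  an <- analyze_movie(sim)
  sp <- an$events[an$events$kind == "split", ]
  expect_equal(nrow(sp), 1)
  expect_lte(abs(sp$frame - 4), 1)     # scheduled at t = 1200 s = frame 4
  expect_lt(abs(sp$partition_fraction - 0.5), 0.1)
  expect_false(sp$ambiguous)
})

test_that("movies without events produce no split or fusion calls", {
  acq <- test_acq(n_frames = 10L, frame_interval = 60, noise = TRUE)
  mot <- motion_config(mean_speed = 0.002, confinement_radius = 0.3)
  init <- data.frame(id = c("a", "b"), x = c(-1.2, 1.2), y = c(0.5, -0.5),
                     z = 0, intensity = c(1600, 1600))
  sim <- simulate_movie(schedule = NULL, motion = mot, acq = acq, seed = 57,
                        nucleus_radius = 2.5, initial_dots = init)
  an <- analyze_movie(sim, max_step = 0.6)
  expect_equal(nrow(an$events), 0)
})

test_that("intensity is approximately conserved across called splits", {
  sim <- three_dot_movie("canonical", seed = 58, noise = FALSE)
  an <- analyze_movie(sim)
  sp <- an$events[an$events$kind == "split" & !an$events$ambiguous, ]
  expect_gt(nrow(sp), 0)
  for (i in seq_len(nrow(sp))) {
    tr <- an$tracks
    pre <- tr[tr$track == sp$parent[i] & tr$frame == sp$frame[i] - 1, ]
    c1 <- tr[tr$track == sp$child1[i] & tr$frame == sp$frame[i], ]
    c2 <- tr[tr$track == sp$child2[i] & tr$frame == sp$frame[i], ]
    expect_lt(abs(pre$intensity - (c1$intensity + c2$intensity)) /
                pre$intensity, 0.15)
  }
})

test_that("batch track edits apply deterministically", {
  tr <- data.frame(track = c(1, 1, 2, 2), frame = c(0, 1, 0, 1),
                   x = 1:4, y = 0, z = 0, intensity = 1)
  ed <- data.frame(op = c("delete_spot", "relabel"),
                   track = c(1, 2), frame = c(1, NA), new_track = c(NA, 9))
  out <- apply_track_edits(tr, ed)
  expect_equal(nrow(out), 3)
  expect_true(all(out$track %in% c(1, 9)))
  cut_ed <- data.frame(op = "cut", track = 9, frame = 1, new_track = 10)
  out2 <- apply_track_edits(out, cut_ed)
  expect_equal(sort(unique(out2$track)), c(1, 9, 10))
})
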