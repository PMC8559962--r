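test_that("stage intervals are run-length encoded with censoring flags", {
  iv <- dot_stage_intervals(c(3, 3, 4, 4, 4, 5), frame_interval = 600)
  expect_equal(iv$count, c(3, 4, 5))
  expect_equal(iv$censoring, c("left_censored", "complete", "right_censored"))
  # complete four-dot stage lasts 3 frames x 10 min = 30 min
  expect_equal(iv$duration[iv$count == 4], 3 * 600)
  # durations tile the observation window
  expect_equal(sum(iv$duration), 6 * 600)
})

test_that("transient count dips are bridged by the debounce rule", {
  counts <- c(3, 4, 4, 3, 4, 4, 5)  # one-frame dip at frame 3
  iv <- dot_stage_intervals(counts, frame_interval = 60, debounce = 2L)
  expect_equal(iv$count, c(3, 4, 5))
  expect_equal(iv$duration[iv$count == 4], 5 * 60)
  # debounce 1 keeps the dip
  iv2 <- dot_stage_intervals(counts, frame_interval = 60, debounce = 1L)
  expect_true(3 %in% iv2$count[-1])
})

test_that("a simulated 72-min four-dot stage is timed within one interval", {
  # schedule: 3-dot 30 min, 4-dot 72 min, then 5-dot; 10-min sampling
  acq <- acquisition_config("custom", n_frames = 16L, ny = 64L, nx = 64L,
                            z_planes = 16L, frame_interval = 600,
                            gaussian_sd = 1, poisson_scale = 1)
  mot <- motion_config(mean_speed = 0.0003, confinement_radius = 0.3)
  sch <- simulate_decluster_schedule("canonical",
    stage_durations = c(0, 0, 1800, 4320, 1e6, 1e6, 1e6))
  sch <- sch[sch$time > 0 & sch$time < 1e6, ]
  init <- data.frame(id = c("Aa", "Ab", "XY4"),
                     x = c(-1.6, 1.6, 0), y = c(0.9, -0.9, 1.4),
                     z = c(0.4, -0.4, 0), intensity = c(4, 4, 10) * 400)
  sim <- simulate_movie(schedule = sch, motion = mot, acq = acq, seed = 61,
                        nucleus_radius = 3.2, initial_dots = init)
  spots <- detect_spots_movie(sim$movie, estimated_xy_diameter = 0.5)
  counts <- as.integer(table(factor(spots$frame, levels = 0:15)))
  iv <- dot_stage_intervals(counts, frame_interval = 600)
  est <- iv$duration[iv$count == 4]
  expect_equal(length(est), 1)
  expect_lte(abs(est - 4320), 600)
})

test_that("intensity ratios report strongest/weakest and vs the reference", {
  r <- intensity_ratio_report(c(6, 4, 4, 4))
  expect_equal(r$strongest_weakest, 1.5)
  expect_equal(intensity_ratio_report(c(5, 5, 5))$strongest_weakest, 1)
  r2 <- intensity_ratio_report(c(10, 2, 2), ids = c("XY4", "Aa1", "Aa2"))
  expect_equal(unname(r2$vs_reference["XY4"]), 5)
  expect_error(intensity_ratio_report(c(1, 0)), "zero")
  expect_error(intensity_ratio_report(3))
  # strongest/weakest is always >= 1
  set.seed(2)
  for (i in 1:20)
    expect_gte(intensity_ratio_report(runif(5, 0.1, 9))$strongest_weakest, 1)
})

test_that("pair separation encodes single-spot frames as zero", {
  a <- data.frame(frame = c(0, 1, 2, 4), x = c(0, 0, 0, 0), y = 0, z = 0)
  b <- data.frame(frame = c(0, 2, 3), x = c(3, 4, 5), y = 0, z = 0)
  s <- pair_separation(a, b)
  expect_equal(s$separation[s$frame == 0], 3)   # both present
  expect_equal(s$separation[s$frame == 1], 0)   # only one detected
  expect_equal(s$separation[s$frame == 3], 0)
  expect_equal(s$separation[s$frame == 4], 0)
  # symmetric in its arguments
  s2 <- pair_separation(b, a)
  expect_equal(s$separation, s2$separation)
  # both absent -> missing, not zero
  s3 <- pair_separation(a[a$frame < 2, ], b[b$frame < 1, ],
                        frames = 0:4)
  expect_true(is.na(s3$separation[s3$frame == 3]))
  # identical positions -> 0 (frame 3 absent in both stays missing)
  expect_equal(pair_separation(a, a)$separation, c(0, 0, 0, NA, 0))
})

test_that("stretch episodes are segmented with outcomes", {
  expect_equal(nrow(stretch_episodes(rep(0, 10))), 0)
  # stretch to 2 um and relax
  sep <- c(0, 0, 0.5, 1.2, 1.8, 2.0, 1.5, 0.8, 0, 0)
  ep <- stretch_episodes(sep, min_separation = 1, min_duration = 3)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$outcome, "relaxed")
  expect_equal(ep$max_separation, 2.0)
  # never returns to zero -> definitive split
  sep2 <- c(0, 0.5, 1.2, 1.8, 2.2, 2.5, 2.8, 3.0)
  ep2 <- stretch_episodes(sep2, min_separation = 1, min_duration = 3)
  expect_equal(ep2$outcome, "definitive_split")
  # too-short runs are not episodes
  expect_equal(nrow(stretch_episodes(c(0, 2, 2, 0, 0), min_duration = 3)), 0)
})

test_that("scheduled stretch episodes are recovered exactly (noise off)", {
  acq <- acquisition_config("custom", n_frames = 24L, ny = 64L, nx = 64L,
                            z_planes = 16L, frame_interval = 60,
                            gaussian_sd = 0, poisson_scale = 0)
  eps <- data.frame(start = c(240, 960), end = c(600, 1320),
                    max_separation = 2)
  sch <- simulate_stretch_schedule(eps, dot = "G23")
  init <- data.frame(id = "G23", x = 0, y = 0, z = 0, intensity = 4000)
  sim <- simulate_movie(schedule = sch, motion = still_motion(), acq = acq,
                        mode = "condensinII_mutant", seed = 62,
                        nucleus_radius = 2.8, initial_dots = init)
  # exact recovery from the simulator's true separation series
  truth_sep <- sim$truth$dots[, c("frame", "stretch_separation")]
  names(truth_sep) <- c("frame", "separation")
  ep <- stretch_episodes(truth_sep, min_separation = 1, min_duration = 2)
  expect_equal(nrow(ep), 2)
  expect_true(all(ep$outcome == "relaxed"))
  expect_equal(ep$max_separation, c(2, 2))
  # the detector-based series finds both episodes at their peak (a two-spot
  # call requires the elongation to exceed the axial resolution, so runs
  # are shorter than in the true series)
  spots <- detect_spots_movie(sim$movie, estimated_xy_diameter = 1.0)
  frames <- 0:23
  sep <- vapply(frames, function(t) {
    sf <- spots[spots$frame == t, ]
    sf <- sf[order(-sf$quality), ]
    if (nrow(sf) < 2) return(0)
    sqrt((sf$x[1] - sf$x[2])^2 + (sf$y[1] - sf$y[2])^2 +
           (sf$z[1] - sf$z[2])^2)
  }, numeric(1))
  ep2 <- stretch_episodes(data.frame(frame = frames, separation = sep),
                          min_separation = 1, min_duration = 1)
  expect_equal(nrow(ep2), 2)
  expect_true(all(ep2$outcome == "relaxed"))
  expect_equal(max(ep2$max_separation), 2, tolerance = 0.15)
})

test_that("radial summaries preserve the peripheral/central ordering", {
  acq <- acquisition_config("custom", n_frames = 3L, ny = 96L, nx = 96L,
                            z_planes = 24L, z_spacing = 0.5,
                            gaussian_sd = 0, poisson_scale = 0)
  init <- data.frame(id = c("peri", "cent"), x = c(2.8, 0.3), y = c(0, 0),
                     z = c(0, 0), intensity = c(2000, 2000))
  sim <- simulate_movie(schedule = NULL, motion = still_motion(), acq = acq,
                        seed = 63, nucleus_radius = 3.2, initial_dots = init)
  seg <- segment_nucleus_movie(sim$movie)
  spots <- detect_spots_movie(sim$movie, estimated_xy_diameter = 0.5)
  tr <- link_tracks(spots, max_step = 0.5)
  # identify the peripheral track by x position
  means <- tapply(tr$x, tr$track, mean)
  peri_id <- as.integer(names(which.max(means)))
  rs_peri <- radial_summary(tr[tr$track == peri_id, ], seg$models)
  rs_cent <- radial_summary(tr[tr$track != peri_id, ], seg$models)
  expect_gt(rs_peri$mean, rs_cent$mean)
  expect_equal(rs_peri$n, 3)
  # constant positions give zero spread
  expect_lt(rs_peri$sd, 0.05)
  # track starting after the averaging window warns and returns NA
  late <- data.frame(frame = 12, x = 1, y = 1, z = 1)
  expect_warning(rs <- radial_summary(late, seg$models, n_frames = 3),
                 "does not cover")
  expect_true(is.na(rs$mean))
})

test_that("group comparison is a classical two-tailed t test", {
  g <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(g$t, 0)
  expect_equal(g$p, 1)
  expect_equal(g$stars, "ns")
  expect_error(compare_groups(c(1, 1, 1), c(2, 2, 2)), "zero variance")
  expect_error(compare_groups(1, c(1, 2)))
  # power: groups shifted by 3 SD at n = 20 are highly significant
  set.seed(77)
  detected <- vapply(1:20, function(i) {
    a <- rnorm(20); b <- rnorm(20, 3)
    compare_groups(a, b)$p < 0.001
  }, logical(1))
  expect_gte(mean(detected), 0.95)
  # matches the reference implementation
  set.seed(78)
  a <- rnorm(12); b <- rnorm(12, 0.5)
  g2 <- compare_groups(a, b)
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(g2$t, unname(ref$statistic))
  expect_equal(g2$p, ref$p.value)
})
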