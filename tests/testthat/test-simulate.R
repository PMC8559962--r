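test_that("de-clustering schedules realize the named programs", {
  sch <- simulate_decluster_schedule("canonical", stage_durations = rep(60, 7))
  expect_equal(sch$kind, rep("split", 7))
  expect_equal(sch$parent,
               c("all", "AbXY4", "Aa", "Ab", "XY4", "X44", "chr4"))
  # dot count goes 1..8: k-th event raises the count to k + 1
  expect_equal(sch$time, cumsum(rep(60, 7)))
  v4 <- simulate_decluster_schedule("variant_four_dot",
                                    stage_durations = rep(60, 7))
  expect_equal(which(v4$parent == "XY4"), 4L)  # XY4 release before Ab split
  expect_lt(which(v4$parent == "XY4"), which(v4$parent == "Ab"))
  v3 <- simulate_decluster_schedule("variant_three_dot",
                                    stage_durations = rep(60, 7))
  expect_lt(which(v3$parent == "XY4"), which(v3$parent == "Aa"))
  expect_error(simulate_decluster_schedule("bogus"), "arg")
})

test_that("split partition fractions encode karyotype intensity shares", {
  sch <- simulate_decluster_schedule("canonical", stage_durations = rep(60, 7))
  expect_equal(sch$partition_fraction[sch$parent == "Aa"], 0.5)
  expect_equal(sch$partition_fraction[sch$parent == "XY4"], 0.4)  # Y: 4 of 10
  expect_equal(sch$partition_fraction[sch$parent == "all"], 4 / 18)
})

test_that("noise-free rendering conserves true dot intensity", {
  acq <- test_acq(n_frames = 3L, noise = FALSE, bleach_rate = 0.01)
  sim <- simulate_movie(schedule = NULL, motion = still_motion(), acq = acq,
                        seed = 5, nucleus_radius = 2.5)
  for (t in 0:2) {
    rendered <- sum(movie_frame(sim$movie, t, "dots"))
    truth <- sum(sim$truth$dots$intensity[sim$truth$dots$frame == t])
    expect_lt(abs(rendered - truth) / truth, 0.01)
  }
  # bleaching follows the configured exponential decay
  i0 <- sim$truth$dots$intensity[sim$truth$dots$frame == 0]
  i2 <- sim$truth$dots$intensity[sim$truth$dots$frame == 2]
  expect_equal(i2 / i0, 0.99^2)
})

test_that("ground-truth step lengths average mean_speed * interval", {
  acq <- test_acq(n_frames = 60L, frame_interval = 5, noise = FALSE)
  mot <- motion_config(mean_speed = 0.03, confinement_radius = 10)
  sim <- simulate_movie(schedule = NULL, motion = mot, acq = acq, seed = 2,
                        nucleus_radius = 2.5)
  d <- sim$truth$dots[order(sim$truth$dots$frame), ]
  steps <- sqrt(diff(d$xn)^2 + diff(d$yn)^2 + diff(d$zn)^2)
  expect_lt(abs(mean(steps) - 0.03 * 5) / (0.03 * 5), 0.15)
})

test_that("trajectories respect the confinement radius", {
  acq <- test_acq(n_frames = 40L, frame_interval = 60, noise = FALSE)
  mot <- motion_config(mean_speed = 0.03, confinement_radius = 0.5)
  sim <- simulate_movie(schedule = NULL, motion = mot, acq = acq, seed = 3,
                        nucleus_radius = 2.5)
  d <- sim$truth$dots
  anchor <- c(d$xn[1], d$yn[1], d$zn[1])
  excursion <- sqrt((d$xn - anchor[1])^2 + (d$yn - anchor[2])^2 +
                      (d$zn - anchor[3])^2)
  expect_true(all(excursion <= 0.5 + 1e-9))
})

test_that("re-simulation with the same seed is bit-identical", {
  acq <- test_acq(n_frames = 4L)
  mot <- motion_config(mean_speed = 0.01, drift_amplitude = 0.05)
  s1 <- simulate_movie(schedule = NULL, motion = mot, acq = acq, seed = 7,
                       nucleus_radius = 2.5)
  s2 <- simulate_movie(schedule = NULL, motion = mot, acq = acq, seed = 7,
                       nucleus_radius = 2.5)
  expect_identical(s1$movie$data, s2$movie$data)
  expect_identical(s1$truth$dots, s2$truth$dots)
  s3 <- simulate_movie(schedule = NULL, motion = mot, acq = acq, seed = 8,
                       nucleus_radius = 2.5)
  expect_false(identical(s1$movie$data, s3$movie$data))
})

test_that("splits partition true intensity by the scheduled fraction", {
  acq <- test_acq(n_frames = 6L, frame_interval = 60, noise = FALSE)
  sch <- simulate_decluster_schedule("canonical",
    stage_durations = c(0, 0, 120, 1e6, 1e6, 1e6, 1e6))
  sch <- sch[sch$time > 0 & sch$time <= 300, ]  # only the Aa split
  init <- data.frame(id = c("Aa", "Ab", "XY4"),
                     x = c(-1.4, 1.4, 0), y = c(0.8, -0.8, 1.2),
                     z = c(0.3, -0.3, 0), intensity = c(4, 4, 10) * 400)
  sim <- simulate_movie(schedule = sch, motion = still_motion(), acq = acq,
                        seed = 4, nucleus_radius = 2.5, initial_dots = init)
  d <- sim$truth$dots
  aa1 <- d$intensity[d$id == "Aa1" & d$frame == 3]
  aa2 <- d$intensity[d$id == "Aa2" & d$frame == 3]
  expect_equal(aa1, aa2)  # 0.5 partition by symmetry
  expect_equal(sim$truth$events$kind, "split")
  expect_equal(sim$truth$events$parent, "Aa")
})

test_that("mutant mode realizes stretch episodes instead of splits", {
  acq <- test_acq(n_frames = 16L, frame_interval = 60, noise = FALSE)
  eps <- data.frame(start = 180, end = 720, max_separation = 2)
  sch <- simulate_stretch_schedule(eps, dot = "G23")
  init <- data.frame(id = "G23", x = 0, y = 0, z = 0, intensity = 8000)
  sim <- simulate_movie(schedule = sch, motion = still_motion(), acq = acq,
                        mode = "condensinII_mutant", seed = 6,
                        nucleus_radius = 2.5, initial_dots = init)
  expect_false(any(sim$truth$events$kind == "split"))
  sep <- sim$truth$dots$stretch_separation
  expect_equal(max(sep), 2, tolerance = 0.15)
  expect_equal(sep[sim$truth$dots$frame == 15], 0)  # relaxed at the end
  # total rendered intensity conserved during stretching (noise off)
  for (t in c(4, 7)) {
    rendered <- sum(movie_frame(sim$movie, t, "dots"))
    truth <- sum(sim$truth$dots$intensity[sim$truth$dots$frame == t])
    expect_lt(abs(rendered - truth) / truth, 0.01)
  }
})

test_that("overexpression mode renders four satellite dots from frame 0", {
  acq <- test_acq(n_frames = 2L, noise = FALSE)
  sim <- simulate_movie(schedule = NULL, motion = still_motion(), acq = acq,
                        mode = "overexpression", seed = 9,
                        nucleus_radius = 2.5)
  expect_equal(sum(sim$truth$dots$frame == 0), 4)
})

test_that("dots initialized outside the nucleus are rejected", {
  acq <- test_acq(n_frames = 2L)
  init <- data.frame(id = "a", x = 5, y = 5, z = 5, intensity = 100)
  expect_error(simulate_movie(schedule = NULL, motion = still_motion(),
                              acq = acq, seed = 1, nucleus_radius = 2.5,
                              initial_dots = init),
               "outside the nucleus")
})

test_that("anaphase simulation: intact bivalents always split 4:4", {
  for (s in 1:5) {
    sim <- simulate_anaphase(pairing = pairing_config(), seed = s,
                             render = FALSE)
    u <- sim$truth$units
    expect_equal(sum(u$pole == 1), 4)
    expect_equal(sum(u$pole == 2), 4)
  }
})

test_that("anaphase simulation: random univalents match the enumeration null", {
  # many truth-only cells; 4:4 fraction ~ 70/256
  pr <- pairing_config(FALSE, FALSE, FALSE, FALSE)
  n44 <- 0; n_cells <- 600
  for (s in seq_len(n_cells)) {
    u <- simulate_anaphase(pairing = pr, null_random = TRUE, seed = s,
                           render = FALSE)$truth$units
    k <- sum(u$pole == 1)
    if (max(k, 8 - k) == 4) n44 <- n44 + 1
  }
  p <- n44 / n_cells
  expect_lt(abs(p - 70 / 256), 3 * sqrt(70 / 256 * (1 - 70 / 256) / n_cells))
  # determinism by seed
  u1 <- simulate_anaphase(pairing = pr, null_random = TRUE, seed = 3,
                          render = FALSE)$truth$units
  u2 <- simulate_anaphase(pairing = pr, null_random = TRUE, seed = 3,
                          render = FALSE)$truth$units
  expect_identical(u1, u2)
})
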