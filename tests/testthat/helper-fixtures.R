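# Shared fixtures: compact acquisition geometries and a standard three-dot
# de-clustering movie plus the pipeline steps applied to it.

test_acq <- function(n_frames = 8L, frame_interval = 60, ny = 48L, nx = 48L,
                     z_planes = 14L, z_spacing = 0.5, noise = TRUE,
                     bleach_rate = 0) {
  acquisition_config("custom", n_frames = n_frames,
                     frame_interval = frame_interval,
                     ny = ny, nx = nx, z_planes = z_planes,
                     z_spacing = z_spacing,
                     gaussian_sd = if (noise) 1 else 0,
                     poisson_scale = if (noise) 1 else 0,
                     bleach_rate = bleach_rate)
}

still_motion <- function() motion_config(mean_speed = 0, drift_amplitude = 0)

# A movie starting at the three-dot stage {Aa, Ab, XY4} that runs the full
# de-clustering program at 5-minute sampling with one event per 3 frames.
three_dot_movie <- function(program = "canonical", seed = 1L, noise = TRUE,
                            n_frames = 21L, drift_amplitude = 0.05) {
  acq <- acquisition_config("custom", n_frames = n_frames, ny = 64L, nx = 64L,
                            z_planes = 16L, frame_interval = 300,
                            gaussian_sd = if (noise) 1 else 0,
                            poisson_scale = if (noise) 1 else 0,
                            bleach_rate = 0.001)
  mot <- motion_config(mean_speed = 0.0005, confinement_radius = 0.3,
                       drift_amplitude = drift_amplitude)
  sch <- simulate_decluster_schedule(program,
    stage_durations = c(0, 0, 900, 900, 900, 900, 900))
  sch <- sch[sch$time > 0, ]
  init <- data.frame(id = c("Aa", "Ab", "XY4"),
                     x = c(-1.6, 1.6, 0), y = c(0.9, -0.9, 1.4),
                     z = c(0.4, -0.4, 0),
                     intensity = c(4, 4, 10) * 400)
  simulate_movie(karyotype = karyotype_male("G2"), schedule = sch,
                 motion = mot, acq = acq, seed = seed,
                 nucleus_radius = 3.2, initial_dots = init)
}

# Detect -> link -> drift-correct -> call events on a simulated movie.
analyze_movie <- function(sim, diameter = 0.5, max_step = 0.9) {
  spots <- detect_spots_movie(sim$movie, estimated_xy_diameter = diameter)
  tr <- link_tracks(spots, max_step = max_step)
  seg <- segment_nucleus_movie(sim$movie)
  dc <- correct_drift(tr, seg$table)
  ev <- detect_splits_fusions(dc$tracks, association_radius = 1.0)
  list(spots = spots, tracks = dc$tracks, drift = dc$drift,
       nucleus = seg, events = ev)
}

# Match detections to ground-truth dot positions of one frame within
# `tol` micrometers (greedy on distance, one-to-one).
match_detections <- function(spots, truth_frame, tol) {
  sp <- spots
  matched_truth <- rep(FALSE, nrow(truth_frame))
  matched_spot <- rep(FALSE, nrow(sp))
  if (nrow(sp) && nrow(truth_frame)) {
    dmat <- outer(seq_len(nrow(sp)), seq_len(nrow(truth_frame)),
                  Vectorize(function(i, j)
                    sqrt((sp$x[i] - truth_frame$x[j])^2 +
                           (sp$y[i] - truth_frame$y[j])^2 +
                           (sp$z[i] - truth_frame$z[j])^2)))
    while (TRUE) {
      m <- which(dmat == min(dmat), arr.ind = TRUE)[1, , drop = FALSE]
      if (dmat[m] > tol) break
      matched_spot[m[1]] <- TRUE
      matched_truth[m[2]] <- TRUE
      dmat[m[1], ] <- Inf
      dmat[, m[2]] <- Inf
      if (all(!is.finite(dmat))) break
    }
  }
  list(tp = sum(matched_spot), fp = sum(!matched_spot),
       fn = sum(!matched_truth))
}

# Brute-force nearest-boundary search: distance from a voxel center to the
# nearest background voxel center (oracle for the distance transform).
brute_force_distance <- function(mask, spacing, idx_yxz) {
  bg <- which(!mask, arr.ind = TRUE)
  p <- declustr:::index_to_um(matrix(idx_yxz, ncol = 3), spacing)
  q <- declustr:::index_to_um(bg, spacing)
  sqrt(min((q[, 1] - p[1])^2 + (q[, 2] - p[2])^2 + (q[, 3] - p[3])^2))
}

# Exhaustive 2^n enumeration of pole assignments (oracle for the analytic
# segregation null).
enumerate_null <- function(n_units) {
  grid <- as.matrix(expand.grid(rep(list(0:1), n_units)))
  k <- rowSums(grid)
  a <- pmax(k, n_units - k)
  tab <- table(a) / nrow(grid)
  data.frame(a = as.integer(names(tab)), probability = as.numeric(tab))
}
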