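# Ground-truthed synthetic two-channel 4D movies.
#
# Channel 1 ("nuclear") is a diffuse spherical nuclear signal (His2Av-mRFP
# analog), channel 2 ("dots") renders punctate markers (Cid-EGFP /
# EGFP-HOAP / TALE-light analogs) as voxel-integrated anisotropic Gaussians
# whose relative intensities derive from the karyotype model. Every movie is
# returned together with the ground truth needed to score the estimators:
# true trajectories, true integrated intensities, the realized event
# schedule, the drift series and the nucleus geometry.

#' Acquisition configuration
#'
#' Geometry, optics and camera model of a simulated acquisition. The two
#' presets mirror the acquisition modes used for spermatocyte territory
#' imaging: `"fine"` = 46 focal planes spaced by 500 nm acquired at 45 s
#' intervals; `"coarse"` = 29 focal planes spaced by 800 nm at 10 min
#' intervals. Any field can be overridden; tests use smaller grids.
#'
#' @param preset `"fine"`, `"coarse"` or `"custom"`.
#' @param n_frames Number of time points.
#' @param frame_interval Seconds between stacks.
#' @param z_planes,z_spacing Axial geometry (count, micrometers).
#' @param xy_pixel Lateral pixel size, micrometers.
#' @param ny,nx Lateral image size in pixels.
#' @param psf_sigma Gaussian PSF sigma, micrometers, `c(xy, z)`.
#' @param gaussian_sd Camera read-noise standard deviation, counts.
#' @param poisson_scale Photon gain: expected counts are drawn as
#'   `rpois(signal * poisson_scale) / poisson_scale`. Set 0 to disable shot
#'   noise.
#' @param bleach_rate Fraction of fluorescence lost per frame.
#' @return An `acquisition_config` list.
#' @export
acquisition_config <- function(preset = c("coarse", "fine", "custom"),
                               n_frames = NULL, frame_interval = NULL,
                               z_planes = NULL, z_spacing = NULL,
                               xy_pixel = 0.125, ny = 128L, nx = 128L,
                               psf_sigma = c(0.13, 0.35),
                               gaussian_sd = 2, poisson_scale = 1,
                               bleach_rate = 0.002) {
  preset <- match.arg(preset)
  def <- switch(preset,
    fine   = list(n_frames = 40L, frame_interval = 45,  z_planes = 46L,
                  z_spacing = 0.5),
    coarse = list(n_frames = 72L, frame_interval = 600, z_planes = 29L,
                  z_spacing = 0.8),
    custom = list(n_frames = 20L, frame_interval = 60,  z_planes = 16L,
                  z_spacing = 0.5))
  cfg <- list(
    n_frames = as.integer(n_frames %||% def$n_frames),
    frame_interval = frame_interval %||% def$frame_interval,
    z_planes = as.integer(z_planes %||% def$z_planes),
    z_spacing = z_spacing %||% def$z_spacing,
    xy_pixel = xy_pixel, ny = as.integer(ny), nx = as.integer(nx),
    psf_sigma = psf_sigma, gaussian_sd = gaussian_sd,
    poisson_scale = poisson_scale, bleach_rate = bleach_rate)
  stopifnot(cfg$xy_pixel > 0, cfg$z_spacing > 0, all(cfg$psf_sigma > 0),
            cfg$frame_interval > 0)
  structure(cfg, class = "acquisition_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Motion configuration for dot trajectories
#'
#' Dots perform anchored confined diffusion: each frame-to-frame step is an
#' isotropic Gaussian displacement whose expected length is
#' `mean_speed * frame_interval`, and positions are pulled back to within
#' `confinement_radius` of the dot's anchor. An optional two-state switch
#' multiplies the step size while in the fast state, emulating transient
#' phases of more rapid movement.
#'
#' @param mean_speed Mean dot speed, micrometers per second (default 0.03,
#'   the interphase centromere speed regime).
#' @param confinement_radius Maximal distance from the anchor, micrometers.
#' @param drift_amplitude Whole-nucleus random-walk drift step per frame,
#'   micrometers (0 disables drift).
#' @param fast_prob Per-frame probability of switching into the fast state
#'   (0 disables the two-state model).
#' @param fast_multiplier Step-size multiplier in the fast state.
#' @param fast_duration Mean number of frames spent in the fast state.
#' @return A `motion_config` list.
#' @export
motion_config <- function(mean_speed = 0.03, confinement_radius = 1.0,
                          drift_amplitude = 0, fast_prob = 0,
                          fast_multiplier = 3, fast_duration = 3) {
  stopifnot(mean_speed >= 0, confinement_radius > 0)
  structure(list(mean_speed = mean_speed,
                 confinement_radius = confinement_radius,
                 drift_amplitude = drift_amplitude,
                 fast_prob = fast_prob, fast_multiplier = fast_multiplier,
                 fast_duration = fast_duration),
            class = "motion_config")
}

# ---------------------------------------------------------------------------
# De-clustering identities and event schedules

# Cluster composition for each named dot identity of the de-clustering
# program, from which true intensities (in centromere units) are derived.
decluster_identities <- function(karyotype) {
  nc <- chromatids_per_homolog(karyotype)
  cc <- cluster_composition
  list(
    all   = cc(list("chr2", 1, nc), list("chr2", 2, nc),
               list("chr3", 1, nc), list("chr3", 2, nc),
               list("chr4", 1, nc), list("chr4", 2, nc),
               list("chrX", 1, nc), list("chrY", 1, nc)),
    AbXY4 = cc(list("chr3", 1, nc), list("chr3", 2, nc),
               list("chr4", 1, nc), list("chr4", 2, nc),
               list("chrX", 1, nc), list("chrY", 1, nc)),
    Aa    = cc(list("chr2", 1, nc), list("chr2", 2, nc)),
    Ab    = cc(list("chr3", 1, nc), list("chr3", 2, nc)),
    XY4   = cc(list("chrX", 1, nc), list("chrY", 1, nc),
               list("chr4", 1, nc), list("chr4", 2, nc)),
    Aa1   = cc(list("chr2", 1, nc)),
    Aa2   = cc(list("chr2", 2, nc)),
    Ab1   = cc(list("chr3", 1, nc)),
    Ab2   = cc(list("chr3", 2, nc)),
    Y     = cc(list("chrY", 1, nc)),
    X44   = cc(list("chrX", 1, nc), list("chr4", 1, nc), list("chr4", 2, nc)),
    X     = cc(list("chrX", 1, nc)),
    chr4  = cc(list("chr4", 1, nc), list("chr4", 2, nc)),
    chr4a = cc(list("chr4", 1, nc)),
    chr4b = cc(list("chr4", 2, nc))
  )
}

decluster_intensities <- function(karyotype) {
  ids <- decluster_identities(karyotype)
  vapply(ids, expected_cluster_intensity, numeric(1), karyotype = karyotype)
}

#' Simulate a centromere de-clustering event schedule
#'
#' Emits the ordered split events of the canonical de-clustering program or
#' one of its two variants. Canonical order: release of the Aa cluster, then
#' the Ab cluster, Aa -> Aa1 + Aa2, Ab -> Ab1 + Ab2, two releases from the
#' XY4 cluster (Y, then separation of X from the chr4 dot), and the final
#' chr4 split. `variant_four_dot` reaches the five-dot stage by a release
#' from the most intense XY4 dot before the Ab split; `variant_three_dot`
#' has that release already at the three-dot stage, before the Aa split.
#'
#' @param program `"canonical"`, `"variant_four_dot"` or
#'   `"variant_three_dot"`.
#' @param stage_durations Numeric vector of length 7: duration in seconds of
#'   the k-dot stage for k = 1..7 (the 8-dot state persists). Defaults
#'   reflect the observed regime where the four-dot stage is shortest (72
#'   min) and flanking stages last longer.
#' @param karyotype A [karyotype_male()] object (for true partition
#'   fractions).
#' @return An `event_schedule` data frame with columns `time`, `kind`,
#'   `parent`, `child1`, `child2`, `partition_fraction` (intensity fraction
#'   of `child1`).
#' @export
simulate_decluster_schedule <- function(program = c("canonical",
                                                    "variant_four_dot",
                                                    "variant_three_dot"),
                                        stage_durations = c(3600, 3600, 9000,
                                                            4320, 6000, 4800,
                                                            7200),
                                        karyotype = karyotype_male("G2")) {
  program <- match.arg(program)
  stopifnot(length(stage_durations) == 7, all(stage_durations >= 0))
  ints <- decluster_intensities(karyotype)
  ev <- function(kind, parent, child1, child2) {
    f <- if (kind == "split")
      unname(ints[child1] / (ints[child1] + ints[child2])) else NA_real_
    data.frame(kind = kind, parent = parent, child1 = child1,
               child2 = child2, partition_fraction = f,
               stringsAsFactors = FALSE)
  }
  e_aa_rel  <- ev("split", "all", "Aa", "AbXY4")
  e_ab_rel  <- ev("split", "AbXY4", "Ab", "XY4")
  e_aa_spl  <- ev("split", "Aa", "Aa1", "Aa2")
  e_ab_spl  <- ev("split", "Ab", "Ab1", "Ab2")
  e_y_rel   <- ev("split", "XY4", "Y", "X44")
  e_x44     <- ev("split", "X44", "X", "chr4")
  e_4_spl   <- ev("split", "chr4", "chr4a", "chr4b")
  events <- switch(program,
    canonical         = rbind(e_aa_rel, e_ab_rel, e_aa_spl, e_ab_spl,
                              e_y_rel, e_x44, e_4_spl),
    variant_four_dot  = rbind(e_aa_rel, e_ab_rel, e_aa_spl, e_y_rel,
                              e_ab_spl, e_x44, e_4_spl),
    variant_three_dot = rbind(e_aa_rel, e_ab_rel, e_y_rel, e_aa_spl,
                              e_ab_spl, e_x44, e_4_spl))
  events$time <- cumsum(stage_durations)
  events <- events[c("time", "kind", "parent", "child1", "child2",
                     "partition_fraction")]
  attr(events, "program") <- program
  class(events) <- c("event_schedule", class(events))
  events
}

#' Simulate a stretch-episode schedule (condensin II mutant regime)
#'
#' Episodes of transient dot elongation: the single dot stretches to
#' `max_separation` and relaxes back, or (with outcome `"definitive_split"`)
#' splits permanently at maximal elongation.
#'
#' @param episodes Data frame with columns `start`, `end` (seconds),
#'   `max_separation` (micrometers, default 2) and optionally `outcome`
#'   (`"relaxed"` or `"definitive_split"`).
#' @param dot Identity of the stretching dot.
#' @return An `event_schedule` data frame of `stretch_start` /
#'   `stretch_end` (or `split`) events.
#' @export
simulate_stretch_schedule <- function(episodes, dot = "G23") {
  if (is.null(episodes$outcome)) episodes$outcome <- "relaxed"
  if (is.null(episodes$max_separation)) episodes$max_separation <- 2
  rows <- lapply(seq_len(nrow(episodes)), function(i) {
    e <- episodes[i, ]
    start <- data.frame(time = e$start, kind = "stretch_start", parent = dot,
                        child1 = NA, child2 = NA, partition_fraction = NA,
                        max_separation = e$max_separation,
                        outcome = e$outcome, stringsAsFactors = FALSE)
    end <- data.frame(time = e$end,
                      kind = if (e$outcome == "definitive_split") "split"
                             else "stretch_end",
                      parent = dot,
                      child1 = if (e$outcome == "definitive_split")
                        paste0(dot, "a") else NA,
                      child2 = if (e$outcome == "definitive_split")
                        paste0(dot, "b") else NA,
                      partition_fraction =
                        if (e$outcome == "definitive_split") 0.5 else NA,
                      max_separation = e$max_separation, outcome = e$outcome,
                      stringsAsFactors = FALSE)
    rbind(start, end)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$time), ]
  class(out) <- c("event_schedule", class(out))
  out
}

# ---------------------------------------------------------------------------
# Rendering primitives

# Add a voxel-integrated anisotropic Gaussian of total integral `intensity`
# to `vol` (dim ny, nx, nz). Separable per-axis integration over voxel
# faces; the rendering window extends 5 sigma so truncation is < 0.01%.
render_gaussian_dot <- function(vol, pos, sigma, intensity, spacing) {
  d <- dim(vol)
  ax <- function(n, sp, mu, sg) {
    lo <- max(1L, floor((mu - 5 * sg) / sp) + 1L)
    hi <- min(n, ceiling((mu + 5 * sg) / sp))
    if (lo > hi) return(NULL)
    edges <- (seq(lo - 1L, hi)) * sp
    w <- diff(stats::pnorm(edges, mean = mu, sd = sg))
    list(idx = lo:hi, w = w)
  }
  # spacing and dims ordered (y, x, z); pos is (x, y, z)
  ay <- ax(d[1], spacing[1], pos[2], sigma[1])
  axx <- ax(d[2], spacing[2], pos[1], sigma[2])
  az <- ax(d[3], spacing[3], pos[3], sigma[3])
  if (is.null(ay) || is.null(axx) || is.null(az)) return(vol)
  blk <- (intensity * outer(outer(ay$w, axx$w), az$w))
  vol[ay$idx, axx$idx, az$idx] <- vol[ay$idx, axx$idx, az$idx] + blk
  vol
}

# Diffuse nuclear sphere with a soft edge: plateau `amplitude` inside,
# sigmoidal falloff of scale `edge` at radius R. The default edge scale of
# 0.12 um gives a 10-90% transition of ~0.5 um, i.e. a PSF-limited boundary.
render_nucleus <- function(dims, spacing, center, radius, amplitude,
                           edge = 0.12) {
  y <- ((seq_len(dims[1]) - 0.5) * spacing[1] - center[2])^2
  x <- ((seq_len(dims[2]) - 0.5) * spacing[2] - center[1])^2
  z <- ((seq_len(dims[3]) - 0.5) * spacing[3] - center[3])^2
  r2 <- outer(outer(y, x, `+`), z, `+`)
  amplitude / (1 + exp((sqrt(r2) - radius) / edge))
}

apply_noise <- function(vol, gaussian_sd, poisson_scale) {
  n <- length(vol)
  out <- vol
  if (poisson_scale > 0)
    out <- stats::rpois(n, pmax(vol, 0) * poisson_scale) / poisson_scale
  if (gaussian_sd > 0)
    out <- out + stats::rnorm(n, 0, gaussian_sd)
  array(pmax(0, round(out)), dim(vol))
}

# One confined-diffusion step for a set of dots. Steps are isotropic
# Gaussians with E|step| = speed * dt; positions exceeding the confinement
# radius are projected back onto the confinement sphere of their anchor.
diffuse_step <- function(pos, anchors, speed, dt, radius) {
  n <- nrow(pos)
  if (n == 0L) return(pos)
  # E of a 3D Gaussian step length with per-axis sd s is s * sqrt(8 / pi) / ...
  # chi_3 mean = sqrt(2) * gamma(2) / gamma(3/2) = 2 sqrt(2 / pi) * ... = 1.5958
  s <- speed * dt / 1.59577
  stp <- matrix(stats::rnorm(3 * n, 0, s), ncol = 3)
  out <- pos + stp
  off <- out - anchors
  d <- sqrt(rowSums(off^2))
  too_far <- d > radius
  if (any(too_far)) {
    out[too_far, ] <- anchors[too_far, , drop = FALSE] +
      off[too_far, , drop = FALSE] * (radius / d[too_far])
  }
  out
}

random_unit_vector <- function() {
  v <- stats::rnorm(3)
  v / vec_norm(v)
}

# ---------------------------------------------------------------------------

#' Simulate a two-channel 4D movie with ground truth
#'
#' Renders a single spermatocyte nucleus: channel 1 carries the diffuse
#' nuclear signal, channel 2 the punctate marker dots whose identities,
#' intensities and split schedule follow `schedule`. Dots perform anchored
#' confined diffusion; a whole-nucleus random-walk drift (if enabled) moves
#' nucleus and dots together; Poisson shot noise, Gaussian read noise and
#' exponential bleaching are applied per frame.
#'
#' Modes: `"wildtype"` realizes split events as scheduled;
#' `"condensinII_mutant"` suppresses split events (unless emitted by a
#' stretch schedule with outcome `definitive_split`) and renders stretch
#' episodes as a line segment of Gaussians with conserved total intensity
#' (mass concentrated at the two ends); `"overexpression"` renders four
#' resolved satellite dots of equal intensity from frame 0 and ignores the
#' schedule.
#'
#' @param karyotype A [karyotype_male()] object.
#' @param schedule An `event_schedule` (see [simulate_decluster_schedule()],
#'   [simulate_stretch_schedule()]); may be `NULL` for event-free movies.
#' @param motion A [motion_config()].
#' @param acq An [acquisition_config()].
#' @param mode `"wildtype"`, `"condensinII_mutant"` or `"overexpression"`.
#' @param seed Integer master seed; substreams for motion, noise and
#'   placement are derived from it.
#' @param nucleus_radius Nucleus radius, micrometers.
#' @param dot_unit_intensity Rendered integrated counts per centromere unit.
#' @param nuclear_amplitude Diffuse-channel plateau, counts.
#' @param initial_dots Optional data frame (`id`, `x`, `y`, `z`, `intensity`)
#'   overriding the automatic initial placement; positions in micrometers
#'   relative to the nucleus center.
#' @param split_separation Initial separation of split children, micrometers.
#' @param child_anchor_separation Separation of the children's confinement
#'   anchors, micrometers: after a split the two products drift apart into
#'   separate territories; their anchors are placed symmetrically about the
#'   parent's anchor at this distance.
#' @return A list with elements `movie` (a [movie()] object) and `truth`
#'   (list of data frames: `dots`, `events`, `drift`, `nucleus`).
#' @export
simulate_movie <- function(karyotype = karyotype_male("G2"),
                           schedule = NULL,
                           motion = motion_config(),
                           acq = acquisition_config("custom"),
                           mode = c("wildtype", "condensinII_mutant",
                                    "overexpression"),
                           seed = 1L,
                           nucleus_radius = 4.5,
                           dot_unit_intensity = 400,
                           nuclear_amplitude = 30,
                           initial_dots = NULL,
                           split_separation = 0.6,
                           child_anchor_separation = 1.6) {
  mode <- match.arg(mode)
  spacing <- c(acq$xy_pixel, acq$xy_pixel, acq$z_spacing)  # (y, x, z)
  dims <- c(acq$ny, acq$nx, acq$z_planes)
  extent <- dims * spacing
  center0 <- c(extent[2], extent[1], extent[3]) / 2       # (x, y, z)
  if (nucleus_radius > min(extent) / 2)
    warning("nucleus does not fit inside the field of view")

  ints <- decluster_intensities(karyotype)

  old <- local_seed(substream_seed(seed, "placement"))
  on.exit(restore_seed(old), add = TRUE)

  # --- initial dot state (positions relative to nucleus center)
  if (!is.null(initial_dots)) {
    st <- data.frame(id = as.character(initial_dots$id),
                     x = initial_dots$x, y = initial_dots$y,
                     z = initial_dots$z,
                     intensity = initial_dots$intensity,
                     stringsAsFactors = FALSE)
  } else if (mode == "overexpression") {
    ids <- paste0("sat", 1:4)
    st <- data.frame(id = ids, x = NA_real_, y = NA_real_, z = NA_real_,
                     intensity = dot_unit_intensity, stringsAsFactors = FALSE)
  } else {
    root <- if (!is.null(schedule) && "all" %in% schedule$parent) "all"
            else if (!is.null(schedule) && any(schedule$kind %in%
                     c("stretch_start", "split")))
              schedule$parent[1]
            else "all"
    st <- data.frame(id = root, x = NA_real_, y = NA_real_, z = NA_real_,
                     intensity = unname(
                       if (root %in% names(ints)) ints[root] * dot_unit_intensity
                       else dot_unit_intensity),
                     stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(st))) {
    if (is.na(st$x[i])) {
      repeat {
        p <- stats::runif(3, -0.6, 0.6) * nucleus_radius
        if (vec_norm(p) < 0.7 * nucleus_radius) break
      }
      st[i, c("x", "y", "z")] <- p
    }
  }
  if (any(sqrt(st$x^2 + st$y^2 + st$z^2) >= nucleus_radius))
    stop("dot initialized outside the nucleus")
  anchors <- as.matrix(st[, c("x", "y", "z")])

  # --- drift series (random walk, applied to everything)
  old_drift <- local_seed(substream_seed(seed, "drift"))
  drift <- matrix(0, acq$n_frames, 3)
  if (motion$drift_amplitude > 0 && acq$n_frames > 1) {
    steps <- matrix(stats::rnorm(3 * (acq$n_frames - 1), 0,
                                 motion$drift_amplitude / sqrt(3)),
                    ncol = 3)
    drift[-1, ] <- apply(steps, 2, cumsum)
  }
  restore_seed(old_drift)

  schedule_realized <- NULL
  if (!is.null(schedule)) {
    sch <- as.data.frame(schedule)
    if (mode == "condensinII_mutant") {
      out_col <- if ("outcome" %in% names(sch)) sch$outcome
                 else rep(NA_character_, nrow(sch))
      keep <- sch$kind %in% c("stretch_start", "stretch_end") |
        (sch$kind == "split" & !is.na(out_col) &
           out_col == "definitive_split")
      sch <- sch[keep, , drop = FALSE]
    } else if (mode == "overexpression") {
      sch <- sch[0, , drop = FALSE]
    }
  } else sch <- NULL

  n_frames <- acq$n_frames
  dt <- acq$frame_interval
  times <- (seq_len(n_frames) - 1L) * dt

  mov <- array(0, c(dims, 2L, n_frames))
  truth_dots <- vector("list", n_frames)
  stretch_state <- list()   # per dot id: list(max_sep, t0, t1, axis, outcome)

  old_motion <- local_seed(substream_seed(seed, "motion"))
  pos <- as.matrix(st[, c("x", "y", "z")])
  ids <- st$id
  intens0 <- st$intensity
  fast_state <- rep(FALSE, nrow(st))

  pending <- if (!is.null(sch) && nrow(sch)) sch[order(sch$time), ] else NULL
  realized <- list()

  for (t in seq_len(n_frames)) {
    tnow <- times[t]
    # realize due events
    while (!is.null(pending) && nrow(pending) > 0 && pending$time[1] <= tnow) {
      e <- pending[1, ]
      pending <- pending[-1, , drop = FALSE]
      i <- match(e$parent, ids)
      if (e$kind == "split") {
        if (is.na(i)) next
        u <- random_unit_vector()
        f <- if (!is.na(e$partition_fraction)) e$partition_fraction else 0.5
        child_pos <- rbind(pos[i, ] + u * split_separation / 2,
                           pos[i, ] - u * split_separation / 2)
        child_anch <- rbind(anchors[i, ] + u * child_anchor_separation / 2,
                            anchors[i, ] - u * child_anchor_separation / 2)
        child_int <- intens0[i] * c(f, 1 - f)
        ids <- c(ids[-i], e$child1, e$child2)
        pos <- rbind(pos[-i, , drop = FALSE], child_pos)
        anchors <- rbind(anchors[-i, , drop = FALSE], child_anch)
        intens0 <- c(intens0[-i], child_int)
        fast_state <- c(fast_state[-i], FALSE, FALSE)
        stretch_state[[e$parent]] <- NULL
        realized[[length(realized) + 1]] <-
          data.frame(time = tnow, frame = t - 1L, kind = "split",
                     parent = e$parent, child1 = e$child1, child2 = e$child2,
                     partition_fraction = f, stringsAsFactors = FALSE)
      } else if (e$kind == "stretch_start") {
        if (is.na(i)) next
        stretch_state[[e$parent]] <- list(
          max_sep = e$max_separation %||% 2, t0 = e$time,
          t1 = NA_real_, axis = random_unit_vector())
        realized[[length(realized) + 1]] <-
          data.frame(time = tnow, frame = t - 1L, kind = "stretch_start",
                     parent = e$parent, child1 = NA, child2 = NA,
                     partition_fraction = NA, stringsAsFactors = FALSE)
      } else if (e$kind == "stretch_end") {
        if (!is.null(stretch_state[[e$parent]]))
          stretch_state[[e$parent]]$t1 <- e$time
        realized[[length(realized) + 1]] <-
          data.frame(time = tnow, frame = t - 1L, kind = "stretch_end",
                     parent = e$parent, child1 = NA, child2 = NA,
                     partition_fraction = NA, stringsAsFactors = FALSE)
      }
    }
    # close finished stretch episodes
    for (nm in names(stretch_state)) {
      ss <- stretch_state[[nm]]
      if (!is.null(ss$t1) && !is.na(ss$t1) && tnow > ss$t1)
        stretch_state[[nm]] <- NULL
    }

    # motion update (not on frame 1)
    if (t > 1 && nrow(pos) > 0) {
      if (motion$fast_prob > 0) {
        enter <- stats::runif(nrow(pos)) < motion$fast_prob
        leave <- stats::runif(nrow(pos)) < 1 / motion$fast_duration
        fast_state <- (fast_state & !leave) | enter
      }
      mult <- ifelse(fast_state, motion$fast_multiplier, 1)
      for (g in unique(mult)) {
        sel <- mult == g
        pos[sel, ] <- diffuse_step(pos[sel, , drop = FALSE],
                                   anchors[sel, , drop = FALSE],
                                   motion$mean_speed * g, dt,
                                   motion$confinement_radius)
      }
    }

    bleach <- (1 - acq$bleach_rate)^(t - 1L)
    intens_t <- intens0 * bleach
    ncenter <- center0 + drift[t, ]

    # render channel 1 (diffuse nuclear)
    mov[, , , 1L, t] <- render_nucleus(dims, spacing, ncenter,
                                       nucleus_radius, nuclear_amplitude)

    # render channel 2 (dots), with stretch rendering where active
    vol <- array(0, dims)
    sigma <- c(acq$psf_sigma[1], acq$psf_sigma[1], acq$psf_sigma[2])
    sep_now <- rep(0, length(ids))
    for (i in seq_along(ids)) {
      p_img <- pos[i, ] + ncenter
      ss <- stretch_state[[ids[i]]]
      if (!is.null(ss)) {
        # elongation profile: triangular up to the scheduled stretch_end,
        # or a growing ramp when the episode terminates in a split (or the
        # movie ends first)
        cand <- if (!is.null(pending) && nrow(pending))
          pending[pending$parent == ids[i], , drop = FALSE] else NULL
        if (!is.null(ss$t1) && !is.na(ss$t1)) {
          t1 <- ss$t1
          triangular <- TRUE
        } else if (!is.null(cand) && nrow(cand)) {
          t1 <- min(cand$time)
          triangular <- cand$kind[which.min(cand$time)] == "stretch_end"
        } else {
          t1 <- times[n_frames]
          triangular <- FALSE
        }
        frac <- (tnow - ss$t0) / max(t1 - ss$t0, dt)
        frac <- min(max(frac, 0), 1)
        sep <- if (triangular) ss$max_sep * (1 - abs(2 * frac - 1))
               else ss$max_sep * frac
        sep_now[i] <- sep
        if (sep > 1e-6) {
          ends <- rbind(p_img + ss$axis * sep / 2, p_img - ss$axis * sep / 2)
          n_bridge <- 5L
          fr <- seq(0, 1, length.out = n_bridge + 2L)[2:(n_bridge + 1L)]
          bridge <- outer(fr, ends[2, ] - ends[1, ]) +
            matrix(ends[1, ], n_bridge, 3, byrow = TRUE)
          w_end <- 0.3; w_bridge <- 0.4 / n_bridge
          vol <- render_gaussian_dot(vol, ends[1, ], sigma,
                                     intens_t[i] * w_end, spacing)
          vol <- render_gaussian_dot(vol, ends[2, ], sigma,
                                     intens_t[i] * w_end, spacing)
          for (b in seq_len(n_bridge))
            vol <- render_gaussian_dot(vol, bridge[b, ], sigma,
                                       intens_t[i] * w_bridge, spacing)
        } else {
          vol <- render_gaussian_dot(vol, p_img, sigma, intens_t[i], spacing)
        }
      } else {
        vol <- render_gaussian_dot(vol, p_img, sigma, intens_t[i], spacing)
      }
    }
    mov[, , , 2L, t] <- vol

    truth_dots[[t]] <- data.frame(
      frame = t - 1L, time = tnow, id = ids,
      x = pos[, 1] + ncenter[1], y = pos[, 2] + ncenter[2],
      z = pos[, 3] + ncenter[3],
      xn = pos[, 1] + center0[1], yn = pos[, 2] + center0[2],
      zn = pos[, 3] + center0[3],
      intensity = intens_t, stretch_separation = sep_now,
      stringsAsFactors = FALSE)
  }
  restore_seed(old_motion)

  # noise (own substream so motion is unchanged when noise is toggled)
  old_noise <- local_seed(substream_seed(seed, "noise"))
  for (t in seq_len(n_frames)) for (ch in 1:2) {
    mov[, , , ch, t] <- apply_noise(mov[, , , ch, t],
                                    acq$gaussian_sd, acq$poisson_scale)
  }
  restore_seed(old_noise)

  m <- movie(mov, voxel = c(x = acq$xy_pixel, y = acq$xy_pixel,
                            z = acq$z_spacing),
             frame_interval = acq$frame_interval,
             channels = c("nuclear", "dots"))
  truth <- list(
    dots = do.call(rbind, truth_dots),
    events = if (length(realized)) do.call(rbind, realized) else
      data.frame(time = numeric(), frame = integer(), kind = character(),
                 parent = character(), child1 = character(),
                 child2 = character(), partition_fraction = numeric()),
    drift = data.frame(frame = seq_len(n_frames) - 1L,
                       dx = drift[, 1], dy = drift[, 2], dz = drift[, 3]),
    nucleus = data.frame(frame = seq_len(n_frames) - 1L,
                         cx = center0[1] + drift[, 1],
                         cy = center0[2] + drift[, 2],
                         cz = center0[3] + drift[, 3],
                         radius = nucleus_radius))
  list(movie = m, truth = truth)
}

#' Simulate anaphase I segregation
#'
#' Entities (intact bivalents or univalents, per [expected_entity_count()])
#' separate toward two poles. An intact bivalent sends its two homologs to
#' opposite poles deterministically; a univalent's pole is an independent
#' fair coin when `null_random` is `TRUE`, otherwise univalent poles
#' alternate. The ground truth records the pole assignment of every homolog
#' centromere (the unit scored in segregation ratios).
#'
#' @param karyotype A [karyotype_male()] object.
#' @param pairing A [pairing_config()].
#' @param null_random Logical; random univalent segregation.
#' @param seed Integer seed.
#' @param acq An [acquisition_config()]; a short movie is rendered.
#' @param pole_separation Final pole-to-pole distance, micrometers.
#' @param dot_unit_intensity Rendered counts per centromere unit.
#' @param render Logical; if `FALSE` only ground truth is produced (fast
#'   path for cohort-scale null simulations).
#' @return List with `movie` (or `NULL`) and `truth`; `truth$units` has one
#'   row per homolog centromere with its `pole` (1 or 2).
#' @export
simulate_anaphase <- function(karyotype = karyotype_male("G2"),
                              pairing = pairing_config(),
                              null_random = FALSE, seed = 1L,
                              acq = acquisition_config("custom",
                                                       n_frames = 8L),
                              pole_separation = 6,
                              dot_unit_intensity = 400,
                              render = TRUE) {
  old <- local_seed(substream_seed(seed, "anaphase"))
  on.exit(restore_seed(old))
  bivalents <- list(chr2 = c("chr2.1", "chr2.2"), chr3 = c("chr3.1", "chr3.2"),
                    chr4 = c("chr4.1", "chr4.2"), XY = c("chrX.1", "chrY.1"))
  ch <- karyotype$chromosomes
  nc <- chromatids_per_homolog(karyotype)
  unit_weight <- function(u) {
    chrom <- sub("\\.\\d$", "", u)
    ch$centromere_weight[match(chrom, ch$name)] * nc
  }
  units <- list(); alt <- 0L
  for (bv in names(bivalents)) {
    homs <- bivalents[[bv]]
    if (pairing[[bv]]) {
      first <- sample(1:2, 1)
      poles <- c(first, 3L - first)
    } else if (null_random) {
      poles <- sample(1:2, 2, replace = TRUE)
    } else {
      poles <- c(alt %% 2L + 1L, (alt + 1L) %% 2L + 1L)
      alt <- alt + 2L
    }
    units[[bv]] <- data.frame(bivalent = bv, unit = homs, pole = poles,
                              weight = unit_weight(homs),
                              intact = pairing[[bv]],
                              stringsAsFactors = FALSE)
  }
  units <- do.call(rbind, units)
  rownames(units) <- NULL

  spacing <- c(acq$xy_pixel, acq$xy_pixel, acq$z_spacing)
  dims <- c(acq$ny, acq$nx, acq$z_planes)
  extent <- dims * spacing
  center <- c(extent[2], extent[1], extent[3]) / 2
  axis <- c(1, 0, 0)
  n_frames <- acq$n_frames
  jitter0 <- matrix(stats::rnorm(3 * nrow(units), 0, 0.3), ncol = 3)
  frames <- vector("list", n_frames)
  mov <- if (render) array(0, c(dims, 2L, n_frames)) else NULL
  sigma <- c(acq$psf_sigma[1], acq$psf_sigma[1], acq$psf_sigma[2])
  for (t in seq_len(n_frames)) {
    frac <- (t - 1) / max(n_frames - 1, 1)
    target <- outer(ifelse(units$pole == 1L, -1, 1) * pole_separation / 2,
                    axis)
    p <- matrix(rep(center, each = nrow(units)), ncol = 3) +
      jitter0 * (1 - frac) + target * frac
    frames[[t]] <- data.frame(frame = t - 1L, id = units$unit,
                              x = p[, 1], y = p[, 2], z = p[, 3],
                              intensity = units$weight * dot_unit_intensity,
                              pole = units$pole, stringsAsFactors = FALSE)
    if (render) {
      vol <- array(0, dims)
      for (i in seq_len(nrow(units)))
        vol <- render_gaussian_dot(vol, p[i, ], sigma,
                                   units$weight[i] * dot_unit_intensity,
                                   spacing)
      mov[, , , 2L, t] <- vol
      mov[, , , 1L, t] <- render_nucleus(dims, spacing, center,
                                         pole_separation * 0.7, 10)
    }
  }
  if (render) {
    old_noise <- local_seed(substream_seed(seed, "noise"))
    for (t in seq_len(n_frames)) for (chn in 1:2)
      mov[, , , chn, t] <- apply_noise(mov[, , , chn, t],
                                       acq$gaussian_sd, acq$poisson_scale)
    restore_seed(old_noise)
  }
  m <- if (render)
    movie(mov, voxel = c(x = acq$xy_pixel, y = acq$xy_pixel,
                         z = acq$z_spacing),
          frame_interval = acq$frame_interval,
          channels = c("nuclear", "dots")) else NULL
  list(movie = m,
       truth = list(units = units, dots = do.call(rbind, frames)))
}
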