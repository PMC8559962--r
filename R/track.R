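# Frame-to-frame track linking with a constant-velocity (autoregressive)
# motion prior, whole-nucleus drift correction, velocity computation, and
# split/fusion event calling with intensity-partition statistics.

#' Link per-frame detections into tracks
#'
#' Detections of consecutive frames are linked by optimal bipartite
#' assignment (Hungarian algorithm) on gated Euclidean costs between each
#' track's predicted position and the candidate spots. The prediction is
#' `position + motion_memory * previous_displacement * elapsed_frames`,
#' a first-order autoregressive (constant-velocity) motion model;
#' `motion_memory = 0` reduces to nearest-neighbour linking. Unmatched
#' spots open new tracks; tracks missing for more than `max_gap` frames are
#' closed. Candidate spots are sorted deterministically within each frame,
#' so linking is invariant to the input row order.
#'
#' @param spots Data frame with columns `frame` (0-based), `x`, `y`, `z`
#'   (micrometers) and optionally `intensity`, `quality`.
#' @param max_gap Maximal number of missed frames bridged within a track.
#' @param max_step Gating radius, micrometers per frame of elapsed time.
#' @param motion_memory Weight of the previous displacement in the
#'   prediction, in `[0, 1]` (default 0.8, a strong constant-velocity
#'   prior).
#' @return A `tracks` data frame: `track`, `frame`, `x`, `y`, `z`,
#'   `intensity`.
#' @export
link_tracks <- function(spots, max_gap = 1L, max_step = 1.0,
                        motion_memory = 0.8) {
  stopifnot(all(c("frame", "x", "y", "z") %in% names(spots)),
            motion_memory >= 0, motion_memory <= 1, max_step > 0)
  if (is.null(spots$intensity) && nrow(spots) > 0L)
    spots$intensity <- NA_real_
  out_cols <- c("track", "frame", "x", "y", "z", "intensity")
  if (nrow(spots) == 0L)
    return(structure(
      stats::setNames(data.frame(integer(), integer(), numeric(), numeric(),
                                 numeric(), numeric()), out_cols),
      class = c("tracks", "data.frame")))
  frames <- sort(unique(spots$frame))
  active <- list()   # id, pos, disp, last_frame
  next_id <- 1L
  rows <- list()
  BIG <- 1e6
  for (t in seq(min(frames), max(frames))) {
    cand <- spots[spots$frame == t, , drop = FALSE]
    cand <- cand[order(cand$x, cand$y, cand$z), , drop = FALSE]
    nC <- nrow(cand); nT <- length(active)
    assign_track <- rep(NA_integer_, nC)   # index into active, per candidate
    if (nT > 0L && nC > 0L) {
      pred <- t(vapply(active, function(a) {
        el <- t - a$last_frame
        a$pos + motion_memory * a$disp * el
      }, numeric(3)))
      gate <- vapply(active, function(a) max_step * (t - a$last_frame),
                     numeric(1))
      cost <- outer(seq_len(nT), seq_len(nC), Vectorize(function(i, j)
        sqrt(sum((pred[i, ] - c(cand$x[j], cand$y[j], cand$z[j]))^2))))
      cost[cost > gate] <- BIG
      n <- nT + nC
      M <- matrix(BIG, n, n)
      M[seq_len(nT), seq_len(nC)] <- cost
      for (i in seq_len(nT)) M[i, nC + i] <- gate[i]         # track unmatched
      for (j in seq_len(nC)) M[nT + j, j] <- max_step        # spot -> new track
      M[(nT + 1):n, (nC + 1):n] <- 0                         # dummy-dummy
      sol <- clue::solve_LSAP(M)
      for (i in seq_len(nT)) {
        j <- sol[i]
        if (j <= nC && M[i, j] < BIG) assign_track[j] <- i
      }
    }
    # update matched tracks / open new ones
    new_active <- active
    for (j in seq_len(nC)) {
      i <- assign_track[j]
      p <- c(cand$x[j], cand$y[j], cand$z[j])
      if (!is.na(i)) {
        el <- t - active[[i]]$last_frame
        new_active[[i]]$disp <- (p - active[[i]]$pos) / el
        new_active[[i]]$pos <- p
        new_active[[i]]$last_frame <- t
        id <- active[[i]]$id
      } else {
        id <- next_id; next_id <- next_id + 1L
        new_active[[length(new_active) + 1L]] <-
          list(id = id, pos = p, disp = c(0, 0, 0), last_frame = t)
      }
      rows[[length(rows) + 1L]] <-
        data.frame(track = id, frame = t, x = p[1], y = p[2], z = p[3],
                   intensity = cand$intensity[j])
    }
    # close tracks that exceeded the gap
    new_active <- Filter(function(a) t - a$last_frame <= max_gap, new_active)
    active <- new_active
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$track, out$frame), ]
  rownames(out) <- NULL
  structure(out, class = c("tracks", "data.frame"))
}

#' Correct whole-nucleus translational drift
#'
#' Replaces each track position by `position - (centroid_t - centroid_0)`,
#' where the centroid series comes from per-frame nuclear segmentation.
#' Missing centroids are linearly interpolated (with a warning).
#'
#' @param tracks A `tracks` data frame (columns `x`, `y`, `z`, `frame`).
#' @param centroids Data frame with `frame`, `cx`, `cy`, `cz` (micrometers),
#'   e.g. `segment_nucleus_movie(m)$table`.
#' @return List with `tracks` (drift-corrected positions in `x`, `y`, `z`;
#'   originals kept as `x_raw`, `y_raw`, `z_raw`) and `drift` (per-frame
#'   translation relative to frame 0).
#' @export
correct_drift <- function(tracks, centroids) {
  stopifnot(all(c("frame", "cx", "cy", "cz") %in% names(centroids)))
  frames <- sort(unique(tracks$frame))
  have <- centroids$frame
  missing <- setdiff(frames, have)
  if (length(missing)) {
    warning("interpolating nucleus centroid at frame(s) ",
            paste(missing, collapse = ", "))
    interp <- function(col) stats::approx(have, centroids[[col]],
                                          xout = frames, rule = 2)$y
    centroids <- data.frame(frame = frames, cx = interp("cx"),
                            cy = interp("cy"), cz = interp("cz"))
  }
  centroids <- centroids[order(centroids$frame), ]
  ref <- unlist(centroids[1, c("cx", "cy", "cz")])
  drift <- data.frame(frame = centroids$frame,
                      dx = centroids$cx - ref[1],
                      dy = centroids$cy - ref[2],
                      dz = centroids$cz - ref[3])
  i <- match(tracks$frame, drift$frame)
  tracks$x_raw <- tracks$x; tracks$y_raw <- tracks$y; tracks$z_raw <- tracks$z
  tracks$x <- tracks$x - drift$dx[i]
  tracks$y <- tracks$y - drift$dy[i]
  tracks$z <- tracks$z - drift$dz[i]
  list(tracks = tracks, drift = drift)
}

#' Per-interval speeds of a track
#'
#' `speed = |pos_{t+1} - pos_t| / elapsed_time` over consecutive observed
#' positions of each track (drift-corrected positions should be supplied).
#'
#' @param tracks A `tracks` data frame (one or several tracks).
#' @param frame_interval Seconds per frame.
#' @return Data frame `track`, `frame_from`, `frame_to`, `speed`
#'   (micrometers per second); zero rows for length-1 tracks.
#' @export
compute_velocities <- function(tracks, frame_interval) {
  stopifnot(frame_interval > 0)
  res <- lapply(split(tracks, tracks$track), function(tr) {
    tr <- tr[order(tr$frame), ]
    if (nrow(tr) < 2L)
      return(data.frame(track = integer(), frame_from = integer(),
                        frame_to = integer(), speed = numeric()))
    d <- sqrt(diff(tr$x)^2 + diff(tr$y)^2 + diff(tr$z)^2)
    dt <- diff(tr$frame) * frame_interval
    data.frame(track = tr$track[-1], frame_from = tr$frame[-nrow(tr)],
               frame_to = tr$frame[-1], speed = d / dt)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Pooled velocity summary
#'
#' Mean and standard deviation of per-interval speeds pooled over all dots
#' and time points, the pooling used for stage-resolved velocity bars.
#'
#' @param tracks A `tracks` data frame.
#' @param frame_interval Seconds per frame.
#' @return List with `mean`, `sd`, `n` (number of intervals).
#' @export
velocity_summary <- function(tracks, frame_interval) {
  v <- compute_velocities(tracks, frame_interval)
  list(mean = mean(v$speed), sd = stats::sd(v$speed), n = nrow(v))
}

#' Call split and fusion events from tracks and intensities
#'
#' A split is called when a new track begins within `association_radius` of
#' an existing track whose integrated intensity drops by a commensurate
#' amount between the flanking frames (drop within a factor
#' `intensity_factor` of the new track's initial intensity); a fusion is the
#' time-reverse. The continuing parent track and the new track are the two
#' children; `partition_fraction` is the continuing child's share of the
#' summed intensities at the first post-split frame. Events with several
#' candidate parents within the radius are flagged `ambiguous` rather than
#' assigned.
#'
#' @param tracks A `tracks` data frame with `intensity`.
#' @param association_radius Micrometers.
#' @param intensity_factor Allowed ratio between the parent's intensity
#'   change and the appearing/disappearing track's intensity.
#' @return Data frame of events: `frame`, `kind` (`"split"`/`"fusion"`),
#'   `parent`, `child1` (continuing track), `child2` (new/ended track),
#'   `partition_fraction`, `ambiguous`.
#' @export
detect_splits_fusions <- function(tracks, association_radius = 1.0,
                                  intensity_factor = 3) {
  stopifnot("intensity" %in% names(tracks))
  byid <- split(tracks, tracks$track)
  first_frame <- vapply(byid, function(tr) min(tr$frame), numeric(1))
  last_frame <- vapply(byid, function(tr) max(tr$frame), numeric(1))
  ids <- as.integer(names(byid))
  at_frame <- function(tr, f) tr[tr$frame == f, , drop = FALSE]
  events <- list()
  t0 <- min(tracks$frame)
  t_end <- max(tracks$frame)
  for (k in seq_along(ids)) {
    fb <- first_frame[k]
    if (fb > t0) {  # candidate split: this track appears mid-movie
      child <- at_frame(byid[[k]], fb)
      # parents: tracks alive at fb and at some frame < fb
      cand <- which(ids != ids[k] & first_frame < fb & last_frame >= fb)
      if (length(cand)) {
        # associate against both the candidate parent's last pre-split
        # position (where the precursor dot was) and its first post-split
        # position (the continuing child)
        dd <- vapply(cand, function(i) {
          tr <- byid[[i]]
          pre <- tr[tr$frame < fb, , drop = FALSE]
          pre <- pre[which.max(pre$frame), , drop = FALSE]
          post <- at_frame(tr, fb)
          d <- Inf
          for (p in list(pre, post)) if (nrow(p))
            d <- min(d, sqrt((p$x - child$x)^2 + (p$y - child$y)^2 +
                               (p$z - child$z)^2))
          d
        }, numeric(1))
        near <- cand[dd <= association_radius]
        # among spatial candidates, keep those whose intensity drop is
        # commensurate with the appearing track's intensity
        stats_of <- lapply(near, function(i) {
          par_tr <- byid[[i]]
          pre <- par_tr[par_tr$frame < fb, , drop = FALSE]
          pre <- pre[which.max(pre$frame), , drop = FALSE]
          post <- at_frame(par_tr, fb)
          if (!nrow(pre) || !nrow(post)) return(NULL)
          drop_amt <- pre$intensity - post$intensity
          ok <- is.finite(drop_amt) && is.finite(child$intensity) &&
            drop_amt > 0 &&
            drop_amt <= intensity_factor * child$intensity &&
            drop_amt >= child$intensity / intensity_factor
          list(ok = ok, post = post$intensity,
               mismatch = abs(drop_amt - child$intensity))
        })
        passing <- near[vapply(stats_of, function(s)
          !is.null(s) && s$ok, logical(1))]
        if (length(passing) > 1L) {
          events[[length(events) + 1L]] <- data.frame(
            frame = fb, kind = "split", parent = NA_integer_,
            child1 = NA_integer_, child2 = ids[k],
            partition_fraction = NA_real_, ambiguous = TRUE)
        } else if (length(passing) == 1L) {
          s <- stats_of[[match(passing, near)]]
          events[[length(events) + 1L]] <- data.frame(
            frame = fb, kind = "split", parent = ids[passing],
            child1 = ids[passing], child2 = ids[k],
            partition_fraction = s$post / (s$post + child$intensity),
            ambiguous = FALSE)
        }
      }
    }
    fe <- last_frame[k]
    if (fe < t_end) {  # candidate fusion: this track ends mid-movie
      child <- at_frame(byid[[k]], fe)
      cand <- which(ids != ids[k] & last_frame > fe & first_frame <= fe)
      if (length(cand)) {
        dd <- vapply(cand, function(i) {
          tr <- byid[[i]]
          post <- tr[tr$frame > fe, , drop = FALSE]
          post <- post[which.min(post$frame), , drop = FALSE]
          pre <- at_frame(tr, fe)
          d <- Inf
          for (p in list(pre, post)) if (nrow(p))
            d <- min(d, sqrt((p$x - child$x)^2 + (p$y - child$y)^2 +
                               (p$z - child$z)^2))
          d
        }, numeric(1))
        near <- cand[dd <= association_radius]
        passing <- integer()
        for (i in near) {
          acc <- byid[[i]]
          pre <- acc[acc$frame <= fe, , drop = FALSE]
          pre <- pre[which.max(pre$frame), , drop = FALSE]
          post <- acc[acc$frame > fe, , drop = FALSE]
          post <- post[which.min(post$frame), , drop = FALSE]
          if (!nrow(pre) || !nrow(post)) next
          gain <- post$intensity - pre$intensity
          if (is.finite(gain) && is.finite(child$intensity) && gain > 0 &&
              gain <= intensity_factor * child$intensity &&
              gain >= child$intensity / intensity_factor)
            passing <- c(passing, i)
        }
        if (length(passing) > 1L) {
          events[[length(events) + 1L]] <- data.frame(
            frame = fe + 1L, kind = "fusion", parent = NA_integer_,
            child1 = NA_integer_, child2 = ids[k],
            partition_fraction = NA_real_, ambiguous = TRUE)
        } else if (length(passing) == 1L) {
          events[[length(events) + 1L]] <- data.frame(
            frame = fe + 1L, kind = "fusion", parent = ids[passing],
            child1 = ids[passing], child2 = ids[k],
            partition_fraction = NA_real_, ambiguous = FALSE)
        }
      }
    }
  }
  if (!length(events))
    return(data.frame(frame = integer(), kind = character(),
                      parent = integer(), child1 = integer(),
                      child2 = integer(), partition_fraction = numeric(),
                      ambiguous = logical()))
  out <- do.call(rbind, events)
  out[order(out$frame), ]
}

#' Apply a batch track-edit table
#'
#' Deterministic replacement for interactive track curation: a table of
#' operations applied in row order. Supported `op` values:
#' `delete_spot` (track, frame), `relabel` (track -> new_track),
#' `cut` (split a track before `frame`; the tail gets `new_track`),
#' `join` (append track `new_track`'s rows to `track`).
#'
#' @param tracks A `tracks` data frame.
#' @param edits Data frame with columns `op`, `track`, `frame`,
#'   `new_track` (NA where unused).
#' @return Edited `tracks` data frame.
#' @export
apply_track_edits <- function(tracks, edits) {
  for (i in seq_len(nrow(edits))) {
    e <- edits[i, ]
    tracks <- switch(as.character(e$op),
      delete_spot = tracks[!(tracks$track == e$track &
                               tracks$frame == e$frame), ],
      relabel = { tracks$track[tracks$track == e$track] <- e$new_track
                  tracks },
      cut = { sel <- tracks$track == e$track & tracks$frame >= e$frame
              tracks$track[sel] <- e$new_track
              tracks },
      join = { tracks$track[tracks$track == e$new_track] <- e$track
               tracks },
      stop("unknown edit op: ", e$op))
  }
  tracks[order(tracks$track, tracks$frame), ]
}
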