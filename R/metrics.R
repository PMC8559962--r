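# Per-cell readouts derived from tracks: dot-count stage intervals with
# censoring, intensity ratios, pair separations with the single-spot zero
# encoding, stretch episodes, radial summaries, and group comparisons.

#' Dot-count stage intervals with censoring
#'
#' Maximal constant-count runs of the per-frame dot-count series become
#' stage intervals. Transient count dips shorter than `debounce` frames
#' that are flanked by equal counts (the signature of a transient fusion)
#' are bridged before run-length encoding. Runs touching the start or end
#' of the observation window are censored -- their durations are lower
#' bounds ("minimal durations").
#'
#' @param counts Integer vector of dot counts, one per frame, or a data
#'   frame with `frame` and `count`.
#' @param frame_interval Seconds per frame.
#' @param debounce Bridge count dips shorter than this many frames.
#' @return Data frame: `count`, `start_frame`, `end_frame` (0-based,
#'   inclusive), `duration` (seconds, `n_frames * frame_interval`),
#'   `censoring` in complete / left_censored / right_censored /
#'   both_censored.
#' @export
dot_stage_intervals <- function(counts, frame_interval, debounce = 2L) {
  if (is.data.frame(counts)) {
    counts <- counts$count[order(counts$frame)]
  }
  stopifnot(all(counts >= 0), frame_interval > 0)
  n <- length(counts)
  if (n == 0L)
    return(data.frame(count = integer(), start_frame = integer(),
                      end_frame = integer(), duration = numeric(),
                      censoring = character()))
  # bridge transient dips
  r <- rle(counts)
  if (length(r$lengths) >= 3L) {
    for (i in 2:(length(r$lengths) - 1L)) {
      if (r$lengths[i] < debounce &&
          r$values[i] < r$values[i - 1L] &&
          r$values[i - 1L] == r$values[i + 1L]) {
        r$values[i] <- r$values[i - 1L]
      }
    }
    counts <- inverse.rle(r)
    r <- rle(counts)
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cens <- rep("complete", length(r$lengths))
  cens[starts == 1L] <- "left_censored"
  cens[ends == n] <- ifelse(starts[ends == n] == 1L, "both_censored",
                            "right_censored")
  data.frame(count = r$values, start_frame = starts - 1L,
             end_frame = ends - 1L,
             duration = r$lengths * frame_interval,
             censoring = cens, stringsAsFactors = FALSE)
}

#' Intensity ratios among the dots of one frame
#'
#' @param intensities Numeric vector of integrated dot intensities (>= 2
#'   dots, all > 0).
#' @param ids Optional dot identity labels.
#' @param reference_id Identity of the reference dot for per-dot ratios
#'   (an Aa1-class dot -- a single unresolved sister-centromere pair of a
#'   large autosome -- when identities are available).
#' @return List with `strongest_weakest` (max/min ratio) and
#'   `vs_reference` (named vector of each dot / reference dot, when the
#'   reference is present).
#' @export
intensity_ratio_report <- function(intensities, ids = NULL,
                                   reference_id = "Aa1") {
  stopifnot(length(intensities) >= 2)
  if (any(intensities <= 0)) stop("zero or negative dot intensity")
  out <- list(strongest_weakest = max(intensities) / min(intensities))
  if (!is.null(ids) && reference_id %in% ids) {
    ref <- intensities[match(reference_id, ids)]
    out$vs_reference <- stats::setNames(intensities / ref, ids)
  }
  out
}

#' Pair separation series with single-spot zero encoding
#'
#' Euclidean distance between two tracks per frame. Frames where exactly
#' one of the two signals was detected encode distance 0 (a single merged
#' spot); frames where both are absent are missing values, never zero.
#'
#' @param track_a,track_b Data frames with `frame`, `x`, `y`, `z`
#'   (drift-corrected).
#' @param frames Frames to evaluate; defaults to the full observed range.
#' @return Data frame `frame`, `separation` (micrometers).
#' @export
pair_separation <- function(track_a, track_b, frames = NULL) {
  if (is.null(frames)) {
    all_f <- c(track_a$frame, track_b$frame)
    frames <- seq(min(all_f), max(all_f))
  }
  ia <- match(frames, track_a$frame)
  ib <- match(frames, track_b$frame)
  sep <- ifelse(
    !is.na(ia) & !is.na(ib),
    sqrt((track_a$x[ia] - track_b$x[ib])^2 +
           (track_a$y[ia] - track_b$y[ib])^2 +
           (track_a$z[ia] - track_b$z[ib])^2),
    ifelse(!is.na(ia) | !is.na(ib), 0, NA_real_))
  data.frame(frame = frames, separation = sep)
}

#' Stretch episodes in a pair-separation series
#'
#' Maximal runs with separation at or above `min_separation` lasting at
#' least `min_duration` frames. An episode's outcome is
#' `"definitive_split"` when the separation never returns to zero between
#' the episode and the end of the observation, otherwise `"relaxed"`.
#'
#' @param series Data frame from [pair_separation()] (or numeric vector).
#' @param min_separation Micrometers (default 1, the two-spot detection
#'   scale at a 1 um estimated diameter).
#' @param min_duration Frames.
#' @return Data frame: `start_frame`, `end_frame`, `max_separation`,
#'   `outcome`.
#' @export
stretch_episodes <- function(series, min_separation = 1.0,
                             min_duration = 3L) {
  if (is.data.frame(series)) {
    frames <- series$frame; sep <- series$separation
  } else {
    sep <- series; frames <- seq_along(series) - 1L
  }
  above <- !is.na(sep) & sep >= min_separation
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_duration)
  if (!length(keep))
    return(data.frame(start_frame = integer(), end_frame = integer(),
                      max_separation = numeric(), outcome = character()))
  out <- lapply(keep, function(i) {
    run <- starts[i]:ends[i]
    after <- if (ends[i] < length(sep)) sep[(ends[i] + 1L):length(sep)]
             else numeric()
    returned <- any(!is.na(after) & after == 0)
    data.frame(start_frame = frames[starts[i]], end_frame = frames[ends[i]],
               max_separation = max(sep[run]),
               outcome = if (returned) "relaxed" else "definitive_split",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Radial-position summary over the first frames of imaging
#'
#' Averages a dot's normalized radial position over the first `n_frames`
#' time points, the convention used for reporting radial dot positions.
#'
#' @param track Data frame with `frame`, `x`, `y`, `z` (micrometers, image
#'   frame).
#' @param nuclei List of `nucleus_model`s indexed by frame (element `t + 1`
#'   is frame `t`), e.g. `segment_nucleus_movie(m)$models`.
#' @param n_frames Number of initial frames to average (default 10).
#' @return List with `mean`, `sd`, `n`; all `NA` (with a warning) when the
#'   track does not cover any of the first `n_frames`.
#' @export
radial_summary <- function(track, nuclei, n_frames = 10L) {
  sel <- track$frame < n_frames
  if (!any(sel)) {
    warning("track does not cover any of the first ", n_frames, " frames")
    return(list(mean = NA_real_, sd = NA_real_, n = 0L))
  }
  tr <- track[sel, , drop = FALSE]
  vals <- vapply(seq_len(nrow(tr)), function(i) {
    nuc <- nuclei[[tr$frame[i] + 1L]]
    d <- distance_to_periphery(c(tr$x[i], tr$y[i], tr$z[i]), nuc)
    radial_position(max(d, 0), nuc$radius)
  }, numeric(1))
  list(mean = mean(vals), sd = stats::sd(vals), n = length(vals))
}

#' Two-sample two-tailed t test with significance stars
#'
#' Classical pooled-variance Student t test by default (Welch by flag),
#' with the conventional significance stars at 0.05 / 0.01 / 0.001.
#'
#' @param a,b Numeric samples (each n >= 2).
#' @param var_equal Pooled variance (classical Student) if `TRUE`.
#' @return List: `t`, `df`, `p`, `stars`.
#' @export
compare_groups <- function(a, b, var_equal = TRUE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    stop("zero variance in both groups")
  ht <- stats::t.test(a, b, var.equal = var_equal)
  p <- ht$p.value
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**"
           else if (p < 0.05) "*" else "ns"
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = p,
       stars = stars)
}
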