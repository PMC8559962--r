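# Movie container: a calibrated multi-frame, multi-channel 3D intensity grid.

#' Construct a movie object
#'
#' A movie is a 5D numeric array with dimensions (y, x, z, channel, frame)
#' plus physical calibration: voxel sizes in micrometers and the frame
#' interval in seconds. Voxel indices are 0-based externally with physical
#' coordinates at voxel centers, i.e. the center of voxel `i` along an axis
#' with spacing `s` lies at `(i + 0.5) * s` micrometers.
#'
#' @param data 5D array, dim `c(ny, nx, nz, n_channels, n_frames)`.
#' @param voxel Named numeric `c(x =, y =, z =)` voxel size in micrometers.
#' @param frame_interval Seconds between frames.
#' @param channels Optional character vector of channel names.
#' @return An object of class `movie`.
#' @export
movie <- function(data, voxel, frame_interval, channels = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 5L,
            all(c("x", "y", "z") %in% names(voxel)),
            all(voxel > 0), frame_interval > 0)
  if (is.null(channels))
    channels <- paste0("ch", seq_len(dim(data)[4]))
  stopifnot(length(channels) == dim(data)[4])
  structure(list(data = data,
                 voxel = voxel[c("x", "y", "z")],
                 frame_interval = frame_interval,
                 channels = channels),
            class = "movie")
}

#' @export
print.movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "movie: %d frame(s) x %d channel(s) x %d z x %d y x %d x voxels\n",
    d[5], d[4], d[3], d[1], d[2]))
  cat(sprintf("  voxel %.3f x %.3f x %.3f um (x, y, z); frame interval %g s\n",
              x$voxel["x"], x$voxel["y"], x$voxel["z"], x$frame_interval))
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  invisible(x)
}

#' Number of frames / channels of a movie
#' @param m A [movie()].
#' @return Integer count.
#' @export
n_frames <- function(m) dim(m$data)[5]

#' @rdname n_frames
#' @export
n_channels <- function(m) dim(m$data)[4]

#' Extract one 3D volume from a movie
#'
#' @param m A [movie()].
#' @param frame 0-based frame index.
#' @param channel Channel index (1-based) or channel name.
#' @return A 3D array `(ny, nx, nz)` with attributes `spacing` (y, x, z
#'   micrometers) and `voxel`.
#' @export
movie_frame <- function(m, frame, channel = 1L) {
  stopifnot(inherits(m, "movie"))
  if (is.character(channel)) channel <- match(channel, m$channels)
  stopifnot(frame >= 0, frame < n_frames(m),
            !is.na(channel), channel >= 1, channel <= n_channels(m))
  vol <- m$data[, , , channel, frame + 1L, drop = FALSE]
  dim(vol) <- dim(m$data)[1:3]
  attr(vol, "spacing") <- unname(c(m$voxel["y"], m$voxel["x"], m$voxel["z"]))
  attr(vol, "voxel") <- m$voxel
  vol
}

vol_spacing <- function(vol, spacing = NULL) {
  sp <- spacing %||% attr(vol, "spacing")
  if (is.null(sp)) stop("volume carries no spacing; pass `spacing`")
  sp
}
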