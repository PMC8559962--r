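# Shared numeric helpers: seeded RNG substreams, separable Gaussian filtering
# on anisotropic 3D grids, local maxima, and voxel/physical coordinate maps.
#
# Convention: a volume is an array with dim = c(ny, nx, nz); physical
# coordinates are in micrometers with the center of voxel (i, j, k) at
# ((j - 0.5) dx, (i - 0.5) dy, (k - 0.5) dz) -- i.e. 0-based voxel indices
# map to centers at (index + 0.5) * spacing.

# Save the global RNG state and set a seed; restore_seed() undoes it.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# Deterministic substream seed derived from a master seed and a label, so
# that e.g. motion noise and camera noise are independent but reproducible.
substream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.integer(seed) %% 1000003L) * 2047L + (h %% 65521L)
}

gaussian_kernel_1d <- function(sigma_vox, radius = ceiling(4 * sigma_vox)) {
  if (sigma_vox <= 0) return(1)
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# Convolve along the first dimension of a matrix with replicate padding,
# via a banded dense kernel matrix (fast for the <= 256-voxel axes used here).
conv1_first <- function(m, kernel) {
  n <- nrow(m)
  r <- (length(kernel) - 1L) / 2L
  idx <- outer(seq_len(n), seq(-r, r), `+`)
  idx[idx < 1L] <- 1L
  idx[idx > n] <- n
  K <- matrix(0, n, n)
  for (j in seq_along(kernel)) {
    K[cbind(seq_len(n), idx[, j])] <- K[cbind(seq_len(n), idx[, j])] + kernel[j]
  }
  K %*% m
}

# Separable Gaussian smoothing of a (ny, nx, nz) volume; sigma_um per axis is
# given in micrometers as c(y, x, z) and divided by the voxel spacing.
gaussian_smooth <- function(vol, sigma_um, spacing) {
  d <- dim(vol)
  sig_vox <- sigma_um / spacing
  out <- vol
  for (axis in 1:3) {
    if (sig_vox[axis] <= 0) next
    k <- gaussian_kernel_1d(sig_vox[axis])
    if (length(k) == 1L) next
    perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    v <- aperm(out, perm)
    dv <- dim(v)
    v <- matrix(v, nrow = dv[1])
    v <- conv1_first(v, k)
    dim(v) <- dv
    out <- aperm(v, order(perm))
  }
  out
}

# Discrete Laplacian with per-axis spacing (replicate boundary).
laplacian3 <- function(vol, spacing) {
  d <- dim(vol)
  shift <- function(v, axis, by) {
    idx <- lapply(d, seq_len)
    i <- seq_len(d[axis]) + by
    i[i < 1L] <- 1L
    i[i > d[axis]] <- d[axis]
    idx[[axis]] <- i
    do.call(`[`, c(list(v), idx))
  }
  out <- array(0, d)
  for (axis in 1:3) {
    out <- out + (shift(vol, axis, 1L) + shift(vol, axis, -1L) - 2 * vol) /
      spacing[axis]^2
  }
  out
}

# 26-connected local maxima of a volume that exceed `threshold`.
# Plateau ties are broken toward the lowest (z, y, x) index: a voxel is kept
# when it is >= all neighbours and > all neighbours that precede it in that
# order is not required -- instead strict inequality is demanded against
# neighbours with smaller linear index, which keeps exactly one voxel per
# constant plateau.
local_maxima3 <- function(vol, threshold = -Inf) {
  d <- dim(vol)
  pad <- array(-Inf, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- vol
  keep <- array(TRUE, d)
  ii <- 2:(d[1] + 1); jj <- 2:(d[2] + 1); kk <- 2:(d[3] + 1)
  center <- pad[ii, jj, kk]
  for (dz in -1:1) for (dx in -1:1) for (dy in -1:1) {
    if (dy == 0 && dx == 0 && dz == 0) next
    nb <- pad[ii + dy, jj + dx, kk + dz]
    # neighbours earlier in (z, y, x) order must be strictly smaller
    earlier <- (dz < 0) || (dz == 0 && dy < 0) || (dz == 0 && dy == 0 && dx < 0)
    keep <- keep & (if (earlier) center > nb else center >= nb)
  }
  which(keep & center > threshold, arr.ind = TRUE)
}

# Voxel-index (1-based array index) <-> physical micrometer coordinates.
# `spacing` is c(y, x, z); positions are matrices with columns x, y, z.
index_to_um <- function(idx_yxz, spacing) {
  cbind(x = (idx_yxz[, 2] - 0.5) * spacing[2],
        y = (idx_yxz[, 1] - 0.5) * spacing[1],
        z = (idx_yxz[, 3] - 0.5) * spacing[3])
}

um_to_index <- function(pos_xyz, spacing) {
  cbind(pos_xyz[, 2] / spacing[1] + 0.5,
        pos_xyz[, 1] / spacing[2] + 0.5,
        pos_xyz[, 3] / spacing[3] + 0.5)
}

vec_norm <- function(v) sqrt(sum(v^2))
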