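# Low-level 3D array numerics shared by the transforms: separable Gaussian
# smoothing and trilinear / nearest-neighbour resampling at arbitrary
# (continuous) source coordinates. Everything here is pure base R on dense
# arrays; volumes in this package are small patches (tens of voxels per axis).

# Truncated Gaussian kernel, radius 3*sigma, renormalized so weights sum to 1.
gaussian_kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k / sum(k)
}

# Smoothing along one axis as a banded-matrix product with rows renormalized
# at the borders: every output value is a convex combination of inputs, so the
# output range never exceeds the input range.
smoothing_matrix <- function(n, sigma) {
  k <- gaussian_kernel(sigma)
  r <- (length(k) - 1L) %/% 2L
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - r):(i + r)
    keep <- j >= 1L & j <= n
    m[i, j[keep]] <- k[keep]
    m[i, ] <- m[i, ] / sum(m[i, ])
  }
  m
}

# Separable 3D Gaussian blur; sigma may be a scalar or length-3 vector (voxels).
gauss_smooth3 <- function(arr, sigma) {
  d <- dim(arr)
  sigma <- rep_len(sigma, 3L)
  out <- arr
  if (sigma[1] > 0) {
    out <- array(smoothing_matrix(d[1], sigma[1]) %*% matrix(out, d[1]), dim = d)
  }
  if (sigma[2] > 0) {
    out <- aperm(out, c(2, 1, 3))
    out <- array(smoothing_matrix(d[2], sigma[2]) %*% matrix(out, d[2]),
                 dim = d[c(2, 1, 3)])
    out <- aperm(out, c(2, 1, 3))
  }
  if (sigma[3] > 0) {
    out <- aperm(out, c(3, 1, 2))
    out <- array(smoothing_matrix(d[3], sigma[3]) %*% matrix(out, d[3]),
                 dim = d[c(3, 1, 2)])
    out <- aperm(out, c(2, 3, 1))
  }
  out
}

# Trilinear sampling of `arr` at continuous 1-based coordinates (x, y, z),
# given as equal-length vectors. Coordinates outside the grid read as `fill`.
sample_trilinear <- function(arr, x, y, z, fill = 0) {
  d <- dim(arr)
  inside <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3]
  out <- rep(fill, length(x))
  if (!any(inside)) return(out)
  x <- x[inside]; y <- y[inside]; z <- z[inside]

  x0 <- pmin(floor(x), d[1] - 1L); x0 <- pmax(x0, 1)
  y0 <- pmin(floor(y), d[2] - 1L); y0 <- pmax(y0, 1)
  z0 <- pmin(floor(z), d[3] - 1L); z0 <- pmax(z0, 1)
  fx <- x - x0; fy <- y - y0; fz <- z - z0

  idx <- function(i, j, k) (k - 1) * d[1] * d[2] + (j - 1) * d[1] + i
  v <- as.vector(arr)
  c000 <- v[idx(x0,     y0,     z0)]
  c100 <- v[idx(x0 + 1, y0,     z0)]
  c010 <- v[idx(x0,     y0 + 1, z0)]
  c110 <- v[idx(x0 + 1, y0 + 1, z0)]
  c001 <- v[idx(x0,     y0,     z0 + 1)]
  c101 <- v[idx(x0 + 1, y0,     z0 + 1)]
  c011 <- v[idx(x0,     y0 + 1, z0 + 1)]
  c111 <- v[idx(x0 + 1, y0 + 1, z0 + 1)]

  c00 <- c000 * (1 - fx) + c100 * fx
  c10 <- c010 * (1 - fx) + c110 * fx
  c01 <- c001 * (1 - fx) + c101 * fx
  c11 <- c011 * (1 - fx) + c111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  out[inside] <- c0 * (1 - fz) + c1 * fz
  out
}

# Nearest-neighbour sampling (for label grids); outside reads as `fill`.
sample_nearest <- function(arr, x, y, z, fill = 0L) {
  d <- dim(arr)
  xi <- round(x); yi <- round(y); zi <- round(z)
  inside <- xi >= 1 & xi <= d[1] & yi >= 1 & yi <= d[2] & zi >= 1 & zi <= d[3]
  out <- rep(fill, length(x))
  idx <- (zi[inside] - 1) * d[1] * d[2] + (yi[inside] - 1) * d[1] + xi[inside]
  out[inside] <- as.vector(arr)[idx]
  out
}

# 1-based voxel-centre coordinate grids for a shape, as long vectors in
# column-major order matching as.vector(array).
coord_grid <- function(d) {
  list(
    x = rep(seq_len(d[1]), times = d[2] * d[3]),
    y = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    z = rep(seq_len(d[3]), each = d[1] * d[2])
  )
}

# Resample a patch through an inverse map: for every output voxel centre the
# map returns the source coordinate to read from. Image is read with trilinear
# interpolation, label with nearest neighbour — the pairing that preserves the
# label-subset invariant.
warp_patch <- function(patch, src_x, src_y, src_z) {
  d <- dim(patch$image)
  img <- array(sample_trilinear(patch$image, src_x, src_y, src_z, fill = 0),
               dim = d)
  lab <- array(as.integer(sample_nearest(patch$label, src_x, src_y, src_z,
                                         fill = 0L)), dim = d)
  volume_patch(clip01(img), lab, patch$spacing)
}
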