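# Shared numeric helpers: sampling, rotation, rasterization, correlation.
# Conventions: arrays are dim c(nx, ny, nz); voxel (i,j,k) (1-based) has its
# center at origin + (i-1, j-1, k-1) * pixel_size (nm); z is the beam axis.

#' Signed integer Fourier frequencies for an axis of length n
#' @param n axis length
#' @return integer vector of length n (0, 1, ..., -1) in FFT order
#' @keywords internal
fft_freq <- function(n) {
  k <- seq_len(n) - 1L
  k[k > n / 2] <- k[k > n / 2] - n
  k
}

#' Normalized cross-correlation of two equal-size arrays
#'
#' Pearson correlation of the flattened voxel values; invariant to global
#' intensity scaling and offset of either argument.
#' @param a,b numeric arrays of identical dimension
#' @return scalar in \[-1, 1\]
#' @export
ncc <- function(a, b) {
  a <- as.vector(a) - mean(a)
  b <- as.vector(b) - mean(b)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) return(0)
  sum(a * b) / den
}

# Zero-mean, unit-norm copy of an image/volume (as vector); all-constant
# input maps to the zero vector.
normalize_vec <- function(x) {
  x <- as.vector(x) - mean(x)
  n <- sqrt(sum(x^2))
  if (n == 0) return(x)
  x / n
}

#' Bilinear interpolation on a matrix
#' @param img numeric matrix
#' @param x,y continuous 1-based pixel coordinates (vectors)
#' @return sampled values; coordinates outside the grid give 0
#' @keywords internal
bilinear_sample <- function(img, x, y) {
  nx <- nrow(img); ny <- ncol(img)
  x0 <- pmin(floor(x), nx - 1); y0 <- pmin(floor(y), ny - 1)
  fx <- x - x0; fy <- y - y0
  out <- numeric(length(x))
  ok <- x >= 1 & x <= nx & y >= 1 & y <= ny
  if (any(ok)) {
    i0 <- x0[ok]; j0 <- y0[ok]; gx <- fx[ok]; gy <- fy[ok]
    idx <- function(i, j) (j - 1) * nx + i
    v <- img[idx(i0, j0)]     * (1 - gx) * (1 - gy) +
         img[idx(i0 + 1, j0)] * gx       * (1 - gy) +
         img[idx(i0, j0 + 1)] * (1 - gx) * gy +
         img[idx(i0 + 1, j0 + 1)] * gx   * gy
    out[ok] <- v
  }
  out
}

#' Trilinear interpolation on a 3D array
#' @param vol numeric 3D array
#' @param pts n x 3 matrix of continuous 1-based voxel coordinates
#' @return sampled values; points outside the grid give 0
#' @keywords internal
trilinear_sample <- function(vol, pts) {
  d <- dim(vol)
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  x0 <- pmin(floor(x), d[1] - 1)
  y0 <- pmin(floor(y), d[2] - 1)
  z0 <- pmin(floor(z), d[3] - 1)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  out <- numeric(nrow(pts))
  ok <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3]
  if (any(ok)) {
    i <- x0[ok]; j <- y0[ok]; k <- z0[ok]
    gx <- fx[ok]; gy <- fy[ok]; gz <- fz[ok]
    idx <- function(i, j, k) ((k - 1) * d[2] + (j - 1)) * d[1] + i
    v <-
      vol[idx(i,     j,     k)]     * (1 - gx) * (1 - gy) * (1 - gz) +
      vol[idx(i + 1, j,     k)]     * gx       * (1 - gy) * (1 - gz) +
      vol[idx(i,     j + 1, k)]     * (1 - gx) * gy       * (1 - gz) +
      vol[idx(i + 1, j + 1, k)]     * gx       * gy       * (1 - gz) +
      vol[idx(i,     j,     k + 1)] * (1 - gx) * (1 - gy) * gz +
      vol[idx(i + 1, j,     k + 1)] * gx       * (1 - gy) * gz +
      vol[idx(i,     j + 1, k + 1)] * (1 - gx) * gy       * gz +
      vol[idx(i + 1, j + 1, k + 1)] * gx       * gy       * gz
    out[ok] <- v
  }
  out
}

#' Rotate (and shift) a 2D image about its center
#'
#' The output is the input rotated counter-clockwise by `angle_deg` (x toward
#' y for positive angles), then shifted by `shift_px` pixels; resampling is
#' bilinear, out-of-frame pixels are 0.
#' @param img numeric matrix
#' @param angle_deg rotation in degrees, counter-clockwise
#' @param shift_px length-2 translation of the rotated image, in pixels
#' @return rotated matrix of the same dimension
#' @export
rotate_image <- function(img, angle_deg, shift_px = c(0, 0)) {
  nx <- nrow(img); ny <- ncol(img)
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  th <- angle_deg * pi / 180
  co <- cos(th); si <- sin(th)
  g <- expand.grid(i = seq_len(nx), j = seq_len(ny))
  # inverse map: source = R(-angle) %*% (dest - shift - c)
  dx <- g$i - cx - shift_px[1]
  dy <- g$j - cy - shift_px[2]
  sx <- co * dx + si * dy + cx
  sy <- -si * dx + co * dy + cy
  matrix(bilinear_sample(img, sx, sy), nx, ny)
}

# Exact image transforms used inside 2D classification: 180-degree rotation
# is an index reversal, integer shifts are pad/crop, so members enter class
# averages without interpolation loss.
shift_int <- function(img, sx, sy) {
  nx <- nrow(img); ny <- ncol(img)
  out <- matrix(0, nx, ny)
  xs <- intersect(seq_len(nx), seq_len(nx) + sx)
  ys <- intersect(seq_len(ny), seq_len(ny) + sy)
  out[xs, ys] <- img[xs - sx, ys - sy]
  out
}

rot180 <- function(img) img[rev(seq_len(nrow(img))), rev(seq_len(ncol(img)))]

#' Rotation matrix about an arbitrary axis
#' @param axis length-3 vector (need not be unit)
#' @param angle_deg rotation angle, degrees, right-handed about `axis`
#' @return 3x3 rotation matrix
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  n <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, n[3], -n[2], -n[3], 0, n[1], n[2], -n[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rotation taking a unit vector onto +z
#' @param n length-3 vector
#' @return 3x3 rotation matrix R with R %*% n ~ c(0,0,|n|)
#' @keywords internal
rotation_to_z <- function(n) {
  n <- n / sqrt(sum(n^2))
  z <- c(0, 0, 1)
  c_ <- sum(n * z)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) return(diag(c(1, -1, -1)))  # 180 deg about x
  ax <- c(n[2] * z[3] - n[3] * z[2],
          n[3] * z[1] - n[1] * z[3],
          n[1] * z[2] - n[2] * z[1])
  rotation_about_axis(ax, acos(c_) * 180 / pi)
}

# Orthonormal basis perpendicular to a unit vector u.
perp_basis <- function(u) {
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

#' Add isotropic Gaussian blobs to a 3D density grid
#'
#' Separable rasterization: each blob touches only voxels within
#' `cutoff` standard deviations, added as an outer product of 1D Gaussians.
#' @param vol 3D array to accumulate into
#' @param centers n x 3 matrix of blob centers (nm, grid frame)
#' @param sigma blob standard deviations (nm), scalar or length n
#' @param weight blob amplitudes, scalar or length n
#' @param pixel_size nm per voxel
#' @param origin nm position of voxel (1,1,1)
#' @param cutoff truncation radius in standard deviations
#' @return the accumulated array
#' @keywords internal
rasterize_gaussians <- function(vol, centers, sigma, weight, pixel_size,
                                origin = c(0, 0, 0), cutoff = 3.5) {
  d <- dim(vol)
  n <- nrow(centers)
  sigma <- rep_len(sigma, n)
  weight <- rep_len(weight, n)
  for (b in seq_len(n)) {
    c_vox <- (centers[b, ] - origin) / pixel_size + 1  # continuous 1-based
    r_vox <- cutoff * sigma[b] / pixel_size
    lo <- pmax(ceiling(c_vox - r_vox), 1)
    hi <- pmin(floor(c_vox + r_vox), d)
    if (any(lo > hi)) next
    ax <- lapply(1:3, function(a) {
      t <- (seq(lo[a], hi[a]) - c_vox[a]) * pixel_size
      exp(-t^2 / (2 * sigma[b]^2))
    })
    vol[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
      vol[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE] +
      weight[b] * (ax[[1]] %o% ax[[2]] %o% ax[[3]])
  }
  vol
}

# Separable Gaussian smoothing of a 3D array via shifted copies
# (kernel truncated at 3 sigma); sigma in voxels.
gaussian_smooth3 <- function(vol, sigma_vox) {
  r <- max(1L, ceiling(3 * sigma_vox))
  w <- exp(-(-r:r)^2 / (2 * sigma_vox^2))
  w <- w / sum(w)
  for (axis in 1:3) {
    acc <- array(0, dim(vol))
    n <- dim(vol)[axis]
    for (s in -r:r) {
      src <- seq_len(n) - s
      ok <- src >= 1 & src <= n
      if (!any(ok)) next
      dst <- seq_len(n)[ok]; src <- src[ok]
      if (axis == 1) acc[dst, , ] <- acc[dst, , ] + w[s + r + 1] * vol[src, , ]
      else if (axis == 2) acc[, dst, ] <- acc[, dst, ] + w[s + r + 1] * vol[, src, ]
      else acc[, , dst] <- acc[, , dst] + w[s + r + 1] * vol[, , src]
    }
    vol <- acc
  }
  vol
}

# Derive a stream of sub-seeds from one integer seed, kept below 2^31.
derive_seeds <- function(seed, n, salt = 0L) {
  (as.integer(seed) * 1000L + salt * 101L + seq_len(n) * 7L) %% 2147483629L
}
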