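# Simplified 3D averaging of aligned segments with optional helical
# symmetrization, and half-set Fourier shell correlation. Direct real-space
# averaging of pre-oriented boxes stands in for regularized-likelihood
# refinement: the orientations come from the 2D classification step
# (in-plane angle + 180-degree rotation + polarity flip + shift).

# Resample a cubic box under out = M x + shift (centered voxel coordinates,
# px units); trilinear, outside -> 0.
resample_affine <- function(box, M, shift_px = c(0, 0, 0)) {
  d <- dim(box)
  ctr <- (d + 1) / 2
  g <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]), k = seq_len(d[3]))
  q <- cbind(g$i - ctr[1] - shift_px[1],
             g$j - ctr[2] - shift_px[2],
             g$k - ctr[3] - shift_px[3])
  src <- q %*% M  # (M^-1 q)^T = q^T M for rotation matrices
  src <- sweep(src, 2, ctr, "+")
  array(trilinear_sample(box, src), d)
}

#' Average aligned subvolumes into a common frame
#'
#' Each box is rotated about z by its in-plane angle (plus 180 degrees for
#' members aligned with the extra in-plane rotation), shifted, and -- for
#' members whose polarity vote is -1 -- rotated 180 degrees about y so all
#' barbed ends point to +x; the transformed boxes are voxel-averaged. With
#' helical parameters the average is additionally symmetrized.
#' @param boxes list of equal-size cubic arrays
#' @param orientations data.frame with columns `inplane` (degrees), `flip`
#'   (logical), `sx`, `sy` (pixels); NULL for identity
#' @param helical optional [helical_params()] for symmetrization
#' @param pixel_size nm per voxel (required when `helical` given)
#' @return 3D array
#' @export
average_aligned <- function(boxes, orientations = NULL, helical = NULL,
                            pixel_size = NULL) {
  if (!length(boxes)) stop("empty input", call. = FALSE)
  n <- length(boxes)
  if (is.null(orientations))
    orientations <- data.frame(inplane = numeric(n), flip = logical(n),
                               sx = numeric(n), sy = numeric(n))
  acc <- array(0, dim(boxes[[1]]))
  flip_y <- diag(c(-1, 1, -1))  # 180 degrees about y
  for (i in seq_len(n)) {
    M <- rotation_about_axis(c(0, 0, 1), orientations$inplane[i])
    sh <- c(-orientations$sx[i], -orientations$sy[i], 0)
    if (orientations$flip[i]) {
      M <- flip_y %*% M
      sh <- as.vector(flip_y %*% sh)
    }
    ident <- isTRUE(all.equal(M, diag(3))) && all(sh == 0)
    acc <- acc + if (ident) boxes[[i]] else resample_affine(boxes[[i]], t(M), sh)
  }
  avg <- acc / n
  if (!is.null(helical)) {
    if (is.null(pixel_size)) stop("pixel_size required for symmetrization",
                                  call. = FALSE)
    avg <- helical_symmetrize(avg, helical, pixel_size)
  }
  avg
}

#' Helical symmetrization of a volume
#'
#' Averages the volume over applications of the helical operator (translate
#' j * rise along x, rotate j * twist about x) for every j in `ops`.
#' @param vol cubic 3D array, filament axis along x through the center
#' @param params a [helical_params()]
#' @param pixel_size nm per voxel
#' @param ops integer operator indices (default j = -3..3)
#' @return symmetrized array
#' @export
helical_symmetrize <- function(vol, params, pixel_size, ops = -3:3) {
  acc <- array(0, dim(vol))
  rise_px <- params$rise / 10 / pixel_size
  for (j in ops) {
    if (j == 0) { acc <- acc + vol; next }
    M <- rotation_about_axis(c(1, 0, 0), j * params$twist)
    acc <- acc + resample_affine(vol, t(M), c(j * rise_px, 0, 0))
  }
  acc / length(ops)
}

#' Fourier shell correlation between two volumes
#'
#' A soft spherical mask (raised cosine out to 0.9 of the box half-width)
#' is applied to both volumes, then the Pearson correlation of Fourier
#' coefficients is computed per spherical shell of one Fourier-voxel width.
#' Resolutions are read where the curve first crosses 0.5 and 0.143,
#' linearly interpolated between shells; a curve that never crosses is
#' flagged `beyond_nyquist`.
#' @param a,b equal-size cubic arrays
#' @param pixel_size nm per voxel
#' @param apply_mask apply the soft spherical mask
#' @return object of class `fsc_curve`: data.frame-like list with
#'   `shell_frequencies` (1/nm), `correlations`, `resolution_at_05`,
#'   `resolution_at_0143` (Angstrom, NA when beyond Nyquist),
#'   `beyond_nyquist` flags
#' @export
fsc_curve <- function(a, b, pixel_size = 1, apply_mask = TRUE) {
  stopifnot(all(dim(a) == dim(b)))
  n <- dim(a)[1]
  if (apply_mask) {
    m <- .soft_sphere_mask(dim(a))
    a <- a * m; b <- b * m
  }
  A <- stats::fft(a); B <- stats::fft(b)
  kx <- fft_freq(dim(a)[1]); ky <- fft_freq(dim(a)[2]); kz <- fft_freq(dim(a)[3])
  r <- sqrt(outer(outer(kx^2, ky^2, "+"), kz^2, "+"))
  shell <- round(r)
  smax <- floor(n / 2)
  sel <- shell <= smax & shell >= 1
  sh <- shell[sel]
  cross <- tapply(Re(A[sel] * Conj(B[sel])), sh, sum)
  pa <- tapply(Mod(A[sel])^2, sh, sum)
  pb <- tapply(Mod(B[sel])^2, sh, sum)
  corr <- as.vector(cross / sqrt(pa * pb))
  corr[!is.finite(corr)] <- 0
  s <- as.integer(names(cross))
  freq <- s / (n * pixel_size)
  nvox <- as.vector(tapply(sh, sh, length))
  res_at <- function(thr) {
    below <- which(corr < thr)
    if (!length(below)) return(list(res = NA_real_, beyond = TRUE))
    i <- below[1]
    if (i == 1) return(list(res = Inf, beyond = FALSE))  # uncorrelated at once
    f <- freq[i - 1] + (corr[i - 1] - thr) / (corr[i - 1] - corr[i]) *
      (freq[i] - freq[i - 1])
    list(res = 10 / f, beyond = FALSE)
  }
  r05 <- res_at(0.5); r0143 <- res_at(0.143)
  structure(list(shell = s, shell_frequencies = freq, correlations = corr,
                 n_shell_voxels = nvox,
                 resolution_at_05 = r05$res, resolution_at_0143 = r0143$res,
                 beyond_nyquist = c(`0.5` = r05$beyond,
                                    `0.143` = r0143$beyond),
                 pixel_size = pixel_size),
            class = "fsc_curve")
}

#' @export
print.fsc_curve <- function(x, ...) {
  cat(sprintf("<fsc_curve> %d shells to %.3f 1/nm; FSC=0.5 at %s A, FSC=0.143 at %s A\n",
              length(x$shell), max(x$shell_frequencies),
              if (x$beyond_nyquist[1]) "beyond Nyquist" else
                sprintf("%.1f", x$resolution_at_05),
              if (x$beyond_nyquist[2]) "beyond Nyquist" else
                sprintf("%.1f", x$resolution_at_0143)))
  invisible(x)
}

.soft_sphere_mask <- function(d) {
  ctr <- (d + 1) / 2
  rmax <- 0.9 * min(d) / 2
  r0 <- 0.7 * min(d) / 2
  g <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]), k = seq_len(d[3]))
  r <- sqrt((g$i - ctr[1])^2 + (g$j - ctr[2])^2 + (g$k - ctr[3])^2)
  w <- numeric(length(r))
  w[r <= r0] <- 1
  ramp <- r > r0 & r < rmax
  w[ramp] <- 0.5 * (1 + cos(pi * (r[ramp] - r0) / (rmax - r0)))
  array(w, d)
}

#' Gold-standard half-set FSC of aligned subvolumes
#'
#' Randomly splits the stack in two (seeded), averages each half
#' independently and returns their [fsc_curve()].
#' @param boxes list of >= 2 cubic arrays
#' @param orientations as in [average_aligned()]
#' @param seed RNG seed for the split
#' @param pixel_size nm per voxel
#' @param helical optional [helical_params()] applied to both half-averages
#' @return an `fsc_curve`
#' @export
split_half_fsc <- function(boxes, orientations = NULL, seed = 1,
                           pixel_size = 1, helical = NULL) {
  n <- length(boxes)
  if (n < 2) stop("need >= 2 subvolumes for a half-set FSC", call. = FALSE)
  if (is.null(orientations))
    orientations <- data.frame(inplane = numeric(n), flip = logical(n),
                               sx = numeric(n), sy = numeric(n))
  half <- withr::with_seed(seed, sample(n, floor(n / 2)))
  a <- average_aligned(boxes[half], orientations[half, , drop = FALSE],
                       helical, pixel_size)
  b <- average_aligned(boxes[-half], orientations[-half, , drop = FALSE],
                       helical, pixel_size)
  fsc_curve(a, b, pixel_size)
}
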