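# Helical actin model: subunit lattice generation and density rasterization.
#
# Actin is modelled as a 1-start helix with a 27.6 Angstrom rise and a
# left-handed 166.7 degree twist per subunit. Each subunit is rendered as a
# short chain of Gaussian lobes along a direction tilted away from the
# filament axis (a chevron), leaning toward the barbed end at its outer
# edge. The tilt matters: a helix of purely isotropic blobs projects to a
# point pattern that is closed under axial flip combined with an azimuthal
# phase shift, i.e. its 2D projection carries no polarity information at
# all. Polarity in projection lives entirely in the correlation between a
# subunit's axial and radial internal structure -- the tilted-monomer
# asymmetry that makes real actin class averages arrowhead-like.

#' Helical lattice parameters
#'
#' @param rise axial translation per subunit, Angstrom (> 0)
#' @param twist rotation per subunit, degrees, signed; negative = left-handed
#'   (the actin convention used by default)
#' @param subunit_radius distance of the subunit center from the filament
#'   axis, nm
#' @param subunit_sigma width (standard deviation) of each subunit lobe, nm
#' @param subunit_tilt tilt of the subunit's long axis away from the
#'   filament axis toward the radial direction, degrees; the outer end
#'   leans toward the barbed end
#' @param subunit_length end-to-end extent of the subunit lobe chain, nm
#' @param n_lobes Gaussian lobes per subunit
#' @return object of class `helical_params`
#' @export
helical_params <- function(rise = 27.6, twist = -166.7,
                           subunit_radius = 1.8, subunit_sigma = 0.65,
                           subunit_tilt = 55, subunit_length = 3.0,
                           n_lobes = 5L) {
  if (rise <= 0) stop("helical rise must be > 0", call. = FALSE)
  if (abs(twist) <= 0 || abs(twist) > 180)
    stop("|twist| must lie in (0, 180]", call. = FALSE)
  if (subunit_radius < 0) stop("subunit_radius must be >= 0", call. = FALSE)
  structure(list(rise = rise, twist = twist,
                 subunit_radius = subunit_radius,
                 subunit_sigma = subunit_sigma,
                 subunit_tilt = subunit_tilt,
                 subunit_length = subunit_length,
                 n_lobes = as.integer(n_lobes)),
            class = "helical_params")
}

#' Gaussian-lobe decomposition of a helical filament
#'
#' Subunit k (k = 0, 1, ...) is centered at axial position k * rise,
#' azimuth phase + k * twist, radius `subunit_radius`; its lobes are spread
#' along the tilted subunit axis (axial component toward the barbed end
#' pairs with the outward radial component). A filament shorter than one
#' rise has exactly one subunit, at the origin.
#'
#' @param params a [helical_params()]
#' @param length filament length, nm (>= 0)
#' @param origin nm position of subunit 0
#' @param axis barbed-end direction (unit vector; normalized internally)
#' @param phase azimuthal phase of subunit 0, degrees
#' @return list with `subunits` (n x 3 matrix of subunit centers) and
#'   `lobes` (data.frame x, y, z, sigma, weight of every Gaussian lobe)
#' @export
helix_lobes <- function(params, length, origin = c(0, 0, 0),
                        axis = c(1, 0, 0), phase = 0) {
  stopifnot(inherits(params, "helical_params"))
  if (length < 0) stop("length must be >= 0", call. = FALSE)
  u <- axis / sqrt(sum(axis^2))
  b <- perp_basis(u)
  rise_nm <- params$rise / 10
  n_sub <- max(1L, floor(length / rise_nm) + 1L)
  if (length < rise_nm) n_sub <- 1L
  k <- seq_len(n_sub) - 1L
  phi <- (phase + k * params$twist) * pi / 180
  radial <- outer(cos(phi), b$e1) + outer(sin(phi), b$e2)
  centers <- matrix(origin, n_sub, 3, byrow = TRUE) +
    outer(k * rise_nm, u) + params$subunit_radius * radial
  ct <- cos(params$subunit_tilt * pi / 180)
  st <- sin(params$subunit_tilt * pi / 180)
  m_off <- seq(-0.5, 0.5, length.out = params$n_lobes) * params$subunit_length
  lobes <- NULL
  for (m in m_off) {
    # subunit direction: ct * barbed-axis + st * outward radial
    p <- centers + m * (ct * matrix(u, n_sub, 3, byrow = TRUE) + st * radial)
    lobes <- rbind(lobes, p)
  }
  lobes <- data.frame(x = lobes[, 1], y = lobes[, 2], z = lobes[, 3],
                      sigma = params$subunit_sigma, weight = 1)
  list(subunits = centers, lobes = lobes)
}

#' Rasterize a noise-free helical filament into a volume
#'
#' @param params a [helical_params()]
#' @param length filament length along the axis, nm
#' @param pixel_size nm per voxel (> 0)
#' @param pad clearance added around the filament, nm
#' @param phase azimuthal phase of subunit 0, degrees
#' @return list with `volume` (a [tomogram_volume()], filament along +x,
#'   barbed end toward +x) and `subunit_coords` (n x 3 matrix, nm, in the
#'   volume frame)
#' @export
build_actin_density <- function(params, length, pixel_size, pad = 6,
                                phase = 0) {
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be positive", call. = FALSE)
  geom <- helix_lobes(params, length, axis = c(1, 0, 0), phase = phase)
  r_max <- params$subunit_radius +
    params$subunit_length / 2 * sin(params$subunit_tilt * pi / 180) + pad
  ax_len <- max(geom$subunits[, 1]) + 2 * pad
  d <- c(ceiling(ax_len / pixel_size) + 1,
         rep(2 * ceiling(r_max / pixel_size) + 1, 2))
  origin <- c(-pad, -r_max, -r_max)
  vol <- array(0, d)
  vol <- rasterize_gaussians(vol, as.matrix(geom$lobes[, c("x", "y", "z")]),
                             geom$lobes$sigma, geom$lobes$weight,
                             pixel_size, origin)
  list(volume = tomogram_volume(vol, pixel_size, origin = origin),
       subunit_coords = geom$subunits)
}

#' Axial density profile of a noise-free filament
#'
#' Line projection of the lobe decomposition onto the filament axis: the
#' projection of an isotropic 3D Gaussian of weight w and width sigma is
#' w * (2 pi sigma^2) * exp(-t^2 / (2 sigma^2)). Sampled on a fine axial
#' grid, this is the oracle for the helical repeat.
#' @param params a [helical_params()]
#' @param length filament length, nm
#' @param sampling axial step, nm (default 0.05 nm = 0.5 Angstrom)
#' @return data.frame with `t` (nm along the axis) and `density`
#' @export
axial_density_profile <- function(params, length, sampling = 0.05) {
  geom <- helix_lobes(params, length)
  t <- seq(-3, length + 3, by = sampling)
  dens <- numeric(length(t))
  for (i in seq_len(nrow(geom$lobes))) {
    s <- geom$lobes$sigma[i]
    w <- geom$lobes$weight[i] * 2 * pi * s^2
    dens <- dens + w * exp(-(t - geom$lobes$x[i])^2 / (2 * s^2))
  }
  data.frame(t = t, density = dens)
}

#' First off-origin peak of the axial autocorrelation
#'
#' Locates the helical repeat: the lag (> 0) of the first local maximum of
#' the mean-subtracted autocorrelation of the axial density profile.
#' @param params a [helical_params()]
#' @param length filament length, nm (default 100)
#' @param sampling axial sampling of the profile, nm
#' @return peak lag in Angstrom
#' @export
axial_autocorr_peak <- function(params, length = 100, sampling = 0.05) {
  prof <- axial_density_profile(params, length, sampling)
  x <- prof$density - mean(prof$density)
  n <- length(x)
  # full linear autocorrelation via zero-padded FFT
  m <- 2^ceiling(log2(2 * n))
  X <- stats::fft(c(x, numeric(m - n)))
  ac <- Re(stats::fft(X * Conj(X), inverse = TRUE))[1:n] / m
  # first local maximum after the origin peak has decayed
  dac <- diff(ac)
  rising <- which(dac > 0)
  if (!length(rising)) stop("no off-origin autocorrelation peak", call. = FALSE)
  i0 <- rising[1]
  peaks <- which(diff(sign(dac)) < 0) + 1  # local maxima indices into ac
  peaks <- peaks[peaks > i0]
  if (!length(peaks)) stop("no off-origin autocorrelation peak", call. = FALSE)
  (peaks[1] - 1) * sampling * 10  # lag index -> nm -> Angstrom
}
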