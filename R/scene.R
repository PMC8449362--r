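# Synthetic pseudopodium scenes with full ground truth: helical actin
# filaments of assigned polarity bundled inside a capped membrane tube
# resting on a support film, optional receptor densities on the outer
# leaflet, additive Gaussian noise and a single-axis missing wedge.
#
# Geometry: the tube axis runs along x at the y-center of the volume, at
# height support_z + tube_radius; the protrusion tip (hemispherical cap) is
# at +x, the cell body side (open end) at x = 0. The beam axis is z and the
# tilt axis is y, so the missing wedge lives in the (kx, kz) plane.

#' Scene specification for the synthetic pseudopodium generator
#'
#' Defaults are the desk-scale study conditions: 256 x 256 x 128 voxels at
#' 1.1 nm/voxel, 20 filaments per scene, a 74% tip-ward polarity
#' composition, a 50-nm-radius membrane tube, +/-60 degrees tilt range.
#'
#' @param volume_shape voxels per axis, length 3
#' @param pixel_size nm per voxel
#' @param n_filaments filaments per scene
#' @param length_range min/max filament length, nm
#' @param tip_fraction probability that a filament's barbed end points
#'   tip-ward, in \[0, 1\]
#' @param tube_radius membrane tube radius (mid-surface), nm
#' @param tube_length axial length of the cylindrical part up to the cap
#'   center, nm (default 85% of the x extent)
#' @param support_z height of the support plane, nm
#' @param receptor_count receptor densities placed on the outer leaflet
#' @param receptor_height total receptor height above the outer leaflet, nm
#' @param receptor_band placement band of heights above the support, nm pair
#' @param noise_sigma additive Gaussian noise SD relative to the filament
#'   peak density
#' @param tilt_range one-sided tilt range, degrees, in (0, 90]
#' @param seed RNG seed for the whole scene
#' @param helical a [helical_params()]
#' @param max_tilt_deg maximum in-plane filament deviation from the tube
#'   axis, degrees
#' @param max_z_tilt maximum filament tilt out of the support plane,
#'   degrees (spread protrusions are flat; bundled actin runs nearly
#'   parallel to the support)
#' @param min_filament_sep minimum distance between filament axes, nm
#' @param tip_sign +1 (tip at +x) or -1
#' @param membrane_weight amplitude of each bilayer leaflet sheet
#' @param support_weight amplitude of the support film sheet
#' @return object of class `scene_spec`
#' @export
scene_spec <- function(volume_shape = c(256, 256, 128), pixel_size = 1.1,
                       n_filaments = 20, length_range = c(80, 200),
                       tip_fraction = 0.74, tube_radius = 50,
                       tube_length = NULL, support_z = 8,
                       receptor_count = 0, receptor_height = 12,
                       receptor_band = c(50, 70), noise_sigma = 0.3,
                       tilt_range = 60, seed = 1,
                       helical = helical_params(), max_tilt_deg = 12,
                       max_z_tilt = 4, min_filament_sep = 10, tip_sign = 1,
                       membrane_weight = 1, support_weight = 0.5) {
  if (pixel_size <= 0) stop("pixel_size must be > 0", call. = FALSE)
  if (tip_fraction < 0 || tip_fraction > 1)
    stop("tip_fraction must lie in [0, 1]", call. = FALSE)
  if (tilt_range <= 0 || tilt_range > 90)
    stop("tilt_range must lie in (0, 90]", call. = FALSE)
  if (is.null(tube_length)) tube_length <- 0.85 * volume_shape[1] * pixel_size
  structure(as.list(environment()), class = "scene_spec")
}

# Membrane mid-surface geometry: capped cylinder along x.
.tube_geom <- function(spec) {
  list(yc = (spec$volume_shape[2] - 1) * spec$pixel_size / 2,
       zc = spec$support_z + spec$tube_radius,
       R = spec$tube_radius,
       cap_x = spec$tube_length)
}

# Signed distance (nm) from points (n x 3) to the tube mid-surface
# (negative inside).
.tube_signed_dist <- function(pts, geom) {
  rho <- sqrt((pts[, 2] - geom$yc)^2 + (pts[, 3] - geom$zc)^2)
  d <- rho - geom$R
  cap <- pts[, 1] > geom$cap_x
  if (any(cap)) {
    d[cap] <- sqrt(rho[cap]^2 + (pts[cap, 1] - geom$cap_x)^2) - geom$R
  }
  d
}

#' Place filaments with ground-truth polarity inside the membrane tube
#'
#' Straight centerlines tilted at most `max_tilt_deg` from the tube axis,
#' kept `min_filament_sep` nm apart; each barbed end is drawn tip-ward with
#' probability `tip_fraction`. The stored point order is randomized
#' independently of polarity, so downstream code cannot read polarity from
#' the trace direction.
#' @param spec a [scene_spec()]
#' @param seed RNG seed (default derived from `spec$seed`)
#' @return list of [filament_trace()] objects
#' @export
place_filaments <- function(spec, seed = derive_seeds(spec$seed, 1, salt = 1L)) {
  geom <- .tube_geom(spec)
  margin <- 6
  r_inner <- geom$R - margin
  if (r_inner < 5 || geom$cap_x < spec$length_range[1] + 10)
    stop("membrane tube too small to host a filament of minimum length",
         call. = FALSE)
  # sequential packing can wedge itself in; restart the whole placement
  # from derived seeds before declaring the tube infeasible
  for (attempt in 1:5) {
    out <- .place_filaments_once(spec, geom, margin, r_inner,
                                 (seed + (attempt - 1L) * 999983L) %%
                                   2147483629L)
    if (!is.null(out)) return(out)
  }
  stop("filament placement failed after bounded retries; ",
       "tube too crowded or too small", call. = FALSE)
}

.place_filaments_once <- function(spec, geom, margin, r_inner, seed) {
  withr::with_seed(seed, {
    traces <- vector("list", spec$n_filaments)
    accepted <- NULL  # sampled points of accepted traces, for separation
    for (f in seq_len(spec$n_filaments)) {
      placed <- FALSE
      for (try in 1:1000) {
        L <- stats::runif(1, spec$length_range[1], spec$length_range[2])
        th <- stats::runif(1, -spec$max_tilt_deg, spec$max_tilt_deg) * pi / 180
        ze <- stats::runif(1, -spec$max_z_tilt, spec$max_z_tilt) * pi / 180
        dir <- c(cos(th) * cos(ze), sin(th) * cos(ze), sin(ze))
        r_mid <- sqrt(stats::runif(1)) * max(r_inner - 4, 1)
        psi <- stats::runif(1, 0, 2 * pi)
        mid <- c(stats::runif(1, L / 2 + 8, geom$cap_x - L / 2 - 8),
                 geom$yc + r_mid * cos(psi), geom$zc + r_mid * sin(psi))
        p0 <- mid - L / 2 * dir
        p1 <- mid + L / 2 * dir
        ends <- rbind(p0, p1)
        if (any(.tube_signed_dist(ends, geom) > -margin)) next
        samp <- seq(0, 1, length.out = max(2, ceiling(L / 5)))
        pts <- cbind(p0[1] + samp * (p1[1] - p0[1]),
                     p0[2] + samp * (p1[2] - p0[2]),
                     p0[3] + samp * (p1[3] - p0[3]))
        if (!is.null(accepted)) {
          dmin <- min(sqrt(outer(pts[, 1], accepted[, 1], "-")^2 +
                           outer(pts[, 2], accepted[, 2], "-")^2 +
                           outer(pts[, 3], accepted[, 3], "-")^2))
          if (dmin < spec$min_filament_sep) next
        }
        placed <- TRUE
        break
      }
      if (!placed) return(NULL)
      accepted <- rbind(accepted, pts)
      tip_ward <- stats::runif(1) < spec$tip_fraction
      # dir has a positive x component; barbed end along +/- dir
      barbed_sign <- if (tip_ward) spec$tip_sign else -spec$tip_sign
      # stored point order is independent of polarity
      flip_order <- stats::runif(1) < 0.5
      step <- 4  # nm between stored polyline points
      s <- seq(0, L, by = step)
      if (s[length(s)] < L - 1e-9) s <- c(s, L)
      poly <- cbind(p0[1] + s * dir[1], p0[2] + s * dir[2], p0[3] + s * dir[3])
      if (flip_order) poly <- poly[rev(seq_len(nrow(poly))), ]
      order_sign <- if (flip_order) -1 else 1  # point order vs dir
      true_polarity <- as.integer(barbed_sign * order_sign)
      traces[[f]] <- filament_trace(
        filament_id = f, points = poly, true_polarity = true_polarity,
        barbed_dir = barbed_sign * dir, phase = stats::runif(1, 0, 360))
    }
    traces
  })
}

# Rasterize all filaments of a scene; returns the density array and the
# filament peak density (the noise amplitude reference).
render_filaments <- function(spec, traces) {
  vol <- array(0, spec$volume_shape)
  for (tr in traces) {
    n <- nrow(tr$points)
    # straight synthetic traces: axis from endpoints, origin at pointed end
    dirv <- tr$points[n, ] - tr$points[1, ]
    L <- sqrt(sum(dirv^2))
    dirv <- dirv / L
    axis <- tr$true_polarity * dirv        # barbed-end direction
    origin <- if (tr$true_polarity > 0) tr$points[1, ] else tr$points[n, ]
    geom <- helix_lobes(spec$helical, L, origin = origin, axis = axis,
                        phase = if (is.null(tr$phase)) 0 else tr$phase)
    vol <- rasterize_gaussians(vol, as.matrix(geom$lobes[, c("x", "y", "z")]),
                               geom$lobes$sigma, geom$lobes$weight,
                               spec$pixel_size)
  }
  list(volume = vol, peak = if (length(traces)) max(vol) else NA_real_)
}

#' Render the membrane tube and place receptor densities
#'
#' The membrane is two parallel Gaussian sheets (bilayer leaflets 5 nm
#' apart, mid-surface at the tube radius); receptors are bent two-lobe
#' blobs attached to the outer leaflet along the local outward normal,
#' placed so their attachment height above the support falls inside
#' `receptor_band`, at least 10 nm apart.
#' @param spec a [scene_spec()]
#' @param seed RNG seed (default derived from `spec$seed`)
#' @return list with `density` (3D array), `placements` (data.frame:
#'   position, outward normal, height_above_support) and `geom` (tube
#'   geometry)
#' @export
place_membrane_and_receptors <- function(spec,
                                         seed = derive_seeds(spec$seed, 1,
                                                             salt = 2L)) {
  geom <- .tube_geom(spec)
  d <- spec$volume_shape
  px <- spec$pixel_size
  leaflet_half_sep <- 2.5   # nm: leaflets at mid-surface +/- 2.5
  sigma_mem <- 1.0
  # signed distance field to the mid-surface, built slice-wise in x
  xs <- (seq_len(d[1]) - 1) * px
  ys <- (seq_len(d[2]) - 1) * px
  zs <- (seq_len(d[3]) - 1) * px
  rho <- sqrt(outer((ys - geom$yc)^2, (zs - geom$zc)^2, "+"))
  dens <- array(0, d)
  sheet <- function(dd) {
    exp(-(dd - leaflet_half_sep)^2 / (2 * sigma_mem^2)) +
      exp(-(dd + leaflet_half_sep)^2 / (2 * sigma_mem^2))
  }
  cyl_sheet <- sheet(rho - geom$R)   # cylinder part, same for every x slice
  cyl_sheet[abs(rho - geom$R) > 6] <- 0
  for (i in seq_len(d[1])) {
    if (xs[i] <= geom$cap_x) {
      dens[i, , ] <- cyl_sheet
    } else {
      dd <- sqrt(rho^2 + (xs[i] - geom$cap_x)^2) - geom$R
      s <- sheet(dd)
      s[abs(dd) > 6] <- 0
      dens[i, , ] <- s
    }
  }
  dens <- dens * spec$membrane_weight
  # support film: thin sheet at z = support_z
  if (spec$support_weight > 0) {
    sup <- spec$support_weight * exp(-(zs - spec$support_z)^2 / (2 * 1.5^2))
    dens <- dens + rep(sup, each = d[1] * d[2])
  }
  membrane_peak <- max(dens)
  # receptor placements on the outer leaflet of the cylinder part
  placements <- NULL
  if (spec$receptor_count > 0) {
    R_out <- geom$R + leaflet_half_sep
    s_lo <- (spec$receptor_band[1] - geom$R + spec$support_z * 0) / R_out
    s_lo <- (spec$receptor_band[1] - (geom$zc - spec$support_z)) / R_out
    s_hi <- (spec$receptor_band[2] - (geom$zc - spec$support_z)) / R_out
    s_lo <- max(-1, s_lo); s_hi <- min(1, s_hi)
    if (s_lo >= s_hi)
      stop("receptor height band has no intersection with the membrane surface",
           call. = FALSE)
    g_lo <- asin(s_lo); g_hi <- asin(s_hi)
    x_lo <- 8; x_hi <- geom$cap_x - 8
    withr::with_seed(seed, {
      pos <- matrix(NA_real_, 0, 3); nrm <- matrix(NA_real_, 0, 3)
      bend_az <- numeric(0)
      tries <- 0
      while (nrow(pos) < spec$receptor_count) {
        tries <- tries + 1
        if (tries > 200 * spec$receptor_count)
          stop("requested receptor count exceeds available surface sites",
               call. = FALSE)
        gam <- stats::runif(1, g_lo, g_hi)
        if (stats::runif(1) < 0.5) gam <- pi - gam  # other side of the tube
        xpos <- stats::runif(1, x_lo, x_hi)
        n <- c(0, cos(gam), sin(gam))
        p <- c(xpos, geom$yc + R_out * cos(gam), geom$zc + R_out * sin(gam))
        if (p[3] + spec$receptor_height + 5 > (d[3] - 1) * px) next
        if (nrow(pos) &&
            min(sqrt(rowSums(sweep(pos, 2, p)^2))) < 10) next
        pos <- rbind(pos, p); nrm <- rbind(nrm, n)
        bend_az <- c(bend_az, stats::runif(1, 0, 2 * pi))
      }
      lob <- receptor_lobes(pos, nrm, bend_az, spec$receptor_height)
      dens <- rasterize_gaussians(dens, as.matrix(lob[, c("x", "y", "z")]),
                                  lob$sigma, lob$weight, px)
      placements <- data.frame(
        x = pos[, 1], y = pos[, 2], z = pos[, 3],
        nx = nrm[, 1], ny = nrm[, 2], nz = nrm[, 3],
        height_above_support = pos[, 3] - spec$support_z)
    })
  }
  list(density = dens, placements = placements, geom = geom,
       membrane_peak = membrane_peak)
}

# Gaussian-lobe decomposition of bent receptors: a "legs" lobe near the
# membrane and a laterally offset "head" lobe. The head center is placed so
# that the density along the normal falls to half its extracellular peak at
# exactly `height` nm above the outer leaflet (Gaussian half-max offset
# sigma * sqrt(2 ln 2)).
receptor_lobes <- function(pos, nrm, bend_az, height,
                           sigma_head = 2.0, sigma_legs = 1.5,
                           w_head = 1.6, w_legs = 1.0, bend = 1.5) {
  head_c <- height - sigma_head * sqrt(2 * log(2))
  out <- NULL
  for (i in seq_len(nrow(pos))) {
    n <- nrm[i, ]
    b <- perp_basis(n)
    lat <- cos(bend_az[i]) * b$e1 + sin(bend_az[i]) * b$e2
    legs <- pos[i, ] + 3.2 * n
    head <- pos[i, ] + head_c * n + bend * lat
    out <- rbind(out,
                 data.frame(x = c(legs[1], head[1]), y = c(legs[2], head[2]),
                            z = c(legs[3], head[3]),
                            sigma = c(sigma_legs, sigma_head),
                            weight = c(w_legs, w_head)))
  }
  out
}

#' Logical mask of the membrane-enclosed volume
#'
#' TRUE inside the tube mid-surface; the input expected by
#' [estimate_normals()].
#' @param spec a [scene_spec()]
#' @return logical 3D array
#' @export
membrane_interior_mask <- function(spec) {
  geom <- .tube_geom(spec)
  d <- spec$volume_shape
  px <- spec$pixel_size
  xs <- (seq_len(d[1]) - 1) * px
  ys <- (seq_len(d[2]) - 1) * px
  zs <- (seq_len(d[3]) - 1) * px
  rho <- sqrt(outer((ys - geom$yc)^2, (zs - geom$zc)^2, "+"))
  mask <- array(FALSE, d)
  cyl <- rho < geom$R
  for (i in seq_len(d[1])) {
    if (xs[i] <= geom$cap_x) mask[i, , ] <- cyl
    else mask[i, , ] <- (rho^2 + (xs[i] - geom$cap_x)^2) < geom$R^2
  }
  mask
}

#' Apply the tomographic imaging model: missing wedge, then noise
#'
#' Fourier coefficients whose (kx, kz) direction lies more than `tilt_range`
#' degrees from the kx axis (tilt axis y, beam axis z) are zeroed -- the
#' single-axis missing wedge; zero-mean Gaussian noise of SD
#' `noise_sigma * noise_ref` is then added. With `noise_sigma = 0` the
#' operation is linear and idempotent.
#' @param vol a [tomogram_volume()] or 3D array
#' @param tilt_range one-sided tilt range, degrees, in (0, 90]
#' @param noise_sigma noise SD relative to `noise_ref`
#' @param noise_ref physical noise reference (default: max of `vol`)
#' @param seed RNG seed for the noise draw
#' @return same type as `vol`
#' @export
apply_imaging_model <- function(vol, tilt_range = 60, noise_sigma = 0,
                                noise_ref = NULL, seed = 1) {
  is_tomo <- inherits(vol, "tomogram_volume")
  grid <- if (is_tomo) vol$grid else vol
  px <- if (is_tomo) vol$pixel_size else 1
  if (tilt_range <= 0 || tilt_range > 90)
    stop("tilt_range must lie in (0, 90]", call. = FALSE)
  if (is.null(noise_ref)) noise_ref <- max(grid)
  d <- dim(grid)
  if (tilt_range < 90) {
    keep <- wedge_keep_mask(d[1], d[3], tilt_range, px)
    for (j in seq_len(d[2])) {
      F <- stats::fft(matrix(grid[, j, ], d[1], d[3]))
      F[!keep] <- 0
      grid[, j, ] <- Re(stats::fft(F, inverse = TRUE)) / length(F)
    }
  }
  if (noise_sigma > 0) {
    withr::with_seed(seed, {
      grid <- grid + stats::rnorm(length(grid),
                                  sd = noise_sigma * noise_ref)
    })
  }
  if (is_tomo) {
    vol$grid <- grid
    vol$tilt_range <- tilt_range
    vol
  } else grid
}

#' Sampled-region mask of the (kx, kz) Fourier plane
#'
#' TRUE where |atan2(|fz|, |fx|)| <= tilt_range, with physical frequencies
#' (accounts for nx != nz); the missing wedge is the complement.
#' @param nx,nz plane dimensions
#' @param tilt_range degrees
#' @param pixel_size nm per voxel (common to x and z)
#' @return logical nx x nz matrix in FFT index order
#' @export
wedge_keep_mask <- function(nx, nz, tilt_range, pixel_size = 1) {
  fx <- fft_freq(nx) / (nx * pixel_size)
  fz <- fft_freq(nz) / (nz * pixel_size)
  ang <- atan2(abs(rep(fz, each = nx)), abs(rep(fx, nz))) * 180 / pi
  m <- matrix(ang <= tilt_range + 1e-12, nx, nz)
  m[1, 1] <- TRUE
  m
}

#' Generate a complete synthetic scene
#'
#' Filaments + membrane (+ receptors) + support film, composited and passed
#' through the imaging model. Bit-reproducible for a fixed `spec$seed`.
#' @param spec a [scene_spec()]
#' @return list with `volume` (a [tomogram_volume()]), `truth` (traces,
#'   receptor placements, tip_axis, tube geometry, filament peak) and `spec`
#' @export
simulate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  traces <- if (spec$n_filaments > 0) place_filaments(spec) else list()
  fil <- if (spec$n_filaments > 0) render_filaments(spec, traces)
         else list(volume = array(0, spec$volume_shape), peak = NA_real_)
  mem <- place_membrane_and_receptors(spec)
  grid <- fil$volume + mem$density
  # noise scales with the filament peak; in filament-free scenes with the
  # membrane sheet amplitude (never with receptor brightness)
  noise_ref <- if (is.na(fil$peak)) mem$membrane_peak else fil$peak
  grid <- apply_imaging_model(grid, spec$tilt_range, spec$noise_sigma,
                              noise_ref = noise_ref,
                              seed = derive_seeds(spec$seed, 1, salt = 3L))
  vol <- tomogram_volume(grid, spec$pixel_size, spec$tilt_range)
  list(volume = vol,
       truth = list(traces = traces,
                    receptor_placements = mem$placements,
                    tip_axis = c(spec$tip_sign, 0, 0),
                    tube = mem$geom,
                    support_z = spec$support_z,
                    filament_peak = noise_ref),
       spec = spec)
}
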