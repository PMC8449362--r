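# Receptor pipeline: membrane normal estimation, membrane-attached density
# picking with height-above-support and normal-tilt filters, oriented
# subtomogram averaging and 3D classification, receptor height measurement,
# rigid-body map fitting, and a Monte-Carlo spatial-randomness test.

#' Estimate outward surface normals from a membrane mask
#'
#' Surface voxels are mask voxels with at least one 6-neighbor outside;
#' normals are the negated gradient of a Gaussian-smoothed copy of the mask
#' (pointing away from the enclosed volume), normalized to unit length.
#' Points with a vanishing gradient are dropped and counted.
#' @param mask logical 3D array, TRUE inside the enclosed volume
#' @param pixel_size nm per voxel
#' @param smooth_sigma smoothing width, voxels
#' @param support_z support-plane height, nm (carried as metadata)
#' @param stride keep every stride-th surface voxel per axis
#' @param downsample integer grid decimation before gradient estimation
#'   (membrane curvature radii are tens of nm, so normals survive 2x
#'   decimation; the full-resolution grid is slow to smooth)
#' @return object of class `membrane_model`: data.frame `surface`
#'   (x, y, z, nx, ny, nz in nm/unit), `support_z`, `dropped` count
#' @export
estimate_normals <- function(mask, pixel_size = 1, smooth_sigma = 2,
                             support_z = 0, stride = 1, downsample = 1) {
  if (!any(mask)) stop("empty membrane mask", call. = FALSE)
  if (downsample > 1) {
    d0 <- dim(mask)
    mask <- mask[seq(1, d0[1], by = downsample),
                 seq(1, d0[2], by = downsample),
                 seq(1, d0[3], by = downsample)]
    pixel_size <- pixel_size * downsample
  }
  d <- dim(mask)
  m <- array(0, d + 2)  # pad so boundary voxels have outside neighbors
  m[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- as.numeric(mask)
  inner <- function(a) a[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  # count 6-neighbors inside
  nb <- m[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] +
        m[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] +
        m[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] +
        m[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] +
        m[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] +
        m[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  surf <- mask & nb < 6
  sm <- gaussian_smooth3(inner(m), smooth_sigma)
  grad <- list(
    x = (cbind3(sm, 1, +1) - cbind3(sm, 1, -1)) / 2,
    y = (cbind3(sm, 2, +1) - cbind3(sm, 2, -1)) / 2,
    z = (cbind3(sm, 3, +1) - cbind3(sm, 3, -1)) / 2)
  idx <- which(surf)
  k <- (idx - 1) %/% (d[1] * d[2]) + 1
  j <- ((idx - 1) %/% d[1]) %% d[2] + 1
  i <- (idx - 1) %% d[1] + 1
  if (stride > 1) {
    keep <- i %% stride == 0 & j %% stride == 0 & k %% stride == 0
    idx <- idx[keep]; i <- i[keep]; j <- j[keep]; k <- k[keep]
  }
  g <- cbind(grad$x[idx], grad$y[idx], grad$z[idx])
  gn <- sqrt(rowSums(g^2))
  ok <- gn > 1e-9
  nrm <- -g[ok, , drop = FALSE] / gn[ok]
  pos <- cbind((i[ok] - 1), (j[ok] - 1), (k[ok] - 1)) * pixel_size
  # sub-voxel refinement: slide each point along its normal onto the 0.5
  # level of the smoothed mask (boundary voxel centers sit up to one voxel
  # inside the true surface, which would bias every downstream distance)
  tgrid <- seq(-1.5, 1.5, by = 0.25) * pixel_size
  prof <- sapply(tgrid, function(t) {
    trilinear_sample(sm, (pos + t * nrm) / pixel_size + 1)
  })
  prof <- matrix(prof, nrow(pos))
  t_ref <- vapply(seq_len(nrow(pos)), function(r) {
    v <- prof[r, ]
    cr <- which(v[-length(v)] >= 0.5 & v[-1] < 0.5)
    if (!length(cr)) return(0)
    c1 <- cr[1]
    tgrid[c1] + (v[c1] - 0.5) / (v[c1] - v[c1 + 1]) * (tgrid[2] - tgrid[1])
  }, numeric(1))
  pos <- pos + t_ref * nrm
  structure(list(
    surface = data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3],
                         nx = nrm[, 1], ny = nrm[, 2], nz = nrm[, 3]),
    support_z = support_z, dropped = sum(!ok)),
    class = "membrane_model")
}

# Shift a 3D array by +/-1 along an axis with edge clamping (central
# differences helper).
cbind3 <- function(a, axis, dir) {
  d <- dim(a)
  idx <- pmin(pmax(seq_len(d[axis]) + dir, 1), d[axis])
  switch(axis,
         a[idx, , , drop = FALSE],
         a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

#' Pick membrane-attached densities with height and tilt filters
#'
#' For every membrane surface point, the density is sampled along the
#' outward normal across `attach_band`; points whose ray maximum exceeds a
#' robust background threshold become candidates. Candidates are rejected
#' (kept = FALSE, with exactly one machine-readable reason) when the
#' membrane attachment height above the support lies outside `height_band`
#' ("height"), when the normal tilts more than `tilt_max` degrees out of
#' the x-y plane ("tilt" -- the membrane must run parallel to the beam),
#' or when a stronger filter-passing pick lies within `min_sep` nm
#' ("separation"; highest density wins). Separation suppression only
#' considers filter-passing picks, so the height/tilt filters and the
#' dedup commute.
#' @param tomo a [tomogram_volume()]
#' @param membrane a `membrane_model` from [estimate_normals()]
#' @param attach_band nm distances from the outer leaflet sampled along
#'   the normal, ordered pair
#' @param height_band kept attachment heights above the support, nm,
#'   inclusive
#' @param tilt_max maximum normal tilt from the x-y plane, degrees
#' @param min_sep minimum pick separation, nm
#' @param threshold_mad candidate threshold: median + threshold_mad * MAD
#'   of all ray maxima
#' @param surface_offset distance from the segmented mid-surface to the
#'   outer leaflet, nm (the attach band is measured beyond it, so the
#'   leaflet's own density does not flood every ray)
#' @param presmooth_sigma matched-filter smoothing of the volume before
#'   ray scoring, nm (receptor-lobe scale); 0 disables
#' @param subtract_background score each ray by its contrast (maximum
#'   minus its own median) instead of its raw maximum, cancelling the
#'   leaflet tail and the orientation-dependent diffuse background
#' @return data.frame of picks: position (x, y, z = surface point, nm),
#'   normal, `height_above_support`, `normal_tilt`, `score`, `peak_dist`
#'   (nm along the normal), `kept`, `reason` (NA when kept)
#' @export
pick_densities <- function(tomo, membrane, attach_band = c(2, 12),
                           height_band = c(50, 70), tilt_max = 20,
                           min_sep = 8, threshold_mad = 3,
                           surface_offset = 2.5, presmooth_sigma = 1.5,
                           subtract_background = TRUE) {
  stopifnot(inherits(tomo, "tomogram_volume"))
  if (attach_band[1] >= attach_band[2] || height_band[1] >= height_band[2])
    stop("bands must be well-ordered", call. = FALSE)
  s <- membrane$surface
  px <- tomo$pixel_size
  grid <- if (presmooth_sigma > 0)
    gaussian_smooth3(tomo$grid, presmooth_sigma / px) else tomo$grid
  ts <- surface_offset + seq(attach_band[1], attach_band[2], by = min(1, px))
  # ray sampling: n_surface x n_steps
  vals <- sapply(ts, function(t) {
    pts <- cbind(s$x + t * s$nx, s$y + t * s$ny, s$z + t * s$nz) / px + 1
    trilinear_sample(grid, pts)
  })
  vals <- matrix(vals, nrow(s))
  # the height/tilt-eligible points are a homogeneous background
  # population; points near the support film or the wedge-degraded tube
  # top see very different rays and would corrupt the statistics
  height_all <- s$z - membrane$support_z
  tilt_all <- asin(pmin(1, abs(s$nz))) * 180 / pi
  eligible <- height_all >= height_band[1] & height_all <= height_band[2] &
    tilt_all <= tilt_max
  if (!any(eligible)) eligible <- rep(TRUE, nrow(s))
  if (subtract_background) {
    # residual against the eligible-population median ray profile
    # (the leaflet tail common to all membrane-attached rays)
    tail_ref <- apply(vals[eligible, , drop = FALSE], 2, stats::median)
    vals <- sweep(vals, 2, tail_ref)
  }
  score <- apply(vals, 1, max)
  peak_dist <- ts[apply(vals, 1, which.max)]
  thr <- stats::median(score[eligible]) +
    threshold_mad * stats::mad(score[eligible])
  cand <- which(score > thr)
  if (!length(cand)) {
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      nx = numeric(0), ny = numeric(0), nz = numeric(0),
                      height_above_support = numeric(0),
                      normal_tilt = numeric(0), score = numeric(0),
                      peak_dist = numeric(0), kept = logical(0),
                      reason = character(0)))
  }
  p <- s[cand, ]
  p$height_above_support <- p$z - membrane$support_z
  p$normal_tilt <- asin(pmin(1, abs(p$nz))) * 180 / pi
  p$score <- score[cand]
  p$peak_dist <- peak_dist[cand]
  p$reason <- NA_character_
  bad_h <- p$height_above_support < height_band[1] |
           p$height_above_support > height_band[2]
  bad_t <- p$normal_tilt > tilt_max
  p$reason[bad_t] <- "tilt"
  p$reason[bad_h] <- "height"   # height reported when both fail
  pass <- is.na(p$reason)
  # dedup among filter-passing picks only (order-independent wrt filters)
  ord <- order(-p$score[pass])
  pass_idx <- which(pass)[ord]
  kept_idx <- integer(0)
  for (i in pass_idx) {
    if (length(kept_idx)) {
      dd <- sqrt((p$x[kept_idx] - p$x[i])^2 + (p$y[kept_idx] - p$y[i])^2 +
                 (p$z[kept_idx] - p$z[i])^2)
      if (min(dd) < min_sep) { p$reason[i] <- "separation"; next }
    }
    kept_idx <- c(kept_idx, i)
  }
  p$kept <- is.na(p$reason)
  # refine kept positions: score-weighted centroid of nearby
  # filter-passing candidates (localizes between surface sample points)
  for (i in which(p$kept)) {
    nb <- which(pass &
                (p$x - p$x[i])^2 + (p$y - p$y[i])^2 + (p$z - p$z[i])^2 <
                  (min_sep / 2)^2)
    if (length(nb) > 1) {
      w <- p$score[nb] - min(p$score[nb]) + 1e-9
      p$x[i] <- sum(w * p$x[nb]) / sum(w)
      p$y[i] <- sum(w * p$y[nb]) / sum(w)
      p$z[i] <- sum(w * p$z[nb]) / sum(w)
      nn <- c(sum(w * p$nx[nb]), sum(w * p$ny[nb]), sum(w * p$nz[nb]))
      nn <- nn / sqrt(sum(nn^2))
      p$nx[i] <- nn[1]; p$ny[i] <- nn[2]; p$nz[i] <- nn[3]
      p$height_above_support[i] <- p$z[i] - membrane$support_z
      p$normal_tilt[i] <- asin(min(1, abs(nn[3]))) * 180 / pi
    }
  }
  rownames(p) <- NULL
  p
}

#' Extract oriented subvolumes around kept picks
#' @param tomo a [tomogram_volume()]
#' @param picks data.frame from [pick_densities()] (kept rows are used)
#' @param box_edge box edge, voxels (even)
#' @param center_offset box center placed this far along the outward
#'   normal from the pick, nm (so membrane and receptor both fit)
#' @return `subvolume_stack`: list of boxes, matching normals, metadata
#' @export
extract_picks <- function(tomo, picks, box_edge = 32, center_offset = 6) {
  picks <- picks[picks$kept, , drop = FALSE]
  boxes <- list(); normals <- NULL; used <- integer(0)
  for (i in seq_len(nrow(picks))) {
    ctr <- c(picks$x[i] + center_offset * picks$nx[i],
             picks$y[i] + center_offset * picks$ny[i],
             picks$z[i] + center_offset * picks$nz[i])
    ex <- extract_subvolume(tomo, ctr, box_edge)
    if (ex$rejected) next
    boxes[[length(boxes) + 1]] <- ex$box
    normals <- rbind(normals, c(picks$nx[i], picks$ny[i], picks$nz[i]))
    used <- c(used, i)
  }
  structure(list(boxes = boxes, normals = normals, box_edge = box_edge,
                 pixel_size = tomo$pixel_size,
                 center_offset = center_offset, pick_rows = used),
            class = "subvolume_stack")
}

#' Average picks in the normal-aligned frame
#'
#' Each box is rotated so its outward normal maps to +z, then all are
#' voxel-averaged. The in-plane angle about the normal is unconstrained and
#' marginalized by the averaging, giving a cylindrically smeared initial
#' model. With `refine_shifts` each box is additionally translation-aligned
#' to the running average by FFT cross-correlation (picking localizes
#' receptors only to a few nm; without refinement that scatter smears the
#' average along every axis).
#' @param stack a `subvolume_stack`
#' @param return_aligned also return the individual aligned boxes
#' @param refine_shifts translational refinement passes (0 disables)
#' @param max_shift refinement search radius, voxels
#' @return list: `model` (3D array), optionally `aligned` (list)
#' @export
align_average <- function(stack, return_aligned = FALSE,
                          refine_shifts = 2, max_shift = 4) {
  n <- length(stack$boxes)
  if (!n) stop("empty stack", call. = FALSE)
  d <- dim(stack$boxes[[1]])
  aligned <- vector("list", n)
  for (i in seq_len(n)) {
    R <- rotation_to_z(stack$normals[i, ])
    aligned[[i]] <- if (isTRUE(all.equal(R, diag(3)))) stack$boxes[[i]]
                    else resample_affine(stack$boxes[[i]], R)
  }
  model <- Reduce(`+`, aligned) / n
  if (refine_shifts > 0) {
    ok <- function(k) abs(k) <= max_shift
    allow <- outer(outer(ok(fft_freq(d[1])), ok(fft_freq(d[2])), "&"),
                   ok(fft_freq(d[3])), "&")
    for (pass in seq_len(refine_shifts)) {
      Fm <- Conj(stats::fft(model - mean(model)))
      for (i in seq_len(n)) {
        cc <- Re(stats::fft(stats::fft(aligned[[i]] -
                                       mean(aligned[[i]])) * Fm,
                            inverse = TRUE))
        cc[!allow] <- -Inf
        sh <- arrayInd(which.max(cc), d) - 1
        sh <- ifelse(sh > d / 2, sh - d, sh)
        # cc peaks where the box equals the model displaced by +sh;
        # undo the displacement
        if (any(sh != 0))
          aligned[[i]] <- shift_int3(aligned[[i]], -sh)
      }
      model <- Reduce(`+`, aligned) / n
    }
  }
  list(model = model, aligned = if (return_aligned) aligned else NULL)
}

# integer 3D shift with zero fill: out[v] = in[v - sh]
shift_int3 <- function(a, sh) {
  d <- dim(a)
  out <- array(0, d)
  src <- lapply(1:3, function(ax) {
    dst <- seq_len(d[ax])
    s0 <- dst - sh[ax]
    ok <- s0 >= 1 & s0 <= d[ax]
    list(dst = dst[ok], src = s0[ok])
  })
  out[src[[1]]$dst, src[[2]]$dst, src[[3]]$dst] <-
    a[src[[1]]$src, src[[2]]$src, src[[3]]$src]
  out
}

#' Alignment-free 3D classification of normal-aligned picks
#'
#' k-partition by normalized cross-correlation to class averages in the
#' normal-aligned frame, restarted from several seeded initializations
#' (the partition with the highest mean within-class correlation wins);
#' the selected class is the one with the highest mean intra-class NCC
#' among classes with at least `member_floor` members.
#' @param stack a `subvolume_stack`
#' @param k classes (>= 2)
#' @param n_iter iterations per restart
#' @param seed RNG seed
#' @param member_floor minimum population of a selectable class
#' @param n_starts independent initializations
#' @return list: `labels`, `class_volumes`, `selected` (class index),
#'   `mean_ncc` per class
#' @export
classify_3d <- function(stack, k = 2, n_iter = 6, seed = 1,
                        member_floor = NULL, n_starts = 5) {
  n <- length(stack$boxes)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (n < k) stop("need at least k boxes", call. = FALSE)
  if (is.null(member_floor)) member_floor <- max(2L, floor(0.1 * n))
  # alignment-free partition: boxes enter in the normal-aligned frame only
  al <- align_average(stack, return_aligned = TRUE,
                      refine_shifts = 0)$aligned
  p <- length(al[[1]])
  X <- t(vapply(al, normalize_vec, numeric(p)))
  one_start <- function(start_seed) {
    # kmeans++-style seeding on correlation distance; a random partition
    # starts both averages at the global mean, a stable mixture
    seeds_i <- withr::with_seed(start_seed, {
      S0 <- sample(n, 1)
      for (j in seq_len(k - 1)) {
        sim <- X %*% t(X[S0, , drop = FALSE])
        d2 <- (1 - apply(sim, 1, max))^2
        d2[S0] <- 0
        S0 <- c(S0, sample(n, 1, prob = pmax(d2, 1e-12)))
      }
      S0
    })
    labels <- max.col(X %*% t(X[seeds_i, , drop = FALSE]),
                      ties.method = "first")
    score <- numeric(n)
    for (iter in seq_len(n_iter)) {
      V <- sapply(seq_len(k), function(c_) {
        mem <- labels == c_
        if (!any(mem)) numeric(p)
        else normalize_vec(colMeans(X[mem, , drop = FALSE]))
      })
      S <- X %*% V
      score <- S[cbind(seq_len(n), max.col(S, ties.method = "first"))]
      labels <- max.col(S, ties.method = "first")
      empty <- setdiff(seq_len(k), unique(labels))
      if (length(empty)) labels[order(score)[seq_along(empty)]] <- empty
    }
    list(labels = labels, objective = mean(score))
  }
  starts <- lapply(derive_seeds(seed, n_starts, salt = 3L), one_start)
  labels <- starts[[which.max(vapply(starts, `[[`, numeric(1),
                                     "objective"))]]$labels
  vols <- lapply(seq_len(k), function(c_) {
    mem <- which(labels == c_)
    if (!length(mem)) return(array(0, dim(al[[1]])))
    Reduce(`+`, al[mem]) / length(mem)
  })
  mean_ncc <- vapply(seq_len(k), function(c_) {
    mem <- which(labels == c_)
    if (length(mem) < 2) return(-Inf)
    v <- normalize_vec(vols[[c_]])
    mean(X[mem, , drop = FALSE] %*% v)
  }, numeric(1))
  eligible <- which(tabulate(labels, k) >= member_floor & is.finite(mean_ncc))
  if (!length(eligible)) eligible <- which.max(tabulate(labels, k))
  selected <- eligible[which.max(mean_ncc[eligible])]
  list(labels = labels, class_volumes = vols, selected = selected,
       mean_ncc = mean_ncc, member_count = tabulate(labels, k))
}

#' Refined average of one 3D class
#'
#' Re-averages the stack members of a class with translational refinement
#' (the final alignment pass after classification has isolated the
#' receptor-bearing subset).
#' @param stack a `subvolume_stack`
#' @param labels classification labels from [classify_3d()]
#' @param class_id class to average
#' @return 3D array
#' @export
refined_class_average <- function(stack, labels, class_id) {
  keep <- which(labels == class_id)
  sub <- stack
  sub$boxes <- stack$boxes[keep]
  sub$normals <- stack$normals[keep, , drop = FALSE]
  align_average(sub, refine_shifts = 2)$model
}

#' Measure receptor height above the outer membrane leaflet
#'
#' In the normal-aligned frame (+z = outward), the extracellular density
#' profile p(z) is the mean over a central disk; the height is the topmost
#' z where p(z) reaches `level` of its extracellular peak, minus the outer
#' leaflet position. No supra-threshold density gives 0, flagged.
#' @param vol normal-aligned class volume
#' @param membrane_z outer-leaflet z position in the box, nm (box frame,
#'   voxel 1 at 0)
#' @param level fraction of the extracellular peak (default 0.5)
#' @param pixel_size nm per voxel
#' @param disk_radius radius of the averaging disk, nm
#' @return list: `height` (nm), `flagged`, `profile` (data.frame z, p)
#' @export
measure_height <- function(vol, membrane_z, level = 0.5, pixel_size = 1,
                           disk_radius = 6) {
  d <- dim(vol)
  ctr <- (d[1:2] + 1) / 2
  rr <- sqrt(outer(((seq_len(d[1]) - ctr[1]) * pixel_size)^2,
                   ((seq_len(d[2]) - ctr[2]) * pixel_size)^2, "+"))
  disk <- rr <= disk_radius
  p <- vapply(seq_len(d[3]), function(k) mean(vol[, , k][disk]), numeric(1))
  z <- (seq_len(d[3]) - 1) * pixel_size
  extra <- z > membrane_z + 1.5  # clear the leaflet sheet itself
  if (!any(extra) || max(p[extra]) <= 0)
    return(list(height = 0, flagged = TRUE,
                profile = data.frame(z = z, p = p)))
  # remove the diffuse pedestal (smeared neighbors, residual noise floor)
  # so the threshold tracks the receptor's own density
  baseline <- stats::quantile(p[extra], 0.25, names = FALSE)
  p <- p - baseline
  pk <- max(p[extra])
  if (pk <= 0)
    return(list(height = 0, flagged = TRUE,
                profile = data.frame(z = z, p = p)))
  thr <- level * pk
  above <- which(extra & p >= thr)
  top_i <- max(above)
  # linear interpolation to the crossing above the topmost supra-threshold z
  z_top <- if (top_i < d[3] && p[top_i + 1] < thr)
    z[top_i] + (p[top_i] - thr) / (p[top_i] - p[top_i + 1]) * pixel_size
  else z[top_i]
  list(height = z_top - membrane_z, flagged = FALSE,
       profile = data.frame(z = z, p = p))
}

#' Rigid-body fit of a reference structure into a density map
#'
#' The reference (pseudo-)atoms are rendered as Gaussians low-passed to the
#' stated resolution on the map grid; an exhaustive coarse rotation grid is
#' scored by translational NCC via FFT cross-correlation, and the best
#' orientation is locally refined (Nelder-Mead over the rotation vector,
#' translation re-optimized by FFT at every step).
#' @param map 3D array (or [tomogram_volume()])
#' @param ref_coords data.frame with x, y, z (nm) and optional weight
#' @param resolution target resolution, Angstrom (Gaussian FWHM)
#' @param pixel_size nm per voxel (taken from `map` if a tomogram_volume)
#' @param rot_step coarse rotation grid step, degrees (<= 15 recommended)
#' @param refine run local refinement
#' @return list: `ncc` (best), `rotation` (3x3), `translation_nm`
#' @export
rigid_fit_score <- function(map, ref_coords, resolution, pixel_size = NULL,
                            rot_step = 15, refine = TRUE) {
  if (inherits(map, "tomogram_volume")) {
    if (is.null(pixel_size)) pixel_size <- map$pixel_size
    map <- map$grid
  }
  if (is.null(pixel_size)) stop("pixel_size required", call. = FALSE)
  d <- dim(map)
  sigma <- resolution / 10 / (2 * sqrt(2 * log(2)))  # FWHM -> sd, nm
  w <- if (is.null(ref_coords$weight)) rep(1, nrow(ref_coords))
       else ref_coords$weight
  P <- as.matrix(ref_coords[, c("x", "y", "z")])
  P <- sweep(P, 2, colMeans(P))  # rotate about the reference centroid
  ctr_nm <- (d - 1) * pixel_size / 2
  Fm <- stats::fft(map - mean(map))
  nm2 <- sqrt(sum((map - mean(map))^2))
  score_rot <- function(R) {
    Q <- P %*% t(R)
    vol <- array(0, d)
    vol <- rasterize_gaussians(vol, sweep(Q, 2, ctr_nm, "+"),
                               sigma, w, pixel_size)
    v <- vol - mean(vol)
    cc <- Re(stats::fft(Fm * Conj(stats::fft(v)), inverse = TRUE)) /
      length(v)
    den <- nm2 * sqrt(sum(v^2))
    if (den == 0) return(list(ncc = -1, shift = c(0, 0, 0)))
    i <- which.max(cc)
    kk <- arrayInd(i, d) - 1
    kk <- ifelse(kk > d / 2, kk - d, kk)
    list(ncc = max(cc) / den, shift = kk * pixel_size)
  }
  # coarse grid: rotation vectors on a spherical grid x angle steps
  angs <- seq(0, 180 - rot_step, by = rot_step)
  axes <- rbind(c(1, 0, 0))
  th <- seq(0, 180, by = 2 * rot_step) * pi / 180
  ph <- seq(0, 360 - 2 * rot_step, by = 2 * rot_step) * pi / 180
  axes <- unique(round(do.call(rbind, lapply(th, function(t)
    cbind(sin(t) * cos(ph), sin(t) * sin(ph), cos(t)))), 6))
  best <- list(ncc = -Inf)
  for (a in seq_len(nrow(axes))) {
    for (g in angs) {
      R <- rotation_about_axis(axes[a, ], g)
      sc <- score_rot(R)
      if (sc$ncc > best$ncc)
        best <- list(ncc = sc$ncc, rotation = R, translation_nm = sc$shift,
                     rotvec = axes[a, ] * g)
    }
  }
  if (refine) {
    obj <- function(rv) {
      ang <- sqrt(sum(rv^2))
      R <- if (ang < 1e-9) diag(3) else rotation_about_axis(rv, ang)
      -score_rot(R)$ncc
    }
    op <- stats::optim(best$rotvec, obj, method = "Nelder-Mead",
                       control = list(maxit = 60, reltol = 1e-4))
    if (-op$value > best$ncc) {
      ang <- sqrt(sum(op$par^2))
      R <- if (ang < 1e-9) diag(3) else rotation_about_axis(op$par, ang)
      sc <- score_rot(R)
      best <- list(ncc = sc$ncc, rotation = R, translation_nm = sc$shift,
                   rotvec = op$par)
    }
  }
  best[c("ncc", "rotation", "translation_nm")]
}

#' Monte-Carlo test of complete spatial randomness of picks on a surface
#'
#' Compares the observed mean nearest-neighbor distance of kept picks to
#' its null distribution under uniform placement on the same surface
#' (sampled from the surface point set); two-sided p-value with the +1
#' correction: p = (1 + #more extreme) / (n_mc + 1), where "more extreme"
#' is a larger absolute deviation from the Monte-Carlo mean.
#' @param picks data.frame with x, y, z (kept picks; >= 5 rows)
#' @param surface data.frame with x, y, z (the membrane surface points)
#' @param n_mc Monte-Carlo replicates (>= 1)
#' @param seed RNG seed
#' @return list: `p_value`, `observed_mean_nn`, `null_mean_nn`,
#'   `n_picks`
#' @export
spatial_randomness_test <- function(picks, surface, n_mc = 999, seed = 1) {
  if (n_mc < 1) stop("n_mc must be >= 1 (null distribution undefined)",
                     call. = FALSE)
  n <- nrow(picks)
  if (n < 5) stop("insufficient picks (need >= 5)", call. = FALSE)
  mean_nn <- function(P) {
    D <- as.matrix(stats::dist(P))
    diag(D) <- Inf
    mean(apply(D, 1, min))
  }
  obs <- mean_nn(as.matrix(picks[, c("x", "y", "z")]))
  S <- as.matrix(surface[, c("x", "y", "z")])
  null <- withr::with_seed(seed, vapply(seq_len(n_mc), function(r) {
    mean_nn(S[sample(nrow(S), n), , drop = FALSE])
  }, numeric(1)))
  mu <- mean(null)
  p <- (1 + sum(abs(null - mu) >= abs(obs - mu))) / (n_mc + 1)
  list(p_value = p, observed_mean_nn = obs, null_mean_nn = mu, n_picks = n)
}

#' Read atomic coordinates from a PDB file
#'
#' Thin wrapper for rigid-body fitting: returns nm-scale coordinates with
#' unit weights (CA atoms by default, all atoms otherwise).
#' @param path PDB file
#' @param ca_only keep only CA atoms when present
#' @return data.frame x, y, z (nm), weight
#' @export
read_pdb_coords <- function(path, ca_only = TRUE) {
  lines <- readLines(path)
  at <- lines[startsWith(lines, "ATOM") | startsWith(lines, "HETATM")]
  if (!length(at)) stop("no ATOM records in ", path, call. = FALSE)
  name <- trimws(substr(at, 13, 16))
  if (ca_only && any(name == "CA")) at <- at[name == "CA"]
  data.frame(x = as.numeric(substr(at, 31, 38)) / 10,
             y = as.numeric(substr(at, 39, 46)) / 10,
             z = as.numeric(substr(at, 47, 54)) / 10,
             weight = 1)
}
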