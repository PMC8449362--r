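# Polarity core: masked central-slab projection of segment subvolumes,
# in-plane rotation to a common filament axis, reference-free 2D
# classification, and polarity labeling of class averages against
# projections of the helical actin model in both axial orientations.
#
# Sign bookkeeping (the load-bearing convention): after rotate_to_axis the
# segment's trace tangent maps to +x of the image. The "plus" templates are
# projections of a model filament whose barbed end points to +x; so a class
# labeled +1 means its members' barbed ends point along their own tangents.
# The 180-degree in-plane rotation allowed during classification flips the
# axis direction, so a member aligned with an extra 180-degree rotation
# contributes the opposite vote. The axial flip is deliberately NOT part of
# the alignment search: in z-projection the axial flip is exactly the
# degree of freedom classification must separate.

#' Masked central-slab projection of a subvolume
#'
#' Applies a soft (raised-cosine) cylindrical mask around the expected
#' filament axis through the box center, then sums the central
#' round(thickness / pixel_size) z-planes.
#' @param box cubic 3D array
#' @param thickness slab thickness, nm (> 0); default the 11-nm working value
#' @param pixel_size nm per voxel
#' @param axis expected filament axis (unit vector, box frame)
#' @param mask_radius cylinder radius, nm; `Inf` disables the mask
#' @param taper raised-cosine taper width, nm
#' @return 2D matrix (x, y)
#' @export
project_slab <- function(box, thickness = 11, pixel_size = 1,
                         axis = c(1, 0, 0), mask_radius = 6, taper = 2) {
  if (thickness <= 0) stop("slab thickness must be > 0", call. = FALSE)
  d <- dim(box)
  if (thickness > d[3] * pixel_size + 1e-9)
    stop("slab thickness exceeds the box", call. = FALSE)
  if (is.finite(mask_radius)) {
    ctr <- (d + 1) / 2
    u <- axis / sqrt(sum(axis^2))
    g <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]), k = seq_len(d[3]))
    p <- cbind(g$i - ctr[1], g$j - ctr[2], g$k - ctr[3]) * pixel_size
    along <- p %*% u
    r <- sqrt(pmax(rowSums(p^2) - along^2, 0))
    w <- numeric(length(r))
    w[r <= mask_radius] <- 1
    ramp <- r > mask_radius & r < mask_radius + taper
    w[ramp] <- 0.5 * (1 + cos(pi * (r[ramp] - mask_radius) / taper))
    box <- box * array(w, d)
  }
  q <- max(1L, round(thickness / pixel_size))
  z0 <- floor((d[3] - q) / 2) + 1
  planes <- box[, , z0:(z0 + q - 1), drop = FALSE]
  apply(planes, c(1, 2), sum)
}

#' Rotate a projected segment image so its filament axis maps to +x
#'
#' The rotation angle comes from the segment tangent projected onto the
#' x-y plane; the residual sub-voxel extraction offset is applied as a 2D
#' shift in the same resampling pass. Tangents within 5 degrees of the beam
#' axis are flagged unusable (the filament axis is unresolvable in
#' projection).
#' @param image 2D matrix
#' @param tangent segment tangent (unit 3-vector)
#' @param offset_nm residual extraction offset, nm (x, y components used)
#' @param pixel_size nm per pixel
#' @param min_axis_angle minimum tangent angle from the z axis, degrees
#' @return list: `image` (aligned), `inplane_angle` (degrees applied),
#'   `usable`
#' @export
rotate_to_axis <- function(image, tangent, offset_nm = c(0, 0),
                           pixel_size = 1, min_axis_angle = 5) {
  txy <- sqrt(tangent[1]^2 + tangent[2]^2)
  if (txy < sin(min_axis_angle * pi / 180))
    return(list(image = image, inplane_angle = NA_real_, usable = FALSE))
  theta <- atan2(tangent[2], tangent[1]) * 180 / pi
  o <- c(offset_nm[1], offset_nm[2]) / pixel_size
  th <- -theta * pi / 180
  rot_o <- c(cos(th) * o[1] - sin(th) * o[2],
             sin(th) * o[1] + cos(th) * o[2])
  out <- rotate_image(image, -theta, shift_px = -rot_o)
  list(image = out, inplane_angle = -theta, usable = TRUE)
}

#' Model projections of the helical actin filament in both polarities
#'
#' "Plus" templates are masked slab projections of a noise-free model
#' filament whose barbed end points toward +x, generated at several
#' azimuthal phases; "minus" templates are their axial flips (projection
#' along z of the filament rotated 180 degrees about y is the x-mirror of
#' the plus projection).
#' The templates pass through the same imaging model as the data (the
#' missing-wedge filter at `tilt_range`), which sharpens the plus/minus
#' score margin on wedge-filtered segments.
#' @param params a [helical_params()]
#' @param box_px image edge, pixels
#' @param pixel_size nm per pixel
#' @param thickness slab thickness, nm
#' @param n_phases azimuthal phases sampled
#' @param mask_radius cylindrical mask radius, nm
#' @param tilt_range wedge filter applied to the model volume, degrees
#'   (90 = no wedge)
#' @param z_tilts out-of-plane filament tilts sampled, degrees; a chiral
#'   helix tilted out of the projection plane projects differently for the
#'   two tilt signs, so both are banked
#' @return list with `plus` and `minus`, each a list of matrices
#' @export
actin_templates <- function(params, box_px, pixel_size, thickness = 11,
                            n_phases = 12, mask_radius = 6,
                            tilt_range = 60, z_tilts = c(-4, 0, 4)) {
  L <- box_px * pixel_size + 6 * params$rise / 10
  ctr <- (box_px + 1) / 2 * pixel_size  # box frame: voxel i at (i-1)*px
  plus <- list()
  for (zt in z_tilts) {
    ax <- c(cos(zt * pi / 180), 0, sin(zt * pi / 180))
    for (i in seq_len(n_phases)) {
      phase <- (i - 1) * 360 / n_phases
      geom <- helix_lobes(params, L,
                          origin = c(ctr, ctr, ctr) - L / 2 * ax,
                          axis = ax, phase = phase)
      vol <- array(0, rep(box_px, 3))
      vol <- rasterize_gaussians(vol,
                                 as.matrix(geom$lobes[, c("x", "y", "z")]),
                                 geom$lobes$sigma, geom$lobes$weight,
                                 pixel_size, origin = c(0, 0, 0))
      vol <- apply_imaging_model(vol, tilt_range, 0)
      plus[[length(plus) + 1]] <-
        project_slab(vol, thickness, pixel_size, axis = ax,
                     mask_radius = mask_radius)
    }
  }
  minus <- lapply(plus, function(im) im[rev(seq_len(nrow(im))), ])
  list(plus = plus, minus = minus)
}

# Variant matrix of normalized, integer-shifted templates for fast scoring:
# columns are normalize_vec(shift(template)); `group` marks plus/minus.
.template_bank <- function(templates, shift_max = 3) {
  shifts <- expand.grid(sx = -shift_max:shift_max, sy = -shift_max:shift_max)
  cols <- list(); group <- character()
  for (side in c("plus", "minus")) {
    for (tm in templates[[side]]) {
      for (s in seq_len(nrow(shifts))) {
        cols[[length(cols) + 1]] <-
          normalize_vec(shift_int(tm, shifts$sx[s], shifts$sy[s]))
        group <- c(group, side)
      }
    }
  }
  list(V = do.call(cbind, cols), group = group)
}

#' Label the polarity of a class average by model-projection matching
#'
#' Normalized cross-correlation of the class average against the plus and
#' minus template banks, maximized over azimuthal phase and integer shifts;
#' the label is the orientation with the higher score, or 0 (unassigned)
#' when the scores differ by less than `margin`.
#' @param class_avg 2D matrix
#' @param templates from [actin_templates()], or a precomputed bank
#' @param margin minimum score difference for an assignment
#' @param shift_max translational search radius, pixels
#' @return list: `label` (+1, -1 or 0), `score_plus`, `score_minus`
#' @export
polarity_of_class <- function(class_avg, templates, margin = 0.05,
                              shift_max = 3) {
  bank <- if (!is.null(templates$V)) templates
          else .template_bank(templates, shift_max)
  sc <- as.vector(normalize_vec(class_avg) %*% bank$V)
  sp <- max(sc[bank$group == "plus"])
  sm <- max(sc[bank$group == "minus"])
  label <- if (abs(sp - sm) < margin) 0L else if (sp > sm) 1L else -1L
  list(label = label, score_plus = sp, score_minus = sm)
}

#' Reference-free 2D classification with translational/180-degree alignment
#'
#' Iterates (a) alignment of every image to its current class average over
#' integer shifts and the 180-degree in-plane rotation, and (b)
#' reassignment to the best-correlating average. Initial classes are seeded
#' kmeans++-style on correlation distance (farthest-point-biased sampling
#' of seed images), which lets distinct helical-phase/polarity modes
#' nucleate separate classes instead of collapsing onto the global mean.
#' Classes that empty are reseeded from the worst-fitting image.
#' Deterministic given the seed.
#' @param images list of equal-size matrices
#' @param k number of classes (>= 2, <= number of images)
#' @param n_iter alignment/assignment iterations
#' @param seed RNG seed (seeding draws)
#' @param shift_max translational search radius, pixels
#' @param init "kmeans++" (default) or "random" partition
#' @return list: `labels` (class per image), `rot180` (logical per image),
#'   `shifts` (n x 2), `score` (best NCC per image), `class_averages`
#'   (list of matrices, class frame), `member_count`
#' @export
classify_2d <- function(images, k, n_iter = 8, seed = 1, shift_max = 2,
                        init = c("kmeans++", "random")) {
  init <- match.arg(init)
  n <- length(images)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (n < k) stop("need at least k images", call. = FALSE)
  dims <- dim(images[[1]])
  p <- prod(dims)
  X <- t(vapply(images, normalize_vec, numeric(p)))
  labels <- if (init == "random") {
    withr::with_seed(seed, sample(rep_len(seq_len(k), n)))
  } else {
    seeds <- withr::with_seed(seed, {
      S <- sample(n, 1)
      for (j in seq_len(k - 1)) {
        sim <- X %*% t(X[S, , drop = FALSE])
        d2 <- (1 - apply(sim, 1, max))^2
        d2[S] <- 0
        S <- c(S, sample(n, 1, prob = pmax(d2, 1e-12)))
      }
      S
    })
    max.col(X %*% t(X[seeds, , drop = FALSE]), ties.method = "first")
  }
  rot <- rep(FALSE, n)
  sx <- integer(n); sy <- integer(n)
  score <- numeric(n)
  shifts <- expand.grid(sx = -shift_max:shift_max, sy = -shift_max:shift_max)
  nv <- 2 * nrow(shifts)
  avg_raw <- vector("list", k)
  for (iter in seq_len(n_iter)) {
    # class averages from aligned members (exact index transforms)
    for (c_ in seq_len(k)) {
      mem <- which(labels == c_)
      acc <- matrix(0, dims[1], dims[2])
      for (i in mem) {
        im <- shift_int(images[[i]], -sx[i], -sy[i])
        if (rot[i]) im <- rot180(im)
        acc <- acc + im
      }
      avg_raw[[c_]] <- acc / max(1, length(mem))
    }
    # variant bank: shift(rot?(avg)) for every class
    V <- matrix(0, p, k * nv)
    for (c_ in seq_len(k)) {
      base <- (c_ - 1) * nv
      for (s in seq_len(nrow(shifts))) {
        V[, base + s] <- normalize_vec(
          shift_int(avg_raw[[c_]], shifts$sx[s], shifts$sy[s]))
        V[, base + nrow(shifts) + s] <- normalize_vec(
          shift_int(rot180(avg_raw[[c_]]), shifts$sx[s], shifts$sy[s]))
      }
    }
    S <- X %*% V
    best <- max.col(S, ties.method = "first")
    score <- S[cbind(seq_len(n), best)]
    labels <- (best - 1L) %/% nv + 1L
    within <- (best - 1L) %% nv
    rot <- within >= nrow(shifts)
    sidx <- within %% nrow(shifts) + 1L
    sx <- shifts$sx[sidx]; sy <- shifts$sy[sidx]
    # reseed empty classes from the worst-fitting images
    empty <- setdiff(seq_len(k), unique(labels))
    if (length(empty)) {
      worst <- order(score)[seq_along(empty)]
      labels[worst] <- empty
      rot[worst] <- FALSE; sx[worst] <- 0L; sy[worst] <- 0L
    }
  }
  # final averages
  for (c_ in seq_len(k)) {
    mem <- which(labels == c_)
    acc <- matrix(0, dims[1], dims[2])
    for (i in mem) {
      im <- shift_int(images[[i]], -sx[i], -sy[i])
      if (rot[i]) im <- rot180(im)
      acc <- acc + im
    }
    avg_raw[[c_]] <- acc / max(1, length(mem))
  }
  list(labels = labels, rot180 = rot, shifts = cbind(sx = sx, sy = sy),
       score = score, class_averages = avg_raw,
       member_count = tabulate(labels, k))
}

#' Label and select classes; derive per-segment polarity votes
#'
#' Classes are labeled by [polarity_of_class()]; those with a score margin
#' below `margin` or fewer than `min_members` members are discarded and
#' their members get vote 0. A member aligned into its class with the extra
#' 180-degree rotation votes opposite to the class label.
#' @param cls result of [classify_2d()]
#' @param templates template bank or [actin_templates()] result
#' @param margin minimum |score_plus - score_minus|
#' @param min_members minimum class population
#' @return list: `class_info` (data.frame: class, member_count, label,
#'   score_plus, score_minus, selected), `votes` (integer per image)
#' @export
select_classes <- function(cls, templates, margin = 0.05, min_members = 10) {
  bank <- if (!is.null(templates$V)) templates else .template_bank(templates)
  k <- length(cls$class_averages)
  info <- do.call(rbind, lapply(seq_len(k), function(c_) {
    pol <- polarity_of_class(cls$class_averages[[c_]], bank, margin = margin)
    data.frame(class = c_, member_count = cls$member_count[c_],
               label = pol$label, score_plus = pol$score_plus,
               score_minus = pol$score_minus)
  }))
  info$selected <- info$label != 0 & info$member_count >= min_members &
    abs(info$score_plus - info$score_minus) >= margin
  if (!any(info$selected))
    stop("all 2D classes discarded (margin/min_members too strict for ",
         "this data)", call. = FALSE)
  votes <- integer(length(cls$labels))
  for (c_ in which(info$selected)) {
    mem <- which(cls$labels == c_)
    votes[mem] <- info$label[c_] * ifelse(cls$rot180[mem], -1L, 1L)
  }
  list(class_info = info, votes = votes)
}

#' Prepare aligned segment projections for one scene/tomogram
#'
#' Segments -> subvolumes -> masked slab projections -> in-plane alignment.
#' The output feeds [run_polarity_pooled()], which classifies the segments
#' of many tomograms together (as the method does: class averaging needs
#' hundreds of members per class).
#' @param tomo a [tomogram_volume()]
#' @param traces list of [filament_trace()]
#' @param config list of stage parameters (see [default_config()])
#' @return list: `segments` (table with usable flag, inplane_angle),
#'   `images` (list, NULL for unusable segments)
#' @export
prepare_polarity_images <- function(tomo, traces,
                                    config = default_config()) {
  cfg <- config
  segs <- do.call(rbind, lapply(traces, resample_trace,
                                spacing = cfg$spacing))
  ex <- extract_segments(tomo, segs, cfg$box_edge)
  segs <- ex$segments
  n <- nrow(segs)
  images <- vector("list", n)
  angles <- rep(NA_real_, n)
  usable <- logical(n)
  for (i in seq_len(n)) {
    if (segs$rejected[i]) next
    tang <- c(segs$tx[i], segs$ty[i], segs$tz[i])
    img <- project_slab(ex$boxes[[i]], cfg$slab_thickness, tomo$pixel_size,
                        axis = tang, mask_radius = cfg$mask_radius)
    al <- rotate_to_axis(img, tang, ex$offsets[i, ], tomo$pixel_size)
    usable[i] <- al$usable
    if (al$usable) {
      images[[i]] <- al$image
      angles[i] <- al$inplane_angle
    }
  }
  segs$usable <- usable & !segs$rejected
  segs$inplane_angle <- angles
  list(segments = segs, images = images)
}

#' Classify pooled segments and assign polarity votes
#'
#' Pools the aligned projections of one or more prepared scenes, runs one
#' reference-free 2D classification over all of them, labels the class
#' averages against the helical model and writes per-segment votes back
#' into each scene's segment table.
#'
#' With `augment_flip` (the default) every image enters the classification
#' twice, once as-is and once axially flipped. This makes the class
#' landscape exactly symmetric under polarity -- without it the landscape
#' can spontaneously organize around the majority orientation and vote
#' accuracy becomes composition-dependent, biasing the resolved subset. A
#' segment's vote then comes from its two copies: they agree (vote), one
#' abstains (the other decides), or they conflict (abstain) -- a built-in
#' mirror-consistency check.
#' @param prepped list of [prepare_polarity_images()] results
#' @param config stage parameters
#' @param seed classification seed
#' @param templates optional precomputed template bank
#' @param augment_flip classify each image together with its axial flip
#' @return list: `segments` (list of per-scene tables with polarity_vote,
#'   class_id), `class_info`, `class_averages`, `log`
#' @export
run_polarity_pooled <- function(prepped, config = default_config(),
                                seed = 1, templates = NULL,
                                augment_flip = TRUE) {
  cfg <- config
  pool <- list(); origin <- NULL
  for (s in seq_along(prepped)) {
    idx <- which(prepped[[s]]$segments$usable)
    for (i in idx) {
      pool[[length(pool) + 1]] <- prepped[[s]]$images[[i]]
      origin <- rbind(origin, c(s, i))
    }
  }
  n <- length(pool)
  if (n < cfg$k)
    stop("too few usable segments for 2D classification", call. = FALSE)
  if (is.null(templates))
    templates <- .template_bank(
      actin_templates(cfg$helical, cfg$box_edge, cfg$pixel_size,
                      cfg$slab_thickness, mask_radius = cfg$mask_radius,
                      tilt_range = cfg$tilt_range),
      shift_max = 3)
  flipx <- function(im) im[rev(seq_len(nrow(im))), ]
  input <- if (augment_flip) c(pool, lapply(pool, flipx)) else pool
  cls <- classify_2d(input, cfg$k, n_iter = cfg$n_iter, seed = seed,
                     shift_max = cfg$shift_max)
  sel <- select_classes(cls, templates, margin = cfg$margin,
                        min_members = cfg$min_members)
  votes <- if (augment_flip) {
    v1 <- sel$votes[seq_len(n)]
    v2 <- -sel$votes[n + seq_len(n)]  # the flipped copy sees mirrored polarity
    ifelse(v1 == v2, v1, ifelse(v1 == 0L, v2, ifelse(v2 == 0L, v1, 0L)))
  } else sel$votes
  labels1 <- cls$labels[seq_len(n)]
  out_segs <- vector("list", length(prepped))
  for (s in seq_along(prepped)) {
    segs <- prepped[[s]]$segments
    segs$polarity_vote <- 0L
    segs$class_id <- NA_integer_
    rows <- origin[, 1] == s
    segs$polarity_vote[origin[rows, 2]] <- votes[rows]
    segs$class_id[origin[rows, 2]] <- labels1[rows]
    out_segs[[s]] <- segs
  }
  nseg <- sum(vapply(out_segs, nrow, integer(1)))
  log <- c(segments = nseg,
           rejected_box = sum(vapply(out_segs, function(x) sum(x$rejected),
                                     integer(1))),
           classified = n,
           voted = sum(votes != 0))
  list(segments = out_segs, class_info = sel$class_info,
       class_averages = cls$class_averages, log = log,
       classification = cls)
}

#' Run the polarity stage on a single scene/tomogram
#'
#' Convenience wrapper: [prepare_polarity_images()] +
#' [run_polarity_pooled()] on one tomogram.
#' @param tomo a [tomogram_volume()]
#' @param traces list of [filament_trace()]
#' @param config stage parameters
#' @param seed classification seed
#' @param templates optional precomputed template bank
#' @return as [run_polarity_pooled()], with `segments` a single table
#' @export
run_polarity_scene <- function(tomo, traces, config = default_config(),
                               seed = 1, templates = NULL) {
  prep <- prepare_polarity_images(tomo, traces, config)
  res <- run_polarity_pooled(list(prep), config, seed, templates)
  res$segments <- res$segments[[1]]
  res
}
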