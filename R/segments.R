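# Segment extraction: oriented coordinates sampled along filament traces at
# fixed arc-length spacing (default 8 nm), and cubic subvolumes cut from the
# tomogram around each coordinate.

#' Construct a filament trace
#' @param filament_id identifier
#' @param points ordered polyline, n x 3 matrix (nm); n >= 2, consecutive
#'   points distinct
#' @param true_polarity +1/-1: barbed end along/against the point order
#'   (synthetic ground truth; NULL for real traces)
#' @param barbed_dir optional ground-truth barbed-end unit vector
#' @param phase azimuthal phase used at rendering (synthetic only)
#' @param tomogram_id optional scene/tomogram identifier
#' @return object of class `filament_trace`
#' @export
filament_trace <- function(filament_id, points, true_polarity = NULL,
                           barbed_dir = NULL, phase = NULL,
                           tomogram_id = NULL) {
  points <- as.matrix(points)
  dimnames(points) <- NULL
  if (nrow(points) < 2) stop("a trace needs >= 2 points", call. = FALSE)
  seglen <- sqrt(rowSums((points[-1, , drop = FALSE] -
                          points[-nrow(points), , drop = FALSE])^2))
  if (any(seglen == 0))
    stop("consecutive trace points must be distinct", call. = FALSE)
  structure(list(filament_id = filament_id, points = points,
                 true_polarity = true_polarity, barbed_dir = barbed_dir,
                 phase = phase, tomogram_id = tomogram_id),
            class = "filament_trace")
}

#' Reverse the point order of a trace
#'
#' Flips all tangents and (when present) the ground-truth polarity sign, so
#' the physical filament is unchanged.
#' @param trace a [filament_trace()]
#' @return the reversed trace
#' @export
reverse_trace <- function(trace) {
  trace$points <- trace$points[rev(seq_len(nrow(trace$points))), ]
  if (!is.null(trace$true_polarity))
    trace$true_polarity <- -trace$true_polarity
  trace
}

#' Sample oriented segment coordinates along a trace
#'
#' Centers lie on the polyline at arc-length multiples of `spacing`,
#' starting at arc length 0; a trace whose total arc length is an exact
#' multiple includes the final point once. Tangents are unit vectors from
#' central differences of the resampled centers (one-sided at the ends).
#' A trace shorter than one spacing yields a single flagged segment at the
#' trace start.
#'
#' @param trace a [filament_trace()]
#' @param spacing arc-length spacing, nm (> 0); default 8 nm
#' @return data.frame of segment records: filament_id, segment_index,
#'   center (x, y, z), tangent (tx, ty, tz), arc_length, short flag
#' @export
resample_trace <- function(trace, spacing = 8) {
  if (spacing <= 0) stop("spacing must be > 0", call. = FALSE)
  pts <- trace$points
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                       pts[-nrow(pts), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  short <- L < spacing
  targets <- if (short) 0 else {
    t0 <- seq(0, L, by = spacing)
    # include the final point once when L is an exact multiple (fp tolerant)
    if (L - t0[length(t0)] > spacing - 1e-9) t0 <- c(t0, L)
    t0
  }
  centers <- sapply(1:3, function(a) stats::approx(s, pts[, a],
                                                   xout = targets)$y)
  centers <- matrix(centers, ncol = 3)
  n <- nrow(centers)
  tang <- matrix(NA_real_, n, 3)
  if (n == 1) {
    v <- pts[nrow(pts), ] - pts[1, ]
    tang[1, ] <- v / sqrt(sum(v^2))
  } else {
    for (i in seq_len(n)) {
      a <- max(1, i - 1); b <- min(n, i + 1)
      v <- centers[b, ] - centers[a, ]
      tang[i, ] <- v / sqrt(sum(v^2))
    }
  }
  data.frame(filament_id = trace$filament_id,
             segment_index = seq_len(n),
             x = centers[, 1], y = centers[, 2], z = centers[, 3],
             tx = tang[, 1], ty = tang[, 2], tz = tang[, 3],
             arc_length = targets, short = short)
}

#' Extract a cubic subvolume around a physical coordinate
#'
#' The box is centered on the voxel nearest to `center`; the residual
#' sub-voxel offset (nm) is recorded for later application as a 2D shift
#' during alignment. Boxes that would extend outside the tomogram are
#' rejected, not zero-padded.
#' @param tomo a [tomogram_volume()]
#' @param center physical coordinate, nm, length 3
#' @param box_edge box edge in voxels (even, > 0)
#' @return list with `box` (array or NULL), `offset_nm` (center minus the
#'   central voxel position) and `rejected` flag
#' @export
extract_subvolume <- function(tomo, center, box_edge) {
  stopifnot(inherits(tomo, "tomogram_volume"))
  if (box_edge <= 0 || box_edge %% 2 != 0)
    stop("box_edge must be even and > 0", call. = FALSE)
  d <- dim(tomo$grid)
  vox <- round((center - tomo$origin) / tomo$pixel_size) + 1
  half <- box_edge / 2
  lo <- vox - half + 1
  hi <- vox + half
  if (any(lo < 1) || any(hi > d))
    return(list(box = NULL, offset_nm = rep(NA_real_, 3), rejected = TRUE))
  off <- center - (tomo$origin + (vox - 1) * tomo$pixel_size)
  list(box = tomo$grid[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]],
       offset_nm = off, rejected = FALSE)
}

#' Extract subvolumes for a whole segment table
#' @param tomo a [tomogram_volume()]
#' @param segments data.frame from [resample_trace()] (rows of several
#'   traces may be concatenated)
#' @param box_edge box edge in voxels
#' @return list with `boxes` (list, NULL where rejected), `offsets` (n x 3,
#'   nm) and the segment table with a `rejected` column added
#' @export
extract_segments <- function(tomo, segments, box_edge) {
  n <- nrow(segments)
  boxes <- vector("list", n)
  offsets <- matrix(NA_real_, n, 3)
  rejected <- logical(n)
  for (i in seq_len(n)) {
    ex <- extract_subvolume(tomo, c(segments$x[i], segments$y[i],
                                    segments$z[i]), box_edge)
    # keep the NULL slot: boxes must stay parallel to the segment rows
    boxes[i] <- list(ex$box)
    offsets[i, ] <- ex$offset_nm
    rejected[i] <- ex$rejected
  }
  segments$rejected <- rejected
  list(boxes = boxes, offsets = offsets, segments = segments)
}
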