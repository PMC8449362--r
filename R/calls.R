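# Filament-level polarity calls and the tip-ward/cell-ward fraction
# statistic. Confidence is an exact binomial tail against p = 1/2: a
# filament is resolved when the probability of seeing a majority at least
# as large by chance is below alpha and it has at least n_min nonzero
# votes; exact ties are unresolved.

#' Aggregate segment votes into a per-filament polarity call
#'
#' @param votes integer vector of per-segment votes in \{-1, 0, +1\}
#' @param alpha one-sided binomial tail threshold (default 0.05; the
#'   stringent criterion uses 0.01)
#' @param n_min minimum number of nonzero votes
#' @return list: `n_votes`, `n_plus`, `n_minus`, `majority` (+1/-1/0),
#'   `majority_fraction`, `confidence_p`, `resolved`
#' @export
vote_filament <- function(votes, alpha = 0.05, n_min = 5) {
  votes <- votes[!is.na(votes)]
  n_plus <- sum(votes == 1)
  n_minus <- sum(votes == -1)
  n_eff <- n_plus + n_minus
  if (n_eff == 0) {
    return(list(n_votes = length(votes), n_plus = 0L, n_minus = 0L,
                majority = 0L, majority_fraction = NA_real_,
                confidence_p = NA_real_, resolved = FALSE))
  }
  m <- max(n_plus, n_minus)
  # P(X >= m), X ~ Binomial(n_eff, 1/2); exact
  p <- stats::pbinom(m - 1, n_eff, 0.5, lower.tail = FALSE)
  tie <- n_plus == n_minus
  majority <- if (tie) 0L else if (n_plus > n_minus) 1L else -1L
  resolved <- !tie && p <= alpha && n_eff >= n_min
  list(n_votes = length(votes), n_plus = n_plus, n_minus = n_minus,
       majority = majority, majority_fraction = m / n_eff,
       confidence_p = p, resolved = resolved)
}

#' Call every filament in a segment table
#' @param segments segment table with `filament_id` and `polarity_vote`
#' @param alpha,n_min see [vote_filament()]
#' @return data.frame, one row per filament
#' @export
call_filaments <- function(segments, alpha = 0.05, n_min = 5) {
  do.call(rbind, lapply(split(segments, segments$filament_id), function(g) {
    v <- vote_filament(g$polarity_vote, alpha = alpha, n_min = n_min)
    data.frame(filament_id = g$filament_id[1], n_votes = v$n_votes,
               n_plus = v$n_plus, n_minus = v$n_minus,
               majority = v$majority,
               majority_fraction = v$majority_fraction,
               confidence_p = v$confidence_p, resolved = v$resolved)
  }))
}

#' Tip direction of a protrusion
#'
#' Principal axis of the membrane mask voxel cloud, oriented toward the
#' capped (free) end -- the end where the cross-sectional spread shrinks.
#' An explicit `override` vector takes precedence and is returned
#' normalized.
#' @param mask logical 3D array (membrane-enclosed volume), or NULL with
#'   `override`
#' @param pixel_size nm per voxel
#' @param override optional tip-axis vector
#' @param max_points voxels subsampled for the PCA
#' @return unit 3-vector
#' @export
tip_direction <- function(mask = NULL, pixel_size = 1, override = NULL,
                          max_points = 50000) {
  if (!is.null(override)) {
    if (sqrt(sum(override^2)) == 0) stop("zero override vector", call. = FALSE)
    return(override / sqrt(sum(override^2)))
  }
  if (is.null(mask) || !any(mask))
    stop("membrane mask empty; supply an override tip axis", call. = FALSE)
  idx <- which(mask)
  if (length(idx) > max_points)
    idx <- idx[seq(1, length(idx), length.out = max_points)]
  d <- dim(mask)
  k <- (idx - 1) %/% (d[1] * d[2])
  j <- ((idx - 1) %/% d[1]) %% d[2]
  i <- (idx - 1) %% d[1]
  pts <- cbind(i, j, k) * pixel_size
  pts_c <- sweep(pts, 2, colMeans(pts))
  ev <- eigen(crossprod(pts_c) / nrow(pts_c), symmetric = TRUE)
  if (ev$values[1] < 1.5 * ev$values[2])
    stop("degenerate (near-spherical) membrane mask; supply an override ",
         "tip axis", call. = FALSE)
  ax <- ev$vectors[, 1]
  # orient toward the capped end: the 10% tail with the smaller
  # cross-sectional spread about the axis
  t_coord <- as.vector(pts_c %*% ax)
  qs <- stats::quantile(t_coord, c(0.1, 0.9))
  spread <- function(sel) {
    if (sum(sel) < 10) return(Inf)
    resid <- pts_c[sel, , drop = FALSE] -
      outer(t_coord[sel], ax)
    mean(sqrt(rowSums(resid^2)))
  }
  s_hi <- spread(t_coord >= qs[2])
  s_lo <- spread(t_coord <= qs[1])
  if (s_hi > s_lo) ax <- -ax
  ax
}

#' Tip-ward/cell-ward polarity fraction summary
#'
#' A resolved filament counts tip-ward when its estimated barbed-end
#' direction (majority vote mapped through the trace orientation) has a
#' positive dot product with the tip axis; a zero dot product counts
#' cell-ward (conservative) and is logged. Fractions are over resolved
#' filaments per tomogram; the aggregate is their mean +/- SD across
#' tomograms, in percent.
#' @param calls data.frame from [call_filaments()], with a `tomogram_id`
#'   column (a single-tomogram table may omit it)
#' @param traces list of [filament_trace()] covering the called filaments
#'   (same tomogram order); keyed by filament_id and tomogram_id
#' @param tip_axis unit 3-vector (or list keyed by tomogram_id)
#' @return list: `per_tomogram` (tomogram_id, n_filaments, resolved_count,
#'   tip_ward_fraction, cell_ward_fraction), `aggregate_mean`,
#'   `aggregate_sd` (percent, tip-ward), `unresolved_fraction`,
#'   `calls` (augmented with tip_ward)
#' @export
summarize_fractions <- function(calls, traces, tip_axis) {
  if (is.null(calls$tomogram_id)) calls$tomogram_id <- 1L
  key <- function(tid, fid) paste(tid, fid, sep = "/")
  tr_dir <- new.env()
  for (tr in traces) {
    n <- nrow(tr$points)
    v <- tr$points[n, ] - tr$points[1, ]
    tid <- if (is.null(tr$tomogram_id)) 1L else tr$tomogram_id
    assign(key(tid, tr$filament_id), v / sqrt(sum(v^2)), envir = tr_dir)
  }
  axis_for <- function(tid) {
    if (is.list(tip_axis)) tip_axis[[as.character(tid)]] else tip_axis
  }
  calls$tip_ward <- NA
  zero_dot <- 0L
  for (r in seq_len(nrow(calls))) {
    if (!calls$resolved[r]) next
    dirv <- get(key(calls$tomogram_id[r], calls$filament_id[r]),
                envir = tr_dir)
    barbed <- calls$majority[r] * dirv
    dp <- sum(barbed * axis_for(calls$tomogram_id[r]))
    if (dp == 0) zero_dot <- zero_dot + 1L
    calls$tip_ward[r] <- dp > 0
  }
  calls$call <- ifelse(!calls$resolved, "unresolved",
                       ifelse(calls$tip_ward, "tip-ward", "cell-ward"))
  per <- do.call(rbind, lapply(split(calls, calls$tomogram_id), function(g) {
    res <- g[g$resolved, ]
    data.frame(tomogram_id = g$tomogram_id[1], n_filaments = nrow(g),
               resolved_count = nrow(res),
               tip_ward_fraction = if (nrow(res)) mean(res$tip_ward) else NA,
               cell_ward_fraction = if (nrow(res)) mean(!res$tip_ward) else NA)
  }))
  excluded <- sum(per$resolved_count == 0)
  per_ok <- per[per$resolved_count > 0, ]
  if (!nrow(per_ok))
    stop("no tomogram has a resolved filament", call. = FALSE)
  agg_sd <- if (nrow(per_ok) > 1) 100 * stats::sd(per_ok$tip_ward_fraction)
            else 0
  list(per_tomogram = per,
       aggregate_mean = 100 * mean(per_ok$tip_ward_fraction),
       aggregate_sd = agg_sd,
       unresolved_fraction = 1 - sum(per$resolved_count) / nrow(calls),
       excluded_tomograms = excluded, zero_dot_count = zero_dot,
       calls = calls)
}
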