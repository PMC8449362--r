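test_that("normals of a flat slab point consistently outward", {
  mask <- array(FALSE, c(24, 24, 24))
  mask[, , 1:10] <- TRUE      # interior below z-plane
  mm <- estimate_normals(mask, pixel_size = 1)
  top <- mm$surface[mm$surface$z > 7 &
                    mm$surface$x > 5 & mm$surface$x < 18 &
                    mm$surface$y > 5 & mm$surface$y < 18, ]
  expect_gt(nrow(top), 50)
  expect_true(all(top$nz > 0.9))
  nn <- sqrt(top$nx^2 + top$ny^2 + top$nz^2)
  expect_true(all(abs(nn - 1) < 1e-6))
  expect_error(estimate_normals(array(FALSE, c(4, 4, 4))), "empty")
})

test_that("normals of a sphere are radial within 5 degrees on average", {
  n <- 40
  g <- expand.grid(i = 1:n, j = 1:n, k = 1:n)
  ctr <- (n + 1) / 2
  mask <- array((g$i - ctr)^2 + (g$j - ctr)^2 + (g$k - ctr)^2 < 14^2,
                rep(n, 3))
  mm <- estimate_normals(mask, pixel_size = 1)
  s <- mm$surface
  radial <- cbind(s$x - (ctr - 1), s$y - (ctr - 1), s$z - (ctr - 1))
  radial <- radial / sqrt(rowSums(radial^2))
  ang <- acos(pmin(1, rowSums(radial * s[, c("nx", "ny", "nz")]))) * 180 / pi
  expect_lt(mean(ang), 5)
})

test_that("picks outside the height band are rejected with reason 'height'", {
  # receptors placed low on the membrane; the 50-70 nm filter must reject
  sp <- small_spec(seed = 81, n_filaments = 0, receptor_count = 6,
                   receptor_band = c(18, 30))
  sc <- simulate_scene(sp)
  mm <- estimate_normals(membrane_interior_mask(sp), sp$pixel_size,
                         support_z = sp$support_z)
  picks <- pick_densities(sc$volume, mm, height_band = c(50, 70),
                          tilt_max = 89)
  expect_true(all(!picks$kept | picks$height_above_support >= 50))
  low <- picks[picks$height_above_support < 45 &
               picks$height_above_support > 15, ]
  expect_gt(nrow(low), 0)
  expect_true(all(low$reason == "height"))
  # same candidates pass when the band matches the placements
  picks2 <- pick_densities(sc$volume, mm, height_band = c(18, 30),
                           tilt_max = 89)
  expect_gt(sum(picks2$kept), 0)
})

test_that("every rejected pick carries exactly one reason and counts reconcile", {
  sp <- small_spec(seed = 82, n_filaments = 0, receptor_count = 8,
                   receptor_band = c(18, 30))
  sc <- simulate_scene(sp)
  mm <- estimate_normals(membrane_interior_mask(sp), sp$pixel_size,
                         support_z = sp$support_z)
  picks <- pick_densities(sc$volume, mm, height_band = c(18, 30),
                          tilt_max = 60)
  expect_equal(sum(picks$kept) + sum(!picks$kept), nrow(picks))
  expect_true(all(is.na(picks$reason) == picks$kept))
  expect_true(all(picks$reason[!picks$kept] %in%
                  c("height", "tilt", "separation")))
  # dedup suppression only ever comes from a kept (filter-passing) pick
  sep <- picks[!is.na(picks$reason) & picks$reason == "separation", ]
  kept <- picks[picks$kept, ]
  if (nrow(sep)) {
    dmin <- apply(sep, 1, function(r) {
      min(sqrt((kept$x - as.numeric(r["x"]))^2 +
               (kept$y - as.numeric(r["y"]))^2 +
               (kept$z - as.numeric(r["z"]))^2))
    })
    expect_true(all(dmin < 8))
  }
  # no two kept picks closer than the separation limit
  if (nrow(kept) > 1) {
    D <- as.matrix(stats::dist(kept[, c("x", "y", "z")]))
    diag(D) <- Inf
    expect_gte(min(D), 8)
  }
  expect_error(pick_densities(sc$volume, mm, attach_band = c(5, 2)),
               "well-ordered")
})

test_that("in-band receptors are recovered by picking at the default SNR", {
  # desk-scale scene of the receptor experiment; bipartite nearest match
  cfg <- read_config(system.file("extdata", "receptor_geometry.yaml",
                                 package = "tomopod"))
  sp <- tomopod:::config_scene_spec(cfg, 911)
  sc <- simulate_scene(sp)
  gt <- sc$truth$receptor_placements
  mm <- estimate_normals(membrane_interior_mask(sp), sp$pixel_size,
                         support_z = sp$support_z, downsample = 2)
  picks <- pick_densities(sc$volume, mm, height_band = c(50, 70),
                          tilt_max = 30, min_sep = 8)
  kp <- picks[picks$kept, ]
  D <- sqrt(outer(kp$x, gt$x, "-")^2 + outer(kp$y, gt$y, "-")^2 +
            outer(kp$z, gt$z, "-")^2)
  matched <- sum(apply(D, 2, min) < 5)
  expect_gte(matched / nrow(gt), 0.9)
})

test_that("a receptor-free membrane yields no more picks than pure noise", {
  sp0 <- small_spec(seed = 83, n_filaments = 0, receptor_count = 0)
  sc0 <- simulate_scene(sp0)
  mm <- estimate_normals(membrane_interior_mask(sp0), sp0$pixel_size,
                         support_z = sp0$support_z)
  kept_mem <- sum(pick_densities(sc0$volume, mm, height_band = c(18, 30),
                                 tilt_max = 60)$kept)
  # pure-noise volume, same membrane model and noise amplitude
  set.seed(84)
  noise <- tomogram_volume(
    array(stats::rnorm(prod(sp0$volume_shape), sd = 0.3),
          sp0$volume_shape), sp0$pixel_size)
  kept_noise <- sum(pick_densities(noise, mm, height_band = c(18, 30),
                                   tilt_max = 60)$kept)
  expect_lte(kept_mem, kept_noise + 3)
})

test_that("align_average is the identity for one +z box and respects rotations", {
  # blob on the rotation axis so the +y-built and +z-built boxes are true
  # rotational images of each other
  box <- blob_box(20, rbind(c(9.5, 9.5, 14)), sigma = 2)
  st <- structure(list(boxes = list(box), normals = rbind(c(0, 0, 1)),
                       box_edge = 20, pixel_size = 1, center_offset = 0),
                  class = "subvolume_stack")
  av <- align_average(st, refine_shifts = 0)
  expect_equal(av$model, box, tolerance = 1e-12)
  # the same geometry built along +y aligns onto the +z model
  box_y <- blob_box(20, rbind(c(9.5, 14, 9.5)), sigma = 2)
  st_y <- structure(list(boxes = list(box_y), normals = rbind(c(0, 1, 0)),
                         box_edge = 20, pixel_size = 1, center_offset = 0),
                    class = "subvolume_stack")
  av_y <- align_average(st_y, refine_shifts = 0)
  expect_gt(ncc(av_y$model, box), 0.99)
  expect_error(align_average(structure(list(boxes = list()),
                                       class = "subvolume_stack")), "empty")
})

test_that("averaging noisy copies beats any single box", {
  set.seed(85)
  clean <- blob_box(20, rbind(c(10.5, 10.5, 13), c(10.5, 10.5, 8)),
                    sigma = 1.8)
  boxes <- lapply(1:10, function(i)
    clean + 0.6 * max(clean) * array(stats::rnorm(20^3), rep(20, 3)))
  st <- structure(list(boxes = boxes,
                       normals = matrix(rep(c(0, 0, 1), 10), 10,
                                        byrow = TRUE)),
                  class = "subvolume_stack")
  av <- align_average(st, refine_shifts = 0)
  singles <- vapply(boxes, ncc, numeric(1), b = clean)
  expect_gt(ncc(av$model, clean), max(singles))
})

test_that("classify_3d separates receptor-bearing from bare boxes", {
  clean <- blob_box(16, rbind(c(8.5, 8.5, 11)), sigma = 2)
  bare <- array(0, rep(16, 3))
  bare[, , 4:6] <- 1  # membrane slab only
  with_rec <- bare + 3 * clean
  set.seed(9)
  boxes <- c(lapply(1:12, function(i)
               with_rec + 0.3 * array(stats::rnorm(16^3), rep(16, 3))),
             lapply(1:12, function(i)
               bare + 0.3 * array(stats::rnorm(16^3), rep(16, 3))))
  st <- structure(list(boxes = boxes,
                       normals = matrix(rep(c(0, 0, 1), 24), 24,
                                        byrow = TRUE)),
                  class = "subvolume_stack")
  cls <- classify_3d(st, k = 2, seed = 9)
  tab <- table(cls$labels, rep(1:2, each = 12))
  expect_equal(sum(apply(tab, 1, max)), 24)  # permutation-invariant purity
  # the selected class is the self-consistent (receptor) one
  expect_gt(ncc(cls$class_volumes[[cls$selected]], with_rec), 0.9)
  expect_error(classify_3d(st, k = 1), "k must be")
})

test_that("classification accuracy is close to the template-threshold oracle", {
  # receptor-bearing vs membrane-only boxes (both classes share the slab,
  # as in a real pick stack) at the working noise level
  set.seed(19)
  clean <- blob_box(16, rbind(c(8.5, 8.5, 11)), sigma = 2)
  bare <- array(0, rep(16, 3))
  bare[, , 4:6] <- 1
  with_rec <- bare + 3 * clean
  truth <- rep(c(TRUE, FALSE), each = 15)
  boxes <- lapply(truth, function(has) {
    (if (has) with_rec else bare) +
      0.3 * array(stats::rnorm(16^3), rep(16, 3))
  })
  st <- structure(list(boxes = boxes,
                       normals = matrix(rep(c(0, 0, 1), 30), 30,
                                        byrow = TRUE)),
                  class = "subvolume_stack")
  cls <- classify_3d(st, k = 2, seed = 29)
  acc_cls <- max(mean((cls$labels == 1) == truth),
                 mean((cls$labels == 2) == truth))
  # oracle: NCC against the two noise-free templates
  acc_orc <- mean(vapply(seq_along(boxes), function(i) {
    (ncc(boxes[[i]], with_rec) > ncc(boxes[[i]], bare)) == truth[i]
  }, logical(1)))
  expect_gte(acc_cls, acc_orc - 0.05)
})

test_that("measured height is 0 for a bare membrane and monotone in the level", {
  bare <- array(0, rep(24, 3))
  bare[, , 8:10] <- 1
  h <- measure_height(bare, membrane_z = 10, pixel_size = 1)
  expect_true(h$flagged)
  expect_equal(h$height, 0)
  # single synthetic receptor: height decreases as the level rises
  # a side receptor (small normal tilt) so the wedge does not smear the
  # head along the measurement axis
  sp <- small_spec(seed = 86, n_filaments = 0, receptor_count = 1,
                   tube_radius = 24, receptor_band = c(28, 36),
                   noise_sigma = 0)
  sc <- simulate_scene(sp)
  gt <- sc$truth$receptor_placements
  picks <- data.frame(x = gt$x, y = gt$y, z = gt$z, nx = gt$nx, ny = gt$ny,
                      nz = gt$nz, kept = TRUE)
  st <- extract_picks(sc$volume, picks, box_edge = 32, center_offset = 6)
  av <- align_average(st, refine_shifts = 0)
  mz <- (32 / 2 - 0.5) * sp$pixel_size - 6  # pick sits on the outer leaflet
  hs <- vapply(c(0.3, 0.4, 0.5, 0.6, 0.7), function(lv)
    measure_height(av$model, mz, level = lv, pixel_size = sp$pixel_size)$height,
    numeric(1))
  expect_true(all(diff(hs) < 1e-9))
  # generator self-consistency: at the 0.5 level the extent is the height
  expect_lt(abs(hs[3] - sp$receptor_height), 1.2)
})

test_that("rigid fitting is exact on self-rendered maps and recovers shifts", {
  set.seed(23)
  ref <- data.frame(x = stats::rnorm(15, 12, 3), y = stats::rnorm(15, 12, 3),
                    z = stats::rnorm(15, 12, 3), weight = 1)
  vol <- array(0, rep(24, 3))
  sigma <- 25 / 10 / (2 * sqrt(2 * log(2)))
  vol <- tomopod:::rasterize_gaussians(vol, as.matrix(ref[, 1:3]) -
                                         matrix(colMeans(as.matrix(ref[, 1:3])),
                                                15, 3, byrow = TRUE) +
                                         matrix((24 - 1) / 2, 15, 3),
                                       sigma, 1, 1)
  fit <- rigid_fit_score(vol, ref, resolution = 25, pixel_size = 1,
                         rot_step = 45, refine = FALSE)
  expect_gt(fit$ncc, 0.99)
  expect_lt(max(abs(fit$translation_nm)), 0.51)
  # a translated map reports the translation within half a voxel
  shifted <- tomopod:::shift_int3(vol, c(3, -2, 0))
  fit2 <- rigid_fit_score(shifted, ref, resolution = 25, pixel_size = 1,
                          rot_step = 45, refine = FALSE)
  expect_equal(fit2$translation_nm[1:2], c(3, -2), tolerance = 0.51)
})

test_that("clustered picks are detected as non-random; small inputs error", {
  th <- seq(0, 2 * pi, length.out = 150)
  surface <- data.frame(x = rep(seq(0, 100, by = 2), each = 150),
                        y = 30 * cos(th), z = 30 * sin(th))
  clustered <- surface[surface$x < 12 & abs(surface$y - 30) < 10, ][1:12, ]
  out <- spatial_randomness_test(clustered, surface, n_mc = 999, seed = 5)
  expect_lte(out$p_value, 0.01)
  expect_error(spatial_randomness_test(clustered, surface, n_mc = 0),
               "n_mc")
  expect_error(spatial_randomness_test(clustered[1:3, ], surface, 99),
               "insufficient")
})

test_that("spatial-randomness p-values are uniform under the uniform null", {
  th <- seq(0, 2 * pi, length.out = 100)
  surface <- data.frame(x = rep(seq(0, 100, by = 2.5), each = 100),
                        y = 30 * cos(th), z = 30 * sin(th))
  set.seed(77)
  ps <- vapply(1:100, function(r) {
    picks <- surface[sample(nrow(surface), 20), ]
    spatial_randomness_test(picks, surface, n_mc = 99, seed = 7000 + r)$p_value
  }, numeric(1))
  ks <- max(abs(sort(ps) - (seq_along(ps) - 0.5) / length(ps)))
  expect_lt(ks, 0.15)
})
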