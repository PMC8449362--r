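test_that("tip_fraction 1 points every barbed end tip-ward", {
  sp <- small_spec(seed = 11, tip_fraction = 1)
  traces <- place_filaments(sp)
  expect_true(all(vapply(traces, function(tr) tr$barbed_dir[1] > 0,
                         logical(1))))
})

test_that("realized tip-ward count follows the binomial composition", {
  # oracle: exact central 99% binomial interval for n = 200, p = 0.74
  sp <- scene_spec(volume_shape = c(512, 320, 320), pixel_size = 1.1,
                   tube_radius = 120, support_z = 8, tube_length = 480,
                   n_filaments = 200, tip_fraction = 0.74, seed = 21)
  traces <- place_filaments(sp)
  n_tip <- sum(vapply(traces, function(tr) tr$barbed_dir[1] > 0, logical(1)))
  bounds <- stats::qbinom(c(0.005, 0.995), 200, 0.74)
  expect_gte(n_tip, bounds[1])
  expect_lte(n_tip, bounds[2])
})

test_that("trace point order is independent of polarity", {
  sp <- small_spec(seed = 31, tip_fraction = 1)
  traces <- place_filaments(sp)
  # all barbed ends tip-ward, yet point order runs both ways
  ord <- vapply(traces, function(tr) {
    sign(tr$points[nrow(tr$points), 1] - tr$points[1, 1])
  }, numeric(1))
  expect_true(length(unique(ord)) == 2)
  # true_polarity recovers the barbed direction through the point order
  for (tr in traces) {
    v <- tr$points[nrow(tr$points), ] - tr$points[1, ]
    expect_gt(sum(tr$true_polarity * v * tr$barbed_dir), 0)
  }
})

test_that("an impossibly small tube raises a placement error", {
  expect_error(
    place_filaments(scene_spec(volume_shape = c(64, 32, 32),
                               tube_radius = 8, tube_length = 30,
                               n_filaments = 2)),
    "too small")
})

test_that("receptor placements respect the height band", {
  sp <- small_spec(seed = 41, n_filaments = 0, receptor_count = 8,
                   receptor_band = c(20, 40))
  mem <- place_membrane_and_receptors(sp)
  expect_equal(nrow(mem$placements), 8)
  expect_true(all(mem$placements$height_above_support >= 20))
  expect_true(all(mem$placements$height_above_support <= 40))
  # placements lie on the outer leaflet of the tube
  d <- tomopod:::.tube_signed_dist(
    as.matrix(mem$placements[, c("x", "y", "z")]), mem$geom)
  expect_true(all(abs(d - 2.5) < 1e-6))
})

test_that("receptor count 0 leaves a smooth membrane with no extracellular density", {
  sp <- small_spec(seed = 42, n_filaments = 0, receptor_count = 0)
  mem <- place_membrane_and_receptors(sp)
  # sample a shell 5-10 nm outside the outer leaflet, above the support
  geom <- mem$geom
  gam <- seq(-0.5, 0.9, length.out = 25)  # stay clear of the support film
  xs <- seq(15, geom$cap_x - 15, length.out = 25)
  pts <- cbind(rep(xs, each = 25),
               geom$yc + (geom$R + 9) * cos(gam),
               geom$zc + (geom$R + 9) * sin(gam))
  vals <- tomopod:::trilinear_sample(mem$density, pts / sp$pixel_size + 1)
  expect_lt(max(vals), 0.02)
})

test_that("an infeasible receptor demand raises a surface-site error", {
  expect_error(
    place_membrane_and_receptors(
      small_spec(n_filaments = 0, receptor_count = 400,
                 receptor_band = c(20, 30))),
    "surface sites")
})

test_that("a 90-degree tilt range leaves the volume untouched", {
  v <- array(stats::rnorm(16 * 12 * 8), c(16, 12, 8))
  expect_equal(apply_imaging_model(v, tilt_range = 90, noise_sigma = 0), v)
})

test_that("the zeroed Fourier fraction matches a brute-force wedge count", {
  nx <- 24; nz <- 16; px <- 1.1
  keep <- wedge_keep_mask(nx, nz, 60, px)
  # oracle: per-voxel angle test with explicit loops
  brute <- matrix(NA, nx, nz)
  for (i in 1:nx) for (k in 1:nz) {
    fx <- (if (i - 1 <= nx / 2) i - 1 else i - 1 - nx) / (nx * px)
    fz <- (if (k - 1 <= nz / 2) k - 1 else k - 1 - nz) / (nz * px)
    brute[i, k] <- atan2(abs(fz), abs(fx)) * 180 / pi <= 60 + 1e-12
  }
  brute[1, 1] <- TRUE
  expect_identical(keep, brute)
  # the continuum wedge solid fraction is 1/3; discrete 24x16 grid nearby
  expect_lt(abs(sum(!keep) / length(keep) - 1 / 3), 0.06)
})

test_that("the wedge filter is idempotent and never increases power", {
  v <- array(stats::rnorm(32 * 24 * 16), c(32, 24, 16))
  w1 <- apply_imaging_model(v, 60, 0)
  w2 <- apply_imaging_model(w1, 60, 0)
  expect_equal(w1, w2, tolerance = 1e-10)
  expect_lte(sum(w1^2), sum(v^2))
})

test_that("the wedge filter is linear", {
  a <- array(stats::rnorm(16^3), rep(16, 3))
  b <- array(stats::rnorm(16^3), rep(16, 3))
  expect_equal(apply_imaging_model(2 * a + 3 * b, 60, 0),
               2 * apply_imaging_model(a, 60, 0) +
                 3 * apply_imaging_model(b, 60, 0),
               tolerance = 1e-10)
})

test_that("scene generation is bit-reproducible under a fixed seed", {
  s1 <- simulate_scene(small_spec(seed = 99, n_filaments = 4))
  s2 <- simulate_scene(small_spec(seed = 99, n_filaments = 4))
  expect_identical(s1$volume$grid, s2$volume$grid)
  expect_identical(traces_to_table(s1$truth$traces),
                   traces_to_table(s2$truth$traces))
})

test_that("noise-free scenes back-project ground truth into nonzero density", {
  sc <- simulate_scene(small_spec(seed = 55, n_filaments = 4,
                                  receptor_count = 4, noise_sigma = 0,
                                  receptor_band = c(18, 30)))
  g <- sc$volume$grid
  px <- sc$volume$pixel_size
  for (tr in sc$truth$traces) {
    # the subunits wind around the centerline at ~1.8 nm radius, so probe
    # a small transverse neighborhood of every trace point
    inner <- tr$points[2:(nrow(tr$points) - 1), , drop = FALSE]
    best <- rep(-Inf, nrow(inner))
    for (off in list(c(0, 0, 0), c(0, 1.8, 0), c(0, -1.8, 0),
                     c(0, 0, 1.8), c(0, 0, -1.8),
                     c(0, 1.3, 1.3), c(0, -1.3, 1.3),
                     c(0, 1.3, -1.3), c(0, -1.3, -1.3))) {
      pts <- sweep(inner, 2, off, "+")
      best <- pmax(best, tomopod:::trilinear_sample(g, pts / px + 1))
    }
    expect_true(all(best > 0.03 * max(g)))
  }
  rp <- sc$truth$receptor_placements
  heads <- cbind(rp$x + 5 * rp$nx, rp$y + 5 * rp$ny, rp$z + 5 * rp$nz)
  expect_true(all(tomopod:::trilinear_sample(g, heads / px + 1) > 0.01 * max(g)))
})
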