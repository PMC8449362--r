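test_that("a full-thickness unmasked slab equals the plain z-sum", {
  box <- array(stats::rnorm(16^3), rep(16, 3))
  img <- project_slab(box, thickness = 16, pixel_size = 1,
                      mask_radius = Inf)
  expect_equal(img, apply(box, c(1, 2), sum), tolerance = 1e-12)
})

test_that("a uniform subvolume projects to a uniform image inside the mask", {
  box <- array(1, rep(24, 3))
  img <- project_slab(box, thickness = 11, pixel_size = 1, mask_radius = 6)
  # pixels on the axis, away from the taper, all equal
  expect_lt(stats::sd(img[8:17, 12:13]), 1e-10)
  expect_error(project_slab(box, thickness = 0), "thickness")
})

test_that("rotate_to_axis maps the tangent onto +x", {
  img <- matrix(stats::rnorm(32^2), 32)
  a1 <- rotate_to_axis(img, c(1, 0, 0))
  expect_equal(a1$inplane_angle, 0)
  expect_equal(a1$image, img, tolerance = 1e-9)
  a2 <- rotate_to_axis(img, c(0, 1, 0))
  expect_equal(a2$inplane_angle, -90)
  # a feature along +y lands along +x after alignment
  im <- matrix(0, 32, 32); im[16:17, 17:28] <- 1
  al <- rotate_to_axis(im, c(0, 1, 0))$image
  expect_gt(sum(al[17:28, 16:17]), 0.8 * sum(im))
})

test_that("rotation preserves total intensity within interpolation tolerance", {
  im <- outer(exp(-(1:32 - 15)^2 / 18), exp(-(1:32 - 18)^2 / 18))
  rot <- rotate_to_axis(im, c(cos(37 * pi / 180), sin(37 * pi / 180), 0))
  expect_lt(abs(sum(rot$image) - sum(im)) / sum(im), 0.01)
})

test_that("tangents within 5 degrees of the beam axis are unusable", {
  img <- matrix(0, 8, 8)
  expect_false(rotate_to_axis(img, c(0.03, 0.03, 0.999))$usable)
  expect_true(rotate_to_axis(img, c(0.3, 0, 0.95))$usable)
})

test_that("two distinct noise-free templates separate perfectly at k = 2", {
  t1 <- outer(exp(-(1:24 - 8)^2 / 8), exp(-(1:24 - 12)^2 / 8))
  t2 <- outer(exp(-(1:24 - 16)^2 / 30), exp(-(1:24 - 12)^2 / 4)) +
    outer(exp(-(1:24 - 6)^2 / 6), exp(-(1:24 - 6)^2 / 6))
  imgs <- c(rep(list(t1), 50), rep(list(t2), 50))
  cls <- classify_2d(imgs, k = 2, n_iter = 5, seed = 3)
  tab <- table(cls$labels, rep(1:2, each = 50))
  # perfect separation up to label permutation
  expect_equal(sum(apply(tab, 1, max)), 100)
})

test_that("classification is reproducible bit-for-bit given a seed", {
  set.seed(10)
  imgs <- lapply(1:30, function(i) matrix(stats::rnorm(256), 16))
  c1 <- classify_2d(imgs, k = 3, n_iter = 4, seed = 7)
  c2 <- classify_2d(imgs, k = 3, n_iter = 4, seed = 7)
  expect_identical(c1$labels, c2$labels)
  expect_identical(c1$shifts, c2$shifts)
  expect_identical(c1$class_averages, c2$class_averages)
})

test_that("polarity scores are invariant to intensity scaling and offset", {
  bank <- get_bank()
  tm <- actin_templates(helical_params(), 32, 1.1, 11)
  img <- tm$plus[[3]]
  a <- polarity_of_class(img, bank)
  b <- polarity_of_class(5 * img + 2, bank)
  expect_equal(a$score_plus, b$score_plus, tolerance = 1e-9)
  expect_equal(a$score_minus, b$score_minus, tolerance = 1e-9)
})

test_that("a model projection labels +1 with near-perfect score; its flip -1", {
  bank <- get_bank()
  tm <- actin_templates(helical_params(), 32, 1.1, 11)
  pol <- polarity_of_class(tm$plus[[1]], bank)
  expect_equal(pol$label, 1L)
  expect_gt(pol$score_plus, 0.99)
  flipped <- tm$plus[[1]][rev(seq_len(32)), ]
  pol2 <- polarity_of_class(flipped, bank)
  expect_equal(pol2$label, -1L)
  expect_gt(pol2$score_minus, 0.99)
})

test_that("class labels agree with member ground truth on noise-free scenes", {
  fx <- get_nf_scene()
  cfg <- default_config()
  res <- run_polarity_pooled(list(fx$prep), cfg, seed = 62,
                             templates = get_bank())
  tp <- truth_map(fx$scene)
  segs <- res$segments[[1]]
  voted <- segs$polarity_vote != 0
  expect_gt(sum(voted), 50)
  expect_gt(mean(segs$polarity_vote[voted] == tp[segs$filament_id[voted]]),
            0.9)
  # every selected class label equals the majority truth of its members
  cls <- res$classification
  n1 <- sum(segs$usable)
  info <- res$class_info
  for (c_ in info$class[info$selected]) {
    mem <- which(cls$labels == c_)
    # map augmented indices back to original segments (mirror copies vote
    # with the opposite sign)
    segs_idx <- which(segs$usable)
    eff <- vapply(mem, function(m) {
      orig <- if (m > n1) m - n1 else m
      sgn <- if (m > n1) -1L else 1L
      sgn * tp[segs$filament_id[segs_idx[orig]]] *
        ifelse(cls$rot180[m], -1L, 1L)
    }, integer(1))
    maj <- if (mean(eff == 1L) >= 0.5) 1L else -1L
    expect_equal(info$label[info$class == c_], maj)
  }
})

test_that("select_classes applies the margin and membership rules", {
  sc <- simulate_scene(small_spec(seed = 63, noise_sigma = 0))
  cfg <- small_config()
  prep <- prepare_polarity_images(sc$volume, sc$truth$traces, cfg)
  imgs <- prep$images[prep$segments$usable]
  cls <- classify_2d(imgs, k = 6, n_iter = 6, seed = 64)
  # margin 0, min_members 0: every class retained
  sel_all <- select_classes(cls, get_bank(), margin = 0, min_members = 0)
  expect_true(all(sel_all$class_info$selected |
                  sel_all$class_info$label == 0))
  # an impossible membership floor discards everything
  expect_error(select_classes(cls, get_bank(), margin = 0.05,
                              min_members = 10000),
               "discarded")
  # min_members excludes small classes
  sel <- select_classes(cls, get_bank(), margin = 0,
                        min_members = max(cls$member_count))
  small_cl <- which(cls$member_count < max(cls$member_count))
  expect_true(all(!sel$class_info$selected[small_cl]))
})

test_that("axially flipping every input flips every vote", {
  # tested on the non-augmented path: the classification of the mirrored
  # set follows the exactly mirrored trajectory (flip augmentation
  # inserts the mirrors into the pool in a different order, which only
  # preserves the property statistically)
  fx <- get_nf_scene()
  cfg <- default_config()
  res1 <- run_polarity_pooled(list(fx$prep), cfg, seed = 66,
                              templates = get_bank(), augment_flip = FALSE)
  prep_f <- fx$prep
  for (i in which(prep_f$segments$usable)) {
    prep_f$images[[i]] <- prep_f$images[[i]][rev(seq_len(32)), ]
  }
  res2 <- run_polarity_pooled(list(prep_f), cfg, seed = 66,
                              templates = get_bank(), augment_flip = FALSE)
  expect_equal(res2$segments[[1]]$polarity_vote,
               -res1$segments[[1]]$polarity_vote)
})

test_that("vote quality is close to the brute-force template-match oracle", {
  # oracle: direct NCC of every raw aligned image against both template
  # banks. Classification trades a little of the matched-filter's
  # per-image accuracy for model-free class averages; it must stay close.
  fx <- get_noisy_pool()
  prepped <- fx$prepped; truths <- fx$truths
  bank <- get_bank()
  res <- run_polarity_pooled(prepped, default_config(), seed = 73,
                             templates = bank)
  acc_cls <- c(); acc_orc <- c()
  for (s in 1:3) {
    segs <- res$segments[[s]]
    tp <- truths[[s]][segs$filament_id]
    v <- segs$polarity_vote != 0
    acc_cls <- c(acc_cls, (segs$polarity_vote == tp)[v])
    for (i in which(segs$usable)) {
      sc_ <- as.vector(tomopod:::normalize_vec(prepped[[s]]$images[[i]]) %*%
                         bank$V)
      vote <- if (max(sc_[bank$group == "plus"]) >
                  max(sc_[bank$group == "minus"])) 1L else -1L
      acc_orc <- c(acc_orc, vote == tp[i])
    }
  }
  expect_gt(mean(acc_cls), 0.7)
  expect_gt(mean(acc_cls), mean(acc_orc) - 0.15)
})
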