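# Shared fixtures, built in code. Small scenes keep the unit tests fast;
# the acceptance tests use the full desk-scale study conditions.

small_spec <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(volume_shape = c(160, 96, 80), pixel_size = 1.1,
         n_filaments = 6, length_range = c(40, 70),
         tube_radius = 28, support_z = 4, tube_length = 150,
         seed = seed),
    list(...))
  do.call(scene_spec, args)
}

small_config <- function(...) {
  args <- utils::modifyList(
    list(volume_shape = c(160, 96, 80), n_filaments = 6,
         length_range = c(40, 70), tube_radius = 28, support_z = 4,
         tube_length = 150, k = 8, min_members = 6, n_min = 3),
    list(...))
  do.call(default_config, args)
}

# template bank, built once per test run
.bank_cache <- new.env()
get_bank <- function() {
  if (is.null(.bank_cache$bank)) {
    tm <- actin_templates(helical_params(), 32, 1.1, 11)
    .bank_cache$bank <- tomopod:::.template_bank(tm, shift_max = 3)
  }
  .bank_cache$bank
}

# cached full-size fixtures for the polarity machinery tests (built once)
get_nf_scene <- function() {
  if (is.null(.bank_cache$nf)) {
    sc <- simulate_scene(scene_spec(seed = 61, noise_sigma = 0))
    prep <- prepare_polarity_images(sc$volume, sc$truth$traces,
                                    default_config())
    .bank_cache$nf <- list(scene = sc, prep = prep)
  }
  .bank_cache$nf
}

get_noisy_pool <- function() {
  if (is.null(.bank_cache$pool)) {
    prepped <- list(); truths <- list()
    for (s in 1:3) {
      sc <- simulate_scene(scene_spec(seed = 70 + s))
      prepped[[s]] <- prepare_polarity_images(sc$volume, sc$truth$traces,
                                              default_config())
      truths[[s]] <- truth_map(sc)
    }
    .bank_cache$pool <- list(prepped = prepped, truths = truths)
  }
  .bank_cache$pool
}

# ground-truth polarity per filament_id from a scene
truth_map <- function(scene) {
  vapply(scene$truth$traces, function(tr) tr$true_polarity, integer(1))
}

# a simple Gaussian-blob cubic test volume
blob_box <- function(n = 24, centers, sigma = 2, weight = 1, px = 1) {
  vol <- array(0, rep(n, 3))
  tomopod:::rasterize_gaussians(vol, centers, sigma, weight, px)
}
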