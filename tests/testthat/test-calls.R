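test_that("the binomial confidence matches exact enumeration", {
  # oracle: direct enumeration of 10-vote outcomes with >= 8 agreeing
  p_enum <- sum(choose(10, 8:10)) / 2^10
  expect_equal(p_enum, 0.0546875)
  v <- vote_filament(c(rep(1, 8), rep(-1, 2)), alpha = 0.05, n_min = 5)
  expect_equal(v$confidence_p, p_enum)
  expect_false(v$resolved)  # 0.0547 > alpha = 0.05
  expect_equal(v$majority, 1L)
})

test_that("unanimous votes resolve, exact ties never do", {
  v <- vote_filament(rep(1, 10))
  expect_true(v$resolved)
  expect_equal(v$majority_fraction, 1)
  tie <- vote_filament(c(rep(1, 5), rep(-1, 5)))
  expect_false(tie$resolved)
  expect_equal(tie$majority, 0L)
  empty <- vote_filament(integer(0))
  expect_false(empty$resolved)
  expect_equal(empty$n_votes, 0)
  zeros <- vote_filament(c(0L, 0L, 0L))
  expect_false(zeros$resolved)
})

test_that("the stringent criterion never resolves what the default left unresolved", {
  set.seed(17)
  for (i in 1:200) {
    n <- sample(0:25, 1)
    votes <- sample(c(-1L, 0L, 1L), n, replace = TRUE)
    lax <- vote_filament(votes, alpha = 0.05)
    strict <- vote_filament(votes, alpha = 0.01)
    expect_true(!strict$resolved || lax$resolved)
  }
})

test_that("tip direction recovers the tube axis and rotates with the scene", {
  sp <- small_spec()
  ax <- tip_direction(membrane_interior_mask(sp), sp$pixel_size)
  expect_gt(sum(ax * c(1, 0, 0)), cos(2 * pi / 180))
  # a tube built along a rotated axis yields the rotated tip direction
  R <- rotation_about_axis(c(0, 0, 1), 30)
  d <- c(64, 64, 64); px <- 1.1
  ctr <- (d - 1) * px / 2
  g <- expand.grid(i = 1:d[1], j = 1:d[2], k = 1:d[3])
  pts <- sweep(cbind(g$i - 1, g$j - 1, g$k - 1) * px, 2, ctr)
  loc <- pts %*% R  # coordinates in the rotated tube frame
  inside <- sqrt(loc[, 2]^2 + loc[, 3]^2) < 12 &
    loc[, 1] > -30 &
    (loc[, 1] < 18 | sqrt((loc[, 1] - 18)^2 + loc[, 2]^2 + loc[, 3]^2) < 12)
  mask <- array(inside, d)
  ax_rot <- tip_direction(mask, px)
  expected <- as.vector(R %*% c(1, 0, 0))
  expect_gt(sum(ax_rot * expected), cos(2 * pi / 180))
})

test_that("tip direction handles overrides and degenerate masks", {
  expect_equal(tip_direction(override = c(0, 3, 0)), c(0, 1, 0))
  expect_error(tip_direction(override = c(0, 0, 0)), "zero")
  ball <- array(FALSE, c(32, 32, 32))
  g <- expand.grid(i = 1:32, j = 1:32, k = 1:32)
  ball[(g$i - 16)^2 + (g$j - 16)^2 + (g$k - 16)^2 < 100] <- TRUE
  expect_error(tip_direction(ball), "override")
  expect_error(tip_direction(array(FALSE, c(4, 4, 4))), "empty")
})

make_calls <- function(majorities, resolved = TRUE) {
  data.frame(filament_id = seq_along(majorities), n_votes = 10,
             n_plus = ifelse(majorities > 0, 9, 1),
             n_minus = ifelse(majorities > 0, 1, 9),
             majority = majorities, majority_fraction = 0.9,
             confidence_p = 0.01, resolved = resolved)
}

straight_traces <- function(dirs) {
  lapply(seq_along(dirs), function(i) {
    filament_trace(i, rbind(c(0, 0, 0), dirs[[i]] * 50))
  })
}

test_that("fractions sum to one and tip-axis negation swaps them exactly", {
  calls <- make_calls(c(1, 1, 1, -1, -1))
  traces <- straight_traces(rep(list(c(1, 0, 0)), 5))
  s1 <- summarize_fractions(calls, traces, c(1, 0, 0))
  expect_equal(s1$per_tomogram$tip_ward_fraction +
               s1$per_tomogram$cell_ward_fraction, 1)
  expect_equal(s1$aggregate_mean, 60)
  s2 <- summarize_fractions(calls, traces, c(-1, 0, 0))
  expect_equal(s2$aggregate_mean, 100 - s1$aggregate_mean)
})

test_that("a single tomogram of unanimous tip-ward calls reports 100% +/- 0", {
  calls <- make_calls(c(1, 1, 1))
  traces <- straight_traces(rep(list(c(1, 0, 0)), 3))
  s <- summarize_fractions(calls, traces, c(1, 0, 0))
  expect_equal(s$aggregate_mean, 100)
  expect_equal(s$aggregate_sd, 0)
})

test_that("a zero dot product counts cell-ward and is logged", {
  calls <- make_calls(1)
  traces <- straight_traces(list(c(0, 1, 0)))  # perpendicular to the tip
  s <- summarize_fractions(calls, traces, c(1, 0, 0))
  expect_equal(s$zero_dot_count, 1L)
  expect_equal(s$per_tomogram$cell_ward_fraction, 1)
})

test_that("the fraction estimator is unbiased across seeds", {
  # vote-level simulation: per-segment votes at 0.9 accuracy, aggregated
  # by the full call/summary machinery across >= 20 seeded replicates
  tip_frac <- 0.74
  rec <- vapply(1:24, function(sd) {
    set.seed(1000 + sd)
    n_f <- 40
    tipward <- stats::runif(n_f) < tip_frac
    dir_sign <- sample(c(1, -1), n_f, replace = TRUE)  # trace order
    true_vote <- ifelse(tipward, 1, -1) * dir_sign
    segs <- do.call(rbind, lapply(1:n_f, function(f) {
      n_s <- sample(8:16, 1)
      votes <- ifelse(stats::runif(n_s) < 0.9, true_vote[f], -true_vote[f])
      data.frame(filament_id = f, polarity_vote = as.integer(votes))
    }))
    calls <- call_filaments(segs)
    traces <- lapply(1:n_f, function(f)
      filament_trace(f, rbind(c(0, 0, 0), c(dir_sign[f] * 50, 0, 0))))
    summarize_fractions(calls, traces, c(1, 0, 0))$aggregate_mean
  }, numeric(1))
  se <- stats::sd(rec) / sqrt(length(rec))
  expect_lt(abs(mean(rec) - 100 * tip_frac), 2.5 * se + 0.5)
})
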