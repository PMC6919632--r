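test_that("the null entry distribution behaves as configured", {
  null0 <- null_entry_distribution(3, 8, sparsity = 0.3, n_sets = 60,
                                   seed = 1)
  expect_identical(null0, null_entry_distribution(3, 8, sparsity = 0.3,
                                                  n_sets = 60, seed = 1))
  # roughly symmetric about zero: random constraints carry no sign bias
  expect_lt(abs(mean(null0$entries)), 0.05)
  skew <- mean((null0$entries - mean(null0$entries))^3) /
    sd(null0$entries)^3
  expect_lt(abs(skew), 0.5)
  # full sparsity leaves nothing to pool
  suppressMessages(
    all_zero <- null_entry_distribution(2, 5, sparsity = 1, n_sets = 5,
                                        seed = 2))
  expect_identical(all_zero$n_entries, 0L)
  # higher sparsity pushes more mass into the near-zero window
  frac <- vapply(c(0.1, 0.8), function(p)
    null_entry_distribution(3, 8, sparsity = p, n_sets = 60,
                            seed = 3)$fraction_window, numeric(1))
  expect_gt(frac[2], frac[1])
})

test_that("null calibration matches the data's near-zero window", {
  expect_warning(
    cfg <- calibrate_null_from_data(rep(-1, 5), s = 2, dim = 6),
    "window")
  expect_identical(cfg$sparsity, 0)
  half <- c(runif(50, -0.1, 0.1), runif(50, 0.5, 1))
  cfg2 <- calibrate_null_from_data(half, s = 3, dim = 8)
  expect_equal(cfg2$sparsity, 0.5)
  set.seed(4)
  inw <- runif(400, -0.19, 0.19)
  cfg3 <- calibrate_null_from_data(c(inw, rep(-1, 100)), s = 3, dim = 8)
  expect_equal(cfg3$noise_variance, var(inw), tolerance = 1e-12)
  expect_error(calibrate_null_from_data(numeric(0), 1, 2), "empty")
})

test_that("calibrated null is rejected by integer-structured ESS entries", {
  # ESS of a simulated complex-balanced toy puts mass at -1, far out in the
  # null's tail: the qualitative data-vs-null contrast
  snap <- xyz_snapshot_cached()
  pipe <- ess_pipeline(snap, dimension = 1)
  ed <- entry_distribution(pipe$row_reduced)
  expect_gt(sum(ed$entries < -0.8), 0)
  cfg <- suppressWarnings(calibrate_null_from_data(ed$entries, s = 1,
                                                   dim = 3))
  nd <- null_entry_distribution(cfg$s, cfg$dim, cfg$sparsity,
                                cfg$noise_variance, n_sets = 200, seed = 5)
  frac_null_far <- mean(abs(nd$entries + 1) < 0.05)
  frac_data_far <- mean(abs(ed$entries + 1) < 0.05)
  expect_gt(frac_data_far, frac_null_far + 0.3)
})

test_that("bootstrap CIs collapse on noiseless data and cover the estimate", {
  snap <- hyperplane_snapshot(n = 150, v = c(1, 1, -1, -1) / 2, b = 0)
  pipe <- ess_pipeline(snap, dimension = 1)
  ci <- bootstrap_row_reduced_cis(snap, pipe$row_reduced, k = 1,
                                  n_replicates = 60, seed = 6)
  expect_identical(ci, bootstrap_row_reduced_cis(snap, pipe$row_reduced,
                                                 k = 1, n_replicates = 60,
                                                 seed = 6))
  expect_true(all(ci$lower <= ci$point + 1e-12))
  expect_true(all(ci$upper >= ci$point - 1e-12))
  expect_lt(max(ci$upper - ci$lower), 1e-8)
})

test_that("bootstrap CI width shrinks with the cell count on noisy data", {
  set.seed(13)
  width_at <- function(n) {
    v <- c(1, 1, -1) / sqrt(3)
    base <- hyperplane_snapshot(n = n, v = v, b = 0, seed = 14)
    noisy <- ensemble_snapshot(base$values + matrix(rnorm(n * 3, 0, 0.05),
                                                    n, 3),
                               base$channel_names, log_space = TRUE)
    pipe <- ess_pipeline(noisy, dimension = 1)
    ci <- bootstrap_row_reduced_cis(noisy, pipe$row_reduced, k = 1,
                                    n_replicates = 80, seed = 15)
    mean(ci$upper - ci$lower)
  }
  w_small <- width_at(60)
  w_big <- width_at(960)
  # bootstrap consistency: ~1/sqrt(n) scaling, so 16x cells ~ 4x narrower
  expect_lt(w_big, w_small / 2)
})
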