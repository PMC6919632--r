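test_that("covariance spectrum finds exact hyperplane normals", {
  v <- c(1, 1, -1) / sqrt(3)
  snap <- hyperplane_snapshot(n = 120, v = v, b = 0.3)
  sp <- fit_covariance_spectrum(snap)
  expect_lt(sp$values[1], 1e-20)
  expect_lt(min(sum((sp$vectors[, 1] - v)^2),
                sum((sp$vectors[, 1] + v)^2)), 1e-16)
  # eigenvectors orthonormal, values ascending
  expect_lt(max(abs(crossprod(sp$vectors) - diag(3))), 1e-8)
  expect_false(is.unsorted(sp$values))
})

test_that("covariance spectrum rejects degenerate input", {
  bad <- matrix(c(1, 2, 0, 3), 2, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(fit_covariance_spectrum(bad), "positive")
  const <- ensemble_snapshot(cbind(a = c(1, 1, 1), b = c(1, 2, 3)),
                             log_space = TRUE)
  expect_error(fit_covariance_spectrum(const), "zero-variance")
})

test_that("gap detection flags ratio jumps and ignores geometric decay", {
  g <- detect_gaps(c(1e-8, 1e-8, 1, 2))
  expect_identical(g$indices, 2L)
  expect_identical(g$chosen, 2L)
  expect_identical(detect_gaps(2^(1:10))$indices, integer(0))
  expect_true(is.na(detect_gaps(2^(1:10))$chosen))
  # a slow and a fast constraint produce two gaps at intermediate time
  net <- toy_network("xyz_slow")
  init <- sample_initial_conditions(net, 300, seed = 55)
  res <- integrate_ensemble(net, init, c(14, 2000))
  sp_mid <- fit_covariance_spectrum(res$snapshots[[1]])
  g_mid <- detect_gaps(sp_mid)
  expect_identical(g_mid$indices, c(1L, 2L))
  # at late time both constraints are converged: eigenvalue 2 is tiny too
  sp_late <- fit_covariance_spectrum(res$snapshots[[2]])
  expect_lt(sp_late$values[2] / sp_mid$values[2], 0.05)
})

test_that("ESS extraction honors gaps, fixed dimensions and nesting", {
  snap <- xyz_snapshot_cached()
  sp <- fit_covariance_spectrum(snap)
  ess <- extract_ess(sp, dimension = 1)
  expect_subspace_equal(ess$basis, cbind(c(-1, -1, 1) / sqrt(3)), tol = 0.05)
  full <- extract_ess(sp, dimension = 3)
  expect_identical(full$dim, 3L)
  expect_error(extract_ess(sp, dimension = 4), "outside")
  nested <- extract_ess(sp, nested = TRUE)
  expect_gt(length(nested), 0)
  for (i in seq_along(nested)[-1])
    expect_lt(max(principal_angles(nested[[i - 1]]$basis,
                                   nested[[i]]$basis)), 1e-8)
})

test_that("row reduction normalizes, sparsifies and preserves span", {
  # single vector: scaled so the largest-magnitude entry (channel 1) is 1
  one <- row_reduce_complete_pivoting(cbind(c(1, 1, -1, -1) / 2))
  expect_equal(unname(one$vectors), matrix(c(1, 1, -1, -1), 1))
  expect_identical(one$pivots, 1L)

  # identity rows are already reduced
  id <- row_reduce_complete_pivoting(diag(3))
  expect_equal(unname(id$vectors[order(id$pivots), ]), diag(3))

  # two rows spanning the (1,-1,0)/(0,1,-1) plane: exact RREF structure
  rr <- row_reduce_complete_pivoting(cbind(c(1, -1, 0), c(0, 1, -1)))
  expect_equal(sort(rr$pivots), c(1L, 2L))
  for (i in 1:2) {
    expect_identical(rr$vectors[i, rr$pivots[i]], 1)
    expect_identical(rr$vectors[i, rr$pivots[-i]], 0)
  }
  expect_subspace_equal(orthonormal_span(t(rr$vectors)),
                        orthonormal_span(cbind(c(1, -1, 0), c(0, 1, -1))))

  # property: span preserved on random bases
  set.seed(99)
  for (i in 1:20) {
    d <- sample(4:8, 1)
    s <- sample(1:(d - 1), 1)
    B <- orthonormal_span(matrix(rnorm(d * s), d, s))
    out <- row_reduce_complete_pivoting(B)
    expect_subspace_equal(orthonormal_span(t(out$vectors)), B)
    expect_true(all(out$vectors[cbind(1:s, out$pivots)] == 1))
  }
  expect_error(row_reduce_complete_pivoting(cbind(c(1, 1, 0), c(1, 1, 0))),
               "rank")
})

test_that("replaying a recorded reduction is bit-identical and pivot-stable", {
  set.seed(12)
  B <- orthonormal_span(matrix(rnorm(6 * 3), 6, 3))
  orig <- row_reduce_complete_pivoting(B)
  again <- replay_row_reduction(B, orig)
  expect_identical(orig$vectors, again$vectors)
  # rotating the basis within its span leaves the replayed entries intact
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  rot <- replay_row_reduction(B %*% Q, orig)
  expect_equal(rot$vectors, orig$vectors, tolerance = 1e-10)
})

test_that("entry pooling drops structural 0s and 1s and smooths the rest", {
  rr <- row_reduce_complete_pivoting(cbind(c(1, -1, 0), c(0, 1, -1)))
  ed <- entry_distribution(rr)
  # surviving entries are the two -1 off-pivot entries
  expect_identical(sort(unique(ed$entries)), -1)
  expect_equal(ed$fraction_window, 0)
  peak <- ed$density$x[which.max(ed$density$y)]
  expect_equal(peak, -1, tolerance = 0.01)
  # density has the kernel's spread around the atom at -1
  sd_emp <- sqrt(sum(ed$density$y * (ed$density$x - peak)^2) /
                 sum(ed$density$y))
  expect_equal(sd_emp, 0.04, tolerance = 0.01)

  # all entries exactly 0/1 -> empty pool reported as missing
  empty <- entry_distribution(row_reduce_complete_pivoting(diag(3)))
  expect_identical(empty$n_entries, 0L)
  expect_true(is.na(empty$fraction_window))
  expect_null(empty$density)
})
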