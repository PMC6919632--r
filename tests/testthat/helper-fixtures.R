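# Shared fixtures built in code.

# Log-space snapshot lying exactly on the hyperplane v . x = b, with
# arbitrary variation in the orthogonal directions.
hyperplane_snapshot <- function(n = 100, v = c(1, 1, -1), b = 0.5,
                                seed = 42) {
  v <- v / sqrt(sum(v^2))
  d <- length(v)
  comp <- svd(cbind(v), nu = d)$u[, -1, drop = FALSE]
  set.seed(seed)
  x <- matrix(rnorm(n * (d - 1)), n, d - 1) %*% t(comp)
  x <- x + b * matrix(v, n, d, byrow = TRUE)
  ensemble_snapshot(x, paste0("ch", seq_len(d)), log_space = TRUE)
}

# Two well-separated spherical Gaussian clusters in log space.
two_cluster_snapshot <- function(n1 = 300, n2 = 300, shift = 8, d = 2,
                                 seed = 7) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n1 * d), n1, d),
             matrix(rnorm(n2 * d, mean = shift), n2, d))
  ensemble_snapshot(x, paste0("m", seq_len(d)), log_space = TRUE)
}

# Simulated late-time xyz ensemble, memoized across tests.
xyz_snapshot_cached <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      net <- toy_network("xyz")
      init <- sample_initial_conditions(net, 300, seed = 101)
      cache <<- integrate_ensemble(net, init, 100)$snapshots[[1]]
    }
    cache
  }
})

expect_subspace_equal <- function(U, W, tol = 1e-8) {
  expect_lt(max(principal_angles(U, W)), tol)
}
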