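test_that("reaction vectors are products minus reactants in species order", {
  sp3 <- c("X", "Y", "Z")
  expect_equal(reaction_vector(reaction(c(X = 1, Y = 1), c(Z = 1)), sp3),
               c(X = -1, Y = -1, Z = 1))
  # catalytic species cancels
  expect_equal(reaction_vector(reaction(c(G = 1), c(G = 1, P = 1)),
                               c("G", "P")),
               c(G = 0, P = 1))
  # doubled reactant complex
  expect_equal(reaction_vector(reaction(c(X = 2), c(E = 1)), c("X", "E")),
               c(X = -2, E = 1))
  expect_error(reaction_vector(reaction(c(W = 1), c(Q = 1)), sp3),
               "outside")
})

test_that("reaction construction enforces its invariants", {
  expect_error(reaction(c(X = 1), c(X = 1)), "identical")
  expect_error(reaction(c(X = -1), c(Y = 1)), "nonnegative")
  expect_error(reaction(c(X = 1), c(Y = 1), rate = 0), "positive")
  expect_error(reaction_network(c("X", "X"), list()), "unique")
  # zero complex is legal
  deg <- reaction(c(P = 1), numeric(0), 2)
  expect_equal(reaction_vector(deg, "P"), c(P = -1))
})

test_that("stoichiometric subspace dimensions match hand computations", {
  expect_equal(stoichiometric_subspace(toy_network("xyz"))$dim, 1L)
  expect_equal(stoichiometric_subspace(toy_network("xyz_slow"))$dim, 2L)
  expect_equal(stoichiometric_subspace(toy_network("cycle3"))$dim, 2L)
  # basis really spans the reaction vectors
  net <- toy_network("xyz")
  b <- stoichiometric_subspace(net)$basis
  expect_subspace_equal(b, cbind(c(-1, -1, 1) / sqrt(3)))
})

test_that("conservation basis is orthogonal to S and completes the space", {
  for (nm in c("xyz", "cycle3", "kinase_phosphatase", "grn2")) {
    net <- toy_network(nm)
    S <- stoichiometric_subspace(net)
    W <- conservation_basis(net)
    expect_equal(S$dim + ncol(W), length(net$species))
    if (ncol(W) > 0)
      expect_lt(max(abs(crossprod(W, S$basis))), 1e-10)
    V <- reaction_matrix(net)
    expect_lt(max(abs(crossprod(W, V))), 1e-10)
  }
  # xyz: totals X - Y and X + Z are conserved
  W <- conservation_basis(toy_network("xyz"))
  for (w in list(c(1, -1, 0), c(1, 0, 1)))
    expect_lt(max(abs(w - W %*% crossprod(W, w))), 1e-10)
  # kinase-phosphatase conserves E, F and S + P
  Wk <- conservation_basis(toy_network("kinase_phosphatase"))
  for (w in list(c(1, 0, 0, 0), c(0, 0, 1, 0), c(0, 1, 0, 1)))
    expect_lt(max(abs(w - Wk %*% crossprod(Wk, w))), 1e-10)
})

test_that("deficiency follows n_complexes - n_linkage - s", {
  expect_identical(deficiency(toy_network("xyz")), 0L)       # 2 - 1 - 1
  expect_identical(deficiency(toy_network("cycle3")), 0L)    # 3 - 1 - 2
  ab <- reaction_network(c("A", "B"), list(reaction(c(A = 1), c(B = 1))))
  expect_identical(deficiency(ab), 0L)                       # 2 - 1 - 1
  expect_gte(deficiency(toy_network("grn2")), 0L)
  expect_gte(deficiency(random_grn(4, seed = 3)), 1L)
})

test_that("weak reversibility reflects strong connectivity of linkage classes", {
  expect_true(is_weakly_reversible(toy_network("cycle3")))
  expect_true(is_weakly_reversible(toy_network("xyz")))
  expect_false(is_weakly_reversible(toy_network("grn2")))
  expect_false(is_weakly_reversible(toy_network("kinase_phosphatase")))
  expect_true(is_weakly_reversible(random_cb_network(6, edge_fraction = 0.05,
                                                     seed = 9)))
})

test_that("mass-action right-hand side matches hand-written rate laws", {
  rhs <- mass_action_rhs(toy_network("xyz"))
  expect_equal(rhs(c(1, 1, 1)), c(X = 0, Y = 0, Z = 0))
  c0 <- c(2, 3, 5)
  expect_equal(unname(rhs(c0)), (5 - 6) * c(1, 1, -1))
  expect_error(rhs(c(-1, 1, 1)), "negative")

  # grn2 toy: dpB/dt = kB gB - delta pB + r gAB - f gA pB
  k <- c(kA = 1.3, kB = 0.7, f = 2.1, r = 0.4, kAB = 5, delta = 1.9)
  rhs2 <- mass_action_rhs(toy_network("grn2", rates = k))
  cc <- c(gA = 0.5, gB = 1.5, pA = 0.2, pB = 0.8, gAB = 0.3)
  expected_pB <- k[["kB"]] * cc[["gB"]] - k[["delta"]] * cc[["pB"]] +
    k[["r"]] * cc[["gAB"]] - k[["f"]] * cc[["gA"]] * cc[["pB"]]
  expect_equal(rhs2(cc)[["pB"]], expected_pB)

  # zero-complex degradation contributes -delta * [P]
  degnet <- reaction_network("P", list(reaction(c(P = 1), numeric(0), 1.9)))
  expect_equal(mass_action_rhs(degnet)(2), c(P = -1.9 * 2))
})

test_that("constraint residuals vanish on exact hyperplanes and are ~1 for isotropic data", {
  snap <- hyperplane_snapshot(n = 80, v = c(1, 1, -1), b = 0.5)
  v <- c(1, 1, -1) / sqrt(3)
  res <- constraint_residual(snap$values, v)
  expect_lt(res$variance, 1e-20)
  expect_equal(res$intercept, 0.5, tolerance = 1e-10)
  # v orthogonal to the data's support directions also gives variance 0
  set.seed(1)
  flat <- cbind(rnorm(50), rnorm(50), 0)
  expect_lt(constraint_residual(flat, c(0, 0, 1))$variance, 1e-20)
  # isotropic unit-variance data projected on a unit vector has variance ~ 1
  set.seed(2)
  iso <- matrix(rnorm(4000 * 3), 4000, 3)
  expect_equal(constraint_residual(iso, c(1, 0, 0))$variance, 1,
               tolerance = 0.15)
  expect_error(constraint_residual(iso[0, ], c(1, 0, 0)), "empty")
  expect_error(constraint_residual(iso, c(0, 0, 0)), "zero")
})
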