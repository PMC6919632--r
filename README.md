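# esskit

Infer reaction-network stoichiometry from the covariance of log-transformed
single-cell multiplex snapshots.

Multiplexed single-cell measurements (FACS, CyCIF, mass cytometry exports)
sample many cells of a population at one instant. If the cells share a
mass-action reaction network and have relaxed toward its steady states, the
steady-state set is *toric* for a broad class of networks (all
complex-balanced ones, and more): after an elementwise logarithm it is an
affine subspace whose orthogonal complement carries the stoichiometry. Each
reaction vector `v = (b1 - a1, ..., bn - an)` of a reaction
`a1 C1 + ... -> b1 C1 + ...` obeys the log-linear constraint

    v . log(c) = log(K),

so the sample covariance of `log(c)` across cells becomes singular along
the stoichiometric subspace `S = span{v}`. esskit extracts that singular
eigenspace — the **effective stoichiometric space (ESS)** — from the
small-eigenvalue principal components, cut at a spectral gap, and
re-expresses it as sparse, integer-like **net reaction** vectors by row
reduction with complete pivoting. Subspaces from different experimental
conditions are compared by principal angles `theta_i` and the metric
`d = sqrt(sum(theta_i^2))`; subpopulations are gated with Gaussian
mixtures before analysis; bootstrap intervals and a sparse-random null
distribution quantify the recovered entries.

The package is aimed at systems biologists who want a mechanistic,
parameter-free reading of single-cell covariance, and it ships the full
simulation apparatus (random deficiency-zero complex-balanced networks,
random gene-regulatory networks, the worked toy examples, stiff ODE
ensemble integration) used to validate the method.

## Worked example

Simulate 300 cells of the reversible association `X + Y <-> Z`
(`k1 = k-1 = 1`) to late time and read the stoichiometry back off the
snapshot:

```r
library(esskit)

net  <- toy_network("xyz")
init <- sample_initial_conditions(net, n_cells = 300, seed = 1)
snap <- integrate_ensemble(net, init, times = 100)$snapshots[[1]]

spec <- fit_covariance_spectrum(snap)   # log, center, eigendecompose
spec
#> eigen_spectrum: 3 channels, 300 cells
#>   eigenvalues (ascending): 5.43e-16, 4.09, 18.7

detect_gaps(spec)
#> gap_report: gaps after indices 1, 2 (chosen: 2; rightmost ratio >= 3)

rr <- row_reduce_complete_pivoting(extract_ess(spec, dimension = 1))
rr
#> row_reduced_basis: 1 net-reaction vector(s) over 3 channels
#>   X Y  Z
#> X 1 1 -1

constraint_residual(log(snap$values), rr$vectors[1, ])$variance
#> [1] 6.84e-31
```

One covariance eigenvalue has collapsed (5.4e-16 against 4.09 — the gap
after index 1), and its eigenvector, normalized to the pivot species `X`,
is `(1, 1, -1)`: the population varies freely along conserved totals but
is pinned to `[Z]/([X][Y]) = K`, i.e. the reaction `X + Y <-> Z` with unit
stoichiometry, recovered without knowing any rate constant. The residual
variance along the recovered vector is numerically zero.

The same machinery handles timescale splitting (`xyz_slow`), toric but
non-complex-balanced systems (`kinase_phosphatase`), hidden species
(`snapshot_channels()` + the maximal-net-reaction guarantee), GMM-gated
subpopulations (`fit_gmm()`, `select_subpopulation()`), condition
comparison (`compare_subspaces()`), and uncertainty
(`bootstrap_row_reduced_cis()`, `null_entry_distribution()`). A thin CLI
over these functions is installed at
`system.file("exec", "esskit", package = "esskit")`. See the methods
vignette (`vignettes/ess-methods.Rmd`) for the model, assumptions and
every tunable default.

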