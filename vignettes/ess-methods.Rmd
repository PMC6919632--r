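---
title: "Effective stoichiometric spaces from single-cell snapshot covariance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effective stoichiometric spaces from single-cell snapshot covariance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esskit)
```

## The model

esskit treats each cell in a multiplexed single-cell experiment (FACS,
CyCIF and similar modalities) as one trajectory of a shared mass-action
reaction network, observed once at a fixed time. For a reaction

\[
a_1 C_1 + \dots + a_n C_n \rightarrow b_1 C_1 + \dots + b_n C_n ,
\]

the *reaction vector* is \(\vec v = (b_1 - a_1, \dots, b_n - a_n)\), and the
*stoichiometric subspace* \(S\) is the span of all reaction vectors.
Trajectories are confined to affine translates (cosets) of \(S\), so every
vector \(w \perp S\) defines a conserved quantity \(w \cdot c(t)\).

For *complex-balanced* networks -- guaranteed whenever the deficiency
\(\delta = n_{\text{complexes}} - n_{\text{linkage classes}} - \dim S\) is
zero and the network is weakly reversible -- the steady-state set is *toric*:
after an elementwise logarithm it is an affine subspace \(V\) whose
orthogonal complement equals \(S\). Every \(\vec v \in S\) then satisfies a
log-linear constraint \(\vec v \cdot \log \vec c = \log K\) with a constant
\(K\) collecting rate constants. Consequently, as a population of cells
relaxes toward steady state, the sample covariance of \(\log \vec c\)
becomes singular exactly along \(S\): the eigenvectors of the smallest
covariance eigenvalues recover stoichiometry without knowing any rate
constant. The package calls the span of those small-eigenvalue eigenvectors
the *effective stoichiometric space* (ESS). Beyond complex balancing, any
network whose steady states lie inside a toric set (the kinase--phosphatase
system in the toy catalog is the canonical example) produces the same
signature, and the recovered vectors are *net reactions* -- integer
combinations of elementary reaction vectors.

Two refinements matter in practice:

* **Timescales.** Fast subnetworks reach their own steady sets first, so at
  intermediate times the ascending eigenvalue spectrum shows several gaps,
  one per resolved timescale, with nested subspaces
  \(S_1 \subset S_2 \subset \dots \subset S\).
* **Unobserved species.** If only \(n\) of \(N\) species are measured, the
  observable complement satisfies
  \(S_{\text{obs}} \oplus 0 = S \cap (\mathbb R^n \oplus 0)\): everything
  recovered is still a net reaction, and every net reaction expressible in
  observed species is recovered.

Measured intensities enter through the linear-fluorescence assumption
\(I_i = k_i c_i\); in log space a gain is an additive shift, so the
covariance, its eigenvectors and the ESS are unchanged
(`apply_gains()` exists precisely to assert this).

## Pipeline and tunable parameters

A typical run is `fit_covariance_spectrum()` → `detect_gaps()` →
`extract_ess()` → `row_reduce_complete_pivoting()`; `ess_pipeline()` chains
them.

* **Gap threshold** (`min_ratio = 3`, dimensionless). Gaps are flagged
  wherever consecutive ascending eigenvalues jump by at least this ratio. A
  ratio test is scale-free; 3 flags the worked examples' gaps while ignoring
  a geometric spectrum (ratio 2). Gap identification is intrinsically
  heuristic -- the original procedure was visual inspection -- so the
  threshold is an explicit knob and a fixed `dimension` can always be passed
  instead. The default *choice* among several gaps is the rightmost one,
  which keeps every resolved timescale.
* **Covariance estimator**: unbiased \(1/(N-1)\) sample covariance of
  natural-log data; channels with zero variance are rejected.
* **Row reduction**: Gauss--Jordan on the transposed basis with *complete*
  pivoting (largest remaining entry; ties toward the lowest column, then
  row index). Pivots are scaled to exactly 1 and eliminated entries set to
  exactly 0; the row/column permutation is recorded so bootstrap replicates
  can replay the identical elimination (`replay_row_reduction()`).
* **Entry pooling** (`entry_distribution()`): bandwidth 0.04 Gaussian
  kernel on the grid \([-1.5, 1.5]\) step 0.005; entries within `1e-9` of
  the structural 0s and 1s are excluded; the fraction inside \((-0.2, 0.2)\)
  summarizes sparsity.
* **GMM gating** (`fit_gmm()`): full-covariance mixtures fit by EM from
  `20 * k` k-means++ restarts, convergence at relative log-likelihood
  change `1e-8`, singular covariances rescued by diagonal jitter of
  `1e-6` times the channel variances. `choose_k()` picks the component
  count at the likelihood-gain elbow; a gain under twice the added
  parameter count is treated as overfitting noise, since best-of-restarts
  selection inflates pure-noise gains well above the chi-square mean.
* **Subspace comparison**: principal angles from the SVD of
  \(U^\top W\) (clipped into \([0,1]\)), with the sine-based residual
  formula below \(10^{-4}\) rad where the arccosine loses precision; the
  scalar metric is \(d = (\sum_i \theta_i^2)^{1/2}\), meaningful only for
  equal dimensions (inter-condition comparisons default to a common 10-D
  cutoff).
* **Resampling**: percentile bootstrap (1000 replicates by default) with
  the replicate basis rotated within its span to best align with the
  original before the recorded elimination is replayed -- eigenvectors are
  only defined up to rotation/sign, and without alignment entries would
  flip arbitrarily between replicates. The null model draws `s` vectors
  uniform on \((-0.5, 0.5)\), zeroes entries with the calibrated sparsity,
  row-reduces, discards pivot columns and adds calibrated Gaussian noise.
  Discarding by column (rather than by value) keeps the zeros inherited
  from sparsification, which are the null's counterpart of the data's
  near-zero peak; value-based exclusion would make the configured sparsity
  unobservable in the null's window fraction.

## What the simulators emulate

`sample_initial_conditions()` plus `integrate_ensemble()` emulate a
clonal population with lognormal cell-to-cell variation in initial
abundances, relaxing under deterministic mass-action kinetics:

* **Complex-balanced ensembles** (`random_cb_network()`): 20 species;
  complexes are single species or unordered pairs of distinct species;
  0.03% of ordered node pairs are sampled as edges and symmetrized (hence
  weak reversibility); candidates are rejected until deficiency is zero;
  rate constants are lognormal with log-variance 0.05 around one of two
  log-means (2.5 and 3), assigned per reversible pair, to create separated
  timescales. Initial conditions: log-mean 4, log-variance 4. "Possible
  edges" are read as ordered distinct node pairs without self-loops, and
  doubled complexes (2X) are excluded by default (`allow_doubled` enables
  them); the source construction is ambiguous on both counts.
* **Gene-regulatory ensembles** (`random_grn()`): `n` genes, `n` proteins,
  and 70% of the `n^2` possible protein-bound genes, with production from
  unbound genes (log-mean 1, log-variance 1), bound production (3, 3),
  reversible binding (3, 1) and a fixed degradation rate `exp(3)`. Initial
  conditions: log-mean 5, log-variance 8. These networks are deliberately
  non-complex-balanced (irreversible production/degradation breaks weak
  reversibility); their binding subnetwork is exactly log-linear at steady
  state, the gene-to-protein balance `k_i g_i = delta p_i` is log-linear
  despite not being a reaction vector, and the per-protein production
  balances are only asymptotically log-linear -- which is why one set of
  eigenvectors converges onto the binding subspace while `n` more tilt away
  from \(S\) by up to about \(\pi/3\).
* **Toy catalog** (`toy_network()`): the worked examples with their printed
  rate constants (`xyz` with \(k_1 = k_{-1} = 1\); `xyz_slow` adding
  \(X \rightleftharpoons Y\) at \(k_f = 0.2, k_r = 0.1\); the three-species
  cycle; the kinase--phosphatase system and its two-enzyme and open
  variants; the two-gene GRN toy). Unprinted rates default to 1.

What the generators do **not** emulate: measurement noise, antibody
cross-reactivity or saturation (the linear-fluorescence assumption is
exact in simulation), stochastic (finite-copy) kinetics, cell cycle or
volume effects, and multimodal populations other than those induced by the
initial-condition distribution. Passing tests therefore demonstrate that
the inference recovers stoichiometry under the model's own assumptions;
they say nothing about robustness to optics-level artifacts in real data.

## Numerical choices

* Rank and span decisions use a relative singular-value cutoff of
  `1e-10`; eigenvalues are clamped at 0; natural logarithms throughout
  (a fixed base change only shifts intercepts).
* Integration uses lsoda (stiff-capable, automatic switching) at
  `rtol = 1e-8`, `atol = 1e-10`, 1e5 step budget. Cells whose integration
  fails are dropped with a warning rather than aborting the ensemble;
  conserved-coset drift is held to `1e-6` relative. Concentrations are
  clipped at `1e-300` before logs.
* `converge_ensemble()` implements the "late time" contract: double the
  horizon until the largest below-gap eigenvalue falls by less than 1% per
  doubling, capped at `t = 1e4`. Fixed-horizon snapshots are used where a
  printed time exists.
* Degenerate inputs: empty bases, rank-deficient reductions (reported with
  effective rank), nonpositive linear-space values (reported by cell and
  channel), unequal-dimension metric requests (angles returned, metric NA)
  all raise early, specific errors.

## Problem sizes

The shipped tests run ensembles of 300 cells for the worked examples (the
study condition), 300 cells for one `n = 7` GRN (48 species, the single
heaviest block at roughly two minutes), bootstrap checks at 50--80
replicates on small fixtures, and null densities at 60--200 sets; the
full-scale defaults (1000 replicates/sets) are exercised at reduced size
only because the statistical assertions already stabilize there.
`scripts/acceptance.R` reruns the four headline quantities at 300 cells
from scratch.

## Limitations

* Gap choice remains heuristic; no random-matrix significance test is
  provided (the asymptotics are inappropriate at 11--26 channels).
* General complex-balance testing for *fixed* rate constants is not
  attempted; deficiency zero plus weak reversibility is used as the
  sufficient certificate, including as the generator's acceptance rule.
* The LDA separation statistic is defined here as the Mahalanobis distance
  between dominant component means under the effective-count-weighted
  pooled covariance. It satisfies the properties the comparison relies on
  (zero for identical populations, affine invariance) but no claim is made
  that it numerically matches any particular published variant.
* Stochastic kinetics, SBML import and FCS binary parsing are out of
  scope; cell tables arrive as CSV/TSV exports.
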