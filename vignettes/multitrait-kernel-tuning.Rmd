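---
title: "Multi-trait Gaussian-kernel GBLUP and bandwidth tuning: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-trait Gaussian-kernel GBLUP and bandwidth tuning: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`gkblup` fits a multi-trait genomic prediction model for plant-breeding
trials in which J lines are evaluated for nT traits across I environments.
Writing Y for the n x nT phenotype matrix ordered first by environment and
then by line,

    Y = 1 mu' + X_E beta_E + Z_L g + Z_EL gE + eps

where `mu` holds one intercept per trait, `beta_E` (I x nT) the environment
main effects, `g` (J x nT) the genetic line effects, `gE` the
genotype-by-environment interaction effects and `eps` the residuals.  The
random terms follow matrix-variate normal laws:

* `g ~ MN(0, K, Sigma_T)` — rows (lines) covary through a J x J kernel
  matrix K built from markers; columns (traits) covary through the genetic
  trait covariance `Sigma_T`;
* `gE ~ MN(0, (Z_E Z_E') ∘ (Z_L K Z_L'), Sigma_T_ge)` — the interaction
  kernel is the elementwise product of the environment-match mask and the
  line kernel, i.e. two observations interact only when they share an
  environment, and then with strength `K[line_a, line_b]`;
* `eps ~ MN(0, I_n, R)` — independent rows, residual trait covariance R.

The trait covariance of the interaction term is estimated as its own matrix
`Sigma_T_ge`, separate from `Sigma_T`: the two terms describe different
biology (stable versus environment-specific genetic signal) and there is no
reason to force a common scale.

The kernel is either the VanRaden genomic relationship matrix
(`linear_grm()`) or, centrally here, the Gaussian kernel

    K[i, j] = exp(-gamma * d2[i, j]) = rho ^ d2[i, j],   rho = exp(-gamma),

with `d2` the scaled squared Euclidean distance between the marker vectors
of lines i and j.  The bandwidth `rho` in (0, 1) is the single tunable
hyperparameter: values near 1 make every line similar to every other
(smooth, almost linear fits), values near 0 make the kernel nearly diagonal
(each line its own island).

### Distance scaling

The raw squared distances between marker vectors grow linearly with the
number of markers, so some normalization is required before a fixed
bandwidth or a fixed search interval can be meaningful.  We divide by the
maximum pairwise squared distance, so `d2` lies in [0, 1] and
`K = rho^d2` spans (rho, 1].  Under this convention every value of the
search grid changes the kernel by a comparable amount and the fixed choice
gamma = 1 (`nt_rho()`, rho = exp(-1) ≈ 0.368) sits mid-range.  The
normalizer is returned as `scale_factor` so that a fitted model can be
applied reproducibly to new lines.  Median scaling is a common alternative;
it changes only the labelling of rho values, not the kernel family.

## Posterior computation

`fit_gibbs()` runs a blocked Gibbs sampler.  Two design choices make it
simple and fast:

1. **Grid completion.**  The sampler always works on the complete
   environment x line grid.  Absent records (unbalanced trials), missing
   trait values and cross-validation test cells are all treated the same
   way: the cell is sampled from its conditional normal given the current
   parameters and the observed traits of the same record (data
   augmentation).  Marginally this leaves the posterior of all parameters
   exactly as if the missing cells were integrated out, and it makes the
   line design balanced by construction.
2. **One eigendecomposition.**  On the completed grid the line incidence
   satisfies `Z_L' Z_L = I * I_J`, and the interaction kernel is block
   diagonal with one copy of K per environment.  A single
   eigendecomposition `K = U D U'` therefore diagonalizes the row structure
   of both the `g` and the `gE` full conditionals.  The remaining
   trait-trait coupling is removed each sweep by simultaneously
   diagonalizing the current effect covariance against the current R
   (a generalized eigenproblem of size nT), after which every update is a
   scalar shrinkage `d*lambda / (1 + d*lambda)` applied elementwise.

The remaining steps are standard: environment means carry a flat prior
(the intercept is reported as their average, `beta_E` as deviations, a
sum-to-zero identification since the model contains both an intercept and
a full environment incidence), and `Sigma_T`, `Sigma_T_ge`, R carry
inverse-Wishart priors with df = nT + 2 and identity scale — weakly
informative with a finite prior mean, standard in Bayesian GBLUP practice.
Predictions are Rao-Blackwellized: the reported value of a masked cell is
the posterior mean of its conditional expectation, not of its sampled
value, which removes one layer of Monte-Carlo noise.

Numerical safeguards: kernel eigenvalues are clamped at `max(d) * 1e-10`;
a jitter of 1e-8 is added to a kernel diagonal only when its smallest
eigenvalue falls below 1e-10 (with a message — the Gaussian kernel is PSD
in exact arithmetic, so this is rescue, not modelling); covariance draws
are symmetrized after every inverse-Wishart draw.

Default chain settings (`prior_spec()`: 3000 iterations, 1000 burn-in,
thinning 2) are sized for datasets of a few hundred lines.  The validation
experiments shipped with the package use shorter, explicitly stated chains
(see below).

## Bandwidth tuning

Three strategies, all optimizing the same objective — the across-trait
mean NRMSE on inner validation folds:

* **NT (no tuning):** gamma = 1, i.e. rho = exp(-1).  One evaluation,
  no inner fitting.
* **GrS (grid search):** rho over `make_grid()`: 0.01 to 0.999 in steps of
  0.04 (25 points) plus the endpoint 0.999 itself, 26 evaluations.  The
  appended endpoint reproduces both the intended point count and the
  intended upper bound of the search interval; ties break toward the
  smallest rho.
* **BO (Bayesian optimization):** a Gaussian-process surrogate with
  Matérn-5/2 covariance on standardized objective values, lengthscale
  re-selected each step by marginal likelihood over a small candidate set,
  fixed noise 1e-6 (the objective is deterministic given seeds), and
  expected improvement maximized on a 512-point lattice in (0.001, 0.999).
  Defaults `n_init = 6` space-filling starts plus `n_iter = 14`
  acquisitions give a 20-evaluation budget — deliberately cheaper than the
  26-point grid.  The reported optimum is the best evaluated point.

## Nested cross-validation

`make_fold_plan()` builds 7 outer folds and, inside each outer-training
set, 5 inner folds.  Folds partition observation records (line x
environment cells), stratified by environment; a line may therefore be in
training in one environment and under test in another, which matches the
"tested lines in tested environments" reading of per-environment accuracy
tables.  A `unit = "line"` switch partitions lines instead for users who
want strictly untested genotypes.  Remainder records of uneven splits are
placed on the currently smallest folds, keeping overall fold sizes within
one of each other.

Per outer fold, `run_strategy()` selects rho on the inner folds (during
inner fits, both the inner-validation cells *and* the outer-test cells are
masked, so no outer-test information can leak into tuning), refits on the
full outer-training set at the selected rho, and records the outer-test
predictions.  One fold plan is shared by all strategies so
relative-efficiency comparisons are paired.  All randomness derives from
one master seed through named substreams (folds, sampler, BO, replicates).
The same sampler seed is used when evaluating different rho values, so
bandwidths are compared under common Monte-Carlo noise.

## Metrics

NRMSE is the root mean squared prediction error divided by the mean of the
observed values; per trait and fold, then averaged over folds, then over
traits.  Relative efficiencies are ratios of NRMSEs
(`re_grs = NRMSE_NT / NRMSE_GrS`, `re_bo = NRMSE_NT / NRMSE_BO`,
`re_grs_bo = NRMSE_GrS / NRMSE_BO`); values above 1 favor the denominator
strategy.  "Global" rows pool all test cells across environments before
normalizing (`global = "pooled"`), which uses the pooled observed mean as
the normalizer; a `mean_of_env` variant averages per-environment NRMSEs
instead.  Pooling is the default because pooled means are larger than any
per-environment mean whenever environments differ in level, giving Global
values below every per-environment value — the behavior seen in published
multi-environment accuracy tables.  Cells whose observed value is missing
are excluded from every metric.

## The synthetic-data generator

`simulate_markers()` draws each marker's allele frequency uniformly from
`maf_range` and line dosages as binomial(2, f); `simulate_phenotypes()`
then draws every term of the model above with known parameters, including
the Gaussian kernel at a known `rho_true`.  Presets reproduce the shapes
of five published multi-environment breeding datasets (rice Japonica and
Indica, groundnut, cotton, wheat disease panels), including their
unbalanced line x environment layouts; `env_line_counts` removes whole
records, never single trait values, which is how real unbalanced trials
look.  Residual scale is set through `signal_fraction`: R is derived from
the realized variance of the simulated genetic terms so that each trait's
genetic fraction of phenotypic variance hits the target (the realized
value is reported in the truth record).

What the generator does **not** emulate: linkage disequilibrium,
population structure, real trait means or genetic architectures.  One
consequence matters for interpreting tests: with independent markers the
pairwise marker distances concentrate around their mean (relative spread
about `1/sqrt(p)`), so after max-scaling the Gaussian kernels for
different rho values differ far less than they would on structured
genotypes, and the inner-CV objective is nearly flat in rho.  Passing
tests therefore demonstrate the machinery (no leakage, correct formulas,
correct sampler) but understate how much bandwidth tuning can matter on
real data — and conversely, exact recovery of `rho_true` from such data is
only weakly identified (see below).

## Validation experiments and problem sizes

The shipped tests and `scripts/acceptance.R` recompute, from scratch:

* the grid contract (26 points, 0.01–0.999);
* preset shape fidelity (Indica 981 records, Disease 2628 records, at the
  full published marker counts);
* agreement of the fixed-variance single-trait sampler with Henderson's
  closed-form BLUP (J = 30, identity kernel, 20,000 retained draws;
  maximum absolute difference is reported and expected under 0.02);
* trait-covariance recovery on model-simulated data (J = 200, I = 3,
  nT = 2, p = 300, rho_true = 0.5, interaction variance 30% of genetic
  variance, signal fraction 0.8, chains 6000/2000).  This fixture is
  deliberately high-information: a recovery check should test the sampler,
  not the identifiability limits of a noisy design.  Across exploratory
  replicates the elementwise error is typically under 0.15, with
  occasional data realizations (one in about six) whose realized effects
  are atypical enough to exceed it;
* bandwidth recovery (J = 150, I = 3, nT = 2, p = 300, rho_true = 0.9,
  signal fraction 0.6, strong interaction variance): grid-search tuning on
  the inner folds of one outer fold per replicate, then NT versus GrS
  refits scored on that outer fold, 10 replicates with short chains
  (300/100 inner, 600/200 outer).  Because of the distance-concentration
  effect above, the objective is flat near its minimum and the selected
  rho scatters over the upper part of the grid rather than landing on the
  single grid point nearest 0.9; the relative efficiency of tuned versus
  fixed bandwidth is the informative summary here;
* the Bayesian optimizer on a known quadratic (within 0.02 of the optimum
  at a 20-evaluation budget, every seed);
* metric identities against brute-force loops, and the no-leakage audit
  (each fold's selected rho re-derived from its logged inner evaluations).

## Known limitations

* The sampler's mixing degrades in deliberately degenerate regimes
  (noise-free responses, bandwidths so close to 1 that the kernel is
  nearly constant): the fitted values remain correct but the split between
  intercept and line effects along the near-constant kernel direction is
  slow to resolve.
* No REML/frequentist path, no trait-specific kernels, no environmental
  covariates, and no marker QC/imputation — inputs are assumed post-QC.
* Posterior equivalence with any particular published analysis is not
  claimed: priors and sampler settings are this package's own documented
  choices.
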