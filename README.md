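# gkblup

Multi-trait Bayesian genomic prediction with a Gaussian marker kernel, and
a benchmarking harness for the question every kernel user faces: **is it
worth tuning the bandwidth, and how?**

## The problem

Genomic selection predicts the performance of candidate breeding lines from
genome-wide markers.  For nT traits measured on J lines across I
environments, `gkblup` fits the matrix-variate mixed model

    Y = 1 mu' + X_E beta_E + Z_L g + Z_EL gE + eps

with `g ~ MN(0, K, Sigma_T)` (lines covary through a marker kernel K,
traits through `Sigma_T`), interaction effects
`gE ~ MN(0, (Z_E Z_E') ∘ (Z_L K Z_L'), Sigma_T_ge)` and residual rows
`eps ~ N(0, R)`, by Gibbs sampling with data augmentation for missing and
held-out cells.  K is either the VanRaden genomic relationship matrix or
the Gaussian kernel

    K[i, j] = rho ^ d2[i, j],    rho = exp(-gamma) in (0, 1),

where `d2` is the max-scaled squared Euclidean marker distance.  The
bandwidth `rho` is the single hyperparameter, selected by one of three
strategies inside a nested (7 outer x 5 inner fold) cross-validation:

* **NT** — no tuning, gamma = 1 (rho = exp(-1));
* **GrS** — grid search over 26 values, 0.01 to 0.999 in steps of 0.04
  plus the endpoint;
* **BO** — Bayesian optimization (Matérn-5/2 Gaussian-process surrogate,
  expected improvement, 20-evaluation budget).

Predictions are scored by NRMSE (RMSE divided by the observed mean) per
trait, environment and fold, and strategies are compared by relative
efficiencies (`NRMSE_NT / NRMSE_GrS` etc.; above 1 means tuning helped).
A synthetic-data generator draws marker panels and phenotypes from the
same generative model with known truth, including presets that reproduce
the shapes of five published breeding datasets.

## Worked example

Simulate a compact trial (60 lines, 3 environments, 2 correlated traits,
150 markers, generative bandwidth 0.9), then compare no-tuning against
grid search on one shared fold plan:

```r
library(gkblup)

cfg     <- synthetic_config(J = 60, I = 3, nT = 2, p = 150, seed = 42)
markers <- simulate_markers(cfg)
sim     <- simulate_phenotypes(markers, cfg)

plan  <- make_fold_plan(sim$pheno, k_outer = 4, k_inner = 3, seed = 42)
prior <- prior_spec(2, n_iter = 800, burn_in = 300, seed = 42)
inner <- prior_spec(2, n_iter = 250, burn_in = 100, seed = 42)

nt  <- run_strategy(sim$pheno, markers, "NT",  plan, prior, inner)
grs <- run_strategy(sim$pheno, markers, "GrS", plan, prior, inner)

agg <- aggregate_metrics(score_prediction_log(rbind(nt$log, grs$log)))
subset(agg, trait == "All" & environment == "Global")
#>  strategy trait environment     nrmse se
#>       GrS   All      Global 0.1006187 NA
#>        NT   All      Global 0.1003830 NA
subset(re_report(agg), trait == "All" & environment == "Global")
#>  trait environment comparison        re
#>    All      Global     re_grs 0.9976578
```

The Global NRMSE is the pooled across-trait prediction error (about 10% of
the phenotype mean here); `re_grs` just below 1 says grid search did not
beat the fixed bandwidth on this small simulated panel.  That is the
expected behavior for unstructured simulated markers — pairwise marker
distances concentrate, the kernel family is nearly flat in `rho`, and
tuning gains are marginal (see the methods vignette for why, and for when
tuning does matter).  Per-fold selected bandwidths are in
`grs$tuning`, per-cell predictions in `grs$log`.

The same pipeline runs from a YAML config via `cmd_benchmark()`, or from
the shell through the thin wrapper `inst/cli/gkblup`
(`gkblup simulate`, `gkblup benchmark`).

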