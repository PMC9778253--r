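Package: gkblup
Title: Multi-Trait Gaussian-Kernel GBLUP with Bandwidth Tuning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Multi-trait Bayesian genomic prediction with a Gaussian
    (radial basis) kernel built from genome-wide markers. Fits the
    matrix-variate mixed model with genotype-by-environment interaction by
    Gibbs sampling with data augmentation for missing phenotype cells, and
    tunes the kernel bandwidth by three strategies (fixed, grid search,
    Bayesian optimization with a Gaussian-process surrogate) inside a
    nested cross-validation that scores predictions by normalized root
    mean squared error and relative efficiency. Includes a synthetic-data
    generator that draws marker panels and multi-environment multi-trait
    phenotypes from the same generative model with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
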