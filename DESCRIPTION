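Package: epiqtl
Title: Reversible-Jump Mapping of Main-Effect and Epistatic QTL in F2 and
    F2:3 Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Bayesian multiple interval mapping for F2 intercross and F2:3
    progeny designs in which the number of epistatic locus pairs is treated
    as unknown and sampled by reversible-jump Markov chain Monte Carlo.
    One latent QTL is entertained per marker interval with additive and
    dominance effects under the F2 metric; pairs of intervals carry all
    four first-order epistatic effects (additive-additive,
    additive-dominant, dominant-additive, dominant-dominant) and are added
    to or deleted from the model during sampling under a truncated Poisson
    prior on the pair count.  Per-effect Gaussian shrinkage priors with
    scaled inverse-chi-square hyperpriors drive negligible effects toward
    zero.  Includes a cross simulator, Kosambi and Haldane map functions,
    genotype imputation from flanking markers, LOD profiling with
    inclusion-count weighting, epistasis selection, variance components,
    and a k-fold cross-validation driver.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
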