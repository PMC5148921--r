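---
title: "Reversible-jump mapping of epistatic QTL: model and methods"
author: "epiqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reversible-jump mapping of epistatic QTL: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In an F2 intercross (or its selfed F2:3 progenies) with p candidate QTL,
first-order epistasis adds 4 p(p-1)/2 candidate effects to the 2p main
effects: every pair of loci can interact through additive-additive (aa),
additive-dominant (ad), dominant-additive (da) and dominant-dominant (dd)
components.  With 104 markers in 7 linkage groups there are 97 marker
intervals, hence 18,624 candidate epistatic effects next to 194 main
effects -- far too many to carry in one regression.  `epiqtl` keeps the
main-effect part of the model fixed and lets the *number of epistatic
pairs* t be a random quantity sampled by reversible-jump MCMC, so at any
moment only the currently supported pairs are in the model (the largest
model dimension we see in practice stays in the low hundreds).

## The genetic model

For individual i,

y_i = mu + sum_k x_ik a_k + sum_k w_ik d_k +
      sum_(k,k') [ eta aa + gamma ad + varpi da + phi dd ]_ikk' + e_i,

with e_i ~ N(0, sigma^2).  One latent QTL is entertained per marker
interval; its genotype codes are the F2-metric orthogonal contrasts
x in {1, 0, -1} and w in {-1/2, 1/2, -1/2} for QQ/Qq/qq, which makes
additive and dominance effects uncorrelated under exact F2 frequencies
(1/4, 1/2, 1/4).  The four epistatic covariates of a pair are the
element-wise products of the two loci's x and w codes.  The epistatic sum
runs over the t pairs currently in the model; a pair always enters and
leaves with all four of its effects (testing isolated components of a pair
would require far longer chains to accumulate evidence).

## Priors

* mu: flat (Jeffreys).
* Every effect (a, d, aa, ad, da, dd) has its own Gaussian prior
  N(0, sigma^2_effect), and each variance has a scaled
  inverse-chi-square hyperprior.  The classical choice (0 degrees of
  freedom, scale 0) makes the joint posterior improper, so the degrees of
  freedom are corrected to n_a = 0.95: the conditional for each variance
  becomes a scaled inverse-chi-square with n_a degrees of freedom and
  scale equal to the squared effect.  This is the shrinkage engine:
  negligible effects drive their own variances toward zero and are pulled
  to zero themselves, while real effects keep their variances open.
* QTL positions lambda_k: uniform on each marker interval.
* The pair count t: truncated Poisson with mean phi, truncated at the
  pair-space size p(p-1)/2 (t counts whole pairs).  phi itself has a
  Gamma(1, 1) hyperprior, giving the conjugate Gamma(t + 1, 2) update.

## One sampler iteration

1. Gibbs draw of mu from N(mean of the fully adjusted residual, sigma^2/n).
2. For every interval, ridge-form Gibbs draws of a_k and d_k: with
   covariate column c and partial residual r (the residual with this
   term's contribution added back), the conditional is Normal with
   precision-weight S = sum(c^2) + sigma^2/sigma^2_effect, mean
   S^-1 sum(c r) and variance S^-1 sigma^2.
3. The same ridge draws refresh the four effects of every pair currently
   in the model (sequentially within a pair).  Without this refresh the
   effects of a retained pair could never move away from their strongly
   shrunken birth values, because a pair's effects are otherwise only
   drawn at its add proposal.
4. Add move: one pair is proposed uniformly among the pairs *not* in the
   model; its four shrinkage variances are initialised at var(y) and its
   four effects are Gibbs-drawn -- a nearly unshrunken ridge draw, so the
   proposal is data-informed and a pair that genuinely improves the fit
   is typically caught the first time it is proposed.  Acceptance ratio
   (computed in log space): likelihood ratio x phi/(t+1) x
   p_d/((t+1) p_a), with move probabilities p_a = p_d = p_0 = 1/3.
   (Initialising the birth variances near zero instead would shrink every
   proposal to the null, making the likelihood ratio ~1 at birth and
   establishment a rare escape event; in a candidate space of thousands
   of pairs, where each pair is proposed only tens of times per run,
   true interactions would essentially never be found.  The
   data-informed birth draw is the reading consistent with the method's
   published behaviour.)
5. Delete move: a victim is drawn uniformly among the t active pairs and
   removed with ratio (likelihood ratio of the reduced model over the
   current one) x t/phi x t p_a/p_d.  This likelihood-ratio direction is
   the one consistent with reversibility against the add move; the other
   direction would preferentially delete the best-fitting pairs.
6. Every shrinkage variance is redrawn as effect^2 / chi^2(n_a), floored
   at 1e-12 (a zero effect would otherwise produce a degenerate scale).
7. sigma^2 is redrawn as e'e / chi^2(n_a + n - 1).
8. QTL genotypes are imputed per interval and individual from the
   three-way product prior(g) x P(m_L | g) x P(m_R | g) x likelihood,
   where the transition factors come from the flanking markers at the
   current lambda_k.  A missing flank simply drops its factor.
9. lambda_k is updated by Metropolis-Hastings with a uniform window
   [max(L_k, lambda - d), min(U_k, lambda + d)], d = 2 cM by default, and
   an explicit Hastings correction for the unequal window lengths at the
   boundaries.  Conditionally on the imputed genotypes the likelihood
   does not involve lambda, so the ratio uses the transition model only.
10. phi ~ Gamma(t + 1, rate 2).

The default schedule is 10,000 burn-in iterations, thinning 20, and
18,000 retained samples.  All acceptance decisions are made in log space.

### Transition matrices

For the F2, P(QTL genotype | marker genotype) at recombination fraction r
follows from the two-locus F2 joint distribution (two independent F1
gametes with coupling probability (1-r)/2 per gamete).  For F2:3
progenies the observed marker code is the F2 plant's genotype while the
latent QTL genotype belongs to the selfed progeny: propagating the parent
joint through one selfing generation yields, e.g.,
P(QQ | MM) = (1-r)^2 + 0.5 r (1-r), and at r = 0 each row is the selfing
segregation of the marker genotype itself.  The genotype update needs the
reversed conditionals P(marker | QTL); these follow by Bayes inversion
with the design's genotype prior ((1/4, 1/2, 1/4) for F2,
(3/8, 1/4, 3/8) for F2:3).  Distances convert to recombination fractions
with the Kosambi function by default (Haldane selectable); no crossover
interference is modelled beyond the flanking-marker factorisation.
Because the printed source for this construction fixes only a single
F2:3 entry, the test suite verifies the full matrices against an
exhaustive gamete-pair enumeration with one independent meiosis per
parental gamete.

### Dynamics of pair establishment

A truly interacting pair is typically caught at its first proposal (the
birth draw is data-informed, see above): its effects immediately lower
the residual sum of squares, the delete ratio collapses, and the pair
stays in the model for most of the remaining run -- the long-chain
behaviour that makes inclusion counts usable as evidence.  Spurious
pairs also enter easily (fitting four effects to noise buys a small
likelihood gain), but their shrinkage variances collapse within a few
iterations and the delete move removes them, producing the
short-chain churn that the inclusion-count threshold and the LOD*
weighting are designed to filter.  Tightly linked neighbours of a true
pair can establish in its stead ("ghost" interactions), which is why
selected pairs should be read as regions rather than exact intervals.

## Post-MCMC summaries

* Interval LOD: W_k = abar_k^2/V(a_k) + dbar_k^2/V(d_k) with V the
  posterior sample variances of the effect chains (the source never
  defines V; posterior moments are the only quantities available from
  the chain), and LOD = W/(2 ln 10).
* Genome profile: each linkage group is tiled by 3-cM bins from its
  origin; a bin's value is the fraction of retained position samples
  falling in it times the maximum interval LOD attained in it.  The
  combination rule is ambiguous in the source ("f(lambda) weighted by the
  LOD of the maximum posterior"); frequency x max-LOD is the default and
  max-LOD alone is available via `weight = "max_lod"`.
* Pair LOD: the same Wald form over a pair's four effects using
  inclusion-conditional moments (samples where the pair was active) with
  a diagonal variance matrix -- full 4x4 covariances are easily singular
  at small inclusion counts (switchable in principle; diagonal is what is
  reported).  Pairs visited fewer than twice report LOD 0 with a flag so
  genome-wide tables are always complete.
* Weighted LOD* = n LOD / N, with n the pair's inclusion count
  ("chain length") and N the retained total, suppresses rarely-visited
  pairs with lucky effect draws.
* Selection is two-stage, following the recommended order: first keep
  pairs with n > 400, then among them those with LOD > 3 (both strict).
* Variance components evaluate each component's fitted contribution at
  posterior-mean effects and posterior-mean design codes (pairs weighted
  by n/N), and report the across-individual variance; the residual
  component is the posterior mean of sigma^2.

## The simulator

`default_scenario()` reproduces the simulated study design: 104 markers
in 7 linkage groups (15, 15, 15, 15, 15, 15, 14) on a uniform 7.8-cM
grid -- the source states only the group and marker counts and a ~7.8 cM
average spacing, so a uniform grid is the neutral choice -- with six
main-effect QTL (a = d = 2) at a seeded random interior marker of each of
groups 1-6, and seven epistatic QTL forming the interval pairs 19x25,
54x72, 59x91 and 59x94 whose four effects are each drawn once from
Uniform(-2, 2).  Epistatic QTL carry no main effect.  QTL sit exactly at
marker positions (the original simulation tied QTL to markers), and the
interval index of every QTL is recorded in the truth metadata.
Genotypes follow the recombination-fraction Markov chain along each
group; F2:3 progenies are produced by one extra selfing with independent
recombinant meioses.  Phenotypes add Gaussian residuals calibrated
against the realized genetic variance -- centred, decorrelated from the
genetic values and rescaled so the sample heritability equals the target
h^2 = 0.5 exactly.  Missing markers are not simulated by default (a
missing-at-random rate is available for robustness checks).

What the simulator does *not* emulate: field-trial structure
(environments, lattice designs, two-stage adjusted means), segregation
distortion, genotyping error, and linkage maps estimated with error.
Passing the validation suite therefore demonstrates correctness of the
sampler and its summaries under the generative model, not robustness to
those real-data complications.

## Scaled-down validation runs

Three run sizes appear in the tests and the acceptance script, chosen as
the smallest problems that still exercise the claims:

* Conditional-distribution oracles use an n = 5 fixture and 50,000 draws
  per conditional against grid-integrated densities (KS < 0.02).
* The dimension chain is validated on a 4-marker, 3-interval map
  (3 candidate pairs) with the likelihood ratio forced to 1 and phi held
  fixed, against the exact stationary law of the implemented add/delete
  kernel obtained by eigen-decomposition (total variation < 0.02 over
  2 x 10^5 iterations).
* Parameter recovery uses `recovery_scenario()`: n = 200, two groups of
  six markers, one main QTL (a = 2, d = 1, interval 1) and one dd = 2
  pair (intervals 5 x 6), h^2 = 0.5.  The QTL sit at group-terminal
  markers so each has a single flanking candidate interval and the
  recovery target is unambiguous.  Chains of 100,000 iterations are
  used; the true pair's inclusion count typically reaches thousands of
  retained samples, and the occasional miss is an established ghost
  pair sharing a locus with the truth.
* The full-scale smoke run uses the default 300 x 104 scenario at
  burn-in 1,000 / thinning 1 / 2,000 retained samples -- enough to
  exercise every output surface end to end and to see several pairs
  running simultaneously (the model dimension peaks around eight active
  pairs), but far too short for the main-effect LOD profile or the
  inclusion-count ranking to stabilise; the default 370,000-iteration
  schedule is the production setting.

## Numerical choices and edge cases

* All acceptance ratios in log space; uniform deviates compared as
  log(u) < log-alpha.
* Variances are floored at 1e-12; a non-finite variance draw (effect^2
  over an underflowed chi-square deviate) is capped at 1e12.
* Positions are clamped 1e-9 cM inside their interval bounds so
  recombination fractions never hit exactly 0 during transition-matrix
  evaluation.
* The k-fold splitter reproduces the real-data protocol sizes: the
  per-fold count is rounded down to the nearest multiple of 10 when it
  is at least 10 (256 individuals in 5 folds gives 50, 50, 50, 50, 56),
  otherwise folds are exactly floor(n/k); assignment is random given the
  seed, since the source states only the sizes.
* One QTL per interval: a pair shares its intervals' positions and
  genotypes with the main effects.  The source hints its implementation
  may have allowed distinct positions for the epistatic QTL of an
  interval; a shared lambda keeps the genetic model coherent and is the
  documented choice here.
* Two engines implement the sampler: a readable R reference and the
  compiled default.  Both consume R's RNG stream in the same order, so a
  seed pins the chain; the test suite asserts cross-engine agreement
  over a short horizon (floating-point summation differences -- R
  accumulates in long double -- eventually decouple the trajectories).

## Known limitations

* No higher-order epistasis, covariates, fixed effects beyond the grand
  mean, or multiple phenotypes.
* Designs other than F2 and F2:3 (backcross, RIL) are out of scope, as
  is de novo linkage-map estimation.
* Inclusion counts are kernel-dependent evidence, not posterior model
  probabilities: the printed add/delete ratios omit the uniform
  pair-selection probability over the inactive set, so the stationary law
  of t is the implemented kernel's rather than a textbook
  Poisson-likelihood compound.  The stationarity test targets exactly the
  implemented kernel for this reason.
* Weakly supported pairs enter and leave the model freely, so short
  chains leave the inclusion-count ranking noisy; pair selection should
  always use the two-stage chain-length/LOD rule rather than raw LOD,
  and tightly linked ghost pairs mean selected interactions localise
  regions, not exact intervals.
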