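---
title: "Models and design of genwin: windowed genomic prediction in a closed breeding population"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design of genwin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question the package addresses

In a closed nucleus line under recurrent selection — the motivating case is
a brown-egg layer-chicken line with discrete, non-overlapping generations —
breeders must decide how many ancestral generations of records to keep in
the training set when predicting the merit of the current cohort. Older
generations add data, but selection and recombination erode both the family
ties and the marker-QTL linkage phases that carry the predictive signal, so
the marginal value of an old generation can be negative. `genwin` provides
the full machinery to study this trade-off: a population simulator with the
relevant structure, pedigree BLUP and Bayesian whole-genome regression,
a windowed training/validation engine, and a quadratic-regression estimator
of the optimal window size.

## Statistical models

### Pedigree BLUP (PBLUP)

The single-trait animal model is `y = X b + Z a + e` with
`Var(a) = A * sigma2_a` (A the numerator relationship matrix) and
`Var(e) = I * sigma2_e`. The fixed classes in `X` are
hatch-within-generation contemporary groups, fitted in cell-means coding:
every record belongs to exactly one class, so the fixed block is full rank
and no identifiability constraint is needed (class estimates are directly
interpretable as class means). EBV come from Henderson's mixed-model
equations with `lambda = sigma2_e/sigma2_a`; validation animals keep their
equations but lose their phenotype rows, so their EBV are parent-average /
relative-driven predictions. A is never formed densely for the evaluation:
`build_a_inverse()` assembles the sparse inverse directly by Henderson's
rules, with inbreeding coefficients taken from a tabular A restricted to
the closure of animals-that-are-parents (small in breeding populations,
where only selected animals reproduce).

Variance components are estimated by REML. The restricted log-likelihood
is profiled in `lambda` using the sparse MME Cholesky (the
derivative-free form: `(n - p) log(y'Py/(n - p)) + log|C| - q log lambda`
up to constants), and maximized by Brent search on `log(lambda)` in
`[1e-3, 1e3]`. This is robust for a single random effect and needs no
specialized REML software; the reported SE of `h2` comes from the
finite-difference curvature of the profile. Variance components are
estimated once per trait on all phenotyped animals and reused across every
training window, which keeps windowed fits comparable and mirrors common
practice when the same trait is evaluated repeatedly.

### BayesB and BayesC0 whole-genome regression

The marker model is `y_im = beta_m + sum_j z_ij u_j + e_i` with dosages
`z_ij` in {0, 1, 2}. BayesB assumes a fraction `pi = 0.95` of SNPs has no
effect; an included effect is normal with its own variance, which carries a
scaled inverse chi-square prior with `nu_j = 4.2` degrees of freedom and
scale `S2_j = sigma_tilde_j2 (nu_j - 2)/nu_j`, where
`sigma_tilde_j2 = sigma_s2 / ((1 - pi) sum_j 2 p_j (1 - p_j))` spreads the
pedigree-estimated additive variance `sigma_s2` over the expected number of
included markers. The residual prior is scaled inverse chi-square with 10
degrees of freedom and scale matched to the REML residual variance; the
prior degrees of freedom are our choice (the source of the variance priors
is the pedigree analysis, their weight is not dictated by it), and 10 keeps
the prior informative without overwhelming a few hundred records.

The sampler is a single-site Gibbs sweep written in C++ (field practice for
these samplers): the inclusion indicator of each SNP is drawn with the
effect integrated out *conditional on the current SNP variance*, the
effect from its normal full conditional when included, and the SNP variance
from its scaled inverse chi-square full conditional (a fresh prior draw
when excluded). This construction is a valid Gibbs scheme with no
Metropolis tuning, which makes it deterministic to test. Genotypes are
used uncentered, exactly as the model equation is written; the fixed class
effects absorb the induced location shifts. Missing genotypes are
mean-imputed (`2 p_j`). SNPs are always processed in sorted-id order, so
the posterior is invariant to the column order of the input matrix. Chains
default to 55,000 iterations with 5,000 burn-in; the package's own tests
and the acceptance analyses use 2,000-50,000 with proportionally looser
tolerances, sizes chosen so the whole suite runs on a laptop-class single
core.

BayesC0 (`pi = 0`, one common SNP variance updated from the pooled full
conditional) estimates the marker-based heritability `h2_q`. The `h2_q`
numerator is the sample variance of the model-implied genetic values of
the training animals at each iteration (the `genic` alternative,
`sum 2pq * sigma2_u`, is available via `h2_definition`); the sample-variance
definition was chosen as the default because it reflects the realized
genetic variance in the analyzed animals rather than an idealized
Hardy-Weinberg population. With both variances held fixed the sampler's
posterior mean collapses to ridge regression, which is how the tests verify
it against a closed form.

Convergence of the variance and `h2_q` chains is checked with a
Heidelberger-Welch diagnostic implemented from the published algorithm
(Cramer-von Mises test on the standardized cusum with AR-spectral variance
at zero, discarding 10% increments of the head up to 40%, plus the
half-width test); the `coda` implementation is used as an independent
cross-check in the test suite, never as the implementation.

### The windowed design, accuracy, and the optimum

For validation generation `G_v` and window size `k`, training animals come
from generations `G_{v-k} .. G_{v-1}`; validation animals are the
genotyped, phenotyped females of `G_v` with phenotypes masked. Windows are
capped at 10 generations for pedigree-based and 8 for marker-based
analyses. Accuracy is `cor(EBV, y - Xb_hat)/sqrt(h2)` with the hatch
estimates `b_hat` taken from a PBLUP fit on **all** phenotyped animals
(validation included): without the validation records the validation
hatch classes would have no estimate at all, and a poorly adjusted
phenotype corrupts every accuracy in the same direction. A training-only
adjustment can be obtained by fitting the baseline on a restricted data
set. The `h2` in the denominator is the pedigree REML estimate — the
conventional standardizer when marker and pedigree analyses are compared
on the same scale.

Per trait and method, all accuracies are pooled over validation
generations and regressed on `y = a k^2 + b k + c`; the optimum is
`min(-b/(2a), 8)`, reported with the significance flag of the quadratic
coefficient (two-sided t-test at p < 0.01). Convex or degenerate fits have
no interior maximum and return a flagged status. Non-significant fits
still yield a numeric optimum, carrying the flag, so that optima can be
correlated with heritability across all traits; both inclusion policies
can be applied downstream by filtering on the flag.

## The synthetic population

No individual-level data from the motivating breeding program are
distributable, so the package ships a generator whose defaults emulate the
*structure* the analysis needs rather than any particular line:

* **LD**: a burn-in of 100 generations of random mating in a population of
  100 (Ne about 100) before recording starts. This produces r2 that decays
  with map distance — the channel by which markers tag QTL — without a
  coalescent dependency. Loci fixed by drift are dropped (the generator
  seeds about 30% extra).
* **Genome**: 10 chromosomes of 1 Morgan, 1,000 panel SNPs, 100 QTL
  off-panel by default (markers tag QTL only through LD; `qtl_on_panel`
  flips this for calibration experiments). Crossovers are Poisson with
  uniform positions (Haldane, no interference).
* **Population**: 9 recorded generations of 600 offspring; 50 sires and 50
  dams selected per generation by truncation on own phenotype (the
  genomic-era regime of the motivating program; the conventional-era
  360/120-of-2000 regime is reachable through the configuration, and the
  round-robin mating design reproduces its 3-dams-per-sire structure).
  Only females are phenotyped in the recorded output, matching the data
  structure of egg traits; phenotypes for both sexes are simulated
  internally so males can be ranked, which acts like sib-based selection
  for males and can be exposed with `phenotype_both_sexes`.
* **Traits**: three additive traits with founder heritabilities 0.20,
  0.50, 0.70, spanning the range of the motivating traits. QTL effects are
  normal, rescaled so founder BV variance equals `h2` of a unit phenotypic
  variance; hatch-within-generation effects are normal with SD 0.25.
  Selection afterwards erodes genetic variance (Bulmer effect and drift),
  so *realized* h2 in later generations sits somewhat below the founder
  target — parameter-recovery checks must and do account for this by
  comparing at the +-0.1 level.
* **Genotyping**: all parents ever used for breeding plus all females of
  recorded generations (fraction configurable); 2% missing calls and 0.2%
  random miscodes injected after inheritance, so the QC filters (call
  rate < 0.95, MAF < 0.025, Mendelian inconsistency rate > 0.05, applied
  in that order with strict inequalities) operate on realistic input.

What the generator does **not** emulate: genotype-by-environment trends
across years, non-additive gene action, overlapping generations,
selective genotyping beyond the parent rule, and real LD born of long
selection history. Tests passing on this population therefore demonstrate
internal correctness and the qualitative mechanics of windowed training —
not quantitative transfer of any particular accuracy value to a real line.

## Numerical choices and edge cases

* All randomness derives from one master seed through tagged substreams
  (`substream_seed`), so each stage is independently reproducible and
  identical reruns are byte-identical.
* REML errors out if the optimum pins at the lower `lambda` bound
  (heritability near 0 would need wider bounds); the `h2 -> 1` boundary is
  tolerated because noise-free phenotypes are a legitimate simulation
  limit.
* MME solves are verified to a 1e-8 relative residual with one step of
  iterative refinement as a fallback; singular systems raise an error.
* Ties in truncation selection are broken by ascending animal id;
  documented so selections are reproducible across platforms.
* A zero-variance MCMC chain yields a "degenerate" diagnostic status, not
  a crash; a convex accuracy curve yields a "no interior maximum" status,
  not a number.
* Scenario sampling is without replacement within each named generation,
  and validation animals are fixed across scenario replicates.

## Problem sizes used by the shipped analyses

The package's tests and the acceptance script run, by design, at desk
scale: the default population (about 5,500 animals, about 900 post-QC
SNPs), chains of 2,000-50,000 draws, 5 replicate populations for the
qualitative checks, and 1,000-1,500 records for parameter recovery. These
sizes were chosen as the smallest at which the checked properties are
stable, and they are stated here as the package's own experimental
conditions.

## Known limitations

* Single-trait models only; the multi-trait selection indices used in real
  programs are out of scope.
* No genomic relationship/single-step methods; pedigree and marker
  information enter through PBLUP and BayesB/BayesC0 respectively.
* `pi` is fixed (0.95), not estimated; estimating it changes individual
  fits but not the within-trait comparisons the package is built for.
* The REML profile search assumes one random effect; maternal or permanent
  environmental effects would need a different variance structure.
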