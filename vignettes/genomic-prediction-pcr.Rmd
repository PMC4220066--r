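---
title: "Principal component regression versus GREML for across-population genomic prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Principal component regression versus GREML for across-population genomic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The prediction problem

Genomic prediction estimates the additive genetic merit (GEBV) of animals
that have marker genotypes but no phenotypes, from a reference set that has
both. The hard version of the problem — addressed by this package — is
*across-population* prediction: the reference animals all come from
populations other than the one being predicted, so the predictive signal
must survive differences in allele frequencies and linkage phase between
populations. Accuracies in this regime are intrinsically low, and the
interesting questions are comparative: how does fixed-effect principal
component regression (PCR) fare against the standard GREML/GBLUP machinery,
and can the number of components be chosen well from reference data alone?

`pcgp` implements the full comparison as a tested pipeline: SNP quality
control, pedigree and genomic relationship matrices, reference-only and
semi-supervised principal component decompositions, two component-ranking
rules, cross-validated model-size selection, REML variance components with
BLUP prediction, best-case accuracy scans, and a multi-population simulator
that stands in for proprietary cattle data.

## Models

**PCR.** With `X` the column-centered `n x p` genotype matrix (codes 0/1/2),
the thin SVD `X = U S V'` gives scores `T = X V = U S`. The regression

&nbsp;&nbsp;&nbsp;&nbsp;`y = 1 mu + T_k g + e`

treats the effects `g` of the first `k` ranked components as *fixed* — no
shrinkage — in deliberate contrast with GREML. Two ranking rules order the
components: `eigen` (decreasing singular value) and `ss` (decreasing
contribution `(t_j' y~)^2 / (t_j' t_j)` to the regression sum of squares,
computed on mean-centered scores and phenotypes; for the mutually
orthogonal score columns of the defining set this equals the per-component
regression sum of squares regardless of entry order, which is why the
marginal form was chosen over an entry-order-dependent sequential one).

**Semi-supervised PCR.** Plain PCR extracts `V` from the reference animals
and projects the test animals (`T_t = X_t V`, centered with reference
means). SSPCR instead runs one SVD on reference *and* test genotypes
together (centered over all animals) and splits the score rows by
membership; test phenotypes are never used. The centering difference is the
method contrast under study and is deliberately not harmonised.

**Model size by cross-validation.** Within the reference set, components
are added one at a time (`k = 0..k_max`, the null model always included)
and the pooled (micro-averaged) held-out mean squared error selects `k`,
ties resolved to the smaller model. Two fold schemes are available: 5-fold
random (sizes differing by at most one) and stratified, one fold per
reference population. In `pcr` mode the decomposition and the ranking are
recomputed from each training fold and the held-out fold is projected —
exactly mirroring, at CV level, what reference-to-test prediction does, so
held-out genotypes cannot leak into the training loadings. In `sspcr` mode
the decomposition uses training plus held-out genotypes; since every fold's
union is the whole reference set, this is one decomposition per reference
set, shared by all folds — the computational shortcut is exact, not an
approximation.

**GREML.** The animal model `y = 1 mu + u + e`, `u ~ N(0, G sigma_u^2)`,
`e ~ N(0, I sigma_e^2)` uses the VanRaden genomic relationship matrix
`G_VR = Z Z' / (2 sum p_i (1 - p_i))`, allele frequencies taken across all
genotyped animals (reference plus test, as the method defines; a
reference-only option exists for leakage-sensitivity experiments). `G_VR`
is regressed toward the pedigree matrix `A`: `G = b G_VR + (1 - b) A`.
REML maximises the restricted likelihood through the eigendecomposition of
`G_rr`: rotating `y` into the eigenbasis turns every likelihood quantity
into a sum over eigenvalues, the intercept and the residual scale are
profiled out analytically, and a Brent search over the variance ratio
`sigma_u^2 / sigma_e^2` (tolerance 1e-8, boundary at zero permitted and
flagged) finishes the job. For a single random effect this reduction is
exact, and the identity `GBLUP = SNP-BLUP ridge regression with
lambda = c sigma_e^2 / sigma_u^2` provides an independent oracle
(`snp_blup()`) used in the tests.

**Blend coefficient.** The reference for `b` gives no closed formula here,
so the package uses a binned attenuation estimator: off-diagonal `(A, G)`
pairs are sorted by `A` into equal-count bins (default 5; undersized bins
merge into a neighbour), and within each bin
`b = 1 - var(G - A) / var(G)`, clipped to `[0, 1]` and summarised by a
pair-count-weighted mean. This behaves correctly in the limits (`b = 1`
when `G = A` exactly, `b -> 0` under dominating marker noise, `b` grows
with marker count) but attenuates *all* deviation of `G` from `A` —
including genuine Mendelian-sampling variation, not only marker-sampling
noise — so on simulated data `b` sits well below the 0.97+ values typical
of dense real panels. A fixed `b` can be supplied instead (`blend_b = 1`
disables blending), and both are worth reporting since blended and
unblended `G` give nearly identical predictions when `b` is close to 1.

**Accuracy.** Within each test population, accuracy is the Pearson
correlation between predicted GEBV and the (pre-adjusted) phenotypes;
zero-variance predictions (the null model) give an undefined accuracy,
reported as `NA` and never silently dropped. On simulated data the report
also carries the correlation with true breeding values, which real data
cannot offer. `rescale_accuracy()` converts phenotype-correlations to the
GEBV scale by dividing by the square root of the trait heritability.

## The simulator

`simulate_study()` generates the study conditions end to end:

* **Population structure.** Ancestral allele frequencies are uniform on
  `base_maf_range` (mirrored to the upper half at random); each
  population's frequencies are Beta-distributed around them with variance
  `F p (1 - p)` — the Balding–Nichols drift model — so per-population `fst`
  controls differentiation directly.
* **Pedigree and genotypes.** Founders are unrelated; each of
  `n_generations` (default 3) of random mating samples a sire and dam per
  offspring within the population (an optional `migration` rate, default 0,
  draws a parent from another population). Genotypes drop through the
  pedigree one uniformly chosen allele per parent per SNP, independently
  across SNPs: there is no linkage map, a deliberate simplification that
  keeps Mendelian oracles exact while pedigree-induced relationships (and
  hence the blend machinery) remain realistic. What this omits is
  population-level LD between QTL and markers, so across-population
  accuracy here reflects relationship capture rather than persistent
  marker-QTL phase — adequate for exercising and comparing the estimators,
  not for forecasting accuracies on any real panel.
* **Phenotypes.** `n_qtl` SNPs get i.i.d. normal effects per trait;
  breeding values are centered QTL genotypes times effects, and residual
  variance is set from the realized breeding-value variance so that
  `var(bv)/var(y)` hits the target heritability. Missing genotypes, when
  requested, are masked completely at random after phenotypes are formed.

Defaults mirror a five-herd dairy design: final-generation sizes
206/210/181/394/618 (1609 genotyped animals), a panel of 5000 SNPs with 300
QTL, `fst = 0.05` per population, and trait heritabilities
(milk 0.30, fat 0.45, protein 0.15) inside the 0.13–0.59 band reported for
pre-adjusted yield phenotypes. The 5000-SNP panel (rather than a 50k chip)
keeps the full demonstration — five leave-one-population-out splits, three
traits, all eight PCR-family combinations, GREML, and every best-case
scan — at a few minutes on a single core; relationship matrices are
essentially converged at that density, so the comparison is unaffected.

## Numerical choices

* The thin SVD is computed from the eigendecomposition of the smaller Gram
  matrix (`X X'` when `p >= n`), which is algebraically the same
  decomposition at a fraction of the cost. Eigenvalues of a Gram matrix
  carry relative error near machine epsilon, i.e. ~1e-8 on the
  singular-value scale, so the numerical-rank cutoff defaults to 1e-7
  relative (`tol` argument); loadings signs are fixed by making each
  column's largest-magnitude entry positive, for bit-reproducible output.
* The per-`k` prediction path orthogonalises ranked score columns by
  classical Gram–Schmidt with one reorthogonalisation pass, applying the
  identical transform to the test columns; it reproduces per-`k` full OLS
  refits to 1e-10 and handles exactly collinear columns by a zero step,
  matching pivoted least squares.
* `G` eigenvalues may dip to -1e-6 times the largest (clipped to zero);
  anything lower is an error rather than silently jittered.
* A saturated PCR (`k = n - 1`, interpolating the reference set) is
  permitted: it is exactly the minimum-norm least-squares predictor and is
  the natural endpoint of the best-case scan when `p > n`.
* Ties in `select_k` and in `best_k` resolve to the smaller model
  (parsimony); undefined accuracies propagate as `NA`, never as zero.
* All randomness (simulation, fold assignment) flows from explicit integer
  seeds through `withr::with_seed`, so every pipeline product — including
  the full demonstration — is bit-reproducible.

## Quality control

Filters run in a fixed order — call rate, then per-population minor allele
frequency, then a pooled three-class Hardy–Weinberg chi-square — with each
removed SNP attributed to the first filter it fails, so reports reconcile
exactly (`p_in = p_out + sum(removed)`). Defaults keep SNPs with call rate
above 0.95, MAF above 0.01 in *every* population, and HWE chi-square below
600; HWE is pooled across populations (per-population MAF is what the
design prescribes; pooled HWE matches the stated criteria, and the
monomorphic convention sets the statistic to 0). Missing calls are
mean-imputed per SNP, preserving column means so downstream centering is
untouched.

## What the tests do and do not show

The test suite pins every estimator to an independent oracle: the tabular
`A` against Monte-Carlo gene-dropping kinship, the SVD against a separate
eigendecomposition, full-rank PCR against (minimum-norm) least squares,
GREML predictions against ridge regression, the rotated restricted
likelihood against a dense-matrix evaluation, and REML heritability
recovery against the simulated truth. Passing these demonstrates that the
*algorithms* are correct under the simulator's assumptions (unlinked loci,
additive effects, random mating). They do not certify accuracy levels on
real dairy data — across-population accuracies there depend on LD
persistence, selection history and trait architecture that the simulator
deliberately omits.

One property-based check is known to fail, and instructively so: with a
single dominant component plus small noise, argmin-of-pooled-MSE
cross-validation selects exactly `k = 1` only about half the time (both
schemes), not near-always. The overselection is intrinsic — the change in
pooled held-out error from one spurious component has a drift-to-noise
ratio that is scale-free and bounded near one half for any fold geometry —
and it is the same phenomenon that makes CV-selected models in this
pipeline (and in the motivating study) carry hundreds of components and
fail to reach the best-case accuracy. The selected-`k` distribution does
concentrate at the true model, and pure-noise phenotypes do yield the null
model in the majority of replicates.

## Known limitations

* No linkage map, dominance, epistasis, genotyping error, or sex
  chromosomes in the simulator; no selection across generations.
* Fixed effects in GREML are intercept-only (phenotypes arrive
  pre-adjusted); single trait, single random effect.
* The blend estimator is a documented stand-in, flagged above; per-bin
  blending is available but scalar blending is the default.
* `plot_`/`autoplot` methods cover the standard diagnostics (score scatter
  by population, CV curve, accuracy trajectory); publication figures are
  left to the user.
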