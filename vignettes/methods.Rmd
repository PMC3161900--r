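---
title: "Models, parameters and design choices in envinet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, parameters and design choices in envinet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`envinet` analyses multi-level omics data from field-sampled organisms:
transcript intensities, binned NMR metabolite spectra and morphometric
indices measured on the same animals across several sampling sites. This
vignette explains the models behind each stage, the parameters that
matter, and the choices we made where the design was genuinely open.

## The synthetic-data model

Every stage of the pipeline is exercised on generated data with planted
ground truth, so it is worth being precise about what the generator
emulates.

**Module structure.** Each planted module is driven by one latent
Gaussian factor $z$ per module. The hub carries the factor exactly
(loading 1); a member $i$ has value $\lambda_i z + s_i \varepsilon_i$
with loading $\lambda_i \sim U(0.5, 0.95)$ and noise scaled so that any
two members correlate at `within_module_correlation` ($w$) while
hub–member correlation is $\sqrt{w} > w$. This star-like dependence —
hub links strictly stronger than member–member links — is what
hub-neighbourhood extraction after data-processing-inequality (DPI)
pruning expects: in a (hub, $i$, $j$) triangle the member–member edge is
the weakest and is the one pruned. At $w = 1$ with no noise all members
are perfectly correlated, a degenerate limit pinned by a test.

**Raw-scale realism.** Transcript rows are exported as linear
intensities $2^{x + b_f}$ with per-feature baselines
$b_f \sim U(7, 12)$; metabolite bins as positive areas on their own
monotone scale; morphometrics (length in cm, weights in g) with
lognormal noise and site-dependent means, so the K/HSI/GSI formulas
operate on realistic magnitudes. Sub-detection is modelled as a global
detection limit at the lowest `subdetect_fraction` quantile of raw
intensity (default 0.02), which concentrates undetectable entries in
weak features — the situation the ≥ 20%-undetectable filter and the
CV rule are designed to clean up. Missingness is a second, independent
mechanism: each molecular entry is masked with probability
`missing_fraction` (default 0.02). Array batch offsets are per-feature
Gaussian shifts (SD `batch_offset_sd`, default 0.5 on the log2 scale)
applied to transcript rows only; clone clusters are parent rows plus
children at a configurable correlation (default 0.8), enabling both the
keep (r > 0.6) and discard branches of clone collapse.

**Study design defaults.** 7 sites × 10 samples, 300 transcripts, 60
metabolite bins, 5 hub modules of 8–15 members, site effect size 2
within-group SD, 3 batches. The first module is site-discriminative:
all its members are shifted in one non-reference site. The time-course
generator uses a residual SD of 0.4 on the log2 scale, a typical array
residual, and plants exact ±log2(fold) shifts at every timepoint. None
of these magnitudes are calibrated to any particular deposited dataset;
they were chosen once as field-realistic values. What passing tests
show is therefore that the *machinery* is correct and calibrated —
real data add annotation noise, uneven group sizes and confounded
batch/site structure that the generator deliberately does not model.

## Preprocessing

The driver enforces the canonical order filter → floor/log2 → quantile
→ de-noise → impute → batch-correct → clone-collapse and refuses other
orders unless overridden. Two ambiguities were resolved as follows:

* *"Undetectable"* means missing **or** ≤ 0 in the raw matrix — the two
  mechanisms the generator produces; the removal boundary (fraction
  ≥ 0.2) is inclusive.
* Quantile normalisation runs before imputation by normalising the
  observed entries of each column against interpolated reference
  quantiles. Tied entries receive the mean of the reference quantiles
  at their tied ranks, which equals the average over all orderings of
  the ties (test-pinned against a brute-force permutation oracle and,
  on tie-free data, against `limma::normalizeQuantiles`).

The CV rule uses SD/mean on log2 values as stated; since a log2 mean
can be ≤ 0 (where CV is undefined) such features are removed and
logged. Singleton clone clusters are kept — the correlation condition
is vacuous.

**PPCA imputation** fits a probabilistic PCA model by EM with features
as observations, replacing missing entries by the posterior-mean
reconstruction each iteration; convergence is declared when the
relative mean-squared change of the imputed entries falls below `tol`
(default 1e-9), and non-convergence returns the result with a warning
rather than an error. On noiseless rank-deficient data the posterior
mean reduces to the subspace projection, so rank-1 completion is exact.

**Batch correction** is the parametric empirical-Bayes location–scale
model: standardise each feature, estimate per-batch location
($\hat\gamma$) and scale ($\hat\delta^2$) effects, shrink them toward a
normal / inverse-gamma prior shared across features (hyperparameters by
moments), and remove the shrunken effects. When within-batch variance
is exactly zero the effects are fully identified and no shrinkage is
applied, so a purely additive offset is removed exactly; per-feature
grand means are re-pinned after adjustment. On well-conditioned noisy
data the result tracks `sva::ComBat` (the same model family) to within
a few hundredths of a log2 unit, which the suite checks.

**NMR processing.** Bins are 0.005 ppm wide, anchored at the first
retained point, with a point exactly on a boundary assigned to the
lower bin; the residual-water exclusion window defaults to 4.70–4.90
ppm and is configurable. The noise threshold splits the bins into 32
equal-width regions (by bin index), takes each bin's SD across samples,
the smallest SD per region, and multiplies the smallest regional value
by 3; sub-threshold bins are zeroed rather than deleted so matrix shape
is preserved. The regional aggregation (minimum over regions) is the
conservative reading of a procedure whose exact aggregation is not
recoverable from the method's description.

## Differential expression

One-way fixed-effects ANOVA across sites and Welch t-tests of each site
against the reference, with BH FDR computed separately over each test
family (the "same FDR" is the same α, not a pooled family). Fold change
is the difference of group means on the log2 scale, exponentiated for
the 1.5-fold cut-off; a feature with zero variance everywhere carries
no evidence and gets p = 1. The up and down lists are disjoint by
construction.

## Chemical-signature inference

The EASE score is the one-sided Fisher exact upper tail computed after
decrementing the overlap cell by one, i.e. $P(X \ge k - 1)$ under the
hypergeometric law with unchanged margins; overlaps of 0 or 1 are
uninformative (p = 1). It is conservative (≥ the Fisher p on the same
table) and monotone in the overlap, both verified exhaustively for all
margins ≤ 30. Inducer sets are tested against the up list and repressor
sets against the down list, with BH families per direction across
chemicals. A direction *qualifies* for FDR multiplication when its
overlap is ≥ 2 and its FDR < 1 — the weakest defensible reading of
combining "where associations were found" — and the threshold is
configurable; the product of raw per-direction FDRs is reported without
re-adjustment, as is conventional for this combination. The universe is
the annotated genes surviving preprocessing.

## Mutual-information network and modules

The MI estimator transforms each variable to normal scores (a copula /
rank transform, making the estimate invariant to monotone feature
scales — important when transcripts, metabolite areas and morphometrics
share one network) and applies a Gaussian-kernel leave-one-out density
estimate with a common bandwidth $h = 0.8\,\sigma n^{-1/6}$ for joint
and marginals. The 0.8 undersmoothing factor was calibrated once
against the closed form $-\tfrac12\log(1-\rho^2)$ for bivariate
Gaussians: at n = 2000 the estimate is within 10% for ρ ∈ {0.5, 0.9},
and the independent null stays below 0.01 nats at n = 500. Estimates
are clamped at zero; a constant input yields MI 0 with a warning.

The significance threshold pools MI values from permuted (hence
independent) variable pairs and fits an exponential tail to the upper
decile of the null. A target of P < 10⁻⁶ is far beyond direct counting
at any feasible permutation count, so the tail is extrapolated; the
calibration is verified by direct counting at p = 0.01, where the
fraction of truly independent pairs crossing the threshold must sit in
[0.005, 0.02], and by monotonicity of the threshold in the target p.

**DPI tolerance.** In every fully connected triple the weakest edge is
removed when its MI is below $(1 - \text{tolerance})$ times the smaller
of the other two, decided against the original edge set (so pruning is
order-independent and idempotent). The package default is 0.15. With
exact MI values a tolerance of 0 is correct, and the pruning then
reduces each planted module to a perfect star around its hub; but at
field-study sample sizes (n ≈ 70) the sampling noise of any MI
estimator is comparable to the hub-member vs member-member MI gap, and
a zero tolerance deletes true hub edges (planted-module Jaccard drops
to ~0.64 on bad seeds). A 0.15 tolerance — the conventional setting in
applications of this algorithm family, whose stated purpose is exactly
this estimation error — restores mean Jaccard ≥ 0.87 on every seed
tried. Tolerance 0 remains available via `apply_dpi(net, tolerance =
0)`.

Modules are the hub plus its direct (1-hop) neighbourhood in the
post-DPI network, one module per hub including isolated hubs (k-hop
neighbourhoods are available behind a flag for sensitivity analysis).
Morphometric, biomarker and metabolite nodes enter MI estimation
identically to transcripts. The module graph connects module pairs by
the overlap index (shared nodes over the smaller module) and exports as
SIF for Cytoscape; layout is delegated there.

## GA module predictivity

The genetic algorithm searches fixed-size feature subsets (chromosome
size 5) with tournament selection, uniform crossover, point mutation
(rate 0.1/gene) and elitism, over a population of 50 for up to 100
generations, 3 independent restarts, stopping early at a fitness goal
of 0.9. Fitness is the cross-validated balanced accuracy of a
3-nearest-neighbour classifier on z-scored features — the canonical
default of this algorithm family; the reported sensitivity and
specificity come from fresh 5-fold stratified cross-validation repeated
3 times and averaged, using out-of-fold predictions only. Multi-class
targets are handled one-vs-rest per class; a module is predictive of a
class when both sensitivity and specificity exceed 0.70, and
`n_classes_predicted` counts predictive classes per module. All
hyperparameters are exposed in `ga_config()`; none are stated by the
original method description, so these defaults balance search quality
against desk-scale runtimes.

## Integration and consensus

Module genes are tested against laboratory-exposure DE lists by the
one-sided Fisher exact test with BH FDR across the whole module × list
table. Two cut-off conventions circulate for this step (P < 0.01 and
FDR < 0.05); both are implemented as a mode switch with FDR < 0.05 the
default, and switching modes moves only the significance flags, never
the p-values. Lab DE lists come in two modes: time-course ANOVA
FDR < 0.05, optionally intersected with |fold| ≥ 2 versus control at
*every* timepoint.

Consensus co-clustering partitions the *columns* (terms) of the binary
annotation matrix into k clusters with five shipped algorithms —
average-, complete- and Ward-linkage hierarchical clustering, k-means
and PAM — and counts, per term, how many algorithms place it with the
designated reference column (the site-predictivity flag). The count
semantics ("out of a maximum of 5"), not any particular algorithm
quintet, is the contract; other algorithms plug in as functions. The
counts are invariant to column order and to duplicating non-reference
columns.

## Numerical choices and degenerate inputs

* BH FDR is `stats::p.adjust(method = "BH")`, verified against a
  literal step-up oracle on 0.01-grid vectors (exhaustively for lengths
  ≤ 2; large fixed-seed samples for lengths 3–6, since full enumeration
  of the grid is combinatorially impossible).
* Fisher/EASE tails use `stats::phyper`; margins are validated and
  inconsistent tables are errors.
* NMR bin assignment subtracts an epsilon (10⁻⁹ of a bin width) before
  the ceiling so floating-point error cannot push an exact boundary
  point into the upper bin.
* `nmr_noise_threshold` with constant bins returns threshold 0 and
  leaves the matrix untouched; `anova_oneway` on an all-constant
  feature returns p = 1; `estimate_mi` requires ≥ 10 samples.
* All randomness — generator, permutation null, GA, k-means restarts —
  derives from explicit integer seeds; identical (config, seed) pairs
  reproduce every output file bit-identically, which the suite asserts
  on the full demo pipeline.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the generator at its
default study design (7 × 10 samples, ~360 features), the MI threshold
at 10⁴–2×10⁴ permuted pairs, the MI closed-form calibration at
n = 2000, the ANOVA null at 1000 features, the GA null batteries at
15–50 seeded runs, and oracle enumerations at margins ≤ 30 and 12-node
graphs. These sizes were chosen so the whole suite completes in
minutes on a single core while leaving each statistical band a
comfortable margin.

## Known limitations

* The MI estimator's absolute values are biased low at small n (like
  all kernel estimators); thresholds derived from the same estimator's
  null are self-consistent, but MI values should not be compared across
  different sample sizes.
* The exponential-tail extrapolation to P < 10⁻⁶ is verified only at
  p = 0.01; the far tail of the true null may decay differently.
* The empirical-Bayes correction assumes batch effects are exchangeable
  across features; confounded batch/site designs are not detected.
* The generator plants clean block modules; real co-expression has
  overlapping, hierarchical structure that hub neighbourhoods only
  approximate.
* No annotation clients (GO/pathway/IPA-style) are included; term
  annotations must be supplied as gene sets (GMT).
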