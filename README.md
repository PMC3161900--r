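# envinet

Multi-level omics network analysis for environmentally sampled non-model
organisms.

Fish, mussels and other sentinel species sampled from contaminated field
sites carry molecular signatures — transcript, metabolite and
morphometric changes — of the chemical mixtures they live in. `envinet`
implements, as a tested and reusable R pipeline, the analysis chain used
to read those signatures in field eco-toxicogenomics:

1. **Preprocessing** of raw array intensities and binned NMR spectra:
   undetectable-spot filtering (a feature is dropped when ≥ 20% of its
   values are missing or ≤ 0), flooring at 0.5 and log2 transform,
   quantile normalisation, de-noising by coefficient of variation
   (SD/mean > 0.9) and dynamic range (max − min < 1.5), probabilistic-PCA
   imputation, parametric empirical-Bayes batch correction, and collapse
   of redundant clone clusters to a representative (kept only when its
   Pearson r to every cluster member exceeds 0.6). NMR spectra are
   segmented into 0.005 ppm bins, total-area normalised, and de-noised at
   3× a 32-region minimum-SD noise estimate. Morphometric indices are the
   standard condition factor K = weight/length³ × 100, HSI = liver
   weight/body weight × 100 and GSI = gonad weight/body weight × 100.
2. **Site-wise differential expression**: one-way ANOVA across sites plus
   Welch t-tests against a clean reference site, each family controlled
   by Benjamini–Hochberg FDR < 0.05 with a 1.5-fold cut-off.
3. **Chemical-signature inference**: directional chemical–gene
   interaction tables (chemical, gene, induce/repress) are tested against
   the up/down DE lists with the EASE score — the conservative one-sided
   Fisher exact test with the overlap cell decremented by one — with BH
   FDR per direction; when a chemical qualifies in both directions the
   two FDRs are multiplied into a combined FDR.
4. **Network inference**: pairwise mutual information (Gaussian-kernel
   leave-one-out estimator on copula-transformed data), a permutation
   null with exponential-tail extrapolation to the P < 10⁻⁶ significance
   threshold, and data-processing-inequality pruning (in every triangle
   the weakest edge is presumed indirect and removed). Modules are each
   designated hub plus its direct neighbourhood; module pairs are related
   by the overlap index |A ∩ B| / min(|A|, |B|).
5. **Module predictivity**: GALGO-style genetic-algorithm selection of
   small feature subsets per module, scored by cross-validated balanced
   accuracy of a 3-nearest-neighbour classifier; a module is predictive
   of a class when one-vs-rest sensitivity and specificity both
   exceed 70%.
6. **Integration**: Fisher exact overlap of module genes with
   laboratory-exposure DE lists (ANOVA FDR < 0.05, optionally 2-fold at
   every timepoint), a binary module-annotation matrix, and consensus
   co-clustering counts (how many of five clustering algorithms place a
   term with the reference site-predictivity column).

A synthetic-data generator (`generate_dataset`) plants hub-anchored
correlated modules, site shifts, batch offsets, sub-detection, missing
values, clone clusters and chemical signatures with known ground truth,
so every stage is testable offline.

## Worked example

```r
library(envinet)

sim <- generate_dataset(synthetic_config(seed = 42))
pre <- preprocess_pipeline(sim$dataset)
pre
#> omics_dataset: 359 features x 70 samples
#>   features: metabolite_bin (60), morphometric (5), transcript (294)
#>   sites: site1, site2, site3, site4, site5, site6, site7

thr <- mi_significance_threshold(pre$values, p_target = 1e-6,
                                 n_perm = 1e4, seed = 1)
net <- apply_dpi(build_network(pre$values, as.numeric(thr)))
net
#> mi_network: 100 nodes, 58 edges (MI >= 0.2587)

mods <- extract_modules(net, intersect(sim$truth$hub_ids, net$nodes))
```

The recovered hub neighbourhoods match the planted modules closely
(Jaccard 0.92, 0.92, 0.93, 0.71 for the four surviving hubs in this
run). Scoring the planted site-discriminative module with the genetic
algorithm:

```r
mem <- intersect(sim$truth$module_membership[[1]], rownames(pre$values))
lab <- ifelse(pre$sample_meta$site == "site2", "site2", "rest")
sel <- ga_select(pre$values[mem, ], lab, ga_config(seed = 1))
sapply(sel$predictions, sens_spec, labels = lab, positive_class = "site2")
#> sensitivity rows ~0.9, specificity ~1.0  ->  predictive (> 70% both)
```

`run_pipeline(pipeline_config())` chains every stage on a small demo
design and writes a reproducible bundle (matrices, SIF networks, GMT
modules, enrichment and predictivity tables, plus a manifest of file
digests; identical config + seed reproduces it bit-identically).

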