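# metica

Metabolic transcriptional components from bulk expression compendia.

## The problem

Bulk expression profiles of tumor biopsies mix the transcriptional
footprints of many regulatory factors — metabolic programs among them —
with tissue composition, batch effects, and noise. `metica` implements a
pipeline that separates such compendia into statistically independent
**transcriptional components (TCs)** and works out which of them describe
metabolic biology:

1. **Consensus ICA** — each dataset's genes × samples matrix `X` is
   decomposed as `X ≈ S Aᵀ`, where the columns of `S` are independent
   gene-weight vectors (one weight per gene per component) and the rows of
   `A` are per-sample **activity scores** (the mixing matrix). Fixed-point
   ICA (log-cosh negentropy, PCA whitening) is run many times on gene
   bootstrap resamples from random starts; run estimates are clustered by
   absolute Pearson correlation of their weights and stable clusters are
   averaged into consensus components, with stability = the fraction of
   runs reproducing the component.
2. **Gene-set enrichment** — each component is scored against each
   metabolic gene set with the two-sample Welch t between member and
   non-member weights, transformed to a signed Z
   (`z = sign(t)·Φ⁻¹(1 − p/2)`) so scores are comparable across sets.
3. **Gene-set consensus clustering** — redundant sets are collapsed by
   Monti-style resampled hierarchical clustering of their enrichment
   profiles (1 − Pearson distance, average linkage, 80% row/column
   subsampling); the cluster count k is the last one before the relative
   gain in the consensus-CDF area falls below 0.01.
4. **mTC selection** — per gene-set cluster, the three TCs with the
   highest single-set |z| and the three with the highest |mean z| are
   selected; the union over clusters defines the metabolic TCs (mTCs).
5. **Cross-dataset concordance** — two mTCs from different datasets are
   concordant when their top genes (|standardized weight| > 3) overlap
   more than a 10,000-draw permutation null expects (p < 0.05) and the
   Spearman correlation of the overlapping weights exceeds 0.5 at
   p < 0.05 (t approximation).
6. **The landscape** — samples are clustered into metabolic subtypes
   (ward.D2 on 1 − correlation of mTC activities, dendrogram cut at the
   first height where the smallest cluster reaches the minimum size),
   per-sample explained variance `a²ᵢₖ/Σⱼa²ᵢⱼ` is averaged per study or
   tissue to flag batch/tissue-driven components, and activities are
   screened against drug IC50 panels and immune-cell fractions with
   Spearman correlation (drugs flagged at |ρ| > 0.2).

Because the real GEO/TCGA/CCLE/GDSC compendia are far beyond desk scale,
the package ships a **synthetic-compendium generator with planted ground
truth** (shared sources across datasets, heavy-tailed top-gene blocks,
redundant gene-set blocks, sample groups, drug/immune targets) so every
stage is validated against a known answer.

## Worked example

The numbered scripts under `analysis/` run the whole study; each is a thin
driver over exported functions and writes its tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_decompose.R
# ... through analysis/06_landscape.R
```

Output of a full run:

```
real compendium bookkeeping: 34494 samples over 4 datasets, 608 metabolic gene sets
D1: 8 consensus components, 8 pass the 90% run-reproducibility screen
  planted-source recovery |r|: min 0.997 over 8 sources
planted blocks: chosen k = 5 (5 planted), ARI vs truth = 1.000
D1: 8 mTCs selected over 8 gene-set clusters
concordant pairs: 4 of 64
  D1: 4/8 mTCs concordant with the other dataset (50%)
subtype study: 4 subtypes at height 0.4, ARI vs planted groups = 1.000
drug screen: 8/80 (component, drug) pairs flagged at |rho| > 0.2
```

Reading: consensus ICA recovers all 8 planted sources per dataset at
|r| ≥ 0.99; the delta-CDF-area rule lands exactly on the 5 planted
gene-set blocks; precisely the 4 sources shared between the two datasets
are called concordant (each dataset's other 4 mTCs are dataset-specific,
hence the 50%); the 4 planted sample groups are recovered as 4 subtypes;
and exactly the 8 planted (component, drug) targets are flagged.

The same machinery is available interactively:

```r
library(metica)
study <- simulate_study(synthetic_config())
fit <- decompose(study$datasets$D1, n_components = 12, n_runs = 25,
                 seed = 1)
enr <- enrich_all(fit$components, study$gene_sets)
head(sort(abs(enr$z[, "TC1"]), decreasing = TRUE), 3)
#> SET_S4_shared_1 SET_S4_shared_3 SET_S4_shared_2
#>        5.260554        4.788298        3.734299
```

## Vignette

`vignettes/metica-methods.Rmd` documents the model and every numerical
choice: the c-ICA estimator and its stability screen, the Welch-z
calibration behavior, the delta-CDF-area rule's desk-scale sensitivity,
the subtype cut-height semantics, and what the synthetic generator does
and does not emulate about real compendia.
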