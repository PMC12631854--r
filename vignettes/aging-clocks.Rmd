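---
title: "Cell-type-specific transcriptomic aging clocks: models and methods"
author: "snClock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-type-specific transcriptomic aging clocks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`snClock` implements a pipeline for building **transcriptomic aging
clocks** from single-nucleus RNA-seq of post mortem brain tissue: from raw
gene-by-cell count matrices, through quality control and pseudobulk
aggregation, to regularized age-regression models, their transfer to
external cohorts, and residual-based **age acceleration** inference for
disease cohorts. The clocks are cell-type-specific: separate models are
trained for oligodendrocytes, astrocytes, microglia, OPCs, excitatory and
inhibitory neurons, and for three pooled levels (glia, neuron, all cells).

This vignette documents the models, their assumptions, the tunable
parameters and defaults, and the design decisions taken where the design
was genuinely open. It states no empirical result beyond what the package
tests and the acceptance script compute.

# The data model

Three containers carry the data:

* `CellCohort` (extends `SingleCellExperiment`) — a genes x cells matrix
  of raw UMI counts (`"counts"`) and, after `logNormalize()`, CP10K
  log-normalized values (`"logcounts"`). Per-cell annotation (donor, cell
  type, QC metrics) lives in `colData`, per-gene flags (mitochondrial,
  sex-related) in `rowData`, and per-donor covariates (age in years, sex,
  post mortem interval in hours, condition, brain pH) in the `donorData`
  slot.
* `PseudobulkSet` (extends `SummarizedExperiment`) — aggregated samples:
  one column per pseudobulk sample with its donor, unit, replicate index,
  number of cells used, and donor age.
* `ClockModel` — the five per-fold elastic-net models of one clock, its
  gene universe, training-sample gene means, donor fold map, and the
  pooled cross-validation test predictions.

# Quality control and normalization

`qcFilter()` keeps nuclei with total counts and detected genes inside
inclusive bounds and a mitochondrial transcript fraction strictly below a
cutoff. The defaults (1,200–100,000 counts, 800–12,000 genes, < 5%
mitochondrial) are the stringent gates used for deeply sequenced
single-nucleus libraries of frozen cortex; all are overridable, and the
synthetic cohorts used in the tests apply gates scaled to their shallower
simulated depth. Bounds on counts and genes are inclusive ("between"),
while the mitochondrial gate is strict, matching the usual phrasing of
these filters; metrics already present in `colData` are trusted (so toy
fixtures can force boundary cases), and missing ones are computed from
the matrix.

`logNormalize()` applies the standard library-size transform
$x_{gc} = \log(1 + c_{gc} \cdot s / \sum_g c_{gc})$ with scale factor
$s = 10{,}000$ (CP10K), the default of the Seurat-style workflow this
pipeline mirrors. `dropMitoSexGenes()` removes flagged genes before any
model sees the data; in the absence of explicit flags, mitochondrial
genes are recognized by the "MT-" prefix and sex-related genes by a
user-supplied list, so results do not silently depend on a hard-coded
gene list.

# Pseudobulk aggregation

Single-cell profiles are noisy; averaging cells of one donor and cell
type trades single-cell resolution for stability. Two aggregations are
provided:

* **Simple pseudobulk** — the mean log-normalized profile over all of a
  donor's cells of a unit: one sample per donor per unit.
* **Bootstrapped pseudobulk** — `nReplicates` (default 100) samples per
  donor, each the mean of `k` cells drawn at random. Sampling is
  *without* replacement when the donor has at least `k` cells and *with*
  replacement otherwise (recorded per sample). Without-replacement
  sampling preserves within-donor variance structure best; the
  replacement fallback keeps small donors usable rather than silently
  dropping them, since the k-selection rule deliberately tolerates up to
  20% of donors below `k`.

`chooseK()` implements that rule: the largest `k` from a candidate grid
(default 25/50/100/200/500, matching the round values used in practice:
oligodendrocytes 200, astrocytes/microglia/OPCs 50, neurons 100, pooled
levels 100 or 500) such that at least 80% of donors have *more* than `k`
cells of the unit. A grid is scanned instead of all integers so the
chosen `k` stays auditable and round. Level pseudobulk pools
oligodendrocytes + astrocytes + OPCs (glia), excitatory + inhibitory
neurons (neuron), or all six major types (all_cells) before sampling.

Bootstrap random streams are derived per (donor, replicate) with
`seedStream()`, a small multiplicative hash of the root seed and integer
keys (all arithmetic below $2^{31}$, so it is exact in doubles and valid
as an R seed). Results are therefore independent of donor iteration
order and reproducible from one root seed.

# Clock models

A clock is an elastic-net regression of chronological age on the
log-normalized expression of the gene universe, fitted with **donor-level
5-fold cross-validation**: donors (never samples) are partitioned into
five folds, each fold's model trains on the other folds' samples and
predicts the held-out donors' samples. This is the device that prevents
leakage — replicate pseudobulk samples of one donor are strongly
dependent, and splitting them across train and test would overstate
accuracy. The pooled held-out predictions (`cvPredictions()`) estimate
generalization to unseen donors; a structural audit in the test suite
asserts that no prediction ever comes from a fold trained on its donor.

The elastic-net mixing parameter defaults to `alpha = 0.5` (ridge 0 and
lasso 1 complete the usual sensitivity grid). The penalty $\lambda$ is
selected per fold by inner cross-validation over a log-spaced path,
grouped by donor for the same leakage reason, at the minimum-MSE point;
a fixed-$\lambda$ override exists for oracle tests and shrinkage limits.
Features are standardized internally with coefficients reported on the
original scale (the glmnet convention); this matters when interpreting
coefficient magnitudes in feature reports. Degenerate folds with constant
response yield intercept-only models rather than errors. At a fixed
$\lambda$ with `standardize = FALSE`, the ridge solution satisfies
$(X_c^\top X_c + n\lambda/\hat\sigma_y I)\,\beta = X_c^\top y$ (glmnet
standardizes the response internally, $\hat\sigma_y$ with denominator
$n$); the test suite checks this against an independently coded closed
form.

Donor-level predictions of bootstrapped clocks average the replicate
predictions of each donor. Performance is summarized as Pearson's *r*
between chronological and predicted age, with its two-sided p-value, and
the mean absolute error in years. When predictions are constant the
correlation is undefined and reported as `NA`, never coerced to 0.

The **naive mean baseline** predicts every test sample as its fold's
training-sample mean age under the same fold structure — the reference
any clock must beat.

**Feature genes** are the genes with non-zero coefficients in *all five*
training rounds; each carries its coefficient averaged across folds and
the sign of that average (the modeled age trend). Per-fold models are
preserved verbatim, and predictions always use them — the averaged
coefficient is interpretive only. `featureOverlap()` summarizes how
feature sets intersect across clocks.

# Transfer to external cohorts

`alignGenes()` reorders external expression to a clock's gene universe.
Genes absent from the external data are imputed with the clock's
training-sample means, so they contribute exactly their average training
signal to the linear predictor — deleting a gene and imputing it is
numerically identical to replacing its values with the training mean (a
tested invariance). When over half the universe is missing the alignment
proceeds with a prominent warning; in that regime predictions degrade
toward the constant obtained when every gene is imputed. External
predictions ensemble the five fold models (their mean), with per-fold
predictions retained for audit.

Two diagnostics explain transfer performance: the fraction of feature
genes *expressed* in the external data (non-zero in at least one
cell/sample by default; the threshold is configurable because "expressed"
has no canonical definition), and **trend concordance** — per feature
gene, the Spearman correlation of expression with donor age,
Benjamini-Hochberg adjusted across the feature set, a gene being
concordant when adjusted p < 0.05 with the same sign as its average
coefficient. Single-cell clocks are tested on per-cell expression,
pseudobulk clocks on per-donor unit means, matching how each clock sees
data. Constant or missing genes have undefined correlation and count as
non-concordant.

# Age acceleration

`computeAgeAcceleration()` fits an ordinary least-squares line of
predicted age on chronological age and defines each sample's
acceleration as its residual, in years. By default the line is fitted on
all supplied samples — controls and disease pooled — which keeps the two
groups' accelerations on a single scale and makes the group contrast
interpretable; a controls-only reference line is available since
per-condition lines are common in displays, and neither mode is asserted
as the only correct one. Residuals over the fitted set sum to zero (a
normal-equations property the tests assert), and accelerations are
invariant to constant offsets in the predictions.

`compareGroups()` regresses acceleration on a 0/1 disease indicator plus
covariates (defaults: age, sex, PMI, brain pH; the list is config-driven
because cohorts differ in what they record, and constant or missing
covariates are dropped with a message). Donor-level accelerations use a
Gaussian GLM with identity link — the response is a continuous residual
in years, so no other family is natural; sample-level (per-cell or
per-replicate) accelerations use a linear mixed model with a random
intercept per donor, the minimal structure for donor grouping.
Significance is the p-value of the disease coefficient (Satterthwaite
for the mixed model); non-convergent mixed fits are flagged with the GLM
path suggested.

# The synthetic cohort generator

`simulateCohort()` draws cohorts with the statistical structure the
analysis assumes, so every stage is testable without restricted human
data:

* donor ages uniform over a range (default 18–94 years, 31 donors,
  emulating a realistic adult post mortem cohort), with sex, PMI and
  brain pH covariates;
* per-donor cell counts per type from a negative binomial, so the
  choose-k rule meets heterogeneous depths;
* UMI counts from a negative binomial on a log link — the standard
  overdispersed model for UMI data — with per-gene base means log-normal
  around a median of 0.3 counts/cell, count dispersion 0.8, and a
  log-normal cell depth factor;
* a configurable number of genes whose log-mean drifts with donor age at
  a default slope of ±0.02/year — roughly a two-fold change across the
  adult lifespan, a realistic magnitude for robust transcriptomic aging
  markers — the remainder age-null, with a fraction flagged
  mitochondrial/sex-related to exercise gene removal;
* optionally, diseased donors whose expression is sampled at an
  *effective age* shifted by a fixed number of years. Modeling disease
  as an age shift (rather than a separate gene program) makes age
  acceleration a well-defined ground truth: a perfect clock should
  recover exactly that shift.

Gene-level parameters are drawn from a dedicated stream of the root
seed, so `makeExternalVariant()` can redraw an independent donor set
under the *same* gene program — the setting in which transferring a
clock is meaningful — and additionally remove a fixed fraction of genes
to emulate external datasets that never measured part of the universe.

What the generator does **not** emulate: batch effects, ambient RNA,
doublets, donor-level expression heterogeneity beyond age and disease,
cell-type misannotation, or realistic gene names. Passing tests
therefore demonstrate correctness of the machinery and recoverability of
signal under the stated model, not performance on real tissue.

# Numerical choices and edge cases

* Count/gene QC bounds inclusive, mitochondrial strict; empty QC results
  warn rather than error.
* Zero-total cells make `logNormalize()` fail loudly with the cell ids.
* Donors with no cells of a unit are omitted from pseudobulk with a log
  message; an empty pool yields an empty `PseudobulkSet` with a warning.
* `chooseK()` falls back to the grid minimum with a warning when no
  candidate satisfies the coverage rule.
* Constant-response folds give intercept-only models; at very large
  penalty every fold collapses to the training-mean age exactly.
* Undefined correlations (constant predictions or constant genes) are
  reported as `NA` and never silently treated as 0 in results; only the
  null-calibration test summary counts an undefined association as zero
  when averaging over replicate cohorts, on the argument that a constant
  prediction carries no age association.

# Problem sizes used in the tests

The test suite and acceptance script run entirely on generated cohorts,
sized as the package's own validation design: signal-recovery uses 30–31
donors, six cell types at ~150 cells/donor/type (or the cohort defaults),
2,000 genes with 100 age-trending; null calibration uses 20 replicate
cohorts of the training cell type at the same gene count; acceleration
calibration and power use a clock trained once on a control cohort and
applied to 200 independently redrawn 40-donor cohorts per scenario; the
transfer sweep uses dropout fractions 0/0.3/0.6 averaged over four donor
redraws.

# Known limitations

* **Null cross-validation correlation is negatively biased.** Under
  donor-level cross-validation, a clock trained on age-null data shrinks
  toward each fold's training-mean age, and fold training means are
  anti-correlated with the held-out donors' ages (for pure fold-mean
  predictions with five equal folds, r is about $-1/\sqrt{6} \approx
  -0.41$; the naive baseline realizes this bound, and fitted null clocks
  land between it and 0, empirically near $-0.2$). Null-cohort cv
  correlations should therefore be compared against the naive baseline,
  not against zero: the meaningful calibration statement is that the
  clock does not *beat* the baseline on null data, which the tests
  assert. A mean null cv *r* within a tight band around zero is not
  attainable under this scheme and the package does not claim it.
* The generator's independence assumptions (no donor random effects, no
  batch structure) make synthetic recovery easier than real-data
  performance; external-transfer results on synthetic cohorts are upper
  bounds in that sense.
* Elastic-net penalty selection by inner CV is seeded but depends on the
  fold draw; two different seeds give (slightly) different feature sets.
  Feature-gene lists should be read as stable signatures only across the
  all-fold intersection, which is what `extractFeatureGenes()` reports.
* The mixed model fits a random intercept per donor only; random age
  slopes are out of scope.

# A minimal end-to-end run

```{r example, eval = FALSE}
library(snClock)

spec <- cohortSpec(nDonors = 31, seed = 1)
cohort <- simulateCohort(spec)
cohort <- qcFilter(cohort, qcThresholds(100, 1e6, 50, 1e5, 0.25))
cohort <- logNormalize(dropMitoSexGenes(cohort))

k <- chooseK(cohort, "excitatory_neuron")
pb <- bootstrapPseudobulk(cohort, "excitatory_neuron", k = k,
                          nReplicates = 100, seed = 2)
model <- trainClock(pb, alpha = 0.5, seed = 3)
evaluateClock(aggregateByDonor(cvPredictions(model)))

ext <- makeExternalVariant(cohort, geneDropoutFraction = 0.3, seed = 4)
extPb <- bootstrapPseudobulk(logNormalize(dropMitoSexGenes(ext)),
                             "excitatory_neuron", k = k, seed = 5)
pred <- applyClockExternal(model, alignGenes(model, extPb)$samples,
                           aggregateByDonor = TRUE)
accel <- computeAgeAcceleration(pred, donors = donorData(ext))
```
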