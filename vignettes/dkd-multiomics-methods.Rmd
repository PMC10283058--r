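---
title: "Methods: urine multi-omics modelling of diabetic kidney disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: urine multi-omics modelling of diabetic kidney disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Diabetic kidney disease (DKD) is staged clinically by the urinary
albumin-to-creatinine ratio (UACR) and the estimated glomerular
filtration rate (eGFR), but both metrics miss early renal damage: a
substantial fraction of diabetics show abnormal urinary microalbumin
(mALB ≥ 30 mg/g) while still UACR-negative — the "grey zone". This
package models a diagnostic strategy that reads two molecular
fingerprints from urine — a metabolite fingerprint (m/z 20–350) and a
peptide profile (m/z 600–20000), both acquired by laser
desorption/ionization time-of-flight mass spectrometry — and combines
them into a stepwise classifier that separates healthy controls (HC),
type 2 diabetes without albuminuria (T2DM), early DKD
(microalbuminuria) and overt DKD, and flags grey-zone patients as
disease rather than T2DM.

No public raw-data accession exists for this kind of cohort, so the
package is built around a first-class synthetic-cohort generator:
every downstream stage — preprocessing, differential statistics,
multivariate projection, the machine-learning bench and the diagnostic
cascade — is developed and tested against cohorts whose ground truth
is known by construction.

## The synthetic cohort

`generate_cohort()` draws a cohort under a log2-normal intensity
model: for sample *i*, replicate *r* and feature *j*,

    intensity = 2 ^ ( baseline_j + shift_{g(i),j} + batch_{b(i),j} + e ),
    e ~ N(0, s),   s = sqrt(log(1 + cv^2)) / log(2)

so the technical coefficient of variation equals `noise_cv` exactly
and planted log2 fold changes are exact by construction. Defaults
follow the study conditions: 501 samples (152 HC, 149 T2DM, 39
grey-zone, 106 early, 55 overt), 227 metabolite and 206 peptide
features, 3 technical replicates, 2 batches, technical CV 0.15 and a
per-batch, per-feature log2 shift of SD 0.25.

Ten metabolites and six peptides are planted as *stepwise-regulated*:
their group means move monotonically along the stage axis
HC → T2DM → early → overt. Each feature's per-stage increment is
`effect_log2fc × U(0.5, 1.5)` (default effect 0.5 log2 units per
stage). The uniform multiplier matters: with identical increments the
three stage-contrast directions would be collinear and the third
cascade layer — early DKD against both its molecular neighbours — would
be an impossible linear problem; real biomarker panels are never
perfectly collinear across stages. Directions are biased the way urine
behaves in DKD: most planted metabolites fall with disease stage and
most planted peptides rise (reduced glomerular filtration retains
larger fragments). The grey-zone group sits at a configurable fraction
(`grey_step_fraction`, default 0.5) of the T2DM → early shift, so it is
molecularly intermediate; setting the fraction to 0 makes grey-zone
indistinguishable from T2DM, which is the null used when evaluating
grey-zone routing.

Clinical covariates are drawn from truncated normals whose bounds are
the KDIGO recruitment definitions (HC/T2DM: UACR < 3 mg/mmol,
mALB < 30 mg/g, eGFR ≥ 60 ml/min/1.73 m²; grey zone: mALB ≥ 30 with
UACR < 3 and eGFR ≥ 60; early DKD: 3 ≤ UACR < 30 with eGFR ≥ 60; overt
DKD: UACR ≥ 30, eGFR free to fall below 60), with stage-trending
location parameters — eGFR decreasing, UACR and mALB increasing. The
constraints hold by construction, not by rejection sampling.

Two metabolite channels act as internal standards: spiked compounds at
fixed, comparable concentrations (log2 baselines 14 and 13.5), carrying
technical noise only — no group, biological or batch variance. Modelling
them as batch-affected would make their post-normalization ratio RSD
measure the curvature of the normalization map rather than platform
noise, which is not what the ratio-stability check is for. The pooled
QC sample (the average biological composition) is injected 8 times per
batch; with many fewer injections the per-feature sample RSD is biased
low (E[s] < σ at n = 3) and the intra-batch median RSD could not sit
near the generative CV.

What the generator does *not* emulate: correlated biological variation
between features (each feature's noise is independent), acquisition
drift within a batch, peak-shape or mass-calibration artifacts,
isotope envelopes, adducts, or missingness. Passing tests therefore
demonstrate the statistical machinery is correct and calibrated, not
that real spectra of this platform would reach the same accuracies; on
these cohorts the planted effects are strong relative to the
replicate-averaged noise, and several classifiers sit near ceiling.

## Preprocessing

`pick_peaks()` retains strict local maxima whose intensity exceeds
3 × the local noise scale, with noise estimated as 1.4826 × the median
absolute deviation of the intensity in a sliding window (default 51
grid points) — robust to peaks inside the window. Only the S/N > 3 rule
is prescribed; the MAD window is this package's noise model, and there
is no baseline subtraction beyond it.

`align_features()` pools peak m/z values across samples, sorts them and
splits at gaps larger than the tolerance — exactly single-linkage
clustering at that height, which the tests verify against `hclust`.
Defaults: ±0.05 Da for metabolites, ±500 ppm for peptides (linear-mode
peptide mass error grows with mass). Features observed in under 70 % of
samples are dropped and remaining gaps imputed with half the feature's
minimum observed value (`filter_impute()`).

`cubic_spline_normalize()` maps each sample's log2-intensity quantiles
onto a reference's quantiles through a monotone (Hyman-filtered) cubic
spline with 7 interior knots, continuing linearly beyond the knot
range. Monotonicity guarantees within-sample rank preservation.
Order-statistic (type 1) quantiles are used because they commute
exactly with monotone maps, which makes re-normalization against the
same reference a no-op (the idempotence property the tests assert at
1e-6). A sample with too few distinct values falls back to median
scaling and is logged. Normalization is applied per modality; replicate
averaging (`average_replicates()`) happens *after* normalization so
that replicate concordance is measured on normalized data.

One consequence worth knowing: quantile normalization forces every
sample onto a common intensity distribution. When a visible fraction of
features genuinely shifts with disease (here 16 of 433), the map leaks
a small opposite shift into null features and attenuates extreme ones.
On the default cohort this moves one or two borderline features across
the q < 0.05 line in either direction. The analysis drivers normalize
(as one would on real spectra, where acquisition drift dominates); the
recovery benchmarks in the tests run on the replicate-averaged raw
matrix, which is the generator's own scale and carries no drift to
remove.

`qc_report()` computes the platform-qualification metrics: Spearman
correlation between two QC injections, per-feature RSD (100 × SD/mean)
medianized within and between batches, and the internal-standard ratio
RSD across all rows.

## Differential statistics

`ttest_features()` tests each feature on the log2 scale. The default is
Welch's unequal-variance test — group variances differ by construction
once effects are planted — with the pooled-variance Student test behind
`var_equal = TRUE`. Log2 fold change is the difference of group means of
log2 intensities, so it is exact for the generative model.
`bh_adjust()` validates the p-value domain and applies the
Benjamini–Hochberg step-up (via `p.adjust`); the test suite pins it
against a literal step-up implementation.

A feature is *stepwise-regulated* when it is significant (q < 0.05,
strict) in every pairwise contrast among the four staged groups
(`stepwise_intersection()` over the six contrasts). Whether monotone
direction should additionally be required is genuinely open; both
readings are available (`require_monotone`), with intersection-only the
default and per-contrast directions always reported.
`clinical_correlation()` screens features against covariates with
Spearman correlation by default (UACR and mALB are heavily skewed) and
flags |r| > 0.3.

## Multivariate projection

`fit_oplsda()` implements O-PLS for a binary response by NIPALS-style
iteration: repeatedly extract the component of X-variation orthogonal
to the class code, deflate it, then fit one predictive PLS component on
the filtered matrix. With a univariate response the weight vector is
available in closed form, so convergence control (tol 1e-10, max 500
iterations) exists for generality. Unit-variance scaling is the
default, classes are coded −1/+1, and multi-group models are out of
scope (stage contrasts are run pairwise). Three algebraic contracts are
enforced by tests: with zero orthogonal components the model *is*
single-component PLS1 (1e-10), orthogonal scores are uncorrelated with
the class code (1e-8), and the total sum of squares is conserved across
components plus residual (1e-8 relative). `oplsda_q2()` reports
Q2 = 1 − PRESS/TSS over stratified 7-fold cross-validation; label
permutation drives its median at or below zero, the standard
chemometric sanity check.

## The machine-learning bench

`split_discovery_validation()` makes the stratified 2:1 split
(per-class discovery counts within one sample of the ratio, seeded).
`train_pairwise()` fits one of the seven fixed algorithms — SVM,
decision tree, naive Bayes, logistic regression, LDA, k-nearest
neighbours, LASSO — choosing hyperparameters by stratified 10-fold CV
on discovery data only. The grids are deliberately small and fixed:
SVM over linear/radial kernels with cost {0.1, 1, 10}; KNN over
k {3, 5, 7, 9}; tree pruning at the CV-minimal complexity; the LASSO λ
path by `cv.glmnet`; NB, logistic and LDA have nothing to tune. All
scorers return positive-class probabilities (native where defined,
logistic link otherwise).

`evaluate()` reports the confusion matrix, accuracy, precision,
recall/sensitivity, specificity, F-measure, Cohen's kappa (chance
agreement from the marginals) and AUC by the rank (Mann–Whitney)
formulation with ties counted one half — all pinned against brute-force
recomputation.

`compare_single_vs_multiomics()` is the single- versus multi-omics
bench: metabolite markers alone, peptide markers alone, and their
concatenation after per-feature z-scoring *within each modality block*
(with statistics learned on discovery data). Without the per-block
standardization the peptide block's larger intensity scale dominates
every distance-based learner; how the original platform fused the two
scales is unstated, so the standardization is declared here as this
package's choice. Markers are screened on discovery data only before
the bench runs — the bench never sees a feature chosen with validation
information.

## The three-layer cascade

`fit_cascade()` trains three L1-penalized logistic scorers: layer 1
separates HC from all disease; layer 2 separates T2DM from DKD
(grey-zone ∪ early ∪ overt); layer 3 separates early DKD from the
remaining DKD. Each layer's panel is the nonzero-coefficient set at the
1-SE λ (falling back to the CV-minimal λ if the sparse rule empties the
panel), and its cutoff is chosen on discovery scores by the Youden
index (ties toward the smaller threshold; a fixed 0.5 is available).
At prediction time (`predict_cascade()`) a sample stops at the first
layer whose score falls below the cutoff — HC at layer 1, T2DM at
layer 2 — and otherwise terminates as EARLY_DKD (layer-3 score at or
above its cutoff, `≥` semantics) or DKD_OTHER. Layers 2–3 train on the
*true* labels of the relevant discovery samples rather than on layer-1
survivors: training on survivors propagates upstream errors into the
downstream fit, while sequential inference is preserved at prediction
time regardless; survivor training remains available by flag.

The terminal partition is four-way. The third layer is a binary
early-vs-other decision, so no final grey-versus-overt disambiguation
is modelled; grey-zone behaviour is reported separately by
`grey_zone_report()` as the fraction of grey-zone samples routed past
layer 2 (i.e. called DKD rather than T2DM) together with the full
true-group × terminal-class ratio table. The informative null for that
fraction is a cohort generated with `grey_step_fraction = 0`.

Models serialize to plain JSON (`cascade_to_json()` /
`cascade_from_json()`) at full numeric precision, and the tests require
bit-identical routing after a round trip.

## Networks and pathways

`bicor()` is the biweight midcorrelation: median-centred values,
Tukey biweights `(1 − u²)²` for |u| < 1 with u = deviation/(9 × MAD,
unscaled), normalized cross-product; zero MAD falls back to Pearson
with a flag. Edge p-values use the Student-t approximation with n − 2
degrees of freedom. `correlation_network()` keeps edges with |r| > 0.3
and p < 0.05 within a group and summarizes positive/negative edge
counts.

The pathway perturbation (JG) score has no published formula, so a
Stouffer-type signed aggregate is declared: each member's two-sided p
maps to `z = sign(log2fc) × Φ⁻¹(1 − p/2)` (p = 0 capped at 1e-300 and
flagged) and the pathway scores `Σz/√k`. It is linear in member z,
scales as √k under duplication, and cancels for balanced panels — a
panel containing both up- and down-regulated members scores near zero
by design, visible for the planted panel in the analysis drivers.
`enrich_hypergeometric()` is the one-sided upper-tail test with BH
adjustment across pathways; `joint_enrichment()` runs it on the pooled
metabolite + protein namespace so a pathway can score through either
entity type. Pathway annotation is user-supplied GMT; no third-party
pathway database is bundled.

## Orchestration and problem sizes

`run_pipeline()` executes the stages in dependency order with per-stage
seeds derived from one global seed, writing CSV/TSV/JSON outputs and a
manifest with parameters, seeds and output checksums; a failed stage
aborts with its name and retains completed outputs. The `analysis/`
scripts are thin narrative drivers over the same functions.

Problem sizes in the tests are chosen to keep the whole suite in the
minutes range while leaving Monte-Carlo error well inside the asserted
margins: null calibration pools 100 cohorts of 30 samples × 250
features; biomarker recovery uses ten full 501-sample cohorts; the
cascade and grey-zone checks one full cohort plus its zero-effect
twin; the multi-omics bench twenty two-group cohorts of 90 samples
with the planted signal split evenly (8 + 8) across modalities; QC one
reduced cohort at 10 % technical CV. `scripts/acceptance.R` recomputes
the same quantities from scratch under a caller-supplied seed.

## Known limitations

* Feature independence in the generator means correlation networks on
  default cohorts detect only the planted co-regulation that comes
  from sharing the stage axis, not realistic metabolite–peptide
  covariance structure.
* At the default effect size several classifiers saturate; the bench
  distinguishes *non-inferiority* of the combined model clearly, but
  differences between the seven algorithms are mostly within seed
  noise.
* The Welch test, the 1-SE λ rule, the Youden cutoff, and the per-block
  z-scoring are declared package choices where the original platform's
  settings are unknowable; all have documented switches.
* Cutoffs, panels and AUCs on synthetic cohorts are not estimates of
  any clinical cohort's values; they demonstrate calibration and
  recoverability under a known truth.
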