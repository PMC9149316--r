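---
title: "Methods: ancestry-informative panels, classification and likelihood maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ancestry-informative panels, classification and likelihood maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`geoancestry` implements a complete biogeographic-ancestry platform for
regional-scale population panels: genotype quality control, construction of
genetically distinguishable ancestry groups from population structure,
selection of a compact ancestry-informative marker (AIM) panel, a
probability-emitting classifier, and geographic rendering of
ancestral-origin likelihood. This vignette explains each model, its
assumptions, the tunable parameters, and the design decisions taken where
the design was genuinely open.

## Data model

Genotypes are diploid biallelic SNPs coded as alternate-allele dosage: 0
(hom ref), 1 (het), 2 (hom alt), with `NA` as the missing-genotype
sentinel. All statistics skip missing cells explicitly; after imputation no
`NA` remains. Samples carry a population label, WGS84 coordinates and
optionally an ancestry-group label; groups ("ethnic geographic groups",
EGGs) are clusters of populations that are internally relatively
homogeneous but distinguishable from one another.

## Quality control

The default pipeline applies, in order: per-SNP missingness (> 5 %
removed), minor allele frequency (< 1 % removed), per-sample missingness
(> 10 % removed), and LD pruning at r² > 0.2 in 1500-SNP windows. The
boundary semantics are strict (a SNP missing in exactly 5 % of samples is
kept), and MAF is computed on observed alleles only.

The LD pruner scans each chromosome in position order and drops a SNP whose
squared Pearson correlation (over pairwise-complete samples) with any of
the previous `window_snps − 1` retained SNPs exceeds the cutoff; of an
offending pair, the later variant by position is removed. This advances one
SNP at a time rather than in the customary `step` jumps: it is strictly
more conservative, deterministic, and it guarantees the invariant that no
retained in-window pair exceeds the cutoff — which the step-wise scan does
not. `step_snps` is accepted for interface compatibility. Zero-variance
pairs are defined to have r² = 0.

Missing genotypes are imputed by the per-SNP modal dosage, with ties broken
toward the lowest dosage code so results are deterministic. Modes are
computed on the training/reference panel and stored in the selected panel,
so new samples at prediction time are imputed with the *training* modes —
this avoids test-set leakage while keeping preprocessing identical across
datasets.

Relatedness is estimated with the KING-robust within-pair coefficient
φ̂ = (N_Aa,Aa − 2·N_AA,aa) / (N_Aa(i) + N_Aa(j)) over shared observed SNPs,
which is robust to population structure; duplicates score 0.5 and full sibs
≈ 0.25. Samples are removed greedily (most offending pairs first; ties
toward higher missingness, then later input order) until no pair reaches
the 3rd-degree cutoff 0.0884. Relatedness removal runs after the marginal
filters and before analysis.

## Population structure and group construction

PCA standardizes each SNP by its estimated allele frequency (centre 2p̂,
scale √(2p̂(1−p̂))) and retains 3 components by default. Outliers — samples
beyond 6 standard deviations on any retained component — are removed and
the PCA recomputed, for up to 3 iterations; 6 σ on the computed components
is the long-standing convention of genotype-PCA outlier trimming. Judging
outliers on the 3 retained components (not a larger eigenbasis) keeps the
criterion aligned with the coordinates actually used downstream.

Populations are reduced to their mean PC coordinates and clustered by
K-means (base R Hartigan–Wong with 10 random restarts under a fixed seed;
with the intended 20–300 population centroids an elaborate initialization
scheme buys nothing). K defaults to 30, i.e. slightly above the number of
groups one expects, since the subsequent rebalancing merges fragments.

Rebalancing enforces group sizes within [25, 150] samples: undersized
groups merge into the nearest group by centroid distance when the merged
size stays within bounds, unmergeable undersized groups are dropped (and
reported), oversized multi-population groups are split by 2-means on their
population centroids. Every merge, split and drop is logged so a human can
review the sequence of decisions, replacing the partly manual curation such
groupings traditionally receive. The procedure is bounded at 50 rounds and
flags anything unresolved (e.g. a single population larger than the upper
bound, which cannot be split).

Group validity is checked with pairwise Hudson FST, computed as a ratio of
averages across SNPs: FST = Σ N_j / Σ D_j with
N_j = (p₁−p₂)² − p₁(1−p₁)/(n₁−1) − p₂(1−p₂)/(n₂−1) and
D_j = p₁(1−p₂) + p₂(1−p₁), where n are observed allele counts. The
ratio-of-averages form avoids the instability of averaging per-SNP ratios,
and the Hudson estimator avoids sample-size weighting artifacts. On
simulated panels the validation suite verifies it recovers the nominal
divergence within ±0.02.

## AIM selection

Selection proceeds in three stages:

1. **Chi-square prefilter.** For each group, each SNP's 2×2 allele-count
   table (group vs rest × ref vs alt) yields a Pearson chi-square
   statistic; the top 2,000 SNPs per group are kept and the union over
   groups forms the candidate set. Allele-count tables are used rather than
   dosage-sum scores because they are symmetric in the allele coding and
   well-defined for any biallelic SNP; monomorphic tables score 0.
2. **Stability selection.** An extremely-randomized-trees classifier
   (320 trees, no bootstrap, one random threshold per candidate feature,
   class-balanced weights) is fitted on each of 5 stratified training
   splits; a SNP survives only if its normalized impurity importance
   exceeds the threshold in *all five* fits. Requiring survival in every
   fold suppresses the overfitting that single-fit importance rankings
   suffer at small sample sizes. Importances are normalized to sum to one
   per fit; the default cutoff 2.7e-5 is referenced to a 54,522-SNP
   candidate set and by default rescaled by `54522 / n_candidates`, since
   an absolute cutoff on quantities that sum to one is only meaningful
   relative to the number of features (`rescale_threshold = FALSE` applies
   the raw constant).
3. **Confusion-driven augmentation.** A classifier trained on the
   survivors is cross-validated; group pairs whose mutual confusion reaches
   20 % of the smaller support are flagged, and flagged pairs joined
   transitively, components of three classes becoming triplets. Each
   flagged pair contributes the 100 SNPs with the highest two-class
   chi-square on its samples; a triplet contributes 100 SNPs separating its
   two most-confused classes from the third plus 100 separating those two
   from each other. Chi-square ranking is used for these contrasts because
   it is the same univariate statistic as the prefilter and directly
   targets the two-class margin; additions already in the panel are
   deduplicated by union.

The panel records, per SNP, its provenance (`stability`, `pair_augment`,
`triplet_augment`) and its training-panel imputation mode. A companion
curve utility retrains the classifier on the top-k SNPs by mean importance
for a series of panel sizes, exposing the saturation point where more
markers stop buying accuracy.

## Ancestry classifier

One L2-penalized binary logistic regression per group (one-vs-rest), with
balanced class weights n/(k·n_c) and inverse regularization strength C = 1;
the ridge solution is obtained by coordinate descent (glmnet) at
λ = 1/(nC) with an unpenalized intercept, which reproduces the common
machine-learning parameterization of the penalized objective
Σ w_i·logloss_i + ‖β‖²/(2C). Per-group sigmoid scores are normalized to sum
to one; this one-vs-rest normalization (rather than a multinomial softmax)
is the scheme the per-class binary fits were optimized under. Ties in the
top group break toward the lexicographically smallest label so reports are
deterministic.

At prediction time, input SNPs are matched to the panel by id; up to 10 %
of the panel may be absent (imputed from stored modes) before prediction is
refused — a cap chosen so mode imputation can never dominate a score. The
model serializes to JSON with 17 significant digits, so loaded models
reproduce predictions exactly without the training data.

Evaluation reports per-class precision, recall, F1 and support, the
confusion matrix, macro (unweighted) and support-weighted averages.
Undefined precision (class never predicted) is reported as 0. For
single-label multiclass prediction the support-weighted recall is
identically the overall accuracy, and per-class F1 is the harmonic mean of
that class's precision and recall; the test suite checks both identities
against a published 29-group validation table shipped with the package
(`north_eurasia_validation_metrics()`), whose macro and weighted rows the
aggregator reproduces at printed precision.

## Geographic likelihood surfaces

Each reference population point receives the predicted probability of its
group. A regular lat/lon grid (default 0.5° cells, 2° margin around the
point bounding box, WGS84, unprojected) is interpolated by inverse-distance
weighting over the 8 nearest points with great-circle distances and power
2; cells coincident with a point take its value exactly, and every cell is
a convex combination of point scores. IDW was chosen because the
interpolation scheme here is a rendering device, not an inferential model:
it is deterministic, exact at the data, and bounded. Plate carrée rendering
distorts cell areas at high latitude; this is a documented display
limitation, not a numerical one.

Two likelihood bands summarize the surface: "more likely" (≥ 0.8 × max) and
"less likely" (≥ 0.4 × max), the former nested in the latter by
construction. The thresholds are free display parameters. Surfaces export
as ESRI ASCII grids (round-trip readable), GeoJSON contour lines at the
band thresholds with the reference points, and PNG heat renders.

## The synthetic panel generator

Because regional reference genotype collections are typically access
restricted, every stage is validated against a hierarchical
Balding–Nichols simulator. Per SNP an ancestral frequency
p ~ Uniform(0.05, 0.95) is drawn; group frequencies are Beta draws around p
at F_b (`fst_between_group`), population frequencies Beta draws around
their group at F_w, and genotypes Binomial(2, p_pop). Populations of one
group are laid out in a compact disc on the map so groups occupy contiguous
areas. The generator plants AIMs (frequency offset of 0.4 in one group,
direction chosen so the full offset fits inside [0.02, 0.98] — otherwise
boundary clipping would silently weaken planted markers), injects
missingness, appends Mendelian full-sib pairs, and can duplicate columns
with noise to create LD blocks for pruner tests. Everything is
deterministic under the configuration seed.

Defaults describe the standard validation panel used by the acceptance
suite: 8 groups × 3 populations × 25 samples (600 samples), 20,000 SNPs,
500 planted AIMs, F_b = 0.05, F_w = 0.01 (a typical within-region human
value), no missingness or relatives unless requested. Single-level panels are available via
`fst_within_group = 0`.

What the simulator does *not* emulate matters for interpreting green
tests: there is no linkage disequilibrium (independent SNPs), no admixed
individuals, no genotyping batch effects, and allele frequencies are
exchangeable across SNPs. Passing recovery tests therefore demonstrate the
selection and classification machinery, not performance on real arrays.

### A caution on planted-AIM recovery at strong background structure

At F_b = 0.05 every "background" SNP is itself substantially
ancestry-informative, and tree-importance mass concentrates on whichever
informative SNPs the trees happen to use: the planted and background
importance distributions overlap heavily, and the five-fold intersection
rule then recovers only part of the planted set at any threshold — raising
recovery necessarily floods the panel with background survivors. This
behavior is a property of impurity-importance stability selection at a few
hundred samples, not of this implementation. With a weakly structured
background (F_b = 0.01), where
planted markers dominate as true AIM panels dominate their genome
background, the suite verifies high recovery at high purity. The
acceptance report states the standard-condition recovery as computed;
downstream classification at these conditions is unaffected (holdout
macro-F1 saturates) because the survivors, planted or not, carry the group
signal.

## Numerical and reproducibility choices

- One seed governs each pipeline run: stratified folds, tree randomness,
  K-means restarts and splits all derive from it; fixed seeds give
  bit-identical panels, models and reports.
- Stratified folds error out when a class has fewer samples than folds,
  advising fewer folds; training requires ≥ 2 samples per class.
- glmnet convergence threshold 1e-9, max 1e5 iterations; incomplete
  convergence warns rather than failing silently.
- Degenerate inputs: zero-variance SNPs are dropped from PCA with a
  warning; SNPs entirely missing error at imputation unless a stored mode
  exists; kinship for pairs sharing no heterozygous SNP is reported as
  missing; empty point sets refuse interpolation.
- Validation problem sizes (chosen to exercise every code path at
  desk scale): unit panels of 120 samples × 2,000 SNPs; recovery panels of
  600 × 10,000–20,000; FST oracles of 200 × 5,000 over 10 seeds; structure
  recovery of 360 × 5,000.

## Known limitations

- The classifier is trained on, and intended for, non-admixed individuals;
  admixed genotypes yield low probabilities everywhere rather than
  admixture fractions.
- Imputation is single-marker modal — adequate for thousands of
  quasi-independent markers, by design not haplotype-aware.
- The rebalancing heuristic is greedy and order-dependent by construction;
  its log is the intended review artifact.
- Geographic surfaces use unprojected degrees; band areas are in cell
  counts, not km².
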