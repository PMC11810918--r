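---
title: "Mental-health phenotyping methods: models, defaults and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mental-health phenotyping methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

mhpheno implements a three-step analysis of self-reported mental-health
symptoms in cohorts of people with HIV (PWH): (1) data-driven phenotype
discovery from questionnaire totals via nonlinear dimension reduction and
hierarchical density clustering, (2) univariate referent-cluster inference,
and (3) gradient-boosted classification of the most and least symptomatic
phenotypes with interaction features, redundancy pruning and
saturation-based feature selection. Because cohort-level item data of this
kind are typically restricted, the package ships a calibrated synthetic
cohort generator that exercises every stage with known ground truth. This
vignette explains the models, the tunable parameters and their defaults,
the numerical choices, and what the synthetic experiments do and do not
establish.

## Instruments and scoring

Four self-report instruments are supported:

* **PHQ-9** (depression): 9 items scored 0–3, total 0–27; severity bands at
  5/10/15/20 (minimal, mild, moderate, moderately severe, severe).
* **BAI** (anxiety): 21 items scored 0–3, total 0–63; bands at 8/16/26.
* **PCL-C** (PTSD): 17 items scored 1–5, total 17–85; a total of at least 33
  flags possible PTSD.
* **CTQ** physical- and sexual-abuse subscales: 5 items each scored 1–5,
  totals 5–25, collapsed to three adversity categories (none/minimal,
  low–moderate, moderate–extreme). The collapse merges the conventional
  moderate and severe bands; the subscale cutoffs (PA: 8 and 10; SA: 6 and
  8) follow the standard published thresholds and are configurable through
  `default_ctq_cutoffs()`, because only the three category labels — not the
  raw cutoffs — are fixed by convention in the source literature.

Missing items fail closed by default (the affected score becomes `NA`);
`missing = "prorate"` imputes a single missing item with the rounded mean of
the observed items, a common scoring convention for these instruments.

## The synthetic cohort

`generate_cohort()` draws a cohort of (by default) 277 participants from
four latent phenotypes — PTSD-dominant (C1), anxiety-dominant (C2), mixed
anxiety/depression (C3) and minimal-symptom (C4) — at prevalences
0.274/0.116/0.469/0.141, and equips each participant with item-level
responses, demographics, HIV treatment indices, medical and medication
flags, and cognitive/motor raw scores. Calibration targets (per-phenotype
means and SDs of the three totals, CTQ category probabilities, demographic
and covariate rates) are the published per-cluster summary statistics of a
reference cohort of Ugandan adults with virally suppressed HIV; they are
exposed in `default_phenotype_targets()` and shipped as
`reference_cluster_summary()`.

Three design points deserve explanation.

**Calibrated truncated discretized normals.** Instrument totals are
integers in a bounded range, so each phenotype's totals are drawn by
rounding and clamping a latent normal. Naive truncation biases the mean
(for a phenotype whose mean sits near the floor the bias can exceed 0.2
points), so the latent mean is calibrated by root finding such that the
*post-truncation* expectation equals the published cluster mean exactly.
SDs are matched only approximately: truncation necessarily shrinks them.
A point-mass distribution (SD 0) is allowed, as one published cluster
reports a BAI of exactly 0 (0).

**Disjoint score windows.** Density clustering assigns identical score
triples to identical clusters, so any phenotype structure discovered by the
upstream method corresponds to *disjoint regions* of the score lattice. A
generator that drew overlapping Gaussians per phenotype would plant a
structure the method could never recover — and in our design experiments
neither this package's pipeline nor an independent reference implementation
(umap-learn plus scikit-learn's HDBSCAN) recovered overlapping phenotypes
reliably. The generator therefore confines each phenotype
to a score window: the PTSD phenotype has PCL-C at or above the clinical
screening threshold of 33 (matching its published description as a cluster
with mean PCL-C above threshold), the minimal-symptom phenotype occupies the
floor band (PCL-C 17–18, BAI 0, PHQ-9 0–1), and the anxiety and mixed
phenotypes occupy bands of roughly ±2 published SDs around their published
means, separated on the BAI axis (anxiety 4–8, mixed 0–2). Windows leave at
least one empty lattice plane between phenotypes and are fully configurable.

**Optional severity coupling.** A Gaussian-copula severity factor
(`score_factor_cor`) can correlate the three totals within a phenotype
while preserving each calibrated marginal exactly (quantile coupling). The
default is 0: coupling concentrates the large mixed cluster onto a thin
diagonal filament of the lattice, which density clustering then fragments;
with independent draws each phenotype fills its window as a compact block.

Item-level responses are allocated so items sum exactly to the drawn total,
with expected loadings proportional to per-phenotype weight profiles. The
default profiles plant the reported item-level signatures: anhedonia-heavy
depression in the PTSD phenotype, vegetative/somatic loading (sleep,
fatigue, appetite; the somatic BAI subset of `bai_somatic_items()`) in the
anxiety phenotype, and reduced endorsement of the cognitive PCL-C items in
the PTSD phenotype. Covariates not published per cluster (CES-D
positive-affect items, Karnofsky score, ART duration) use documented
baseline distributions with a modest planted gradient for the
positive-affect items, consistent with the reported importance of
happiness/hopefulness ratings for separating the PTSD from the
minimal-symptom phenotype. `plant_classifier_signal()` overrides any
feature's phenotype association with a recorded known-truth effect.

What the generator does **not** emulate: realistic inter-item correlation
beyond the planted profiles, missing data, measurement error in the
covariates, longitudinal structure, or the marginal PCL-C threshold
prevalence of the real cohort (the windowed PTSD phenotype makes the
cohort-level flag prevalence equal that phenotype's prevalence, about 27%,
whereas the reference cohort reports 15.2%). Passing recovery tests on this
generator therefore demonstrates that the pipeline recovers *separable*
planted structure at realistic sample sizes and noise levels — not that any
particular real cohort contains such structure.

## Phenotype discovery

`phenotype_clustering()` embeds the n-by-3 matrix of BAI/PHQ-9/PCL-C totals
with a compact UMAP implementation and clusters the embedding with
HDBSCAN.

The UMAP step (`embed_scores()`) follows the reference algorithm: exact
k-nearest neighbors (k = 15 by default), smoothed-kNN calibration of
per-point bandwidths to a fixed local connectivity (target `log2(k)`),
probabilistic t-conorm symmetrization, spectral initialization from the
normalized graph Laplacian (with a PCA fallback for degenerate graphs), and
stochastic gradient optimization of the fuzzy cross-entropy with negative
sampling (500 epochs at these data sizes, learning rate decaying from 1,
five negative samples per positive, gradient clipping at ±4). All
randomness derives from the config seed; repeated runs are bit-identical.

Two numerical choices matter for questionnaire totals specifically:

* **Raw score units, not z-scores** (`standardize_inputs = FALSE`). All
  three instruments live on integer lattices. Z-scoring rescales the PCL-C
  lattice (pooled SD around 8–9) to roughly a third of the PHQ-9 lattice
  spacing, after which between-phenotype gaps measured in PCL-C units are
  *smaller* than within-phenotype lattice gaps measured in PHQ-9 units — a
  geometry in which no density method can find the boundary. In raw units
  every instrument has spacing 1 and a two-point score gap is always wider
  than a within-cluster step. Standardization remains available for inputs
  on heterogeneous scales.
* **De-duplication jitter** (`dedup_jitter = 0.05` score units). Integer
  totals produce exactly duplicated rows; duplicate groups have zero core
  distance, which makes their density effectively infinite and surfaces
  them as spuriously stable micro-clusters. Seeded Gaussian jitter far below
  the lattice spacing breaks ties without moving any point across a score
  level.

The HDBSCAN step (`cluster_embedding()`) implements mutual-reachability
distances (core distance of order `min_samples`), a minimum spanning tree,
the condensed cluster hierarchy under `min_cluster_size`, excess-of-mass
cluster selection (the root is never selectable, so structureless data is
all noise), and noise labeling. Its behavior was verified against
scikit-learn's HDBSCAN: on identical embeddings the two produce identical
partitions. `min_cluster_size` defaults to `max(10, ceiling(0.08 n))` —
about 22 at n = 277 — with `min_samples = min_cluster_size`; on duplicate-
heavy lattices smaller minima (e.g. 4% of n) let groups of a dozen
near-duplicates through as spurious clusters. Both parameters are exposed.

Cluster validity is summarized by the mean silhouette over non-noise points
(`evaluate_silhouette()`, via the cluster package). Noise handling follows
the outliers-as-their-own-group reading: noise points keep label 0 and are
excluded from silhouettes and summaries; `reassign_noise = TRUE` attaches
each noise point to the nearest cluster centroid for analyses that need a
complete partition.

`label_phenotypes()` names clusters with a deterministic rubric: rank by
mean PCL-C descending; the first cluster at or above the screening
threshold (33) is *PTSD*; among the rest the cluster with the lowest
aggregate elevation (mean of range-normalized totals) is *minimal_symptom*;
with exactly four clusters the remaining two split on mean BAI (*anxiety*
above, *mixed_anxiety_depression* below). With any other cluster count the
uncovered clusters are labeled `unlabeled`, never dropped.

## Referent-cluster inference

`compare_to_referent()` tests each cluster against a referent (by default
the highest-numbered cluster; in practice the minimal-symptom cluster) on
age, sex, education, viral-load detectability and the two CTQ categories.
Continuous variables use the Welch t-test (Satterthwaite df) and
categorical variables the Pearson chi-square without continuity correction;
both choices reproduce the published referent contrasts (sexual abuse
p = 0.03, physical abuse p = 0.26) from the printed category counts, and
both are configurable (pooled-variance t, Yates correction, Fisher exact
fallback). Summary-statistic input is supported so printed tables can be
tested without raw data. Expected cell counts below 5 raise a warning.
P-values are reported unadjusted, matching the source convention; report
tables use two decimals with `<0.001` below that threshold
(`format_p()`), and raw values are retained.

## Boosted classification

`classify_phenotypes()` separates the PTSD phenotype from the
minimal-symptom phenotype using the feature inventory of
`default_classifier_features()` (demographics, treatment indices,
functional status, medical/medication flags, cognition, CTQ items, CES-D
positive-affect items — never the three phenotype-defining instruments).

* **Redundancy pruning.** Features whose absolute Pearson correlation
  exceeds 0.65 are grouped by transitive closure; within each group only
  the member with the highest maximal information coefficient (MIC) against
  the class label survives, ties broken lexicographically.
* **MIC estimator** (`mic()`). Grid-search normalized mutual information
  with the conventional grid bound B(n) = n^0.6: for every grid shape
  a-by-b with a·b ≤ B, equal-frequency and equal-width partitions of each
  axis are evaluated and MI is normalized by log2(min(a, b)); the maximum
  over grids is returned. This estimator omits the dynamic-programming cut
  optimization of the original MIC publication in favor of speed and
  simplicity; it attains about 1 for noiseless functional relationships
  (including non-monotone ones invisible to Pearson r) and stays below 0.2
  under independence at n = 1000.
* **Interaction features** (`build_interactions()`). For each unordered
  pair, a product column (synergy: risk tied to joint movement in the same
  direction) and quotient columns (divergence). Quotients are computed on
  min-max-scaled inputs as A'/(B' + 1e-6), so no division by zero can
  occur; the reverse orientation is kept only when it is not redundant
  (|r| ≤ 0.65) with the forward one. With the full inventory the pair set
  is capped to the `interaction_pool` (default 8) base features strongest
  by MIC, keeping the candidate pool tractable.
* **Cross-validated F1** (`cv_f1()`). Stratified 5-fold CV repeated 5 times
  (25 trials). Per trial, a gradient-boosted tree ensemble with logistic
  loss (xgboost behind the `boost_config()` contract: 50 rounds, depth 3,
  learning rate 0.3, single thread, exact splits) is fit on the training
  folds; held-out probabilities come from the sigmoid link and class
  membership from the 0.5 boundary; F1 is the harmonic mean of precision
  and recall for the designated positive class. Per-repeat fold seeds
  derive deterministically from the global seed.
* **Saturation-based forward selection** (`select_features()`). Candidates
  are ranked by a cheap screening CV (one 5-fold repeat); the top 3 are
  re-scored with the full 25-trial CV, and the best joins the model only if
  its mean-F1 gain exceeds `saturation_sd` (default 1) times the current
  model's trial SD — the "no better than 1 SD" saturation rule. The
  shortlist re-evaluation exists because with dozens of noise candidates a
  single 5-fold screen occasionally misranks a distractor first, and a
  greedy that stops on the first failed candidate would end prematurely.
  The saturation reference is the current best model by default; comparing
  against the first one-feature model instead (`base = "first"`) is the
  alternative reading of the rule and is available by flag. Selection stops
  at `max_features` (default 10) or pool exhaustion; the trace records
  every decision.
* **Model products.** Partial-dependence curves (`partial_dependence()`)
  average predicted probabilities over the data with one feature clamped to
  each grid value; interaction surfaces (`interaction_heatmap()`) do the
  same on a grid for a feature pair. Both are emitted as plain tables;
  plotting is left to the caller.

Sex and marital status are encoded as binary indicators; any other
character column is ordinal-encoded by factor level, and the encoding is
implicit in the feature matrix handed to the booster.

## Validation design and problem sizes

The test suite validates each stage against an independent oracle where one
exists (brute-force silhouette and Pearson chi-square, confusion-matrix F1,
`stats::t.test`, closed-form toy examples) and uses property-based
simulations elsewhere, at sizes chosen to keep the default suite fast while
leaving sampling error well below the tested margins:

* phenotype recovery: 20 default cohorts (n = 277), adjusted Rand index of
  non-noise labels vs latent truth, pass bound ARI ≥ 0.7 in ≥ 80% of seeds;
* feature-selection recovery: 3 informative features (logistic coefficient
  2.5, individually detectable at n = 300) among 50 noise features, 20
  seeds, at least 2 of 3 recovered in ≥ 80% of seeds; null designs (zero
  coefficients) must stop immediately at chance-level F1;
* interaction benefit: 20 planted-synergy designs (n = 240), mean F1 with
  interactions no worse than one trial-SD below the mean F1 without.

The planted selection effect size is deliberately clear of the saturation
rule's detection boundary: at coefficients near 1.5 the marginal F1 gain of
a genuine second feature roughly equals the trial SD, and the 1-SD rule —
operating exactly as specified — truncates selection, which would test the
rule's sharpness rather than the selector's correctness.

## Known limitations

* The synthetic phenotypes are separable by construction; real cohorts may
  contain phenotypes that density methods cannot cleanly separate, and the
  package will report few clusters, low silhouettes, or high noise
  fractions in that case rather than fail.
* The MIC estimator is a simplified grid search; absolute values are not
  comparable with implementations using the ApproxMaxMI optimization,
  though orderings of clearly distinct associations are stable.
* The UMAP implementation targets small tabular inputs (exact kNN, dense
  spectral initialization); it is not suitable for tens of thousands of
  rows.
* Severity-band cutoffs, CTQ collapse cutoffs, and every clustering and
  boosting hyperparameter are conventions exposed in configuration objects;
  conclusions can and should be checked for robustness across those
  settings.
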