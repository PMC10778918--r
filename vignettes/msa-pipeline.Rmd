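---
title: "Calling LOH from matched blood/urine peaks and modelling marker profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling LOH from matched blood/urine peaks and modelling marker profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The assay and its readout

Bladder tumours shed cells into urine, and loss of heterozygosity (LOH) at
short tandem repeat (STR) loci in that tumour-derived DNA can be detected
by comparing urine sediment against a blood (germline) control. After
multiplex PCR and capillary electrophoresis, each locus of each specimen
presents as one or two allele peaks with heights measured in relative
fluorescence units (RFU). At a heterozygous locus the evidence for LOH is
an imbalance of the urine allele ratio relative to the blood allele ratio:

    ratio = (urine allele1 / urine allele2) / (blood allele1 / blood allele2)

with allele 1 the smaller-size allele in both specimens. In a healthy
matched pair the two specimens carry the same germline, so the ratio
scatters around 1; loss of one allele in the tumour fraction drives it
towards 0 (or, with the labels reversed, towards infinity). The quantity
is naturally analysed on the log scale, where healthy noise is symmetric
around 0.

`msapipe` implements the complete path from the instrument's tab-delimited
peak export to a cohort-level model comparison: per-locus calling,
per-sample acceptance, cohort cleaning, binary encoding, and a staged
machine-learning evaluation.

## Locus calling rules

A locus receives exactly one of four calls:

* **Non-Evaluable** — any required peak (either specimen) is absent from
  the RFU acceptance window `[200, 100000]`. The floor protects against
  stochastic amplification of degraded DNA; the ceiling against detector
  saturation.
* **Non-Informative** — the blood locus is homozygous. With a single
  germline allele no allele balance exists, so LOH is undetectable.
  The evaluability gate is applied first: a homozygous locus whose urine
  peaks fail the window is Non-Evaluable, not Non-Informative, because
  nothing about that locus could be measured.
* **Positive** (LOH) — the ratio falls strictly below the marker's lower
  cut-off or strictly above its upper cut-off.
* **Negative** — otherwise. A ratio exactly at a cut-off is Negative:
  the cut-offs define the healthy range inclusively, and a tie in a
  screening assay should not assert disease.

Two judgment calls the underlying measurement forces:

* **Allele matching.** Fragment sizing jitters by fractions of a base
  pair, so urine alleles are matched to blood alleles by nearest size
  within a 1 bp tolerance rather than exact equality.
* **Complete allele dropout.** A heterozygous blood locus whose urine
  shows only one in-window allele is scored **Positive** with the missing
  allele's height imputed at the 200 RFU detection floor, and flagged
  `dropout`. Complete loss of one allele is the strongest possible LOH
  signal; the imputation keeps the reported ratio finite and conservative
  (the true ratio is at least as extreme). The alternative reading —
  scoring dropout as Non-Evaluable — would systematically discard the
  clearest positives, which we consider indefensible for a detection
  assay.

A run is only interpreted when its positive control passes
(`validate_positive_control()`): every expected control locus must show a
peak within 1 bp of its expected size with an in-window height.

## Sample acceptance and the overall genotype

A sample qualifies when at least 8 of its loci received a Negative,
Positive or Non-Informative call (Non-Evaluable loci carry no
information about the specimen, only about the run). A sample failing
this on its first analysis is flagged for one repeat; failing twice it is
reported QNS ("quantity not sufficient"). Accepted samples receive an
overall genotype from their count of Positive markers: 0 `negative`, 1–2
`LOH-low`, 3–4 `LOH-medium`, 5+ `LOH-high`.

## Cut-off calibration

Per-marker cut-offs are a configuration input (`cutoff_table()`, YAML or
JSON on disk). When a matched healthy panel is available,
`calibrate_cutoffs()` estimates them as `exp(mean ± k·SD)` of the healthy
log-ratios, with `k = 3` by default: under approximately log-normal noise
about 0.3% of healthy heterozygous loci fall outside, which the test
suite verifies by Monte-Carlo on an independent panel. Two degenerate
cases are handled explicitly: a marker with fewer than two heterozygous
pairs is flagged and omitted (no spread estimate exists), and a
zero-variance panel is widened to a minimum half-width of 0.05 on the log
scale so the bounds never collapse onto 1. Whether cut-offs should be
log-symmetric at all is an open question of the assay; the calibrator
centres them on the healthy mean rather than forcing symmetry around 1,
and the boundary-inclusive Negative convention makes calls invariant to
that choice at the boundary itself.

## Cohort cleaning and encoding

Samples dominated by uninformative loci carry almost no usable signal and
distort the downstream model. `filter_noninformative()` removes every
sample with 5 or more loci that are Non-Informative or Non-Evaluable
(homozygous sites, insufficient peak height, or a combination), after
excluding QNS samples outright. The survivors are encoded as a binary
matrix — 1 for Positive, 0 for any non-positive call — with a
`status` label column (`cancer`/`normal`). We read the cleaning rule as
the union of both uninformative call types because both deprive the
classifier of the same thing, an interpretable marker value; the
threshold is configurable.

## The staged model suite

`msa_suite()` evaluates six cumulative modelling stages over a common
plan of repeated stratified 80/20 train/test splits (default 20 splits in
package workflows; 100-split designs are common for this kind of
comparison, but the mean AUC stabilises well before that, and dispersion
across splits is reported either way):

1. **base** — stochastic gradient boosting (SGB) on the binary markers.
   The classifier is an additive ensemble of shallow trees fit stagewise
   to the residuals of the existing ensemble, with row and per-split
   column subsampling. Seven parameters matter (`tree_depth`, `min_n`,
   `loss_reduction`, `sample_size`, `mtry`, `learn_rate`, plus the
   ensemble size); defaults are depth 3, `min_n` 5, no loss-reduction
   floor, 80% row subsampling, all columns, learning rate 0.1, 150
   trees — standard settings for small tabular problems. Optional
   per-split tuning (`tune = TRUE`) runs a random search over a
   documented grid under stratified 5-fold cross-validation
   (leave-one-out via `cv_folds = "loo"`), maximising mean CV AUC with
   ties broken towards the simpler model (smaller depth, then smaller
   learning rate). We default to 5-fold because it estimates AUC
   per-fold (leave-one-out cannot) at a fraction of the cost.
2. **M1_count** — adds `marker_count`, the per-sample count of positive
   markers. Total LOH burden is itself diagnostic, beyond which markers
   are positive.
3. **M2_outlier** — random-forest proximity outlier removal. The
   proximity of two cases is the fraction of trees in which they share a
   terminal node; each case is scored by its mean proximity to its own
   class, and cases more than 1 SD below their class mean are removed.
   If a class's scores have zero spread, nothing is removed.
4. **M3_upsample** — the minority class of the training fold is resampled
   with replacement to parity (the design has a 3:1 cancer:normal
   imbalance). Test folds are never resampled.
5. **M4_topk** — keeps the `top_k` (default 8) markers by permutation
   importance: the mean increase in prediction RMSE when a marker's
   column is independently permuted, measured against the fitted model.
   A constant column has importance exactly 0, and the expectation of the
   score does not depend on the repetition count K — so the package
   default of K = 10000 for the standalone function is scaled to K = 200
   in suite workflows and K = 100 in tests without changing what is
   estimated, only the Monte-Carlo jitter of the ranking. The ranking
   model is fit on the markers alone: with `marker_count` present the
   burden feature absorbs most of the signal and per-marker importances
   collapse towards zero, making the ranking uninformative.
6. **stacked** — on the M4 feature set, a two-layer stack: first-level
   features are the SGB probability and the decision values of two
   radial-kernel one-class SVMs (one trained on cancer cases only, one on
   normal cases only, `nu = 0.1`); the second layer is an elastic-net
   logistic regression (`alpha = 0.5`, penalty by internal 5-fold CV).
   First-level features for the combiner are generated out-of-fold by
   5-fold CV within the training fold, so the stacker never sees a
   first-level prediction of a case that produced it.

Every stage's transformations — outlier removal, up-sampling, importance
ranking, marker selection, first-level stacking features, tuning — are
computed from the training fold alone under the default configuration. A
leakage sentinel in the test suite verifies the consequence: on
label-shuffled data every stage's mean test AUC sits at chance.

### Where outlier removal happens: two scopes

The one genuinely open design point is whether outlier removal shrinks
only the training fold or the whole cohort. `outlier_scope = "train"`
(default) is the leakage-safe reading: test folds are untouched, and the
measured AUC is honest generalisation error. `outlier_scope = "all"`
removes the proximity outliers from the cohort once, before splitting,
so the later stages are split and scored on the reduced cohort — the
cleaned-up cohort itself becomes the object of study. This is the
configuration under which a monotone improvement of AUC across stages
appears, because the removed cases are exactly the ambiguous ones.
Results under `"all"` should be read as replication of that procedure,
not as validation: information from the removal step reaches the test
folds. The package exposes both and the acceptance machinery exercises
both (the sentinel under `"train"`, the stage-ordering check under
`"all"`).

## The synthetic cohort generator

The study data the pipeline targets are not public, so the generator
(`cohort_spec()`, `generate_peak_cohort()`, `generate_healthy_panel()`,
`generate_marker_matrix()`) emulates the design the analysis assumes,
with planted ground truth for recovery tests. Defaults, chosen once as
the study conditions:

* 300 cancer / 100 normal samples (3:1), 15 markers;
* heterozygosity 0.8 per locus (≈20% homozygosity, which is the main
  driver of Non-Informative calls);
* 8 LOH-enriched markers at rate 0.5 in cancer urine, the remaining 7 at
  the background 0.02; spurious LOH in normal urine at 0.02 (individual
  markers are highly specific in healthy donors);
* degradation probability 0.05 per locus (urine peaks below the 200 RFU
  floor); peak heights log-normal with median 2000 RFU and CV 0.5, both
  safely inside the acceptance window; log allele-balance noise SD 0.15
  between specimens;
* LOH as multiplicative suppression of one urine allele by a factor
  uniform in [0.1, 0.4] — far enough outside any calibrated cut-off to be
  detectable, close enough that calibration quality matters. A
  suppression that would land the peak below the detection floor is
  emitted as complete allele dropout, which is how such loci present on
  the instrument.

No distributional description of real peak heights was available to fit;
these are stand-ins with the right orders of magnitude. The generator
deliberately omits PCR stutter, dye pull-up, electrophoretic mobility
artifacts, and clinical confounders (hematuria, infection). Passing
tests therefore demonstrate that the calling rules, cleaning rules and
modelling stages do what they claim on data with this structure — not
that the assay achieves any particular clinical accuracy. On the default
planted design the post-removal cohorts are nearly separable and AUCs
saturate near 1; the informative comparisons are the orderings and the
recovery rates, not the absolute values.

## Numerical choices and degenerate inputs

* Split sizes round in favour of training (`floor` of the test
  fraction, per class when stratified), with an epsilon guard against
  floating-point undershoot.
* AUC is the Mann–Whitney rank statistic (ties at half credit),
  identical to the trapezoidal area; the test suite checks it against
  exhaustive pair counting and an external reference.
* Confusion metrics threshold probabilities at 0.5 with cancer positive.
* A locus with more than two peaks keeps the two tallest (stutter
  survivors), then orders by size.
* All-constant stacking features collapse to an intercept-only combiner
  that predicts the prevalence.
* PCA views fix signs by making each component's largest-magnitude
  loading positive; a constant matrix returns zeros with a warning.
* Every stochastic step (generation, splitting, subsampling, SVM-free
  stages alike) derives from explicit seeds, and the end-to-end driver
  `run_msa_analysis()` derives all of them from one global seed, so a
  rerun reproduces the report exactly.

## Problem sizes

Package workflows use 20 splits on 300–400-sample cohorts, permutation
importance at K = 200 (tests at K = 100), random forests of 300–500
trees, and 150-tree boosters. These sizes put the full synthetic
pipeline — generation, calibration, calling, cleaning, six stages over
20 splits — in the low minutes on a single core while leaving all
Monte-Carlo margins comfortably wider than the effects being checked.

## Known limitations

* Cut-off values for a deployed assay are a configuration input; the
  calibrator reproduces the procedure (healthy-panel ratios), not any
  laboratory's proprietary cut-off table.
* The dropout-as-Positive convention and the union reading of the
  cleaning rule are documented interpretations of ambiguous assay
  language; both are configurable or flagged in output.
* The marker panel treats the one primer pair that yields two
  amplification products as two independent markers, matching how the
  binary matrix is laid out (15 markers from 14 primer sets).
* Synthetic validation bounds what can be claimed: the pipeline recovers
  planted structure; clinical performance requires the real cohort.
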