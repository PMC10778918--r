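# msapipe

Microsatellite analysis (MSA) of matched **urine and blood** specimens for
bladder cancer detection: from raw capillary-electrophoresis peak heights
to loss-of-heterozygosity (LOH) calls, and from binary marker profiles to
a staged machine-learning model comparison.

The package is aimed at assay developers and biostatisticians working
with STR (short tandem repeat) marker panels who need (a) a rule-exact,
tested implementation of peak-ratio LOH calling with per-marker cut-offs
and sample acceptance criteria, and (b) a reproducible evaluation harness
for the modelling pipeline that turns marker profiles into a cancer/normal
classifier.

## The model

**Locus calling.** At a heterozygous locus, LOH in urine-derived DNA is
detected from the allele peak-height ratio

```
ratio = (urine allele1 / urine allele2) / (blood allele1 / blood allele2)
```

(allele 1 = smaller size in both specimens). A locus is *Positive* when
the ratio escapes the marker's `(lower, upper)` cut-offs, *Negative*
otherwise; loci with peaks outside the 200–100,000 RFU acceptance window
are *Non-Evaluable* and homozygous blood loci are *Non-Informative*.
Samples need ≥ 8 qualifying loci (with one repeat allowed) or they are
QNS; accepted samples get an overall genotype from their positive-marker
count (0 / 1–2 / 3–4 / ≥ 5 → negative / LOH-low / LOH-medium / LOH-high).
Cut-offs can be calibrated from a matched healthy panel as
`exp(mean ± 3·SD)` of the log-ratios.

**Modelling.** Cleaned profiles are encoded as a binary samples × markers
matrix and evaluated over repeated stratified 80/20 splits through six
cumulative stages: a stochastic-gradient-boosting base model
`f(x) = Σ_t a_t h_t(x)`; an engineered marker-burden count; random-forest
proximity outlier removal (cases > 1 SD below their class's mean
within-class proximity); minority-class up-sampling; permutation-importance
selection of the top-8 markers (mean RMSE increase under column
permutation); and a stacked ensemble combining the boosting probability
with two radial-kernel one-class SVM scores through elastic-net logistic
regression. A synthetic cohort generator with planted ground truth makes
every stage testable.

## Worked example

Simulate the default study design (300 cancer / 100 normal, 15 markers of
which 8 are LOH-enriched), calibrate cut-offs from 50 healthy pairs, call
LOH, clean, and evaluate all six model stages over 10 splits:

```r
library(msapipe)

spec <- cohort_spec(seed = 7)   # default study design: 300 cancer / 100 normal
report <- run_msa_analysis(spec = spec, seed = 7, n_splits = 10,
                           importance_K = 100, outlier_scope = "all")
print(report)
#> MSA analysis report (input: spec, seed 7)
#>   400 samples profiled, 115 removed in cleaning
#>   matrix: 285 samples x 15 markers
#> MSA model suite: 6 stage(s) over 10 split(s)
#>   base        AUC 0.982 (SD 0.008)  accuracy 0.953
#>   M1_count    AUC 0.982 (SD 0.008)  accuracy 0.935
#>   M2_outlier  AUC 1.000 (SD 0.000)  accuracy 1.000
#>   M3_upsample AUC 1.000 (SD 0.000)  accuracy 1.000
#>   M4_topk     AUC 1.000 (SD 0.000)  accuracy 1.000
#>   stacked     AUC 1.000 (SD 0.000)  accuracy 1.000

head(report$suite$importance, 8)
#>  feature importance rank
#>      M02    0.09302    1
#>      M03    0.09127    2
#>      M04    0.08572    3
#>      M05    0.07309    4
#>      M01    0.06770    5
#>      M06    0.06177    6
#>      M08    0.05388    7
#>      M07    0.01264    8
```

Reading the output: 115 of the 400 simulated samples are removed by the
acceptance and cleaning rules (QNS, or ≥ 5 non-informative loci — the
generator plants ~20% homozygosity plus degradation, so this is
expected attrition, not failure). The base boosting model already
separates the planted signal well (AUC 0.982); removing proximity
outliers from the whole cohort (`outlier_scope = "all"`, so the later
stages study the reduced cohort itself) lifts them to saturation on this
synthetic design. The importance ranking recovers the
8 planted LOH-enriched markers (`M01`–`M08`) as the top 8. On the
leakage-safe default (`outlier_scope = "train"`) test folds are never
altered and the AUCs stay honest generalisation estimates; see the
vignette for when to use which.

Lower-level entry points mirror the worked pipeline:
`generate_peak_cohort()`, `calibrate_cutoffs()`, `call_cohort()`,
`sample_profiles()`, `filter_noninformative()`, `binarize()`,
`msa_suite()`, plus `roc_auc()`, `confusion_metrics()` and `pca_view()`.
A thin CLI with `simulate` / `call` / `prep` / `model` / `all`
subcommands is installed at `inst/cli/msapipe`.

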