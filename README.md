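# pachycnv

Deep-phenotype stratification of unilateral choroidal neovascularization
(CNV) and the pachychoroid CNV score, as a tested R package plus a
reproducible analysis workflow.

Neovascular age-related macular degeneration is heterogeneous: some eyes
have classic drusen-driven disease with a thin choroid (AMD-type), others
have CNV on a pachychoroid background — thick choroid, choroidal vascular
hyperpermeability (CVH), pachyvessels (PNV-type). The two respond
differently to anti-VEGF therapy, but there are no agreed diagnostic
criteria. This package is for retina researchers and biostatisticians who
want to (a) stratify a phenotyped CNV cohort without supervision, (b)
apply or re-derive the compact CNV score that separates the two types, and
(c) relate the score to visual outcome.

## What it implements

**Unsupervised stratification.** Standardize 61 baseline features →
PCA → gap statistic → k-means on all retained principal components.
The gap statistic compares the within-cluster dispersion

    W_k = Σ_r D_r / (2 n_r)        (D_r: ordered-pair squared distances)

with its expectation under a uniform reference null in the PCA-rotated
bounding box: gap(k) = E*[log W_k] − log W_k, with the chosen k the
smallest one whose gap is within one standard error of the first local
maximum. Clusters are labeled by mean fellow-eye subfoveal choroidal
thickness (SFCT): thicker ⇒ PNV-type.

**The CNV score.** A logistic log-odds score,

    score = −7.04 + 0.16·(age/10) + 0.52·female + 1.99·CVH
            − 0.34·(RT/100) + 1.37·(SFCT_affected/100)
            + 1.24·(SFCT_fellow/100) − 1.68·drusenA

(RT = affected-eye central retinal thickness in µm, SFCT in µm, binary
flags 0/1). Positive ⇒ PNV-type, with probability `plogis(score)`. The
package both ships these published weights and re-derives weights from any
labeled cohort (3:1 split, plain logistic fit, 2-decimal rounding), plus
threshold diagnostics (accuracy/sensitivity/specificity, trapezoid AUC)
and cutoff-bin positive predictive values.

**Outcome association.** Last-observation-carried-forward completion of
follow-up visual acuity and OLS of the logMAR change at months 3 and 12 on
the score, adjusted for age, sex and baseline logMAR.

**Synthetic cohort generator.** The patient-level data are not deposited,
so `default_config()` encodes the published two-class structure (289
AMD-type + 248 PNV-type; all printed per-cluster means/SDs/prevalences)
and `simulate_cohort()` draws reproducible cohorts with correlated SFCT
pairs, physiologic truncation and follow-up visits, so the whole pipeline
is testable end to end.

## Worked example

```r
library(pachycnv)

# score one patient with the published weights: 66-year-old man, CVH+,
# RT 455 um, SFCT 508/503 um, no soft drusen
pt <- tibble::tibble(age = 66, sex = 0, cvh_either = 1,
                     retinal_thickness_affected = 455,
                     sfct_affected = 508, sfct_fellow = 503,
                     drusen_a_either = 0)
cnv_score(pt)
#> [1] 7.6558        # strongly PNV-type; plogis(7.66) > 0.999

# simulate the study-condition cohort and rediscover its structure
cfg    <- default_config()
cohort <- simulate_cohort(cfg)
cl     <- cluster_cohort(cohort, seed = 202, k_max = 10, B = 100)
cl$gap$chosen_k
#> [1] 2             # the gap statistic picks two clusters
mean(cl$assignments == cohort$true_cluster)
#> [1] 0.9534451     # fraction of patients assigned to their generating class
```

The same steps as a narrative workflow live under `analysis/`
(`01_simulate_cohort.R` → `04_visual_outcomes.R`); each script prints what
it found and writes its tables under `results/`. Stage 3, for example,
reports for the default seeds:

```
split: 402 training / 135 validation
validation: accuracy 0.844, sensitivity 0.814, specificity 0.868, AUC 0.940
```

i.e. on synthetic data the re-derived 7-predictor score separates the
discovered clusters with AUC ≈ 0.94 — the behaviour the design targets,
not a reproduction of real-data coefficients. `run_pipeline()` executes
all stages in one call from a `pipeline_config()`.

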