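# immunoscore

Survival-driven immunoscore analysis for advanced colorectal cancer with
distant metastasis.

## What this package does, and for whom

Pathology groups quantify tumor-infiltrating immune cells by
immunohistochemistry and image analysis: densities of lymphocyte markers
(CD3, CD4, CD8, FOXP3, in cells/mm²) and macrophage markers (CD68, CD163, in
pixels/mm²), measured in up to three regions per patient — the primary tumor
center (CT), its invasive margin (IM), and a distant metastasis (DM). This
package takes those per-patient density tables plus clinical/survival data
and runs the full prognostic-scoring workflow:

1. **Dichotomization.** Each (marker, region) density is split into
   high/low against overall survival by the *maximal chi-square method*:
   every distinct observed density is a candidate threshold, each admissible
   split is scored by the two-sample log-rank statistic

   χ² = ( Σⱼ d₁ⱼ − dⱼ n₁ⱼ/nⱼ )² / Σⱼ dⱼ (n₁ⱼ/nⱼ)(1 − n₁ⱼ/nⱼ)(nⱼ − dⱼ)/(nⱼ − 1),

   summing observed-minus-expected events and hypergeometric variances over
   distinct event times j, and the maximizing threshold is selected
   (`maxstat_cutoff()`). Median cutoffs are the transparent alternative.
2. **Composite scores.** Binary flags (density ≥ cutoff → high) are summed
   into three models: **IS** (CD3/CD8 × CT/IM, 0–4, low 0–2),
   **IS-M** (+ CD3/CD8 in DM, 0–6, low 0–3), and **IS-ma** (+ CD163 in
   CT/IM with inverted polarity — low macrophage density scores 1; 0–6,
   low 0–3). Patients missing any component core are not evaluable for that
   model only.
3. **Prognostic evaluation.** Kaplan–Meier curves and log-rank tests per
   score class, univariate Cox hazard ratios for every clinicopathologic
   factor, and one multivariate fit per score model (adjusted for age, pT,
   pN, metastasis timing, lymphatic and perineural invasion), with optional
   stratification by KRAS/PIK3CA/BRAF status.
4. **Heterogeneity.** Paired within-patient comparisons of a marker across
   regions, by-organ summaries of the metastatic lesion, and Pearson
   concordance of duplicated cores.

A synthetic cohort generator (`generate_cohort()`) reproduces the
distributional structure this analysis assumes — right-skewed log-normal
densities anchored to published-scale medians/IQRs, regional and by-organ
heterogeneity, region-level missing cores, proportional-hazards survival
with censoring — so the entire pipeline is testable without patient data.

## Worked example

```r
library(immunoscore)

coh <- generate_cohort(cohort_config(n_patients = 196, seed = 42))
coh
#> <crc_cohort> 196 patients, 142 events, 3528 density cells (48 missing cores)

cuts <- build_cutoff_table(coh, method = "maxstat")
head(as.data.frame(cuts)[, c("marker","region","cutoff","statistic","n_low","n_high")], 3)
#>   marker region cutoff statistic n_low n_high
#> 1    CD3     CT 108.00     4.903    24    172
#> 2    CD3     IM 353.15    28.240    89    104
#> 3    CD3     DM  72.75    24.109    97     94

scores <- classify_cohort(coh, cuts)
dist <- score_distribution(scores$score[scores$model == "IS_M"], "IS_M")
c(evaluable = dist$n, low = dist$n_low, pct_low = dist$pct_low)
#> evaluable       low   pct_low
#>       188        48      25.5

rep <- prognostic_report(coh, scores)
subset(rep$multivariate, model_id == "multivariate_IS_M" & term == "IS_Mlow")[,
       c("term","hr","ci_lo","ci_hi","p")]
#>     term   hr ci_lo ci_hi        p
#>  IS_Mlow 3.52  2.35  5.28 9.33e-10
```

Reading the output: 48 cores were masked as lost (region-level), leaving 188
of 196 patients evaluable for the metastasis-inclusive model. Each cutoff row
gives the selected threshold, its maximal log-rank chi-square, and the
resulting group sizes. The multivariate hazard ratio of 3.52 says that, after
adjustment for the six clinical factors, patients in the low IS-M class die
at 3.5 times the rate of the high class — this cohort was simulated with a
true adverse effect for each low lymphocyte component, so a strong low-class
hazard is the expected recovery. (The maxstat statistic is *selected* over
many candidate splits; use `maxstat_permutation_p()` for an honest p-value.)

File-based runs use the same machinery end to end:

```r
cfg <- run_config(densities = "densities.csv", clinical = "clinical.csv",
                  cutoff_method = "maxstat", out_dir = "results_dir", seed = 1)
run_pipeline(cfg)   # cutoffs.json, scores.csv, km_curves.csv, cox_*.csv, ...
```

or from a shell: `Rscript inst/cli/immunoscore.R run --simulate 196 --seed 7 --out out/`.

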