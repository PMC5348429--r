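---
title: "Immunoscore models for metastatic colorectal cancer: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immunoscore models for metastatic colorectal cancer: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunoscore)
```

## The problem

Tumor-infiltrating immune cells carry prognostic information in colorectal
cancer. The immunoscore (IS) condenses the densities of CD3+ and CD8+
lymphocytes in the tumor center (CT) and invasive margin (IM) into an integer
score: each of the four (marker, region) components contributes 1 when the
patient's density is *high* relative to a cohort-level threshold. In patients
with distant metastases there is a case for also scoring the metastatic
lesion (DM), and for incorporating tumor-associated macrophages, which carry
the opposite prognostic direction to lymphocytes. This package implements
the resulting family of three composite models and everything needed to
evaluate them:

* **IS** — CD3 and CD8 in CT and IM; range 0–4; low 0–2, high 3–4.
* **IS-M** (metastatic) — IS plus CD3 and CD8 in DM; range 0–6; low 0–3,
  high 4–6.
* **IS-ma** (macrophage) — IS plus CD163 in CT and IM with inverted
  polarity (a *low* macrophage density scores 1); range 0–6; low 0–3,
  high 4–6.

Densities arrive pre-computed from image analysis: nuclear counts per mm²
for lymphocyte markers (CD3, CD4, CD8, FOXP3) and positive-pixel counts per
mm² for macrophage markers (CD68, CD163). Units are a property of the marker
family and are validated, never converted.

## Survival-driven dichotomization

The central methodological step is turning each continuous (marker, region)
density into a binary high/low flag against overall survival. We use the
maximal chi-square method: every distinct observed density is a candidate
threshold `c`; patients split into low (`density < c`) and high
(`density >= c`); each admissible split is scored by the two-sample log-rank
chi-square, computed from first principles as the squared sum of
hypergeometric observed-minus-expected event counts over distinct event
times divided by the summed hypergeometric variances; the candidate with
the maximal statistic wins.

Several details of this scan are genuinely open choices; the package fixes
them as follows.

* **Tie side.** A density exactly at the threshold is classified *high*,
  globally, for both the maxstat and the median rules. Some convention is
  needed so that a median-valued patient has a determinate flag.
* **Tie-break among equal maxima.** The smallest cutoff wins. This makes
  the scan deterministic; any rule on the maximizing set would be
  statistically equivalent.
* **Candidate grid.** Distinct observed values only — the scan is an
  exhaustive empirical search, with no interpolation between order
  statistics.
* **Minimum arm size.** Splits leaving either arm below 10% of the sample
  (`min_group_fraction = 0.10`, configurable) are inadmissible. Maximally
  selected statistics are notoriously unstable at extreme splits; without a
  constraint the scan can select a threshold isolating a handful of
  patients.
* **Multiplicity.** The maximal statistic is *selected*, so it is not
  chi-square distributed under the null and its nominal p-value is
  anti-conservative. The package reports the raw maximal statistic and, when
  asked, a permutation p-value (`maxstat_permutation_p()`) that recomputes
  the full scan under label permutations. No asymptotic corrections for
  maximally selected statistics are implemented.

A median cutoff (`median_cutoff()`, mean of the central order statistics for
even n) is available as the transparent alternative; both methods flow
through the same `build_cutoff_table()` surface, which computes each
(marker, region) cell on exactly the patients with a surviving core for that
cell and skips cells with fewer than 10 evaluable observations.

## Scoring and missing cores

Tissue-microarray cores get lost. Missingness is tracked per
(patient, marker, region), and a lost core voids *all* markers of that
region — the reader marks the whole region missing when its rows are absent.
Composite scores require every component: a patient lacking a DM core still
receives an IS and IS-ma but no IS-M. Not-evaluable is a value, not an
error, and evaluability propagates per model independently.

Classification summaries (`score_distribution()`) report per-category counts
and low/high percentages against the number of patients evaluable *for that
model*, rounded half-up to one decimal — the convention of clinical
cohort tables.

## Survival analysis

Kaplan–Meier estimation, the k-group log-rank test, and Cox regression are
delegated to the `survival` package behind thin, typed wrappers. Choices
that were open:

* **Ties.** Cox fits use the Efron approximation. Follow-up is recorded at
  month resolution, so ties are ubiquitous and Breslow would be visibly
  biased toward zero.
* **Intervals.** Hazard-ratio CIs are Wald intervals on the log scale.
* **Reference levels.** Fits are parameterized to match conventional
  reporting: T4 vs T1–3, N1–2 vs N0, synchronous vs metachronous,
  invasion present vs absent, and score *low vs high* — the high
  (favorable) class is the reference, so a hazard ratio above 1 means low
  scores do worse.
* **Age.** The default multivariate fits dichotomize age at 65 years;
  a continuous parameterization is available (`age_term = "continuous"`).
  Both are legitimate and they answer slightly different questions; the
  binary form matches how the other covariates enter.
* **Multivariate sets.** Each score model is adjusted, in its own fit, for
  age, pT, pN, metastasis timing, and lymphatic and perineural invasion.
  One score model per fit: the three models share four components and are
  strongly collinear.

The internal first-principles log-rank routine (`logrank_chisq2()`) that
powers the cutpoint scan doubles as an independent cross-check: on tie-free
data the Cox score test at coefficient zero must equal the log-rank
chi-square, and the test suite verifies this identity to 1e-6.

## Regional heterogeneity

`paired_region_test()` compares a marker's density between two regions
within patients, using complete pairs only. The paired t-test is the
default, with the Wilcoxon signed-rank test as the rank-based alternative;
quartiles everywhere use linear interpolation between order statistics
(type 7). Identical paired vectors return statistic 0 and p = 1 by
convention. By-organ summaries of the metastatic lesion require at least 3
patients per site; sparser sites are flagged rather than dropped.
`core_concordance()` gives the Pearson correlation between duplicated cores
of the same region, the standard check that single-core sampling is
representative.

## The synthetic cohort generator

No patient-level data ship with the package; `generate_cohort()` produces
cohorts with the statistical structure the analysis assumes, so every stage
is testable.

* **Densities** are log-normal per (marker, region), with `meanlog` set to
  the log of the reference median and `sdlog` solved from the reference IQR
  via the normal quartile spread (`(log q3 − log q1) / (2 Φ⁻¹(0.75))`);
  the anchors are the published-scale summaries in
  `crc_density_reference()`. Within a marker, the three regions share a
  Gaussian copula with exchangeable correlation 0.3 — a modelling choice:
  duplicated-core studies suggest within-region correlations near 0.5–0.7
  and weak CT–IM coupling, and 0.3 is a deliberately moderate middle value.
* **Metastatic organs** are drawn from a fixed mix (liver-dominant), and DM
  densities are scaled by per-organ multipliers (lymphocytes enriched in
  non-regional lymph nodes, FOXP3 in lung, everything lowest in ovary). The
  multipliers are normalized to mixture-weighted geometric mean 1 so the
  marginal DM medians stay on their anchors.
* **Survival** follows a proportional-hazards model with Weibull(1.1,
  scale 60 months) baseline. The linear predictor sums a log hazard ratio
  of log(1.45) for each unfavorable lymphocyte component (CD3/CD8 low in
  CT, IM, DM) and 0 for the CD163 components — a positive IS-M effect and a
  null macrophage-specific effect. *True* component states are defined
  against the generating marginal median, not against any estimated cutoff,
  so cutpoint recovery is a genuine inference task. Follow-up is censored
  administratively at 104.6 months with 20% uniform dropout and rounded to
  0.1 months, yielding roughly 70% events and a median follow-up near 40
  months.
* **Missing cores** are masked region-wise in disjoint patients at rates
  3/196 (one primary region, CT or IM at random) and 5/196 (DM), so the
  default 196-patient cohort has exactly 193 patients evaluable for IS and
  IS-ma and 188 for IS-M.
* **Clinical covariates** are drawn at realistic prevalences (e.g. 39% pT4,
  81% node-positive, 66% synchronous, 54% KRAS-mutant) with modest hazard
  effects (age ≥ 65, stage, timing, invasion), all centered in the linear
  predictor so the baseline remains the median patient.

Everything is reproducible: generation runs in a private RNG stream
(Mersenne-Twister, inversion) seeded by the config and restores the
caller's RNG state.

### What the generator does and does not emulate

It reproduces right-skewed marginals, region and organ heterogeneity,
region-level core loss, proportional hazards with realistic censoring, and
the availability counts. It does **not** emulate: spatial structure within
a slide, measurement error of the image algorithms, informative missingness
(cores are lost completely at random), non-proportional hazards, or
correlation *between* markers. Passing tests therefore demonstrate that the
pipeline correctly recovers structure of this idealized kind — not that the
scores are prognostic in any particular real cohort.

One consequence is worth flagging. With heavy-tailed log-normal margins and
correlation 0.3, the raw-scale paired t-test has little power for the
moderate CT-vs-IM shift in CD3 (the between-patient spread dwarfs the
median difference), even at n = 196, although rank tests do better. The
heterogeneity checks in the test suite therefore use the several-fold
CT-vs-DM contrast, where both tests detect the shift reliably. Detecting a
CT-vs-IM-sized shift on raw densities requires either stronger within-patient
coupling or a log-scale/rank test.

## Verification strategy and problem sizes

The test suite checks each layer against an independent route:

* the maxstat scan against an exhaustive per-candidate `survdiff` scan,
  exactly, on 200 random small instances (n ≤ 50);
* threshold recovery on 200 simulated samples (n = 400, hazard ratio 4
  above a threshold of 200): the scan must land within ±25% of the truth in
  at least 95% of seeds;
* Cox recovery of a twofold hazard at n = 2000 with ~20% censoring, and the
  score-test/log-rank identity on tie-free fixtures;
* the product-limit estimator against its exponential closed form at
  n = 5000;
* generator fidelity at n = 10000 (medians within 5% of their anchors) and
  the exact 193/188 availability counts at n = 196;
* end-to-end: across 100 simulated 196-patient cohorts, the multivariate
  IS-M term is significant at p < 0.05 in at least 90% of seeds.

These sizes were chosen so each check is decisive yet the whole suite runs
in about a minute.

## Known limitations

No proportional-hazards diagnostics, time-varying covariates, or
competing-risks machinery (censoring of non-disease deaths is taken as
given). No correction for the multiplicity of the maximal statistic beyond
the permutation option. Percentile-based or CD45RO-based score variants are
out of scope. Cutoffs estimated by the maximal chi-square method are
cohort-dependent and should not be transported between cohorts without
revalidation — the package deliberately recomputes them per dataset.
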