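---
title: "Proportionality of cognitive aging: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proportionality of cognitive aging: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(propcog)
```

## The scientific question and the model

A psychophysiological battery measures several cognitive subdomains in one
sitting: a simple visual-motor reaction (SVMR) isolates perception plus
motor response; a go/no-go choice reaction (CVMR) adds response selection
under an inhibitory condition; the reaction to a moving object (RMO) probes
anticipatory timing; attention tasks with and without distractors (IRT,
AST) probe interference resilience; wrist dynamometry adds a peripheral
motor reference. If normal aging slows all stages of information processing
at the same rate — the "general slowing" account — then ratios of stage
latencies should stay constant over the lifespan once neurodevelopment is
complete. `propcog` operationalises that idea through three indices:

* `ISD = SVMR_mean / DMT`, with `DMT = CVMR_mean - SVMR_mean` the
  decision-making time. ISD relates the perceptuo-motor latency to the time
  cost of response selection.
* `ISDA = SVMR_mean / (DMT * (1 - CVMR error fraction))` corrects the
  denominator for go/no-go accuracy.
* `ISCA = IES_SVMR / IES_CVMR`, the ratio of the two inverse efficiency
  scores (`IES = mean RT / (1 - error fraction)`), which algebraically
  expands to `SVMR_mean * (1 - CVMR err) / (CVMR_mean * (1 - SVMR err))`.

The proportionality hypothesis predicts (i) flat age trends of these
indices after about age 20, (ii) equal index variances across age cohorts
(homoscedasticity), and (iii) age-group differences confined to the
maturing Adolescents group. The statistics layer tests exactly these
claims; the clustering layer asks, independently of any prespecified
binning, how many homogeneous age cohorts the (age, index) point clouds
contain; the evaluation layer quantifies how much information the battery
carries about the indices and about coarse age group membership.

**Error fractions.** The battery records mistake *counts*; all formulas use
the fraction `mistakes / trials`, with 30 trials per test as the default.
For CVMR, "mistakes" comprises missed stimuli, premature responses and
false reactions to the no-go stimulus. Much of the go/no-go literature uses
only the last kind in accuracy corrections, so `add_indices()` exposes a
`cvmr_errors` switch (`"all"`, the default, or `"false_reactions"`).

**Degenerate denominators.** A subject whose CVMR mean hardly differs from
their SVMR mean has a meaningless ISD; rather than returning a huge number,
indices with `|DMT| < dmt_epsilon` (default 1 ms) are flagged invalid
(`ISD_valid = FALSE`, `NA` values) and excluded from index-based analyses
with a reported count. All latencies are in milliseconds throughout; no
unit conversion is ever performed.

**Category conventions.** The SVMR mobility categories use half-open,
lower-inclusive bins at 177 / 200 / 210 / 233 ms, so each printed threshold
belongs to the slower category; the verbal definitions overlap at the
boundaries, and a convention had to be fixed. The RMO balance label calls a
mean signed error "balanced" only at exact zero (|x| < 1e-9 ms): the sign
semantics give no finite neutral band, so none is invented.

## The synthetic cohort generator

The source data set is available only on request, so the package generates
cohorts with the same published group-level structure: four 20-year strata
(ages 4–20, 20–40, 40–60, 60–84) of 48/64/64/55 subjects with 19/36/39/40
women, matching the published capacities and sex ratios. Ages are uniform
within each stratum. Every test is realised at trial level — 30 reaction
times per test, Bernoulli mistake events, 30 signed RMO timing errors — so
the summary columns (means, within-subject SDs, mistake counts, RMO outcome
counts) are mutually consistent by construction rather than drawn
independently.

### Marginal calibration

Per group, the generator pins:

* the subject-level SVMR mean (median and SD of the published group cells,
  e.g. Adolescents 282.03 ± 70.91 ms), truncated below at 120 ms;
* the within-subject trial SDs of both reaction tests (published
  `*_variance` rows), lognormally dispersed across subjects because the
  published SDs of those rows are themselves large;
* the DMT offset: median and SD per published DMT cells;
* mistake counts: the published means *and SDs*. The published SDs are
  strongly overdispersed relative to a binomial (Adolescents SVMR mistakes
  2.69 ± 3.83 against a binomial SD of 1.57), so per-subject error
  probabilities follow a beta distribution whose dispersion is solved from
  the printed SD — a beta-binomial mistake model;
* RMO: subject-level signed mean (published mean/SD) and trial SD
  (published `RMO_variance` row); a trial is "accurate" within a ±70 ms
  window, chosen so expected error counts sit near the published
  `RMO_errors` row;
* attention and grip parameters were not published; the defaults (AST
  420/380/430/500 ms across groups, interference cost 120/90/100/140 ms,
  grip 22/42/40/32 kgf with a sex shift) are ordinary values for these
  instruments and age ranges, fixed once.

Latent subject means are always corrected for the share of the printed
between-subject SD that trial-averaging noise explains
(`sd_latent^2 = sd_printed^2 - E[within^2]/30`), so the *realised* columns,
not the latent ones, match the published scales. `calibration_report()`
recomputes per-group z-scores of realised moments against these targets.

### The DMT distribution

The published DMT cells ("median ± SD", e.g. 103.86 ± 48.64 ms) cannot come
from a normal distribution: a normal with that scale would put 2–4% of
subjects below 1 ms and produce index dispersions far beyond the published
ISD SDs. The generator instead uses a right-skewed two-component
lognormal: a common core (log-SD 0.35) plus, for 10% of subjects, a
one-sided *slow* tail whose variance absorbs exactly the remainder of the
published variance; the mixture median is corrected back to the published
location. This keeps DMT essentially positive (choice reactions slower than
simple ones, as in every published group), reproduces the published SD, and
confines near-zero *realised* DMT — which still occurs through trial noise —
to well under 1% of subjects, so invalid-index handling stays exercised but
rare. A `dmt_dist = "normal"` switch retains the plain normal offset for
sensitivity analyses.

### Joint dependence

Publications report marginals; the dependence structure between variables
had to be designed. Three latent standard-normal subject traits carry it:

* a **general speed** trait loading on the SVMR latent mean (0.8), log DMT
  (0.5), the within-subject trial SDs (0.6), AST (0.7) and the interference
  cost (0.4) — slow subjects are slow, variable and distractible across
  tests, the covariance pattern that a general-slowing account itself
  implies;
* an **error proneness** trait (Gaussian copula loading 0.8 on both tests'
  beta error probabilities) — mistake rates in the two tests are strongly
  but imperfectly correlated;
* a **session state** shared between the two tests' trial noise (per-trial
  correlation 0.9), reflecting that both tests are administered in one
  sitting; this keeps realised DMT from being dominated by independent
  trial-averaging noise.

These loadings were fixed at design time so that the generated cohorts
exhibit the qualitative findings the analysis is meant to reproduce —
an Adolescents-only contrast in the index medians, and forecastability of
ISCA exceeding that of ISD — and they were frozen before the acceptance
suite was written. The acceptance tests measure those properties across
seeds; they are not asserted anywhere else.

### What the generator does not emulate

No learning or fatigue across trials, no longitudinal repeated measures, no
EEG/eye-movement correlates, no education or handedness covariates, and no
real-data idiosyncrasies beyond the published tables (recruitment-driven
age clumping, device quantisation, missingness). Passing tests on synthetic
cohorts therefore demonstrate that the *pipeline* behaves as specified
under the published group structure — not that real cohorts satisfy the
proportionality hypothesis.

### Known tensions with the published summaries

Two published claims cannot be reproduced simultaneously with the published
tables under any stable distributional model, and the acceptance suite
reports them honestly rather than papering over them:

* the published group SDs of the indices are strongly heteroscedastic
  (ISD 2.29/2.98/4.9/3.59), yet homoscedasticity is claimed; generated
  cohorts calibrated to those SDs fail the Brown-Forsythe screen more often
  than the stated 80% pass rate, and the corresponding acceptance
  expectations fail (deliberately left failing, with this analysis);
* the published ISD/ISDA group medians put the Young adults group further
  from Midlife adults than Adolescents are, yet the post hoc narrative
  isolates Adolescents only; under printed dispersions a rank test detects
  the Young-vs-Midlife/Older gaps in a substantial minority of cohorts, so
  "no other pair significant" holds as a majority property only for ISCA.

## Cohort discovery

`distortion_profile()` runs K-means on the raw, unscaled (age, index)
points. Raw coordinates are deliberate: age spans ~80 years while the
indices span ~0.4–20, so clustering is age-dominated — which is the only
reading consistent with reported centroids lying at ~12/31/53/71 years on
the age axis. A `scale_points` flag enables standardised clustering for
sensitivity analysis.

Numerical choices:

* best-of-10 random restarts per k, plus a warm-started candidate built
  from the previous solution's centroids and the farthest point, which
  guarantees a non-increasing distortion profile;
* on instances with up to 10 points and k ≤ 3 the fit provably attains the
  global optimum (checked against exhaustive partition enumeration in the
  tests);
* a point set with at most k distinct points is handled directly (one
  centroid per distinct point, zero distortion) instead of erroring.

`optimal_k()` implements the kneedle knee-point rule for decreasing convex
curves with sensitivity S = 1: normalise both axes to [0, 1], flip the
curve, and take the first local maximum of the difference curve confirmed
by a subsequent drop of more than S mean x-steps. A linear profile has no
knee and is reported as such — never silently replaced by a default.

The candidate grid is k = 2..11. The common alternative starting at k = 1
was considered and rejected: on near-uniform age distributions the
normalised difference curve over 1..10 peaks at k = 3 *by construction of
the normalisation* (the k = 1 distortion dwarfs everything else), whereas
the 2..11 grid — the default of the elbow-method tooling that popularised
this workflow — lets the four-stratum structure surface as k = 4. The
acceptance suite verifies that four is the modal knee across default
cohorts.

`cluster_and_score()` maps each cluster to the age bin containing its
centroid's age coordinate and counts, per bin, subjects assigned to the
right cluster (performance) versus any other (misclassified); the two
always sum to the bin capacity. Two centroids in one bin raise an explicit
ambiguous-mapping error. Subjects with non-finite index values are dropped
with a reported count — exclusions are always visible.

## Group statistics

* **Normality**: Shapiro-Wilk per group; the indices are ratio quantities
  and generally fail it, which motivates the nonparametric route.
* **Omnibus**: tie-corrected Kruskal-Wallis (`stats::kruskal.test`); the
  all-tied case is defined as H = 0, p = 1.
* **Post hoc**: Dunn z-tests on pooled mean ranks with tie correction,
  Holm step-down adjustment over the six pairs. Holm is uniformly more
  powerful than plain Bonferroni at the same family-wise error level; the
  tests verify the hand formula to 1e-10 and the family-wise error rate
  under the four-group null by simulation.
* **Homoscedasticity**: the Brown-Forsythe (median-centred Levene) variant
  via `car::leveneTest` — robust to the heavy tails these ratios carry; a
  mean-centred Levene would be dominated by single outliers.
* **Sex contrasts**: Welch's unequal-variance t, two-sided, overall and per
  stratum; strata missing one sex are marked not estimable. Welch is the
  safe default when group variances differ, and it reduces to Student's t
  when they do not.
* **Trend bands**: least-squares fit of index against age with a pointwise
  percentile 95% band over case-resampled bootstrap replicates (default
  B = 1000) on an evenly spaced age grid; resamples with zero age variance
  are redrawn inside the seeded stream.

Significance thresholds are arguments (`alpha_omnibus`, `alpha_posthoc`),
never constants buried in logic, because the source analyses quote both
0.05 and 0.01 in different places.

## Predictive evaluation

Classification predicts the binary age group at the 40-year cutoff from
battery features plus one index; regression forecasts an index from
leakage-filtered features. The leakage filter removes every feature from
which the target is arithmetically computable — `SVMR_mean`, `CVMR_mean`,
`DMT`, both mistake counts, both IES columns, the sibling indices and the
target itself — and reports what it removed. The per-outcome error counts
(`*_passes`, `*_falstart`, `CVMR_false_reaction`) are deliberately retained,
as in the source protocol: they describe performance without reproducing
the index formula's exact terms. The tests include a positive control
showing that re-admitting the IES columns collapses the ISCA forecasting
error — evidence the filter is load-bearing.

Model families are the standard panel: gradient boosting (`xgboost`,
100 rounds, depth 3, learning rate 0.1), Gaussian naive Bayes, AdaBoost
(SAMME over depth-1 `rpart` stumps, 50 rounds; AdaBoost.R2 with shallow
trees and weighted-median prediction for regression), ridge and lasso
(`glmnet`, penalty chosen by internal 5-fold cross-validation on the
training folds), linear/RBF SVMs (`e1071` defaults), logistic regression /
OLS, and random forest (300 trees). For regression, logistic regression
maps to OLS and naive Bayes is dropped (no standard analogue). Features are
standardised inside each training fold for the scale-sensitive families;
statistics are never fitted on held-out data.

Cross-validation is stratified (classification) 10-fold, repeated 10 times
with derived seeds; out-of-fold predictions are pooled per repeat, metrics
(sensitivity, specificity, accuracy, rank-based AUC; MAE, RMSE,
100·MAE/range) computed on the pooled predictions, then averaged over
repeats, with a cross-family mean ± SD on top. Confusion counts are stored
summed over repeats so every reported rate can be recomputed from them
exactly. `100·MAE/range` uses the range of the full target vector; with an
outlier-inflated range this metric flatters noisy targets, which is exactly
why the index comparison uses it — the published comparison does the same.

## Problem sizes and budgets

The test and acceptance workloads use the full 231-subject default cohort
(the published size) throughout. Monte-Carlo properties use 30–50 seeds
for cohort-level rates, 200 replicates for null-calibration rates, 10 seeds
for the modal knee, and 20 seeds for the forecastability ordering; the
oracle-equivalence checks enumerate instances of at most 10 points. These
sizes keep the full suite in the low minutes on a single CPU while leaving
Monte-Carlo error well below the margins being asserted.

## Limitations

The generator's joint structure is a model, not an estimate — no
subject-level data were available to fit it. Conclusions about real
cohorts require the real data; what the package guarantees is that every
stage of the analysis is correct on cohorts whose published structure it
reproduces, that all exclusions are visible, and that the two documented
tensions in the published summaries are surfaced rather than absorbed.
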