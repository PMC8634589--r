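# propcog

Cross-sectional studies of cognitive aging ask whether distinct cognitive
functions — information processing speed, response selection, inhibitory
control — decline *proportionally* across the lifespan, or whether some
decline faster than others. `propcog` implements a complete analysis
pipeline for visual-motor reaction-time batteries recorded in the POBA
(Psychophysiological Outcomes of Brain Atrophy) column dialect, aimed at
researchers in psychophysiology and epidemiological modelling who work with
such batteries.

## The quantities at its core

For each subject the battery yields a simple visual-motor reaction (SVMR), a
go/no-go choice reaction (CVMR), a reaction to a moving object (RMO),
attention tasks without/with distractors (AST / IRT), and wrist dynamometry
(WDR/WDL). From these the package derives:

- **DMT** = CVMR_mean − SVMR_mean, the decision-making time (time cost of
  response selection, ms);
- **IES** = mean RT / (1 − error fraction), the inverse efficiency score
  combining speed and accuracy;
- the proportionality indices
  **ISD** = SVMR_mean / DMT,
  **ISDA** = SVMR_mean / (DMT · (1 − CVMR error fraction)), and
  **ISCA** = IES_SVMR / IES_CVMR
  = SVMR_mean · (1 − CVMR err) / (CVMR_mean · (1 − SVMR err));
- **TRVI** = IRT_mean − AST_mean (attention interference cost) and
  **AC** = WDR_MMS / WDL_MMS (grip asymmetry).

If cognitive subdomains decline at the same pace, the indices should stay
flat over age after maturation, with equal variance across age cohorts.

The pipeline then (1) discovers age cohorts without supervision — K-means on
raw (age, index) points, distortion-score profile over a k grid, kneedle
knee-point selection of k — and scores clusters against the 20-year age
bins; (2) tests proportionality with nonparametric statistics
(Kruskal-Wallis omnibus, Dunn post hoc with Holm step-down, Brown-Forsythe
homoscedasticity, Welch sex contrasts, bootstrap trend bands); and
(3) evaluates the indices' informative value with repeated stratified
cross-validation over a panel of standard model families (classification of
the over/under-40 age group; leakage-filtered regression forecasting of each
index).

The study cohort itself is available only on request, so the package ships a
**calibrated synthetic cohort generator**: 231 subjects in four 20-year
strata (48/64/64/55; 134 women, 97 men; ages 4–83) whose group-level
locations, scales and mistake-count dispersions match the published
summaries. See the methods vignette (`vignettes/proportional-cognitive-aging.Rmd`)
for the generator's latent-trait structure and every calibration decision.

## Worked example

```r
library(propcog)

# one subject's battery -> derived indices
b <- subject_battery(
  svmr = svmr_result(30, mean_rt = 265, rt_sd = 52, passes = 2, falstarts = 1),
  cvmr = cvmr_result(30, mean_rt = 372, rt_sd = 88, passes = 1, falstarts = 1,
                     false_reactions = 2),
  age = 47, sex = "F")
derive_indices(b)
#> <derived_indices> DMT=107.00 ISD=2.477 ISDA=2.858 ISCA=0.686 valid=TRUE

# a full synthetic cohort and the proportionality analysis
coh <- sample_cohort(default_config(seed = 1))
coh
#> <poba_cohort> 231 subjects in 4 groups (seed 1); 0 invalid ISD

group_comparison(coh$table, "ISCA")
#> <group_comparison> ISCA  (KW H=33.54 p=2.48e-07; Levene W=1.80 p=0.148)
#>          group  n    median      mean         sd   shapiro_p
#>    Adolescents 48 0.7486575 0.7689293 0.15330756 0.000712809
#>  MidlifeAdults 64 0.6991292 0.6766593 0.10780502 0.169481564
#>    OlderAdults 55 0.6871600 0.6761302 0.09716518 0.784561511
#>    YoungAdults 64 0.6419461 0.6215242 0.09944202 0.019172784
#> groups differing from all others: Adolescents, YoungAdults

# unsupervised cohort discovery on (age, ISCA)
ok <- is.finite(coh$table$ISCA)
prof <- distortion_profile(cbind(coh$table$age[ok], coh$table$ISCA[ok]), seed = 1)
optimal_k(prof)
#> <knee_point> k = 4

cluster_and_score(coh$table, "ISCA", k = 4, seed = 1)
#> <clustering_summary> ISCA, k=4 (0 subjects dropped)
#>               centroid_age performance misclassified
#> Adolescents          13.79          48             0
#> YoungAdults          32.59          58             6
#> MidlifeAdults        53.49          55             9
#> OlderAdults          73.70          41            14
```

Reading the output: the subject's choice reaction cost 107 ms of
decision-making time on top of a 265 ms simple reaction; the ISCA of 0.686
says their speed-accuracy efficiency in the simple task is about 69% of
that in the go/no-go task. At cohort level, the Kruskal-Wallis test rejects
equality of the four age-group ISCA medians, the Dunn post hoc isolates the
Adolescents group (highest median, 0.749), and the Brown-Forsythe test
finds no evidence of heteroscedasticity (p = 0.148) — the proportionality
pattern. The knee of the distortion profile selects four clusters, whose
centroids sit near the centres of the four 20-year age bins.

`run_pipeline(pipeline_config())` chains all stages and writes the cohort
CSV, report tables and a content-hashed manifest to a directory.

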