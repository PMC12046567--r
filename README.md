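# sleepart

Sleep-health trajectories across cognitive-aging pathways.

## The problem

In longitudinal aging cohorts, older adults follow qualitatively different
cognitive trajectories: most age without persistent impairment ("normal"),
some progress to stable mild cognitive impairment (MCI) without dementia, and
some progress to dementia. How the **amount**, **regularity**, and **timing**
("ART") of sleep change along each of these pathways — and when those changes
begin relative to diagnosis — is hard to study because it requires
multi-modal sleep measurement (self-report, wrist actigraphy, rest–activity
rhythms) repeated over many years, plus a model flexible enough to let
trajectories bend smoothly around each person's own diagnosis ages.

`sleepart` implements that full analysis pipeline for researchers in sleep
epidemiology and cognitive aging, and — because the cohort data such studies
use are typically restricted-access — ships a seeded synthetic-cohort
generator so that every stage is testable against known ground truth.

## What the package computes

**Actigraphy preprocessing** (`flag_nonwear`, `downsample_to_60s`,
`detect_sleep_intervals`, `count_valid_days`): zero-count runs > 4 h mark
device nonwear and exclude the surrounding 24 h; 15 s epochs are low-pass
filtered (65-tap Hamming FIR, cutoff at the new Nyquist) and decimated to
60 s; the principal nightly rest interval per noon-to-noon day is found by an
adaptive log-count threshold (2-means split) with morphological smoothing and
an 18 h validity cap; sessions need ≥ 5 valid days to enter the analytic
samples.

**Rest–activity rhythm features** (`fit_extended_cosine`,
`interdaily_stability`, `intradaily_variability`, `rest_interval_summaries`,
`self_report_midpoint`): the extended (sigmoidally transformed) cosine model

    y(t) = min + amp · F( cos(2π(t − φ)/24) ),   F(c) = 1 / (1 + e^{−β(c−α)})

yields *alpha* (relative rest duration) and *acrophase* φ (clock time of peak
activity); the nonparametric statistics are

    IS = N Σ_h (x̄_h − x̄)² / (24 Σ_i (x_i − x̄)²)        (interdaily stability, [0,1])
    IV = N Σ_{i≥2} (x_i − x_{i−1})² / ((N−1) Σ_i (x_i − x̄)²)   (intradaily variability)

on hourly mean counts; sleep timing features are circular summaries of the
nightly rest-interval midpoints.

**Pathway assignment** (`assign_pathway`): dementia if any dementia
diagnosis; stable MCI if two consecutive annual visits are both MCI (single
MCI years often revert, so one is not enough); normal otherwise. Onset ages
are read off the visit grid.

**Trajectory model** (`build_design`, `fit_mixed_spline`,
`backward_eliminate`, `predict_typical`): a weighted linear mixed-effects
model with cubic polynomial age terms, pathway main effects and age×pathway
interactions, and one truncated-cubic knot per diagnosis event at the
subject's *own* onset age — `((age − k)₊)³` — so each fitted trajectory is
C²-smooth while still bending around diagnosis. Random intercept and age
slope per subject (unstructured covariance, REML); residual variance divided
by the observation weight (valid actigraphy days). Backward elimination
drops non-significant higher-order terms one at a time under a strict
hierarchy.

**Contrasts** (`within_pathway_change`, `between_pathway_difference`,
`run_benchmark_grid`, `adjust_bh`, `label_effect_size`): standardized
contrasts d = (difference in typical-participant predictions) / σ_std with
σ_std = √(intercept variance + residual variance), evaluated on benchmark-age
grids (primary {82, 86, 90, 94} plus four sensitivity sets) under assumed
diagnosis schedules, Benjamini–Hochberg-adjusted within each (aim, domain)
family, and labeled very small / small / moderate / large at |d| = 0.2 / 0.5
/ 0.8.

## Worked example

Simulate one actigraphy session and extract its features:

```r
library(sleepart)
s <- simulate_epoch_actigraphy(actigraphy_sim_params(days = 8), seed = 1)
extract_session_features(s)
#>   alpha    IS    IV acrophase rest_length_h rest_midpoint_h log_midpoint_sd
#> 1 0.173 0.998 0.122     14.01        10.058           2.471           -1.73
```

The simulated rhythm peaked at 14:00 (acrophase 14.01), was highly stable
day to day (IS 0.998) with little fragmentation (IV 0.122), and the detected
nightly rest interval averaged 10.1 h centered at 02:28.

Simulate a 300-subject cohort whose dementia pathway loses 0.9 standardized
units of the outcome between ages 82 and 94 (and nothing on the other
pathways), then recover that change end to end:

```r
coh <- generate_cohort(sim_config(n_subjects = 300, seed = 1))
dat <- merge(coh$visits, coh$truth, by = "subject"); dat$outcome <- 0
beta <- setNames(rep(0, 14), colnames(build_design(dat)$X))
beta["(Intercept)"] <- 7
beta["knot_dem"] <- -0.9 / 64          # -0.9 SD from ages 82 to 94
tp  <- trajectory_params(beta, re_cov = diag(c(0.5, 0)), sigma2 = 0.5)
out <- simulate_feature_outcomes(coh, tp, seed = 2, covariates = character(0))

des <- build_design(out)
fit <- backward_eliminate(fit_mixed_spline(des), des)
g <- run_benchmark_grid(list(tst = fit), sets = benchmark_sets()["primary"],
                        domains = c(tst = "amount"))
g[g$aim == "within", c("pathway", "d", "ci_lo", "ci_hi", "p_adj", "label")]
#>    pathway      d  ci_lo  ci_hi p_adj      label
#>     normal  0.000  0.000  0.000     1 very small
#>  stableMCI  0.000  0.000  0.000     1 very small
#>   dementia -0.901 -0.945 -0.856     0      large
```

The estimated within-dementia change (d = −0.901, large) matches the
injected −0.9; the flat pathways are correctly reported as zero after
backward elimination.

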