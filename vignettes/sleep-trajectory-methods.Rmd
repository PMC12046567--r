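---
title: "Methods: modeling sleep-health trajectories across cognitive-aging pathways"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modeling sleep-health trajectories across cognitive-aging pathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepart)
```

# Overview

`sleepart` estimates how the amount, regularity, and timing of sleep change
with age along three cognitive-aging pathways — normal aging, stable mild
cognitive impairment (MCI), and progression to dementia — from three kinds of
longitudinal input: epoch-level wrist-actigraphy counts, annual cognitive
diagnoses, and self-reported sleep items. This vignette documents the models,
the tunable parameters, the numerical choices, and what the synthetic-data
generator does and does not emulate.

# Actigraphy preprocessing

**Nonwear.** Wrist devices record exact zeros when removed. Every maximal run
of zero counts strictly longer than `threshold_h` (default 4 h) is treated as
nonwear, and the full `window_h` (default 24 h) window centered on the run's
midpoint is excluded, clipped to the recording. Whether the exclusion window
should be centered on the run's midpoint, its start, or the containing
calendar day is genuinely ambiguous in the source methods; we default to the
midpoint (symmetric, least sensitive to run length) and expose
`center = "start"` as an alternative. Counts are never modified — only the
exclusion mask — so masking decisions remain auditable.

**Downsampling.** Sleep detection operates on 60 s epochs, so 15 s series are
low-pass filtered and decimated 4:1. The filter is a 65-tap Hamming-windowed
FIR with cutoff at the new Nyquist frequency (1/120 Hz), normalized to exact
unit DC gain, applied as a zero-phase centered convolution with reflection
padding, followed by averaging each block of four filtered epochs. The tests
verify < 0.1% attenuation of a 24 h component and < 1% leakage of energy at
the old Nyquist. A 60 s epoch is excluded if any of its four source epochs
was excluded, the conservative direction.

**Rest-interval detection.** The cited detection literature specifies a
behavior class (automatic threshold plus artifact smoothing) rather than an
exact algorithm, so the detector here is fully specified and configurable:
per complete noon-to-noon day (so a night is never split), counts are
transformed as ln(count + 1), a 2-means split of the day's unmasked
log-counts gives two cluster centers whose midpoint is the rest threshold,
the binary rest classification is smoothed by morphological closing then
opening with a 30 min structuring element, and the longest rest bout is the
day's rest interval. Candidates longer than 18 h are discarded as invalid
(a device face-down on a table produces an "all-rest" day). The 2-means step
uses deterministic quantile-based initial centers so detection is a pure
function of its input. Days with a constant count profile short-circuit: all
zeros means rest throughout (removed by the 18 h cap); constant activity
means no detectable rest.

**Valid days.** A valid recording day is a complete noon-to-noon window with
at least `min_frac` (default 0.9) of epochs unmasked; a valid sleep day also
has a detected interval. Sessions need ≥ 5 valid recording days for the
rest-activity rhythm sample and ≥ 5 valid sleep days for the actigraphy sleep
sample. The 0.9 fraction is a design default (the source methods state only
the 5-day rules); it is configurable.

# Rest–activity rhythm features

The extended cosine model passes a 24 h cosine through an anti-logistic
transform:

$$y(t) = \mathrm{min} + \mathrm{amp}\cdot F\!\big(\cos(2\pi (t-\varphi)/24)\big),
\qquad F(c) = \frac{1}{1+e^{-\beta(c-\alpha)}}.$$

`min` (counts) is the trough level, `amp` (counts) the range, φ (clock hours)
the acrophase, α ∈ [−1, 1] the width parameter (higher α narrows the active
peak, i.e., more time at rest), and β > 0 the steepness of the rest–active
transition. Fitting is bounded Levenberg–Marquardt least squares on
`bin_min`-minute bin means (default 10 min — a speed/variance compromise; use
finer bins when exact recovery matters), multi-started over φ ∈ {0, 6, 12,
18} to avoid the period's local minima. Convergence is *full* with no active
bound, *partial* when α or β finishes on a bound (β ∈ (0, 50]), and *failed*
otherwise; shape parameters from failed fits are null because α and φ are
unidentifiable when the fitted amplitude degenerates (constant input).

Interdaily stability and intradaily variability use the standard
nonparametric formulas on hourly-binned unmasked means, with any trailing
partial day dropped so the length is a multiple of 24 (hourly bins are the
convention of the nonparametric rhythm literature; the bin width is not
restated per session). IS is in [0, 1] by construction. IV has nominal range
[0, 2] but is unbounded above (an alternating hourly sequence gives exactly
4), so out-of-nominal values are returned with a flag rather than capped —
capping would silently bias regularity trajectories.

Sleep-timing features are circular: the session midpoint is the circular
mean of nightly rest-interval midpoints, and the midpoint SD is computed on
deviations unwrapped to (−12, 12] h around that mean. The SD is reported as
ln(SD + ε) with ε = 1/120 h (30 s) so that a perfectly regular session is
finite; the offset choice matters only below the device's timing resolution.
Self-reported midpoint is the midpoint of the bed→wake arc taken forward in
time, undefined when bed = wake.

# Pathway assignment

Dementia dominates: any dementia diagnosis puts the subject on the dementia
pathway with onset at the first such visit. Otherwise two *consecutive* MCI
visits define stable MCI — a single MCI year reverts to normal cognition too
often to index stable impairment. "Consecutive" means adjacent visits at most
`gap_max_yr` = 1.5 years apart (annual visits with scheduling jitter); larger
gaps break consecutiveness. MCI onset is the age at the *first* visit of the
earliest qualifying pair (the moment stable impairment began; the
`onset_visit = "second"` convention is available). A lone MCI diagnosis at
the end of follow-up is classified normal by the literal rule but flagged
`censored_mci`, since follow-up ended before the rule could resolve.

# The trajectory model

For outcome $y_{ij}$ of subject $i$ at age $a_{ij}$ (centered at 82 years, a
typical median first-visit age, for numerical conditioning):

$$y_{ij} = \mathbf{x}_{ij}^\top\beta + b_{0i} + b_{1i}(a_{ij}-82) + \varepsilon_{ij},
\qquad \varepsilon_{ij} \sim N(0,\ \sigma^2 / w_{ij}),$$

where $\mathbf{x}$ contains 1, age, age², age³, pathway dummies (normal is
reference), all age×pathway interactions, one truncated cubic per diagnosis
event — $((a - k_{\mathrm{MCI}})_+)^3$ and $((a - k_{\mathrm{dem}})_+)^3$,
each evaluated at the subject's *own* onset age and identically zero for
subjects without that onset — and mean-centered covariates. $(b_{0i},
b_{1i})$ have an unstructured 2×2 covariance, fitted by REML (`lme4`).
Weights $w$ are the session's valid actigraphy days (1 for self-report
models) and are normalized to mean 1 internally, which makes the fit exactly
invariant to rescaling all weights.

A *single* truncated cubic per knot is deliberate: it makes every fitted
trajectory continuous with continuous first and second derivatives at the
knot, so diagnosis-related change accrues gradually instead of the elbow a
linear spline would produce. Adding lower-order truncated terms would break
that smoothness, which is why they are not offered.

Degenerate inputs are handled explicitly: when the data are perfectly
interpolated (zero residual variance, as in noise-free validation runs) the
mixed model is unidentified and the weighted-least-squares solution is
returned with zero variance components and a boundary flag; the same
fallback catches optimizer failure.

**Backward elimination.** Per-term p-values are Wald t with residual degrees
of freedom $n - \mathrm{rank}(X)$ (the default behavior class of the
software family used for such models; with thousands of observations the df
choice is immaterial). The single eligible term with the largest p ≥ 0.05 is
removed and the model refitted, until all eligible terms are significant.
Eligible terms are only the highest-order age×pathway interaction per
pathway, the highest-order age main effect *provided no interaction of equal
or higher order remains*, and the knot terms; pathway main effects, the
intercept, and covariates are never removed. This preserves the marginality
hierarchy throughout.

**Typical-participant predictions.** Covariates are mean-centered in the
design, so the prediction at the covariate reference profile (average
covariate levels, proportion-weighted for binary covariates) is simply the
prediction with covariate columns at zero. Knot terms are evaluated at a
benchmark schedule rather than subject-specific onsets.

# Benchmark contrasts

A benchmark set is four increasing ages with assumed schedules: normal has
no knots; stable MCI has MCI onset at the second age; dementia has MCI onset
at the second and dementia onset at the third. The primary set is
{82, 86, 90, 94} with sensitivity sets {80, 84, 88, 92}, {84, 88, 92, 96},
{82, 85, 88, 91}, and {80, 86, 90, 94}. Segment changes start 0.1 yr after
each interior boundary (ages 82–86, 86.1–90, 90.1–94 on the primary set).

The standardized contrast is $d = \mathbf{c}^\top\hat\beta / \sigma_{std}$
with a Wald CI from $\sqrt{\mathbf{c}^\top \hat V \mathbf{c}}$, treating the
standardizer as fixed. The source methods never state the denominator of d;
we default to $\sigma_{std} = \sqrt{\hat\sigma^2_{int} + \hat\sigma^2}$ —
the model-based SD of a single observation for an average-age subject, the
common convention for mixed-model standardized effects — and expose the
residual-only alternative. Between-pathway differences evaluate each pathway
under its own schedule at one age and are exactly antisymmetric; abutting
within-pathway segments sum exactly to the overall change because d is
linear in the predictions.

Multiplicity control is Benjamini–Hochberg within each (benchmark set, aim,
domain) family, where the aims are the overall within-pathway changes, the
segment changes, and the between-pathway differences at the first and last
ages, and the domains are amount / regularity / timing. The named procedure
is BH, i.e., FDR control per family (not FWER), and each benchmark set is
its own analysis.

# The synthetic cohort generator

The generator produces the study's input structure with known truth at two
fidelity levels.

**Feature level** (`generate_cohort` + `simulate_feature_outcomes`): pathway
mixture (0.590, 0.134, 0.276), entry ages ~ N(81.2, 7.12²) truncated at 65,
annual visits with ±0.1 yr jitter truncated by a 0.12 per-visit dropout
hazard (mean ≈ 5–6 visits, capped at 10), MCI onset ~ N(85.7, 6.05²) and
dementia onset ~ N(88.2, 6.70²) rounded to the realized visit grid, transient
single-year MCI diagnoses sprinkled at rate 0.08 without ever forming a
consecutive pair, and about half of dementia-path subjects passing through a
recorded stable-MCI phase when follow-up allows. These defaults are the
marginal summaries of the cohort structure the pipeline targets and are
fixed; outcomes are then drawn from the *same* design construction the
estimator uses, plus multivariate-normal random effects and Gaussian noise,
which is what makes exact recovery testing possible. Stable-MCI subjects are
guaranteed at least two visits (the pathway is otherwise inexpressible).

**Epoch level** (`simulate_epoch_actigraphy`): 15 s counts around the
extended-cosine mean curve, negative-binomial noise (size parameter default
5, the overdispersion regime of wrist counts; 0 disables noise, in which
case counts equal the mean curve exactly rather than being integer-rounded,
so noise-free parameter recovery is well defined), a nightly sleep window
multiplying the mean by a suppression factor (< 1 so sleep is detectable;
default 0.02 leaves sparse movement during sleep, so true sleep is not
mistaken for device removal), nonwear insertions as exact zero runs, and a
default noon start so every simulated day is a complete noon-to-noon window.

What the generator does **not** emulate: realistic device artifacts beyond
zero runs, napping, within-sleep wake, informative missingness beyond the
simple dropout hazard, or any mechanistic link between the simulated
activity rhythm and the cognitive pathway. Passing tests therefore
demonstrate that the estimators recover what they claim to estimate under
the stated noise models — not that the pipeline's scientific conclusions
transfer to any particular real cohort.

# Validation scales and known limitations

The validation suite uses problem sizes chosen to make Monte-Carlo bands
tight while keeping a full run in minutes: 2000 subjects for
pathway-assignment agreement, 500 subjects × 200 replicates for CI coverage,
800 subjects × 50 replicates for elimination behavior, and 300 subjects × 20
seeds for end-to-end recovery of an injected dementia-path change of 0.9 SD.

Limitations worth knowing:

- The elimination procedure's chained hierarchy means a true-zero cubic
  *main* effect survives whenever either cubic interaction is falsely
  retained; its long-run elimination rate is ≈ 0.95³, not 0.95. This is a
  property of the procedure, not of the implementation.
- Wald CIs with residual df are slightly anticonservative for
  between-subject effects in small cohorts; coverage is validated at the
  cohort sizes above.
- The death indicator covariate is time-fixed; mortality-informative dropout
  is not modeled beyond the hazard.
- Rest-interval detection reports one principal interval per day and no
  within-interval awakenings.
- IS/IV interpolate across fully-masked hours linearly; sessions dominated
  by nonwear should be (and are) excluded by the valid-day rules.
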