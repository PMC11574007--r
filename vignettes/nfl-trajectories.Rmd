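---
title: "Methods: comparative CSF and plasma NfL trajectory modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative CSF and plasma NfL trajectory modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the statistical methods it
implements, the assumptions behind them, the numerical choices made where
the methods leave room, and what the synthetic cohort generator can and
cannot tell you about real data.

## Disease clock and staging

All trajectory analyses are anchored on the estimated years to symptom
onset, `EYO = age_at_visit - expected_onset_age`. The expected onset age is
the arithmetic mean of reported onset ages for the participant's variant;
when no variant-level information exists the parental onset age is the
fallback (`expected_onset_age()`). EYO is computed identically for carriers
and non-carriers, and is frozen per input dataset: the variant mean is
computed once on the pre-exclusion cohort, not recomputed as rows are
dropped, so exclusions cannot shift anyone's disease clock.

Exclusion rules run in a fixed order and log every removal:
non-pathogenic/Dutch-type variant carriers, participants with competing
neurological disorders, carriers whose CDR sequence reverts (CDR > 0
followed by a later 0), and — per visit, not per person — non-carrier
visits with EYO strictly greater than +15 years. The strict reading of
"> 15" keeps a visit at exactly 15.0; applying it per visit keeps a
participant whose earlier visits remain informative. Stage labels
(`classify_stage()`) partition everyone left: carriers all-zero CDR are
presymptomatic, all-positive symptomatic, a monotone 0 → >0 switch is a
converter. Two boundary decisions keep the partition total: a single-visit
carrier is presymptomatic (CDR 0) or symptomatic (CDR > 0), since
converting requires at least two visits; and a sequence like (0, 0, 0.5) is
treated as a converter even though a literal reading of "CDR > 0 at all
subsequent visits" would leave it unclassifiable.

## Assay QC

Samples are measured in duplicate. The coefficient of variation of a pair
uses the n−1 sample SD (for two points, `|r1 − r2|/√2`) over the pair mean,
in percent — the standard assay-QC convention; the CV is symmetric and
scale-invariant. Pairs with CV > 20% and single-replicate measurements are
flagged. CSF measurements with a flag use the remeasured pair when one
exists (`remeasured_used`); plasma is never remeasured, so flagged plasma
keeps its initial values (`initial_used`). The reported value is always the
mean of the available replicates, and no row is ever silently dropped.
Analyses run on `log10` concentrations.

One bookkeeping subtlety: the *mean* of two-point sample CVs is a biased
estimate of the generating replicate CV (E|z₁−z₂|/√2 ≈ 0.80·σ), so the
generator's replicate-CV calibration is checked with the pooled RMS CV
(√mean(CV²)), which is unbiased to first order.

## The Bayesian trajectory model

For an outcome (baseline log10 NfL, or extracted annual rate of change) the
model has fixed effects for mutation status, the linear and restricted-cubic
EYO components, their status interactions, age, sex and BMI, plus a family
random intercept and a Gaussian residual. The three-knot restricted cubic
spline uses the Harrell normalization — cubic term
`[(x−t₁)₊³ − (x−t₂)₊³(t₃−t₁)/(t₃−t₂) + (x−t₃)₊³(t₂−t₁)/(t₃−t₂)]/(t₃−t₁)²` —
which is zero below the first knot, C² everywhere, and linear beyond both
boundary knots, so EYO contributes exactly two design columns. Knots sit at
the 0.10/0.50/0.90 empirical quantiles (type-7, linear interpolation) of the
pooled carrier + non-carrier sample for each outcome; pooling is the common
default where nothing dictates group-specific knots.

Priors are weakly informative and deliberately boring: Normal(0, 10²) on
fixed effects *after internal standardization of the predictors* (the draws
are transformed back to the raw scale), and half-Normal(0, 5) on both SDs.
The sampler is a Gibbs scheme: conjugate multivariate-normal updates for
the coefficients, conjugate normal updates for family effects, univariate
slice sampling (stepping-out, Neal 2003) on the log of each SD, and an
ancillarity–sufficiency interweaving step for the family SD. The
interweaving step matters: in the centered parameterization the family SD
mixes an order of magnitude more slowly, and without it split-R̂ for that
one parameter hovers just above the 1.01 gate. Defaults are 4 chains × 1000
post-warmup draws after 500 warmup iterations; split-R̂ < 1.01 for every
reported parameter is required before downstream operations accept the fit
(`force = TRUE` overrides, for diagnostics only). Identical seeds give
identical draws. The sampler is cross-checked in the test suite against an
independent JAGS implementation of the same model on a fixed dataset.

## Divergence points

The difference between the carrier and non-carrier curves depends only on
the status-related coefficients, so covariates cancel and no reference
values are needed for the difference; group curves for plotting are
evaluated at the sample mean age and BMI with sex marginalized at the
sample male proportion. On a grid from −30 to +15 EYO in 0.1-year steps
(truncated to the observed range), the equal-tailed 95% credible band of
the difference is computed pointwise.

The reported divergence point is the onset of *persistent* separation: the
earliest grid EYO from which the band excludes 0 at every later grid point.
The naive alternative — the first single grid point whose band excludes
0 — is reported alongside (`first_crossing_eyo`) but is not the estimate,
for a calibration reason that is easy to verify by simulation: scanning a
pointwise 95% band across a ~450-point grid of a smooth 3-parameter curve
family excludes 0 *somewhere* in roughly a quarter to a third of null
datasets, whereas an isolated interior exclusion almost never persists to
the end of the disease course. Requiring persistence restores near-nominal
null behaviour without touching the band itself.

Recovery behaviour, quantified in the acceptance suite at a low-noise
condition (200 carriers/200 non-carriers; residual, subject and family SDs
of 0.00375/0.00375/0.0025 log10 units; 1% replicate CV; true divergence at
EYO −20): the estimated persistent onset sits a couple of years *after* the
true departure, because the generating curve leaves zero quadratically and
must first clear the credible band. At realistic noise (defaults) the same
estimand lands around 5 years late. That asymmetry is a property of the
estimand — "first detectable separation" — not a bug; read reported
divergence EYOs as conservative (late) bounds on the biological departure.

The penalized-spline alternative (`gam_trajectory()`) fits per-group cubic
regression splines in `mgcv` with GCV-chosen smoothing and declares
divergence where the two groups' pointwise 95% bands stop overlapping.
Comparing independent per-group bands is a stricter criterion than a
credible band on the modelled difference, so the GAM estimate is expected
to be later — which is also why it serves as a useful cross-check rather
than a replacement. One numerical caveat: on a zero-residual (noiseless)
fit GCV cannot identify the effective degrees of freedom — every basis
dimension interpolates a line equally well — so the meaningful invariant,
and the one tested, is that the fitted curve is exactly the line.

## Rates of change and group comparisons

Per-person annualized slopes are empirical-Bayes (BLUP) estimates from
`lme4`: outcome on years from baseline, family intercept, per-participant
random slope and intercept. Two properties are worth knowing. First, in the
zero-residual limit the BLUPs equal the per-subject OLS slopes exactly.
Second, shrinkage under the *correlated* intercept+slope model is toward a
conditional mean given the subject's intercept, so a BLUP can land slightly
outside the segment between the subject's OLS slope and the population
mean; the guaranteed and tested forms are strict variance contraction and
smaller mean absolute deviation from the population mean than OLS.

A consequence for two-stage analyses: shrinkage strength depends on each
subject's visit count and follow-up length. Under the default visit
protocol (biennial, annual once symptomatic) symptomatic subjects have
shorter windows, are shrunk harder, and the slope-vs-EYO relation flattens
artificially right at the cadence switch near EYO 0. At realistic noise
this artifact can dominate the true plasma plateau in the segmented
analysis and can mimic a CSF slope change. The bifurcation recovery tests
therefore run on generator-truth slopes plus small estimation noise, where
the breakpoint machinery itself is being tested rather than the compound
two-stage pipeline; pipeline output on noisy cohorts should be read with
this artifact in mind.

Group contrasts of extracted slopes (and of the plasma/CSF ratio, computed
on the absolute pg/ml scale for interpretability) use a mixed model with
family intercept and age/sex/BMI covariates; all pairwise contrasts among
NC/presymptomatic/converter/symptomatic come from `emmeans` with
Satterthwaite degrees of freedom and Holm adjustment. Holm was chosen
because it is assumption-light and uniformly dominates Bonferroni; the
method is a parameter (`adjust`), not a constant. Covariate selection uses
AIC over all eight subsets of {age, sex, BMI} with Akaike weights
`w_i ∝ exp(−Δ_i/2)` and cumulative weights in ascending-AIC order.

## Segmented regression

`fit_segmented()` implements the iterative linearization for one
breakpoint: at the current ψ, regress on `x`, `(x−ψ)₊` and the gap
indicator `V = −1{x>ψ}`, update `ψ ← ψ + γ̂/ĉ`, repeat to a 1e-6 tolerance
with a 100-iteration cap. Three numerical safeguards, each motivated by a
measured failure: step-halving on the profile RSS (the undamped update
oscillates between adjacent data points); treating a stalled damped step as
convergence (the profile minimum can sit at a kink, where the linearized
update cannot settle but the estimate is already optimal); and a final
±0.5-year fine polish on the exact profile objective (the profile RSS is
piecewise quadratic with kinks at data points, and its global minimizer is
recovered to within 0.01 of an exhaustive grid search in the acceptance
suite). Multi-start uses the quartiles of `x` plus the two best points of a
coarse 19-point profile scan, with best-RSS selection. ψ is constrained to
the inner 2–98% quantile range of `x`.

Absence of a breakpoint is itself a claim, so `detect_bifurcation()`
declares one only when the Davies-bound score-type test of the slope change
(max |t| over a 10-point ψ grid, with the Davies correction for taking a
maximum of correlated statistics) is significant at α = 0.05 *and* the
delta-method SE of ψ is below 25% of the x-range. The SE guard exists
because a "significant" slope change with a breakpoint known only to within
a third of the observation window localizes nothing.

## Imaging coupling

Precuneus volumes are ICV-adjusted by the residual method with non-carriers
as the reference group (`adjusted = volume − b·(ICV − mean ICV_ref)`), so
adjusted volume is uncorrelated with ICV among controls. Coupling models
regress the time-varying imaging outcome on time with age×time, sex×time,
BMI×time and NfL-slope×time interactions, per-participant random slopes and
a family intercept; the NfL-slope×time coefficient (imaging units per year
per unit NfL slope) is the quantity of interest. Converters are merged into
the symptomatic group for this analysis (an option,
`sym_includes_converters`). When the random-slope fit fails in small
groups, the model falls back to random intercepts with a warning.

## What the synthetic generator does and does not emulate

The generator draws families, variants (with variant-specific expected
onset ages ~N(46, 5²) years), covariates, and per-subject random effects
(family intercept 0.05, subject intercept 0.08, subject slope 0.005 log10
units, residual 0.05; CSF–plasma correlations 0.6/0.5), then builds mean
log10 trajectories: base levels 2.35 (CSF) and 0.72 (plasma) log10 pg/ml at
the covariate reference, age +0.010/yr, male +0.05 (CSF only), BMI −0.008
per kg/m² (plasma only) — magnitudes chosen to land the simulated Table-1
style descriptives in the right range. The carrier disease component is
`D(e) = ½·a·g(e−d)²` with `g` a softplus of scale 2.5 years, so the rate of
change grows like `a·(e−d)₊`: flat before the divergence EYO `d = −20`,
then accelerating (a = 0.0020 CSF, 0.0015 plasma per year²). For plasma
only, beyond the plateau EYO `p = +3.6` the rate stops increasing
(configurable post-plateau curvature, default 0). CDR converts at the
expected onset plus N(0, 2²) years and progresses stepwise; visits are
biennial, annual once symptomatic; dropout is visit-level MCAR (8%);
duplicate replicates carry multiplicative lognormal noise at 7% CV; 2.4%
of carriers get injected reverter sequences and three participants get
competing-disorder outlier profiles, to exercise the exclusion rules.
Imaging: volumes couple to the true NfL slope in symptomatic carriers
(−2500 mm³/yr per log10/yr by default); PiB follows a sigmoid amyloid rise
that can be switched off (`pib_amplitude = 0`) to generate amyloid change
truly independent of NfL.

What it deliberately does not emulate: assay calibration curves and batch
effects, informative dropout, variant-level onset heterogeneity beyond a
per-variant mean, regional imaging beyond a single precuneus summary, and
any real-data idiosyncrasies of the cohort the design is modelled on.
Passing recovery tests therefore demonstrates that the estimators recover
the truth *under this generative structure* — correct code and adequate
power — not that the real data satisfy the same assumptions.

## Test problem sizes

The suites run at sizes chosen to exercise every code path while keeping a
full run to a few minutes: cohorts of 100–567 participants; 20-seed
recovery experiments for the divergence point (4 chains × 500 post-warmup
draws), breakpoint and imaging coupling; 200 replicates for the
family-wise-error calibration of the group comparisons; and a 20-dataset
oracle-equivalence sweep for the segmented fit. The acceptance script runs
the complete default-cohort pipeline at full MCMC settings.

## Known limitations

The divergence estimand is detection-limited and therefore biased late;
the two-stage slope-then-segment analysis inherits differential-shrinkage
artifacts at stage boundaries; the Davies bound is conservative, so true
but weak slope changes are missed more often than α suggests; the Gibbs
sampler covers the Gaussian family-intercept model only (no
heteroscedastic or serially correlated residuals); and EYO itself is
treated as known, whereas in reality expected onset ages carry estimation
error that smears all EYO-anchored curves.
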