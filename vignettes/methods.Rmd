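---
title: "Methods: cardiodynamic ECG and concentration-QTc analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cardiodynamic ECG and concentration-QTc analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cqtr)
```

`cqtr` analyzes the cardiodynamic design used to assess QTc liability of
anticancer agents that cannot be given to healthy volunteers: a
single-arm patient study with triplicate Holter ECG extractions on a
drug-free baseline day and on the first and steady-state dosing days, at
clock times matched to the post-dose pharmacokinetic sampling.  This
vignette explains the statistical machinery, the choices made where the
design was genuinely open, and what the accompanying virtual-cohort
generator does and does not emulate.

## QT correction

QT shortens as heart rate rises, so the raw interval is corrected to the
RR = 1 s scale.  The package always corrects the replicate-averaged
point (averaging before correction), and carries RR in seconds and
QT/QTc in milliseconds.

* **Fridericia**: `QTcF = QT / RR^(1/3)`; **Bazett** (`RR^(1/2)`) is
  available as an optional method but never the default.
* **Individual**: `QTcI = QT / RR^b`, with `b` the subject's OLS slope
  of `log QT` on `log RR` over all drug-free replicate-level pairs
  (baseline day plus the Day 1 predose triplicate).  The power law is
  linear only on the log-log scale, so that is where the regression is
  run; the replicate level (rather than triplicate means) is used
  because all drug-free pairs carry information about the subject's
  QT-RR relationship.

The correction-then-averaging order matters in principle (the two do
not commute through the power law); the package fixes
averaging-then-correction, which treats the triplicate mean as the
best estimate of the time point's true intervals.

## Time-matched baseline change and central tendency

For drug day *d* and nominal time *t*, `dQTc(d, t)` subtracts the
baseline-day value at the same *t*.  Times without a baseline
counterpart are dropped (and logged): the steady-state day has no 24 h
extraction, so no 24 h change is reported there, and the Day 1 predose
point belongs to the drug-free baseline rather than the treated data.

The primary analysis fits, per metric, a repeated-measures linear mixed
model with a fixed effect for every day-by-time cell and a random
subject intercept (compound-symmetric covariance), by REML.  Published
analyses of this design state the model class but not the covariance
structure or degrees-of-freedom method; the package uses the simplest
member of the class and documents it so alternatives can be swapped:

* random subject intercept, independent residuals;
* containment degrees of freedom (subjects in the cell minus one);
* one-sided upper bound `LS mean + t(0.95, df) * SE` per cell.

On balanced complete data the LS means coincide with raw cell means
exactly, and with a single cell the analysis reduces to the one-sample
*t* bound — both are enforced by tests.  The design-stage half-width
uses the normal quantile, `1.645 * sd / sqrt(n)`: at the conventional
planning SD of 9 ms and 36 subjects this gives 2.47 ms, and only the
normal (not *t*) version reproduces the sub-2.5 ms planning bound.

## Categorical analyses

Strict inequalities, compound rules requiring both conditions, and
one count per subject/day/category: QTc above 450/480/500 ms, dQTc
above 30/60 ms, PR above 200 ms with a >25% increase from baseline, and
QRS above 110 ms with a >25% increase.  The 25% reference is the
time-matched baseline value, falling back to the subject's baseline-day
mean when the matched time is missing (which baseline the relative rules
should use is not standardized; the fallback is logged).  The default
incidence denominator is subjects with at least one observation on the
day.

## Non-compartmental pharmacokinetics

AUC uses the linear-log trapezoidal rule: the linear trapezoid on
rising, flat, or zero-bounded segments and the logarithmic trapezoid
`(C1 - C2) * dt / ln(C1/C2)` on strictly declining positive segments.
The log rule is exact under mono-exponential decline and never exceeds
the linear chord, a property the tests verify.

The terminal slope is fitted by log-linear regression.  Since the point
selection rule is rarely published, the package uses a reproducible
default: candidate sets are the last *k* >= 3 positive points strictly
after Tmax; sets spanning at least two estimated half-lives are
preferred, and the highest adjusted R² wins.  A numerically flat or
rising fit returns a *not estimable* flag, not an error.  Terminal
fits are skipped entirely for profiles spanning 12 h or less (the
steady-state day is sampled over one dosing interval only, where a
within-interval "terminal" slope would be meaningless); that day
instead contributes the 0-10 h window AUC and the accumulation ratio
against the matching first-dose window.

Summary conventions: geometric mean with log-variance CV%
(`100 * sqrt(exp(s²) - 1)`) for concentrations and AUCs, median (range)
for Tmax, arithmetic mean (SD) for half-life and accumulation ratio.
Metabolite-to-parent ratios are means of per-subject ratios — a ratio
of summary means is a different (and not generally recoverable)
quantity.

## The concentration-QTc hierarchy

The exposure-response model for subject *i*, observation *j*:

    y_ij = theta0 + f(C_ij; theta) + eta_i + eps_ij,
    eta_i ~ N(0, omega^2),  eps_ij ~ N(0, sigma^2)

with `f` one of: 0 (no effect), `slope * C` (linear),
`Emax * C / (EC50 + C)`, or `Emax * C^gamma / (EC50^gamma + C^gamma)`.
Between-subject variability is on the intercept only, and the residual
is additive — the natural scale for a baseline-corrected quantity
already in milliseconds.

**Estimation.** Because the single random effect enters additively, the
marginal distribution of each subject's vector is multivariate normal
with compound-symmetric covariance `sigma^2 I + omega^2 J`.  The
package maximizes this exact marginal likelihood directly (Woodbury
identity for the per-subject determinant and quadratic form), so there
is no linearization step to document and the objective is the true
-2 log-likelihood.  Tests cross-check the linear case against an
independent linear mixed-model implementation to numerical agreement.
A further structural fact keeps the optimization small and robust:
*every* fixed effect — intercept, slope or Emax coefficient, covariate
shifts — enters the mean linearly once EC50 and gamma are fixed, so
they are concentrated out exactly by generalized least squares and the
numerical search runs over at most four parameters (log EC50, log
gamma, log omega, log sigma).  EC50 and gamma are constrained to
data-driven boxes (EC50 within `[1e-3, 1e2] * Cmax`, gamma within
`[0.1, 10]`), with a boundary flag when a bound is active.  Richer
forms are warm-started from their nested parent, which also guarantees
the nested-OFV monotonicity the tests assert.  Standard errors come from the numerical Hessian of the
-2 log-likelihood with delta-method transforms for log-scale
parameters; both absolute SEs and SE% are reported.

**Selection.** Along the nested chain (no effect -> linear; no effect
-> Emax -> sigmoid Emax) each step is a likelihood-ratio test at
alpha = 0.05 per added parameter; a candidate survives only if every
test back to the root passes (stepwise model building).  Survivors are
compared by AIC (the linear and Emax branches are not nested in each
other) and ties go to fewer parameters.  The thresholds are
configurable; published analyses of this design typically state the
model classes but not the selection arithmetic.

**Covariates.**  Sex, BMI and ECOG status enter as additive intercept
shifts, screened by forward LRT at alpha = 0.01; constant covariates
are skipped with a log entry.

**Bootstrap.** Subjects (not observations) are resampled with
replacement, preserving within-subject correlation; each replicate is
refit warm-started at the point estimate, failed replicates are dropped
(warning above 20%), and parameters are summarized by median and 5th /
95th percentiles, with a percentile band for the fitted line over the
observed concentration range.

**Heart rate.** The same machinery fits concentration-HR.  In the
pipeline the HR response is the time-matched *change* in HR by default:
dosing happens at a fixed clock time, so circadian HR variation is
partly collinear with the concentration profile, and a model with no
time term would book the circadian swing as a drug effect.  Subtracting
the same-clock-time baseline removes that confound.  Absolute HR (whose
intercept estimates the population heart rate) remains available.

## Effect-size simulation

From a fitted (or externally specified) model, each simulated patient
draws `theta0 + f(C_ref) + eta + eps`; the simulated spread is thus the
*total* SD `sqrt(omega^2 + sigma^2)`.  This interpretation — including
both variance components — is adopted because a reported simulated-SD
near the total rather than the between-subject SD is only consistent
with residual variability being included.  Summaries report moments,
interpolated percentiles, CV% (missing when the mean is zero) and the
percentage of draws above 30/60 ms; `tail_probability()` gives the
analytic normal counterpart, and a property test confirms the two
converge.  The default reference concentration is 2760 nM, a
geometric-mean steady-state Cmax scale for 50 mg BID dosing.

## The virtual cohort generator

The generator exists so that every downstream stage is testable without
patient-level data.  It emulates:

* the sampling skeleton — triplicates on Days -1/1/10 at the Day 1 PK
  times (24 h coverage on Days -1/1, 10 h on Day 10), PK to 72 h after
  the first dose, BID dosing from Day 4 to the Day 10 morning dose;
* one-compartment first-order-absorption PK with superposition across
  doses and independent log-normal between-subject variability (CV
  40%) on clearance and volume.  Defaults (`ka` 0.76 /h, `CL/F` 2.48
  L/h, `V/F` 58.7 L, 50 mg, amount scale 1e6/518.9 nM per mg/L) are
  calibrated to a population median single-dose Tmax of 4 h on the
  sampling grid, a median t1/2 of 16.4 h, and a first-dose geometric
  mean Cmax near 1500 nM;
* metabolites as scaled, lagged parent copies (fixed concentration
  ratios 0.45/0.41, slower formation rates) — enough to exercise
  metabolite-ratio summaries, with no mechanistic claim;
* QT physiology `QT = a * RR^b` with `a` = 410 ms and a log-normal
  subject exponent (mean 0.33, SD 0.07); RR combines a subject level
  (mean 0.80 s, between-subject SD 0.08 s, i.e. population HR near 75
  bpm), a circadian cosine (amplitude 0.08 s, acrophase 20 h
  post-morning-dose), and a time-point jitter (0.04 s) shared by the
  triplicate;
* QT noise at three levels: subject-by-day baseline drift (3.9 ms),
  between-time-point residual (4.5 ms), within-triplicate replicate
  noise (4 ms).  Jointly these give a total SD of time-matched QTc
  change near 9 ms — the conventional planning SD for this design —
  with a between-subject component of the baseline-corrected intercept
  of about 5.5 ms;
* an optional injected concentration effect on QT (none, linear, or
  sigmoid Emax) evaluated at the model-predicted concentration at the
  ECG's nominal time, with no PK measurement error in the linkage;
* subject covariates (sex ~64% female, log-normal BMI around 26.5,
  ECOG 0/1) and a Day 10 evaluability flag (default probability 0.75 of
  having received the full pre-steady-state dosing run, mirroring
  typical attrition in this population).

What it deliberately does **not** emulate: QT/RR hysteresis, food or
drug-interaction effects on PK, nonlinear accumulation, assay error in
concentrations, or dropout beyond the evaluability flag.  Two
consequences deserve emphasis.  First, a linear one-compartment model
cannot jointly reproduce the observed first-dose Cmax, AUC, half-life
and steady-state accumulation of a drug with nonlinear or
multi-compartment disposition; the defaults prioritize the Tmax/t1/2
medians and first-dose Cmax scale, so steady-state exposures
over-accumulate relative to what a real drug with these single-dose
properties might show.  Second, the generator's subject-by-day QT drift
is an inter-occasion variance component that the analysis model (random
subject intercept only — the structure reported for this design) does
not contain; on cohort-generated null data the effect-model selection
rate therefore runs above its nominal level (roughly 20-25% rather than
~10%).  Passing operating-characteristic tests on the directly
simulated design conditions does not certify behavior under variance
structures the model does not represent — which is exactly the kind of
limitation a real concentration-QTc analysis faces.

## Numerical choices and degenerate inputs

* Zero-variance responses collapse the central-tendency model to cell
  means with zero SE rather than erroring.
* `omega` and `sigma` are optimized on the log scale with floors well
  below the data scale; `omega` hitting its floor is flagged.
* A flat concentration profile yields a *not estimable* terminal slope
  (slope threshold -1e-12 guards against sign noise on constant data).
* Quantiles use linear interpolation between order statistics
  (configurable); exceedance percentages use strict inequalities.
* Model-selection ties (identical OFV) go to fewer parameters.
* All randomness is explicitly seeded: cohort generation derives
  per-subject streams from the master seed, and bootstrap/simulation
  seeds are separate required settings, so identical configurations
  reproduce identical outputs byte for byte.

## Problem sizes used by the test suite

The suite's simulation studies use 200 replicates for coverage and
selection operating characteristics (50 subjects x 10 observations,
between-subject SD 7.17 ms, residual 6.5 ms), 100 outer replicates with
B = 200 for bootstrap coverage on the same 50 x 10 design, 100
replicates for Emax recovery (100 subjects x 19 observations, the
per-subject count of the Holter schedule), and dense-grid profiles for
the NCA closed-form checks.  In the Emax recovery study the maximal
effect and the fitted concentration-response curve are recovered to
well within 20% in the median, while EC50 itself — the weakly
identified parameter of a saturating model observed with realistic
noise — carries a median error near 20-30%; the tests assert exactly
these behaviors.  Percentile bootstrap intervals at 50 subjects run
1-2 coverage points below nominal, a known small-sample property of the
method rather than a defect of the resampling.
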