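---
title: "Models and methods behind clotlyse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind clotlyse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clotlyse)
```

clotlyse analyses turbidimetric fibrin clot assays — plasma absorbance at
340 nm read every 12 s for two or more hours while thrombin/CaCl~2~ trigger
clot formation and tPA drives lysis — and the paired pre/post cohort
statistics built on them. This vignette explains the models, the tunable
parameters, the numerical choices and the limits of what the synthetic data
can demonstrate.

## The turbidity curve model

The synthetic generator uses a phenomenological two-logistic model,

$$A(t) = b + a\,S\!\Big(\frac{t-t_0}{\tau_f}\Big)\Big[1 -
S\!\Big(\frac{t-t_m}{\tau_l}\Big)\Big],$$

with $S$ the standard logistic, $b$ the baseline absorbance (AU), $a$ the
amplitude (AU), $t_0$ the formation onset (s), $\tau_f$ the formation
timescale (s), $t_m$ the lysis midpoint (s) and $\tau_l$ the lysis
timescale (s). The model has monotone formation and lysis phases with a
smooth plateau between them, and it is cheap to evaluate on an arbitrarily
fine grid, which is what makes a brute-force parameter oracle practical.
It is *not* a kinetic model: no thrombin generation, protofibril growth or
plasmin kinetics are represented, only the curve morphology the plate
reader sees.

Defaults: $b = 0.05$, $a = 0.40$, $t_0 = 600$, $\tau_f = 60$,
$t_m = 3600$, $\tau_l = 300$, reading noise SD $0.003$ AU i.i.d. per
reading. The onset sits ten formation timescales into the run so that the
pre-onset tail of the logistic (< 3e-5 AU) does not contaminate a baseline
estimated from the first readings; the resulting lag time of roughly six
minutes is typical for this assay. The noise SD is deliberately small
relative to the 0.01 AU lag threshold so lag detection is stable.

`ground_truth_parameters()` evaluates the noiseless model on a 0.1 s grid
and reads all assay parameters off by direct scan. It is the oracle the
12-s extraction is tested against: lag, time of maximum and both lysis
times must agree within one 12-s grid step, absorbances within 1e-3 AU and
the lysis area within 1%, over hundreds of random parameter sets.

## Parameter extraction

Five readouts are computed per well, following the standard definitions for
this assay family:

* **baseline** — mean of the first 3 readings (thrombin is added
  immediately before reading starts, so the earliest points are pre-clot);
* **lag time** — first time absorbance exceeds baseline + 0.01 AU,
  linearly interpolated between the bracketing samples;
* **maximum absorbance** — the highest value recorded, earliest time on
  ties (reported raw, not baseline-subtracted; the baseline-subtracted
  amplitude is carried alongside for generator round-trips);
* **50% / 100% lysis times** — elapsed time from the maximum until
  absorbance falls to `max − 0.5·(max − baseline)`, and to
  `baseline + 0.01` respectively. The 50% reduction is taken relative to
  `max − baseline` (a raw-max reading can be unreachable when the baseline
  exceeds half the maximum), and the return-to-baseline band is symmetric
  with the lag threshold because an exact return is unattainable under
  noise;
* **clot lysis area** — trapezoidal integral of absorbance above baseline
  from the time of maximum to the 100% lysis crossing (or to the trace end,
  flagged `truncated`). Negative excursions are clipped at zero.

A clot formation time (time of maximum minus lag) is also reported; it is
an interpretation — the quantity is commonly discussed but rarely defined
operationally — and is labelled as such. Because it is ambiguous whether a
study's headline "lysis time" means the 50% or the 100% variant, both are
always computed and reported.

**Noise handling.** Threshold crossings are detected on a centred 3-point
moving average of the trace (`smooth_window = 3`; set 1 to disable). The
reason is quantitative: with 0.003 AU noise, a raw first-crossing detector
fires whenever a single reading fluctuates over the 0.01 AU threshold,
biasing the lag early by about 19 s (1.6 grid steps); with the 3-point
average the bias drops to under 5 s, within one grid step. The maximum and
the area intentionally keep the raw readings, matching the
"highest value recorded" definition. Two consequences of that definition
are worth knowing: the recorded maximum of a noisy trace is an order
statistic and sits ~2 noise SDs above the true plateau (≈ +0.007 AU at the
default noise, i.e. under 2% of a typical maximum); and on broad plateaus
the *time* of the noisy maximum can wander by minutes, which propagates
into elapsed lysis times and the area of noisy curves. The cohort-level
statistics in this package operate on the tabulated per-sample values, so
they are unaffected, but single noisy wells inherit this measurement
convention.

Duplicate wells are averaged per sample over the unflagged replicates;
flags (`no_clot`, `no_return_to_baseline`, `truncated`) from any replicate
are surfaced as warnings, and a sample with no clean replicate is an
explicit sample-level failure rather than a number.

## Reagent arithmetic

`assay_concentration_table()` recomputes the final in-well concentrations
from the dilution chains of the standard protocol (thrombin 200 U/mL
diluted 1:10; activation mixture of 54 µL diluted thrombin + 270 µL 1 M
CaCl~2~ + 11.7 mL buffer; tPA 100 µg/mL diluted twice; 25 µL plasma +
75 µL lysis mixture + 50 µL activation mixture per 150 µL well). Two
volume conventions are exposed: the physically correct
sum-of-added-volumes, and a "stated-total" reading in which a quoted
make-up volume is treated as the mixture's total. The commonly quoted
7.7 mM CaCl~2~ figure is reproduced only under the stated-total reading
(the sum convention gives 7.5 mM), and the quoted 0.35 µg/mL tPA figure is
not reproducible from the stated volumes under either convention (the
arithmetic gives ≈ 0.083 µg/mL). Both are reported as computed —
documented discrepancies, not silent corrections.

## The synthetic paired cohort

`generate_cohort()` draws a paired pre/post cohort from a single-latent-
factor Gaussian model. Subject $i$ carries an "adiposity" factor with a
subject-level component and a period innovation
($\mathrm{corr}(a_{i,pre}, a_{i,post}) = \rho$); each variable $v$ loads on
it with $\lambda_v$ and adds its own unique part, split between a
subject-level intercept (share $\phi$) and period noise. Marginal means
and SDs per period are matched exactly by construction; skewed
non-negative variables (hs-CRP, PAI-1, triglycerides, glucose) are drawn
on the log scale with moment-matched lognormal parameters so the printed
mean/SD pairs (e.g. hs-CRP 2.88 ± 4.04 mg/L post) are attainable without
negative draws. Dichotomous states (dysglycemia, metformin, statin) are
thresholded from the latent score of a clinically related source variable
at the quantile matching the configured proportion. Default means, SDs and
proportions are the studied bariatric-surgery cohort's printed values;
two quantities the study reports only qualitatively get fixed defaults
chosen once: fibrinogen 3.4 ± 0.8 g/L unchanged across periods (the study
found no significant change but prints no values), and lag/lysis-time
distributions (lag ≈ 360 s, 50% lysis ≈ 1200 s, 100% lysis ≈ 2400 s, no
material pre/post change) on the scale typical for tPA-driven lysis
assays.

**Calibrating the within-subject correlations.** A subtlety drives the
whole calibration: with two periods, within-subject centering leaves each
subject contributing ±half its pre/post difference, so the population
repeated-measures correlation is the *uncentered* correlation of paired
differences — the common post-surgery shift that moves BMI and maximum
absorbance down together is itself within-subject covariation. With the
configured mean shifts this term alone contributes about 0.7 to the
BMI–max-absorbance correlation. `implied_rmcorr()` computes the implied
correlation in closed form (including exact natural-scale covariances for
the lognormal variables), and `cohort_config()` solves each target
variable's loading by root-finding so the implied value hits its
configured target (defaults: the published association table, e.g. 0.693
for BMI). Because the mean-shift term dominates, the solved loadings act
as residual fine-tuning and can legitimately come out small or negative;
they are reported in the config for inspection. The defaults
$\rho = \phi = 0.35$ keep every variable's pre/post latent correlation at
0.35 (so paired tests face genuinely paired data) while leaving enough
difference variance for all targets to be reachable — at larger values the
mean-shift floor alone would exceed some targets.

Per-sample turbidity curves are calibrated so each curve's *true*
(oracle) maximum equals the subject's sampled maximum absorbance — the
amplitude is rescaled by the peak of the two-logistic product and the
onset solved from the closed-form lag relation — and its true lag equals
the sampled lag time. The curve-derived 50%/100% lysis times track the
tabulated values only approximately; the tabulated values are the ones
the cohort statistics consume. Sampled maxima below baseline + 0.02 AU
are clipped up before curve synthesis so every generated well forms a
detectable clot.

**What the generator does not emulate.** Real plasma curves show
drift, occasional optical artefacts, heteroscedastic noise, and
between-plate effects; the generator's noise is i.i.d. Gaussian on a
shared grid. Real clinical variables have skew and ceiling effects beyond
the lognormal family, and their cross-correlations are richer than one
factor can express. Passing tests therefore demonstrate that the
*pipeline* is correct and calibrated under the stated model, not that the
model captures every feature of patient plasma.

## Cohort statistics

The pre/post workflow mirrors standard practice for small paired cohorts:

* Normality of the **paired differences** is tested with Shapiro–Wilk
  (`stats::shapiro.test`); the paired Student's t-test is used when
  normality is not rejected at 0.05, the Wilcoxon matched-pairs
  signed-rank test otherwise. Testing differences (not each arm) is a
  deliberate choice: the t-test's assumption concerns the differences.
  Wilcoxon follows the signed-rank conventions: zero differences dropped,
  exact distribution for n ≤ 25 without ties, tie-corrected normal
  approximation otherwise.
* Dichotomous variables use Pearson's chi-squared with the **Yates
  continuity correction on by default**; on the published counts the
  corrected test reproduces the printed P values (.13 for metformin, .4
  for statin) whereas the uncorrected one does not (.07 for metformin).
* Significance is fixed at P ≤ .05 with no multiplicity adjustment,
  matching the source workflow.
* `attrition_report()` computes funnel rates with each stage's losses
  relative to that stage's entrants.

## Repeated-measures correlation and the mixed model

`rmcorr()` implements the analysis-of-covariance formulation directly:
center both variables within subject, estimate the common slope $b$ by
least squares, and report
$r = \mathrm{sign}(b)\sqrt{SS_x/(SS_x+SS_e)}$ with error df
$N - k - 1$; the p value comes from the t transform of $r$ and the 95% CI
from the Fisher z-transform with SE $1/\sqrt{df-1}$ (the analytic interval
— no bootstrap). The implementation is ~15 lines of linear algebra and is
cross-checked in the tests against an explicit dummy-coded design-matrix
fit to 1e-10.

`fit_random_intercept_lmm()` fits
$y_{ij} = \beta_0 + \beta_1 x_{ij} + u_i + \varepsilon_{ij}$ through
`lme4::lmer`. REML is the default (ML is a flag) because variance
components from 32 subjects are noticeably biased under ML. Slope
inference is Wald-normal with no small-sample df correction — an
approximation, stated as such; simulation at the study size (32 subjects
× 2 periods) puts the CI coverage at roughly 94–95%. Boundary fits with
$\hat\sigma_u^2 = 0$ are accepted (the slope then reduces to OLS).
Covariates enter in their natural units with no standardisation, so
slopes against a small-magnitude outcome like maximum absorbance are
themselves small. `adjusted_period_effect()` fits
`outcome ~ period + adjustor + (1 | subject)` to ask whether a pre/post
difference survives adjustment — e.g. whether a lysis-area change
persists after adjusting for maximum absorbance.

## Problem sizes and numerical choices

The test suite exercises: oracle equivalence over 200 random curve
parameter sets; rmcorr-vs-ANCOVA equality to 1e-10; LMM/rmcorr parameter
recovery and CI coverage over 600 simulations at 32 × 2; paired-test power
(500 simulations) and type-I error (2000 simulations); and large-n
(n = 2000) moment calibration of the generator. These sizes give
Monte-Carlo error comfortably below each assertion's tolerance while the
whole suite runs in about two minutes. Tolerances follow the sampling
grid: one 12-s step for times, 1e-3 AU for absorbances, 1% for areas.
Ties in the maximum break to the earliest time; all threshold crossings
interpolate linearly; integration is trapezoidal with exact interpolated
endpoints.

## Known limitations

* The time of a noisy maximum wanders on broad plateaus (see above),
  which inflates the variance of curve-derived lysis times and areas.
* Fisher-z CIs for rmcorr are slightly conservative at 31 error df.
* The lognormal moment-matching guarantees means and SDs, not higher
  moments; extreme printed SD/mean ratios (hs-CRP post: 4.04/2.88) imply
  heavy right tails.
* The single-factor correlation structure matches the configured
  pairwise targets against maximum absorbance but does not control
  covariate–covariate correlations among themselves.
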