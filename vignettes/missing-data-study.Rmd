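---
title: "Simulating and repairing missing serial creatinine: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and repairing missing serial creatinine: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scrmiss)
```

## The problem

Longitudinal cohort studies of kidney function accumulate missing serum
creatinine (Scr) measurements over successive exams, and the sicker the
participant the more likely the value is to be missing — missingness that
is *informative* (NMAR), not ignorable. Analyses that simply drop or
naively fill such values can distort both the biomarker's distribution
and its estimated association with clinical outcomes.

`scrmiss` implements a complete, seeded simulation laboratory for this
problem: it generates a synthetic cohort with the statistical structure
of a large American-Indian cardiovascular cohort (three Scr exams over
roughly a decade, cardiovascular events linked to current Scr), deletes
values under four known missingness mechanisms, repairs the data with
five remedial methods, and scores every method by how well it recovers
(a) the Scr distribution and (b) the proportional-hazards association
between current Scr and cardiovascular disease (CVD).

## The synthetic cohort generator

`generate_cohort()` draws, per subject: gender (64.1% female), age
(normal 54.9 (7.4) years truncated to [45, 74]), diabetes (37.3%), and a
baseline Scr from a log-normal with arithmetic mean 0.88 and SD
0.25 mg/dL. Serial values follow a log-scale random walk,

$$\mathrm{Scr}_{t+1} = \mathrm{Scr}_t \exp(\delta + b\,Z_i + \varepsilon_{it}),
\qquad \varepsilon_{it} \sim N(0, \sigma^2),$$

where $Z_i$ is a latent "rapid progressor" indicator with prevalence
$p$. The four progression parameters $(\delta, \sigma, p, b)$ are the
exact solution of the four moment equations that pin the Exam-2 and
Exam-3 arithmetic means and SDs at 0.90 (0.44) and 0.94 (0.88) mg/dL:
a small extreme-progressor fraction ($p \approx 0.004$, $b \approx 1.21$
per interval) combined with moderate diffuse noise
($\sigma \approx 0.34$) is what produces an Exam-3 SD comparable to its
mean — i.e. the growing right skew of declining renal function — without
ever producing a negative concentration. A single log-normal cannot do
this while keeping the mean drift so small.

The choice of a *log-normal with a progressor mixture* (rather than, say,
a gamma family or a monotone latent-trajectory model) is the main place
the generator goes beyond what the calibration targets force; the
inter-exam correlation of Scr is not pinned by any published marginal, so
the residual noise that the moment equations deliver is a calibration
choice, not an empirical one.

Event times come from a piecewise-exponential proportional-hazards
model: the log hazard is linear in the *current* (exam-updated) Scr plus
age, gender and diabetes terms, so the time-dependent Cox fit has a
well-defined true coefficient. The default true hazard ratio is 1.15 per
1 mg/dL. The baseline rate (0.008274 events/person-year at the covariate
reference) is calibrated so that 19.7% of subjects experience an event
before administrative censoring at 14 years; exams sit at years 0, 4
and 9. Units throughout: mg/dL for Scr, years for time. Prevalent CVD at
baseline is not simulated — only incident events enter the comparison —
and death is not modelled as a competing risk.

## Missingness mechanisms

Four mask generators delete Scr cells from the complete table, all
calibrated to marginal missingness of 20/30/40% at Exams 1–3
(`calibrate_offsets()` solves for per-exam additive offsets by exact
expected-rate bisection, integrating over the previous exam's mask
distribution rather than simulating):

* **MCAR** — independent Bernoulli deletion at the design rates.
* **Autoregressive (MAR)** — Exam 3 deletion probability rises by 0.353
  when Exam 2 is missing; Exam 2 is independent of Exam 1.
* **Autoregressive + covariates (MAR)** — linear-probability predictors
  in gender, age, a transformed age term and prior missingness. The
  printed Exam-2 age predictor is internally inconsistent as stated (it
  is negative at every cohort age when both age terms are read
  literally), so the second age term is a configurable transform
  `g(age)` in {ln, sqrt, identity}, defaulting to `ln` to match the
  explicit logarithm in the Exam-3 predictor, with the per-exam offset
  recalibration guaranteeing the design rates regardless of the choice.
  Predictors are clamped to [0.001, 0.999]: an identity-link linear
  predictor strays outside [0, 1] at extreme ages.
* **Selection model (NMAR)** — each cell is deleted with probability
  $\operatorname{expit}(\alpha_j + \beta_j\, y_{ij})$ where $y_{ij}$ is
  the subject's *true, possibly unobserved* Scr at that exam, fitted per
  gender. The defaults use $\beta = 1.5$ per mg/dL at every exam — the
  sign chosen so that high-creatinine (sick) subjects are preferentially
  lost, which biases observed-case means downward, the direction a
  morbidity-driven dropout process produces — with $\alpha$ calibrated
  to the 20/30/40% rates.

## The selection-model likelihood

`troxel_negloglik()` is the joint likelihood of the serial values and
their missingness under a first-order Markov-normal outcome model
($y_1 \sim N(\mu_1, \sigma_1)$;
$y_t \mid y_{t-1} \sim N(a_t + b_t y_{t-1}, \tau_t)$) with logistic
selection on the current value. Observed cells contribute
$f(y_t \mid y_{t-1})\,(1 - \pi_t(y_t))$; missing cells contribute
$\int f(y \mid y_{t-1})\, \pi_t(y)\, dy$, evaluated by Gauss–Hermite
quadrature and nested across consecutive missing exams (the Exam-1
marginal anchors the recursion). Scr is log-transformed by default
before the normal Markov model, since the raw scale is strongly
right-skewed.

Numerical choices:

* Quadrature order 40 by default; the negative log-likelihood changes by
  less than $10^{-6}$ between orders 40 and 80 on the standard test
  fixture, and the replicated coverage study below uses order 16, where
  the difference from order 40 is already far below the Monte-Carlo
  noise of a single replicate.
* The likelihood and its full analytic gradient (selection *and*
  outcome parameters) are implemented in compiled code with one closed
  integration order per missingness pattern; a vectorized R engine
  evaluates the identical quadrature rule and the two agree to machine
  precision in the test suite. Standard errors come from the inverted
  central-difference Hessian of the analytic gradient (step
  $10^{-5}(1+|\theta|)$; the coefficient-level Hessian in
  `fit_missingness_glm()` uses direct function differences with step
  $10^{-4}(1+|\theta|)$).
* `fit_troxel()` first maximizes over $(\alpha, \beta)$ with the
  Markov-normal parameters fixed at their available-case estimates
  (profile fit), then — when `joint = TRUE` — continues into a full
  joint maximization over all parameters from that starting point.
  Under strong selection the available-case outcome estimates are
  themselves biased (the observed cells are a selected sample), which
  propagates into the profiled $(\hat\alpha, \hat\beta)$; the joint
  maximizer is the consistent estimator, and it is what the package's
  interval-coverage validation exercises (200 replicates at n = 5000:
  two-standard-error intervals cover the generating values for about
  95% of replicates, for both parameters). The profile fit remains the
  default because it is fast, stable, and adequate for moderate
  selection; the vignette of record for any substantive analysis should
  state which was used.
* All-observed masks are rejected as degenerate (the selection
  intercepts diverge); underflowing likelihood contributions are floored
  at $10^{-300}$ rather than propagating `-Inf`.

The MAR mechanisms are fitted by `fit_missingness_glm()`, an
identity-link binary GLM maximized directly (BFGS on the Bernoulli
log-likelihood with fitted probabilities clamped inside (0, 1)), which
reports coefficients, Hessian-based standard errors, t-values and the
residual deviance for likelihood-ratio comparison of nested mechanism
models.

## Remedial methods

* **LD** — listwise deletion; kept as a row filter so downstream fits
  see the reduced sample size.
* **Mean** — observed-case mean of the same exam. Preserves the exam
  mean exactly and never inflates the SD (both are asserted in the test
  suite).
* **AV** — adjacent value: the nearest observed exam's value, the
  previous exam winning the Exam-2 tie, consistent with assuming kidney
  function does not recover after a clinical or sub-clinical event.
  All-missing rows are flagged unresolved and excluded downstream.
* **MI** — chained-equations multiple imputation written for this
  package (m = 5 chains, 10 cycles by default): each exam's log-Scr is
  regressed on age, gender, diabetes and the other two exams' current
  completed values; each cycle draws the regression parameters from
  their large-sample posterior and adds residual noise, so the
  imputation is proper. m and the cycle count are conventional defaults,
  not calibrated quantities.
* **PM** — pattern-mixture restricted imputation: the MI chains with
  every imputed draw restricted by a threshold — the 10th, 25th or 50th
  percentile of the model-predicted Scr values for that exam's missing
  cells — via inverse-CDF truncated-normal sampling (never rejection, so
  a tight bound cannot stall the chain).

The PM restriction *direction* deserves a note. The method's published
description pairs an upper-bound restriction with the rationale that
low-creatinine patients are the ones lost; yet the same study's NMAR
results show observed-case means biased *low*, which is what selection
against high-creatinine patients produces, and its PM means sit above
the unrestricted-MI means — the signature of a lower-bound restriction.
Both directions are implemented and `pattern_mixture_impute()` defaults
to the literal published direction (`upper_bound`). The *pipeline*
default, however, is `lower_bound`, because the pattern-mixture
assumption must point in the direction of the NMAR mechanism it is
meant to compensate: under the package's default mechanism (high Scr
preferentially missing) the analyst's correct prior is that missing
values are *larger* than the imputation model predicts. With that
pairing, completed-data means rise monotonically in the threshold
percentile toward the complete-data value, reproducing the qualitative
pattern the method is known for.

## Evaluation surface

For every mechanism × method cell the pipeline reports per-exam
mean/SD, exam-wise adjusted hazard ratios (subjects contribute full
follow-up from Exam 1, the covariate fixed at the chosen exam's value —
landmarking is deliberately not applied), and a time-dependent hazard
ratio on the counting-process expansion (`long_format()`), all adjusted
for age, gender and diabetes, Efron tie-handling throughout (synthetic
event times are continuous, but imputed data sets can create near-ties).
Multiply-imputed fits are pooled on the log-HR scale by Rubin's rules
with Barnard–Rubin degrees of freedom. `rank_methods()` orders methods
within each mechanism by mean absolute log-HR discrepancy from the
complete-data fit across all fitted cells, ties broken by mean
recovery; the complete-data row ranks first with discrepancy zero by
construction.

## Reproducibility and problem sizes

Every stochastic stage takes its seed from one master seed through a
counter-based derivation (`derive_seed()`), so adding replicates never
perturbs earlier ones and identical configurations are bit-identical.
The replicated validation studies in the test suite use sizes chosen to
make Monte-Carlo error small relative to the assertion bands: the
cohort calibration and imputation invariants run at the full study size
n = 2264; selection-model interval coverage uses 200 replicates of
n = 5000 (quadrature order 16, joint maximization); the
informative-missingness pipeline comparison uses 100 replicates of the
full n = 2264 study restricted to the NMAR mechanism; hazard-ratio
recovery uses a single n = 20000 cohort.

## What passing tests do and do not show

The generator emulates marginal moments, event incidence and a
creatinine-linked hazard; it does not emulate assay error, visit-time
jitter, informative censoring by death, diabetes incidence over time,
eGFR, or urinary markers. Conclusions about method rankings therefore
transfer to real cohorts only insofar as the real missingness resembles
the simulated mechanisms; the NMAR selection strength in particular
(β = 1.5 per mg/dL) is a design choice on which the *magnitude* (not
the direction) of the LD and mean-substitution distortions depends
strongly. No claim is made that the package reproduces any specific
published table computed on restricted data.
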