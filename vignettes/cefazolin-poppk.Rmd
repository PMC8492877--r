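---
title: "Population pharmacokinetics of prophylactic cefazolin: model, estimation and simulation methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population pharmacokinetics of prophylactic cefazolin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cefapk)
```

## The problem

Cefazolin is the standard antibiotic for surgical-site-infection
prophylaxis in total hip arthroplasty. The clinical questions the
analysis addresses are whether a fixed 2000 mg IV bolus keeps total
plasma concentrations above the therapeutic threshold for the whole
operation, whether obese patients need the guideline-doubled dose, and
whether renal function should change the regimen. `cefapk` implements
the full analysis chain: a nonlinear mixed-effects (population PK)
model, SAEM maximum-likelihood estimation, covariate selection,
simulation-based diagnostics, and Monte-Carlo dosing simulations — plus
a synthetic-cohort generator so that every stage is testable without
patient data.

## Structural and statistical model

Disposition follows a mammillary compartment model (1, 2 or 3
compartments) with instantaneous IV bolus input and linear elimination.
For a bolus `D` the central concentration is a sum of exponentials,

    C(t) = (D / Vc) * sum_j c_j exp(-lambda_j t),

where the decay rates `lambda_j` are the eigenvalues of the micro-rate
matrix (quadratic roots for 2 compartments, trigonometric cubic roots
for 3) and the coefficients come from partial fractions; multiple doses
superpose linearly. `concentrationProfile()` evaluates this closed form;
the test suite verifies it against an independent stiff ODE integration
to a relative error below 1e-6, together with exact superposition and
mass balance.

Between-subject variability is log-normal. Writing `phi_i = log psi_i`
for subject `i`'s log-parameters,

    phi_i = mu_i + eta_i,   eta_i ~ N(0, Omega),

with `Omega` diagonal except for a single CL-Vc covariance (the only
correlation supported by the data). The clearance model carries the
renal covariate as a centred power law,

    CL_i = theta_CL * (CrCL_i / 80)^theta_CrCL * exp(eta_CL,i),

with CrCL the CKD-EPI estimate and the centering constant fixed at 80.
Observations follow a combined error model
`y_ij = f_ij + (a + b f_ij) eps_ij`; the final model is proportional
only (`a = 0`, `b = 0.12`, i.e. 12% CV).

`cefazolinFinalModel()` returns the published estimates (CL 2.86 L/h at
CrCL 80 with exponent 0.79, Vc 5.2 L, Q 10.9 L/h, Vp 4.56 L; log-scale
SDs 0.32/0.57/0.66/0.10 with CL-Vc correlation 0.83). The reported
variability entries are interpreted as log-scale SDs x 100 (approximate
CV%), not variances: a variance of 32 would imply a biologically
impossible ~e^5.7-fold spread, and only the SD reading reproduces the
published target-attainment table (checked by simulation in the
acceptance tests). The estimated correlation is likewise taken on the
eta scale.

## SAEM estimation

`saemFit()` implements stochastic approximation EM:

* **E-step**: per subject, Metropolis-within-Gibbs sampling of `phi_i`
  — one independent proposal from the conditional prior `N(mu_i,
  Omega)` followed by componentwise random walks whose scales adapt
  toward a 40% acceptance rate during exploration.
* **M-step**: generalised least squares for the fixed effects on
  stochastically approximated sufficient statistics; `Omega` from
  approximated second moments, projected onto the diagonal-plus-CL-Vc
  structure (correlation clamped to |rho| <= 0.98); the error
  parameters from approximated residual statistics (a Nelder-Mead
  subproblem for the combined model).
* **Step sizes**: 1 during `nBurn` exploration iterations, then
  `k^-0.7`. During exploration, variances may shrink by at most 5% per
  iteration (simulated-annealing floor) so the chain explores before
  the approximation freezes.

Defaults (`saemControl()`): 300 exploration + 200 smoothing iterations,
5 kernel transitions per iteration. Starting values come from
model-free heuristics (Vc from dose/Cmax, CL from a trapezoid-plus-tail
AUC); the fit does not need user initials. Everything is reproducible
from one integer seed, and two runs with the same seed produce
bit-identical traces.

Records below the 5 mg/L limit of quantification are excluded from the
likelihood with a logged count. Formal censored-likelihood (M3)
handling is deliberately out of scope; under the study design fewer
than ~2% of records are affected, almost all at 8 h in
high-clearance subjects.

The marginal log-likelihood is computed by importance sampling: a
multivariate-t proposal (5 df) centred at each subject's empirical
Bayes mode and scaled by the local curvature, with the Monte-Carlo
standard error reported. BIC uses the subject-count convention
`-2 logL + k log(N_subjects)`, the usual choice for mixed models where
subjects are the independent units (the convention is a visible
argument of `bic()`). Relative standard errors come from a
finite-difference Hessian of the importance-sampling log-likelihood
under common random numbers (the proposal and draws are frozen at the
fitted model, which makes the surface smooth in the parameters).
Empirical Bayes estimates are per-subject posterior modes started at
`eta = 0`; shrinkage is `100 (1 - SD(EBE)/omega)`.

## Covariate machinery and selection

Renal function is derived two ways — Cockcroft-Gault (mL/min) and the
2009 CKD-EPI creatinine equation (mL/min/1.73 m2) — and lean body
weight by the Janmahasatian (2005) formula, the field standard, since
no formula is fixed by the analysis itself. Serum creatinine is
accepted in umol/L or mg/dL (88.4 umol/L per mg/dL). The covariate
retained in the final clearance model is the CKD-EPI estimate with the
centering constant 80 as printed; the mL/min-vs-normalised-units
labelling ambiguity is inherited from the source and does not affect
the computation, which uses the CKD-EPI value as produced.

`forwardStepwise()` adds one candidate link at a time (continuous
covariates as centred power laws, sex as a multiplicative factor),
accepts the largest BIC drop, and stops when no candidate lowers the
BIC; the trace records every evaluated model, its BIC change and the
affected omega. `compareStructural()` ranks 1/2/3-compartment fits the
same way. Candidate fits that fail are skipped with a warning, never
silently dropped.

## The synthetic cohort

`cohortDesign()` encodes the study conditions: 100 subjects; age mean
67 (24-91); 49% female; weight mean 76 kg (48-123) with a 0.5
weight-height correlation so that the induced BMI distribution has a
realistic tail (~28% above 30 kg/m2, ~6% above 35); serum creatinine
log-normal by sex, calibrated so the induced CKD-EPI clearance has
mean ~83 with range clamped to the observed 17-129 (out-of-range draws
are redrawn); surgery duration mean 1.16 h (0.49-2.48) and
injection-to-incision delay mean 0.85 h (0.18-2.23), both truncated
normal. The underlying location parameters are set so the *realized*
truncated means match these targets. Dosing follows the protocol rule
(2000 mg at induction, 4000 mg when BMI > 35 **and** TBW > 100 kg, a
half-dose redose at exactly 4 h after injection when surgery runs
longer — the redose clock is anchored at the injection, the natural
reading of the 4-h redosing recommendation). Sampling is at 3 min
(encoded 0.05 h), 20 min (1/3 h), end of surgery, 3 h and 8 h.

What the generator does **not** emulate: the joint dependence structure
of the real covariates beyond weight-height (only marginals are
matched), assay drift, sample-handling error, dropout, and any
within-subject time-variation of covariates. Passing tests therefore
demonstrate correct recovery of a data-generating process *like* the
study's, not properties of the original patients.

## Dosing simulations

`simulatePopulation()` draws etas from the fitted distribution
(including the CL-Vc correlation) and evaluates noise-free profiles:
residual error is excluded by default because the target is exposure,
not assay replication; a flag includes it. `pta()` reports the percent
of subjects at or above the total-concentration threshold
(`efficacyThreshold(4, 0.2) = 20` mg/L for the 4 mg/L MIC at 80%
protein binding) at the evaluation times — 2.01 h (mean
injection-to-closure) and 4 h. `toxicityExceedance()` tracks the 360
mg/L neurotoxicity cutoff pointwise and integrates each subject's time
above it with linear-interpolated crossings. `compareRegimens()`
contrasts the doubled regimen (4000 + 2000 mg) against the standard
one (2000 + 1000 mg) for obese covariate profiles as
individual-typical (`eta = 0`) curves; an ensemble mode is available
through `simulatePopulation()`.

A numerical caveat: the pointwise median of the simulated ensemble
tracks, but does not exactly equal, the typical (`eta = 0`) curve —
with four correlated log-normal effects entering a nonlinear function
the deviation reaches ~4% mid-profile. It is exactly zero at `t -> 0`,
where the profile is a single log-normal factor.

## Diagnostics

`pcVpc()` applies the Bergstrand prediction correction (each record
scaled by bin-median population prediction over its own population
prediction) to observations and to 1000 simulated replicates by
default, with 5th/50th/95th percentiles in quantile-based time bins
(default 6; duplicate quantile edges merge bins, which also handles
empty bins) and 90% confidence bands per percentile. `npde()` follows
the simulation-based decorrelation construction: per subject, the mean
and covariance of the simulated vectors define a Cholesky whitening;
ranks of the whitened observation among whitened simulations (midpoint
ties, clamped away from 0/1) map through the standard-normal quantile.
A singular simulated covariance is ridge-regularised with a warning.
`gofTable()` tabulates observed values against population (`eta = 0`)
and individual (EBE) predictions. All diagnostics are exactly
reproducible from their seeds, and the plots (`plotVpc()`, `plotGof()`,
`plotNpde()`) are thin ggplot2 layers over the tables — the tables, not
the pixels, are the tested surface.

## Numerical choices and problem sizes

* Random-effect covariances are floored at 1e-10 before Cholesky;
  omegas numerically at zero pin their eta to zero rather than
  entering a degenerate prior.
* Non-finite likelihood contributions from overflowing parameter
  proposals are treated as log-density -Inf (the proposal is simply
  rejected).
* The test suite runs its replicate studies at 50-100 subjects with a
  shortened SAEM schedule (200 exploration / 120 smoothing iterations,
  3 kernel transitions), the smallest budget at which the fitted
  likelihood reliably lands within a few points of the full-schedule
  optimum — a requirement for BIC comparisons, whose signals (structural
  gaps of hundreds of points, covariate gaps of tens) must dominate the
  fit-to-fit noise. The full defaults reproduce the published-scale
  analysis in ~15 s per fit.
* Monte-Carlo target-attainment runs use 1e5 subjects per covariate
  profile, making the binomial standard error at most 0.16 percentage
  points.

## Limitations

Infusion dosing, saturable elimination, inter-occasion variability,
censored-likelihood BLQ handling and a full Omega correlation search
are out of scope. Target-site (joint capsule) kinetics are not
modelled — plasma is the analysis matrix. The BIC sample-size
convention and the SAEM schedule of the original analysis are not
reported anywhere; both are explicit, documented arguments here.
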