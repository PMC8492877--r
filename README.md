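# cefapk — population pharmacokinetics of prophylactic cefazolin

Cefazolin is the first-line antibiotic for preventing prosthetic joint
infection in total hip arthroplasty. Whether its fixed 2000 mg IV bolus
should be adapted to body weight or renal function is a live clinical
question: prophylaxis works when total plasma concentrations stay above
20 mg/L (the 4 mg/L MIC of the target staphylococci corrected for ~80%
protein binding) throughout surgery, while prolonged concentrations
above 360 mg/L carry neurotoxicity risk.

`cefapk` is an R implementation of the complete population-PK analysis
chain for this problem, aimed at pharmacometricians and clinical
pharmacologists:

* **Model.** Two-compartment IV-bolus kinetics in closed form
  (1- and 3-compartment variants included), log-normal between-subject
  variability with a CL–Vc correlation, proportional residual error,
  and a centred power law for renal function on clearance:

  CL_i = θ_CL · (CrCL_i / 80)^θ_CrCL · e^{η_i},  η ~ N(0, Ω)

* **Estimation.** A stochastic approximation EM (SAEM) engine with
  Metropolis-within-Gibbs conditional sampling, importance-sampling
  marginal likelihood, empirical Bayes estimates, shrinkage, and
  finite-difference standard errors.
* **Selection.** BIC-ranked structural comparison (1/2/3 compartments)
  and forward-stepwise covariate search (age, body-size descriptors,
  Cockcroft-Gault and CKD-EPI clearance, sex).
* **Diagnostics.** Prediction-corrected VPC, normalized prediction
  distribution errors (NPDE), goodness-of-fit tables and plots.
* **Simulation.** Virtual cohorts reproducing the study design
  (protocol dosing with the obesity doubling rule, five-point sampling,
  5 mg/L LLOQ), probability of target attainment, toxicity exceedance,
  and regimen comparison for obese patients.

## Worked example

Simulate a study-like cohort from the published final model, refit it,
and simulate target attainment:

```r
library(cefapk)

model <- cefazolinFinalModel()        # published final estimates
dat   <- simulateStudy(cohortDesign(n = 100), model, seed = 11)
dat
#> PKEventData: 100 subjects, 100 dose and 500 observation records (3 below LLOQ 5 mg/L)

fit <- saemFit(dat, model, saemControl(seed = 42))
fixedEffects(fit)
#>                  cl                  vc                   q                  vp
#>           2.9710603           5.4995419          10.5566976           4.6463873
#> beta_crcl_ckdepi_cl
#>           0.8159805
etaShrinkage(fit)[c("cl", "vc")]
#>        cl        vc
#> 0.6334165 2.3377007
```

The typical clearance (2.97 L/h) and renal exponent (0.82) recover the
generating values 2.86 and 0.79 within sampling error, and shrinkage
below 10% shows the five-sample design individualises CL and Vc well.
Target attainment for a borderline-renal-function profile:

```r
s  <- regimenScenario(covariates = list(crcl_ckdepi = 120),
                      grid = c(0, 2.01, 4))
cm <- simulatePopulation(model, s, n = 1e5, seed = 620)
pta(cm, efficacyThreshold(4, 0.2), c(2.01, 4))$pta
#>   time    pta
#> 1 2.01 100.00
#> 2 4.00  95.92
```

Even at the fastest renal-clearance profile, ~96% of simulated subjects
stay above 20 mg/L four hours after a single 2000 mg bolus — the basis
for the conclusion that neither weight- nor renal-adapted dosing is
needed for typical hip-arthroplasty durations.

A full configured run (simulate → structural comparison → covariate
selection → fit → diagnostics → scenarios) is driven by a YAML file:

```r
runPipeline("run.yaml")          # or: Rscript inst/scripts/run_pipeline.R --config run.yaml
```

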