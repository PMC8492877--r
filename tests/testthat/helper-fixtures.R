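# Shared fixtures: all synthetic data are generated in code at test time.

# Published final-model parameter values used as generating truth.
finalModel <- function() cefazolinFinalModel()

# Reduced SAEM budget used where a test needs several fits: large enough
# that the fitted likelihood is within a few points of the full-schedule
# optimum (shorter schedules can stall tens of points away, which would
# corrupt BIC comparisons), small enough to keep multi-fit tests fast.
quickControl <- function(seed = 1)
  saemControl(nBurn = 200, nSmooth = 120, nKernel = 3, nIS = 1500,
              seed = seed)

# Moderate budget for single-fit recovery checks.
fitControl <- function(seed = 1)
  saemControl(nBurn = 200, nSmooth = 120, nKernel = 3, nIS = 2000,
              seed = seed)

smallStudy <- function(n = 50, seed = 1, model = finalModel())
  simulateStudy(cohortDesign(n = n), model, seed = seed)

# Random positive disposition parameters for property tests.
randomParams <- function(nComp) {
  pkParameters(cl = exp(rnorm(1, log(3), 0.4)),
               vc = exp(rnorm(1, log(5), 0.4)),
               q = exp(rnorm(nComp - 1, log(c(9, 2)[seq_len(nComp - 1)]), 0.4)),
               vp = exp(rnorm(nComp - 1, log(c(5, 12)[seq_len(nComp - 1)]), 0.4)))
}

# Independent ODE oracle for the mammillary bolus model (deSolve).
odeConcentration <- function(params, dose, times) {
  n <- params@nComp
  vc <- params@vc
  k10 <- params@cl / vc
  kin <- if (n > 1) params@q / vc else numeric(0)
  kout <- if (n > 1) params@q / params@vp else numeric(0)
  rhs <- function(t, A, p) {
    dA1 <- -k10 * A[1] - sum(kin) * A[1] + sum(kout * A[-1])
    list(c(dA1, kin * A[1] - kout * A[-1]))
  }
  out <- deSolve::lsoda(c(dose, rep(0, n - 1)), c(0, times), rhs,
                        parms = NULL, rtol = 1e-10, atol = 1e-10)
  out[-1, 2] / vc
}
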