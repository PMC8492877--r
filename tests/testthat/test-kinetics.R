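# Closed-form compartment kinetics.

test_that("bolus limit, empty dosing and input validation", {
  p <- pkParameters(cl = 2.86, vc = 5.2)
  d <- data.frame(time = 0, amount = 2000)
  expect_equal(concentrationProfile(p, d, 1e-12), 2000 / 5.2,
               tolerance = 1e-9)
  expect_equal(concentrationProfile(p, NULL, c(0, 1, 5)), c(0, 0, 0))
  expect_equal(concentrationProfile(p, d[0, ], 2), 0)
  expect_error(concentrationProfile(p, d, -1), "non-negative")
  expect_error(concentrationProfile(p, data.frame(time = 0, amount = -5), 1),
               "positive")
  expect_error(pkParameters(cl = -1, vc = 5), "positive")
  expect_error(pkParameters(cl = 1, vc = 5, q = 2), "nComp - 1")
})

test_that("closed form matches an independent ODE solution", {
  skip_if_not_installed("deSolve")
  set.seed(42)
  times <- c(0.05, 0.5, 1, 3, 8)
  for (case in 1:100) {
    nComp <- sample(1:3, 1)
    p <- randomParams(nComp)
    dose <- runif(1, 500, 4000)
    cf <- concentrationProfile(p, data.frame(time = 0, amount = dose), times)
    ode <- odeConcentration(p, dose, times)
    expect_lt(max(abs(cf - ode) / ode), 1e-6)
  }
})

test_that("superposition over doses and dose linearity are exact", {
  p <- pkParameters(cl = 2.86, vc = 5.2, q = 10.9, vp = 4.56)
  d1 <- data.frame(time = 0, amount = 2000)
  d2 <- data.frame(time = 4, amount = 1000)
  both <- rbind(d1, d2)
  t <- c(4.5, 6, 8)
  expect_equal(concentrationProfile(p, both, t),
               concentrationProfile(p, d1, t) +
                 concentrationProfile(p, d2, t), tolerance = 1e-14)
  # superposition at t = 6 equals the two single-dose curves at 6 and 2 h
  expect_equal(concentrationProfile(p, both, 6),
               concentrationProfile(p, d1, 6) +
                 concentrationProfile(p, d1, 2) / 2, tolerance = 1e-14)
  # doubling every dose doubles the curve, exactly
  expect_equal(concentrationProfile(p, transform(both, amount = 2 * amount), t),
               2 * concentrationProfile(p, both, t), tolerance = 1e-14)
})

test_that("mass is conserved: compartments plus eliminated drug sum to dose", {
  set.seed(7)
  for (nComp in 1:3) {
    p <- randomParams(nComp)
    dose <- 2000
    for (tEnd in c(0.5, 4)) {
      amounts <- cefapk:::.compartmentAmounts(p, dose, tEnd)
      eliminated <- p@cl * integrate(
        function(s) concentrationProfile(p, data.frame(time = 0,
                                                       amount = dose), s),
        0, tEnd, rel.tol = 1e-12)$value
      expect_lt(abs(sum(amounts) + eliminated - dose) / dose, 1e-8)
    }
  }
})

test_that("concentration decays strictly after the last dose", {
  set.seed(11)
  for (nComp in 1:3) {
    p <- randomParams(nComp)
    tt <- seq(5, 30, by = 0.5)  # well past the 4 h redose
    cc <- concentrationProfile(
      p, data.frame(time = c(0, 4), amount = c(2000, 1000)), tt)
    expect_true(all(diff(cc) < 0))
  }
})
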