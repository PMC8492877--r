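# Target-attainment machinery.

test_that("efficacy threshold converts free MIC to total concentration", {
  expect_identical(efficacyThreshold(4, 0.2), 20)
  expect_identical(efficacyThreshold(4, 1), 4)
  expect_identical(efficacyThreshold(2, 0.2), 10)
  expect_error(efficacyThreshold(4, 0), "unbound")
  expect_error(efficacyThreshold(4, 1.2), "unbound")
})

test_that("population simulation honours variability settings and seed", {
  m <- finalModel()
  s <- regimenScenario(covariates = list(crcl_ckdepi = 90),
                       grid = seq(0, 8, by = 0.25))
  # no variability: every subject is the typical one
  m0 <- m; m0@omega[] <- 0
  cm0 <- simulatePopulation(m0, s, n = 20, seed = 1)
  expect_equal(unname(cm0[1, ]), unname(cm0[20, ]))
  typ <- concentrationProfile(
    individualParameters(m, covariates = list(crcl_ckdepi = 90)),
    s$doses, attr(cm0, "times"))
  expect_equal(unname(cm0[1, ]), typ, tolerance = 1e-12)
  # log-normal ensemble: the median curve tracks the typical curve.
  # Exact equality holds only where a single log-normal factor dominates
  # (e.g. t -> 0, where C = D/Vc e^-eta); with four correlated etas the
  # pointwise median deviates systematically by up to ~4% mid-profile.
  cm <- simulatePopulation(m, s, n = 3e4, seed = 2)
  med <- apply(cm, 2, median)
  expect_lt(max(abs(med - typ) / typ), 0.05)
  expect_lt(abs(med[1] - typ[1]) / typ[1], 0.01)
  expect_identical(simulatePopulation(m, s, n = 50, seed = 3),
                   simulatePopulation(m, s, n = 50, seed = 3))
})

test_that("PTA fractions behave monotonically", {
  m <- finalModel()
  cms <- lapply(c(120, 90, 60, 30), function(crcl) {
    s <- regimenScenario(covariates = list(crcl_ckdepi = crcl),
                         grid = c(0, 2.01, 4))
    simulatePopulation(m, s, n = 2e4, seed = 400 + crcl)
  })
  p4 <- vapply(cms, function(cm) pta(cm, 20, 4)$pta$pta, numeric(1))
  # faster clearance, lower exposure at 4 h
  expect_true(all(diff(p4) >= 0))
  # threshold zero attains everywhere; PTA non-increasing in threshold
  expect_equal(pta(cms[[1]], 0, c(2.01, 4))$pta$pta, c(100, 100))
  for (thr in c(10, 20, 40))
    expect_gte(pta(cms[[1]], thr, 4)$pta$pta,
               pta(cms[[1]], thr + 10, 4)$pta$pta)
  expect_error(pta(cms[[1]], 20, 5), "grid")
})

test_that("toxicity exceedance tracks the 360 mg/L cutoff", {
  m <- finalModel()
  typ <- individualParameters(m, covariates = list(crcl_ckdepi = 80))
  grid <- seq(0, 8, by = 0.005)
  cc <- concentrationProfile(typ, data.frame(time = 0, amount = 2000), grid)
  cm <- matrix(cc, 1, dimnames = NULL)
  attr(cm, "times") <- grid
  tox <- toxicityExceedance(cm, cutoff = 360)
  # 2000 mg into Vc = 5.2 L starts at 384.6 > 360: immediate exceedance
  expect_gt(cc[2], 360)
  expect_gt(tox$durationAbove[1], 0)
  expect_equal(tox$fractionAbove$fraction[2], 1)
  # cutoff above the peak: nothing exceeds
  toxHigh <- toxicityExceedance(cm, cutoff = 500)
  expect_equal(toxHigh$durationAbove[1], 0)
  expect_true(all(toxHigh$fractionAbove$fraction == 0))
})

test_that("regimen comparison orders the toxic duration as reported", {
  m <- finalModel()
  profiles <- data.frame(crcl_ckdepi = c(70, 85, 95, 105, 115),
                         bmi = 37, tbw = 105)
  cr <- compareRegimens(m, profiles)
  s <- cr$summary
  for (i in 1:5) {
    a <- s[s$profile == i & s$regimen == "A", ]
    b <- s[s$profile == i & s$regimen == "B", ]
    # the doubled regimen spends strictly longer above 360 mg/L
    expect_gt(a$durationAboveToxicity, b$durationAboveToxicity)
    # both regimens hold the therapeutic threshold through 4 h
    cva <- cr$curves[cr$curves$profile == i & cr$curves$regimen == "A", ]
    cvb <- cr$curves[cr$curves$profile == i & cr$curves$regimen == "B", ]
    expect_true(all(cva$conc[cva$time <= 4] >= 20))
    expect_true(all(cvb$conc[cvb$time <= 4] >= 20))
  }
  # same initial dose: curves coincide exactly until the redose differs
  crSame <- compareRegimens(
    m, profiles[1, , drop = FALSE],
    regimenA = data.frame(time = c(0, 4), amount = c(2000, 2000)),
    regimenB = data.frame(time = c(0, 4), amount = c(2000, 1000)))
  ca <- crSame$curves[crSame$curves$regimen == "A", ]
  cb <- crSame$curves[crSame$curves$regimen == "B", ]
  expect_equal(ca$conc[ca$time < 4], cb$conc[cb$time < 4])
  expect_true(all(ca$conc[ca$time >= 4] > cb$conc[cb$time >= 4]))
})
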