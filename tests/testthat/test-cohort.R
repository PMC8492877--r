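# Virtual-cohort generator, protocol dosing rule, sampling schedule and
# forward simulation.

test_that("cohort marginals match the study's baseline table", {
  co <- generateCohort(cohortDesign(n = 1000), seed = 1)
  expect_gte(mean(co$age), 64); expect_lte(mean(co$age), 70)
  expect_true(all(co$age >= 24 & co$age <= 91))
  expect_true(all(co$tbw >= 48 & co$tbw <= 123))
  obese <- mean(co$bmi > 30)
  expect_gte(obese, 0.24); expect_lte(obese, 0.34)
  expect_true(all(co$crcl_ckdepi >= 17 & co$crcl_ckdepi <= 129))
  expect_identical(generateCohort(cohortDesign(n = 50), seed = 9),
                   generateCohort(cohortDesign(n = 50), seed = 9))
})

test_that("cohort means converge to the design targets", {
  co <- generateCohort(cohortDesign(n = 1e4), seed = 2)
  relerr <- function(x, target) abs(mean(x) - target) / target
  expect_lt(relerr(co$age, 67), 0.02)
  expect_lt(relerr(co$tbw, 76), 0.02)
  expect_lt(relerr(co$crcl_ckdepi, 83), 0.02)
  expect_lt(relerr(co$duration, 1.16), 0.02)
  expect_lt(relerr(co$delay, 0.85), 0.02)
  expect_error(generateCohort(cohortDesign(n = 10, ageRange = c(91, 24))),
               "ageRange")
})

test_that("protocol dosing implements the doubling and redosing rules", {
  # doubling needs BOTH BMI > 35 and TBW > 100
  expect_equal(protocolDoses(36, 105, 1.2),
               data.frame(time = 0, amount = 4000))
  expect_equal(protocolDoses(36, 95, 1.2),
               data.frame(time = 0, amount = 2000))
  expect_equal(protocolDoses(33, 110, 1.2),
               data.frame(time = 0, amount = 2000))
  # redosing at 4 h from injection, half the initial dose
  long <- protocolDoses(27, 80, 4.5)
  expect_equal(long, data.frame(time = c(0, 4), amount = c(2000, 1000)))
  expect_equal(sum(long$amount), 3000)
  expect_equal(protocolDoses(36, 105, 4.5)$amount, c(4000, 2000))
  # pure function: same inputs, same doses
  expect_identical(protocolDoses(27, 80, 4.5), protocolDoses(27, 80, 4.5))
  expect_error(protocolDoses(25, 70, -1), "after the injection")
})

test_that("sampling schedule includes end-of-surgery and deduplicates", {
  expect_equal(samplingTimes(0.85, 1.16), c(0.05, 1 / 3, 2.01, 3, 8))
  expect_length(samplingTimes(1.5, 1.5), 4)  # closure at exactly 3 h
  expect_error(samplingTimes(0.5, 0), "after incision")
})

test_that("simulated datasets respect the design and the noise model", {
  d <- cohortDesign(n = 100)
  dat <- simulateStudy(d, finalModel(), seed = 5)
  r <- eventRecords(dat)
  nObs <- sum(r$EVID == 0)
  expect_gte(nObs, 460); expect_lte(nObs, 510)  # study acquired 484
  expect_true(all(r$BLQ[r$EVID == 0] == (r$DV[r$EVID == 0] < 5)))
  expect_true(validObject(dat))
  # noise-free, variability-free simulation reproduces the typical curves
  m0 <- popPKModel(2, c(cl = 2.86, vc = 5.2, q = 10.9, vp = 4.56),
                   covariates = list(candidateCovariate(
                     "crcl_ckdepi", "cl", center = 80, coef = 0.79)),
                   errB = 1e-12)
  co <- generateCohort(cohortDesign(n = 5), seed = 6)
  co$delay <- 1; co$duration <- 1
  dat0 <- simulateDataset(co, m0, d, seed = 7)
  r0 <- eventRecords(dat0)
  for (i in 1:5) {
    p <- individualParameters(m0, covariates = co[i, , drop = FALSE])
    obs <- r0[r0$ID == i & r0$EVID == 0, ]
    expect_equal(obs$DV,
                 concentrationProfile(p, data.frame(time = 0, amount = 2000),
                                      obs$TIME),
                 tolerance = 1e-6)
  }
})

test_that("few records fall below the LLOQ for median-renal-function subjects", {
  co <- generateCohort(cohortDesign(n = 2000), seed = 8)
  mid <- co[co$crcl_ckdepi > 70 & co$crcl_ckdepi < 95, ]
  dat <- simulateDataset(mid, finalModel(), cohortDesign(), seed = 9)
  r <- eventRecords(dat)
  late <- r[r$EVID == 0 & r$TIME == 8, ]
  expect_lt(mean(late$BLQ), 0.05)
})
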