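# pcVPC, NPDE and goodness-of-fit diagnostics.

# Dataset with every subject identical (same covariates, doses, times):
# prediction correction must then be the identity within each bin.
test_that("prediction correction is a no-op for a homogeneous design", {
  m <- finalModel()
  co <- generateCohort(cohortDesign(n = 20), seed = 1)
  co[, c("age", "tbw", "bmi", "scr", "crcl_cg", "crcl_ckdepi", "lbw")] <-
    lapply(co[, c("age", "tbw", "bmi", "scr", "crcl_cg", "crcl_ckdepi",
                  "lbw")], function(x) rep(x[1], nrow(co)))
  co$sex <- co$sex[1]; co$delay <- 0.9; co$duration <- 1.1
  dat <- simulateDataset(co, m, cohortDesign(), seed = 2)
  v <- pcVpc(dat, m, nSim = 120, seed = 3)
  r <- eventRecords(dat)
  obs <- r$DV[r$EVID == 0 & r$BLQ == 0]
  expect_equal(sort(v$obs$pcObs), sort(obs), tolerance = 1e-12)
  # and disabling the correction gives the same plain percentiles
  v0 <- pcVpc(dat, m, nSim = 120, seed = 3, predictionCorrected = FALSE)
  expect_equal(v$bins$obs50, v0$bins$obs50, tolerance = 1e-12)
})

test_that("observed percentiles fall inside the simulated bands under the true model", {
  # Each percentile falls in its 90% band with 90% marginal probability,
  # but the checks within one dataset are correlated (the same extreme
  # subjects move every bin), so calibration is judged on the aggregate
  # coverage over replicate datasets.
  m <- finalModel()
  cov <- vapply(1:6, function(s) {
    dat <- smallStudy(n = 80, seed = s)
    b <- pcVpc(dat, m, nSim = 300, seed = 1000 + s)$bins
    stopifnot(all(b$obs05 <= b$obs50 & b$obs50 <= b$obs95))
    mean(c(b$obs05 >= b$sim05lo & b$obs05 <= b$sim05hi,
           b$obs50 >= b$sim50lo & b$obs50 <= b$sim50hi,
           b$obs95 >= b$sim95lo & b$obs95 <= b$sim95hi))
  }, numeric(1))
  expect_gte(mean(cov), 0.75)
  expect_equal(formals(pcVpc)$nSim, 1000)  # default replicate count
})

test_that("NPDE are calibrated under the true model and detect misfit", {
  m <- finalModel()
  dat <- smallStudy(n = 80, seed = 6)
  nd <- npde(dat, m, nSim = 1000, seed = 7)
  n <- nrow(nd)
  expect_lt(abs(mean(nd$npde)), 3 / sqrt(n))
  expect_lt(abs(var(nd$npde) - 1), 3 * sqrt(2 / (n - 1)))
  # deliberately halved clearance: strong, detectable bias
  bad <- m
  bad@theta["cl"] <- m@theta["cl"] / 2
  ndBad <- npde(dat, bad, nSim = 1000, seed = 7)
  # under the five-point schedule two early samples carry no clearance
  # signal, diluting the global mean; the bias is still decisive
  expect_gt(abs(mean(ndBad$npde)), 0.75)
  expect_lt(suppressWarnings(stats::ks.test(ndBad$npde, "pnorm"))$p.value,
            1e-10)
  # reproducible given the seed
  expect_identical(nd, npde(dat, m, nSim = 1000, seed = 7))
})

test_that("NPDE null distribution passes repeated normality screening", {
  m <- finalModel()
  pass <- 0
  for (rep in 1:10) {
    dat <- smallStudy(n = 60, seed = 70 + rep)
    nd <- npde(dat, m, nSim = 600, seed = rep)
    p <- suppressWarnings(stats::ks.test(nd$npde, "pnorm")$p.value)
    if (p > 0.01) pass <- pass + 1
  }
  expect_gte(pass, 9)
})

test_that("single-observation subjects reduce to the marginal quantile", {
  m <- popPKModel(1, c(cl = 3, vc = 5), omega = c(cl = 0.3, vc = 0.2),
                  errB = 0.1)
  rec <- do.call(rbind, lapply(1:40, function(i)
    data.frame(ID = i, TIME = c(0, 2), EVID = c(1, 0), AMT = c(2000, NA),
               DV = c(NA, 80 + 12 * i), MDV = c(1, 0))))
  dat <- eventDataset(rec, data.frame(id = 1:40, crcl_ckdepi = 80))
  nd <- npde(dat, m, nSim = 800, seed = 9)
  # with one observation there is no decorrelation: the npde is a plain
  # normal score, monotone in the observed value for a shared design
  expect_true(all(diff(nd$npde[order(nd$ID)]) >= 0))
  expect_true(all(abs(nd$npde) < qnorm(1 - 1 / 1600) + 1e-9))
})

test_that("GOF table reconciles PRED, IPRED and the observations", {
  # no variability, (numerically) no noise: OBS = IPRED = PRED
  m0 <- popPKModel(2, c(cl = 2.86, vc = 5.2, q = 10.9, vp = 4.56),
                   errB = 1e-12)
  co <- generateCohort(cohortDesign(n = 8), seed = 10)
  dat <- simulateDataset(co, m0, cohortDesign(), seed = 11)
  fit <- new("PKFit", model = m0, data = dat, logLik = NA_real_,
             logLikSE = NA_real_, bic = NA_real_, nParams = 0,
             ebes = empiricalBayes(data = dat, model = m0),
             shrinkage = setNames(numeric(0), character(0)),
             rse = setNames(numeric(0), character(0)),
             trace = matrix(0, 0, 0), control = list(), converged = TRUE,
             messages = character(0))
  g <- gofTable(fit, nSim = 500, seed = 12)
  expect_equal(g$PRED, g$IPRED, tolerance = 1e-9)
  expect_equal(g$OBS, g$IPRED, tolerance = 1e-6)
  # a well-specified fit regresses observed on IPRED with slope near 1
  m <- finalModel()
  dat2 <- smallStudy(n = 50, seed = 13)
  fit2 <- saemFit(dat2, m, quickControl(seed = 4), computeLL = FALSE)
  g2 <- gofTable(fit2, nSim = 500, seed = 14)
  sl <- unname(coef(lm(OBS ~ 0 + IPRED, data = g2))[1])
  expect_gt(sl, 0.9); expect_lt(sl, 1.1)
  # plots assemble without error
  expect_s3_class(plotGof(g2), "ggplot")
  expect_s3_class(plotNpde(g2), "ggplot")
  expect_s3_class(plotVpc(pcVpc(dat2, m, nSim = 120, seed = 15)), "ggplot")
})
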