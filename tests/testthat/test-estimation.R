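# SAEM engine, marginal likelihood, empirical Bayes estimates and
# shrinkage.

test_that("BIC arithmetic follows the subject-count convention", {
  expect_equal(bic(-50, 3, 100), 100 + 3 * log(100))
  expect_equal(bic(-50, 3, 100), 113.8155, tolerance = 1e-6)
  expect_equal(bic(-50, 0, 100), 100)
  expect_error(bic(-50, 3, 0))
})

test_that("two SAEM runs with the same seed are bit-identical", {
  dat <- smallStudy(n = 20, seed = 1)
  ctl <- saemControl(nBurn = 40, nSmooth = 30, nKernel = 2, nIS = 500,
                     seed = 77)
  f1 <- saemFit(dat, finalModel(), ctl)
  f2 <- saemFit(dat, finalModel(), ctl)
  expect_identical(f1@trace, f2@trace)
  expect_identical(f1@logLik, f2@logLik)
  expect_identical(f1@ebes, f2@ebes)
})

test_that("near-zero variability fits agree with a pooled NLS oracle", {
  skip_if_not_installed("minpack.lm")
  # one-compartment data with no between-subject variability
  gen <- popPKModel(1, c(cl = 3, vc = 5), errB = 0.1)
  co <- generateCohort(cohortDesign(n = 30), seed = 4)
  dat <- simulateDataset(co, gen, cohortDesign(), seed = 5)
  fit <- saemFit(dat, gen, saemControl(nBurn = 150, nSmooth = 100,
                                       nKernel = 3, seed = 2),
                 computeLL = FALSE)
  expect_lt(max(as.numeric(omegaSd(fit))), 0.06)
  # pooled weighted NLS on the same records (proportional weights)
  r <- eventRecords(dat)
  obs <- r[r$EVID == 0 & r$BLQ == 0, ]
  doseOf <- r[r$EVID == 1, ][match(obs$ID, r$ID[r$EVID == 1]), "AMT"]
  nls <- minpack.lm::nlsLM(
    DV ~ dose / vc * exp(-cl / vc * TIME),
    data = cbind(obs, dose = doseOf),
    start = list(cl = 2, vc = 4),
    weights = 1 / pmax(obs$DV, 1)^2)
  est <- coef(nls)
  expect_equal(unname(fixedEffects(fit)["cl"]), unname(est["cl"]),
               tolerance = 0.03)
  expect_equal(unname(fixedEffects(fit)["vc"]), unname(est["vc"]),
               tolerance = 0.03)
})

test_that("marginal likelihood is exact without random effects", {
  # one subject, one observation, one compartment, omega = 0:
  # the marginal density is the plain Gaussian density
  m <- popPKModel(1, c(cl = 3, vc = 5), errB = 0.1)
  rec <- data.frame(ID = 1, TIME = c(0, 1), EVID = c(1, 0),
                    AMT = c(2000, NA), DV = c(NA, 350), MDV = c(1, 0))
  dat <- eventDataset(rec, data.frame(id = 1))
  ll <- computeLogLik(data = dat, model = m, nSamples = 10)
  f <- concentrationProfile(pkParameters(3, 5),
                            data.frame(time = 0, amount = 2000), 1)
  expect_equal(ll$logLik, dnorm(350, f, 0.1 * f, log = TRUE))
  expect_equal(ll$se, 0)
})

test_that("marginal likelihood matches a quadrature oracle", {
  # 1-compartment, etas on CL and Vc: compare importance sampling against
  # 2-D Gauss-Hermite quadrature (Golub-Welsch nodes, independent path)
  m <- popPKModel(1, c(cl = 3, vc = 5), omega = c(cl = 0.3, vc = 0.25),
                  corr = 0.5, errB = 0.1)
  co <- generateCohort(cohortDesign(n = 4), seed = 11)
  dat <- simulateDataset(co, m, cohortDesign(), seed = 12)
  ll <- computeLogLik(data = dat, model = m, nSamples = 20000, seed = 3)

  gh <- function(k) {  # Golub-Welsch for exp(-x^2) weight
    J <- diag(0, k)
    for (j in seq_len(k - 1)) J[j, j + 1] <- J[j + 1, j] <- sqrt(j / 2)
    e <- eigen(J, symmetric = TRUE)
    list(x = e$values, w = sqrt(pi) * e$vectors[1, ]^2)
  }
  nd <- gh(40)
  S <- cefapk:::.omegaMatrix(m@omega, m@corr)
  Sinv <- solve(S)
  r <- eventRecords(dat)
  oracle <- 0
  for (id in unique(r$ID)) {
    obs <- r[r$ID == id & r$EVID == 0 & r$BLQ == 0, ]
    dose <- r[r$ID == id & r$EVID == 1, ]
    logg <- function(eta) {  # log of likelihood x prior
      p <- pkParameters(3 * exp(eta[1]), 5 * exp(eta[2]))
      f <- concentrationProfile(p, data.frame(time = dose$TIME,
                                              amount = dose$AMT), obs$TIME)
      sum(dnorm(obs$DV, f, 0.1 * f, log = TRUE)) -
        0.5 * drop(eta %*% Sinv %*% eta) - log(2 * pi) -
        0.5 * determinant(S)$modulus
    }
    # the integrand is far more peaked than the prior: centre and scale
    # the quadrature at its own mode (plain change of variables)
    opt <- optim(c(0, 0), function(e) -logg(e))
    h <- 1e-4
    H <- matrix(0, 2, 2)
    for (a in 1:2) for (b2 in 1:2) {
      ea <- eb <- c(0, 0); ea[a] <- h; eb[b2] <- h
      H[a, b2] <- (logg(opt$par + ea + eb) - logg(opt$par + ea - eb) -
                   logg(opt$par - ea + eb) + logg(opt$par - ea - eb)) /
        (4 * h^2)
    }
    A <- t(chol(solve(-H)))
    gsum <- 0
    for (i1 in seq_along(nd$x)) for (i2 in seq_along(nd$x)) {
      x <- c(nd$x[i1], nd$x[i2])
      eta <- opt$par + sqrt(2) * drop(A %*% x)
      gsum <- gsum + nd$w[i1] * nd$w[i2] *
        exp(logg(eta) + sum(x^2))
    }
    oracle <- oracle + log(gsum * 2 * det(A))
  }
  expect_lt(abs(ll$logLik - oracle), max(3 * ll$se, 0.02))
})

test_that("Monte-Carlo error shrinks like one over root sample size", {
  m <- finalModel()
  dat <- smallStudy(n = 15, seed = 21)
  ll1 <- computeLogLik(data = dat, model = m, nSamples = 1000, seed = 1)
  ll2 <- computeLogLik(data = dat, model = m, nSamples = 4000, seed = 1)
  expect_lt(ll2$se, ll1$se)
  expect_lt(abs(ll1$logLik - ll2$logLik), 4 * (ll1$se + ll2$se))
  expect_gt(ll1$se / ll2$se, 1.3)  # expect about 2
  expect_lt(ll1$se / ll2$se, 3)
})

test_that("empirical Bayes modes behave at both information extremes", {
  # all observations below the limit of quantification: prior mode 0
  m <- popPKModel(1, c(cl = 3, vc = 5), omega = c(cl = 0.3, vc = 0.3),
                  errB = 0.1)
  rec <- data.frame(ID = c(1, 1, 2, 2), TIME = c(0, 8, 0, 1),
                    EVID = c(1, 0, 1, 0), AMT = c(2000, NA, 2000, NA),
                    DV = c(NA, 2, NA, 300), MDV = c(1, 0, 1, 0))
  dat <- eventDataset(rec, data.frame(id = 1:2), lloq = 5)
  eb <- suppressWarnings(empiricalBayes(data = dat, model = m))
  expect_equal(unname(eb[1, ]), c(0, 0))
  expect_false(all(eb[2, ] == 0))

  # rich data + diffuse prior: the mode approaches the individual NLS fit
  skip_if_not_installed("minpack.lm")
  truth <- pkParameters(4.2, 6.1)
  tt <- c(0.1, 0.25, 0.5, 1, 1.5, 2, 3, 4, 5, 6, 7, 8)
  f <- concentrationProfile(truth, data.frame(time = 0, amount = 2000), tt)
  set.seed(31)
  y <- f * (1 + 0.05 * rnorm(length(tt)))
  rec <- rbind(data.frame(ID = 1, TIME = 0, EVID = 1, AMT = 2000,
                          DV = NA, MDV = 1),
               data.frame(ID = 1, TIME = tt, EVID = 0, AMT = NA, DV = y,
                          MDV = 0))
  dat <- eventDataset(rec, data.frame(id = 1))
  mDiffuse <- popPKModel(1, c(cl = 3, vc = 5),
                         omega = c(cl = 2, vc = 2), errB = 0.05)
  eb <- empiricalBayes(data = dat, model = mDiffuse)
  nls <- minpack.lm::nlsLM(y ~ 2000 / vc * exp(-cl / vc * tt),
                           start = list(cl = 3, vc = 5),
                           weights = 1 / f^2)
  expect_equal(3 * exp(eb[1, "cl"]), unname(coef(nls)["cl"]),
               tolerance = 0.02)
  expect_equal(5 * exp(eb[1, "vc"]), unname(coef(nls)["vc"]),
               tolerance = 0.02)
})

test_that("shrinkage formula covers its boundary cases", {
  om <- c(cl = 0.3, vc = 0.4)
  eb <- cbind(cl = c(-0.3, 0.3), vc = c(0, 0))
  res <- shrinkagePct(eb, om)
  expect_equal(unname(res["vc"]), 100)       # all modes at zero
  eb2 <- cbind(cl = c(-0.3, 0.3) * sqrt(1 / 2), vc = c(-0.4, 0.4) *
                 sqrt(1 / 2))
  expect_equal(unname(shrinkagePct(eb2, om)), c(0, 0), tolerance = 1e-9)
  expect_true(is.na(shrinkagePct(eb, c(cl = 0, vc = 0.4))["cl"]))
})

test_that("standard errors have the magnitude expected for this design", {
  dat <- smallStudy(n = 60, seed = 41)
  fit <- saemFit(dat, finalModel(), fitControl(seed = 6), computeLL = FALSE)
  fit <- fitStandardErrors(fit, nSamples = 400, seed = 2)
  rse <- fit@rse
  expect_true(all(is.finite(rse[c("log_theta_cl", "log_theta_vc")])))
  # reported study-scale orders: a few percent on CL, tens at most
  expect_lt(rse["log_theta_cl"], 15)
  expect_gt(rse["log_theta_cl"], 0.5)
  expect_lt(rse["beta_crcl_ckdepi_cl"], 60)
})
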