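# Stochastic approximation EM for the nonlinear mixed-effects model.
#
# Individual log-parameters phi_i = B_i beta + eta_i with eta_i ~ N(0,
# Omega); Omega is diagonal apart from the CL-Vc covariance. Observations
# y_ij = f(t_ij, exp(phi_i)) + (a + b f) eps. The E-step samples phi_i by
# Metropolis-within-Gibbs (an independent proposal from the conditional
# prior plus componentwise random walks with adapted scales); the M-step
# updates beta by generalised least squares on stochastically approximated
# sufficient statistics, Omega by the approximated second moments projected
# onto the block structure, and the error parameters from approximated
# residual statistics. Variances are annealed during the exploration phase
# (they may shrink by at most a fixed factor per iteration) so the chain
# explores before the step size decays.

#' SAEM settings
#'
#' @param nBurn Exploration-phase iterations (step size 1, annealing on).
#' @param nSmooth Smoothing-phase iterations (step size `k^-stepExponent`).
#' @param nKernel MCMC kernel transitions per SAEM iteration.
#' @param stepExponent Exponent of the phase-2 step-size decay, in (0.5, 1].
#' @param anneal Per-iteration variance floor factor during exploration.
#' @param nIS Importance samples for the marginal log-likelihood.
#' @param seed Integer seed controlling the whole fit.
#' @param rwInit Initial componentwise random-walk SD.
#' @param targetAccept Target acceptance rate for random-walk adaptation.
#' @return A settings list consumed by [saemFit()].
#' @export
saemControl <- function(nBurn = 300, nSmooth = 200, nKernel = 5,
                        stepExponent = 0.7, anneal = 0.95, nIS = 5000,
                        seed = 12345, rwInit = 0.25, targetAccept = 0.4) {
  stopifnot(nBurn > 0, nSmooth > 0, nKernel > 0,
            stepExponent > 0, stepExponent <= 1, anneal > 0, anneal < 1)
  list(nBurn = as.integer(nBurn), nSmooth = as.integer(nSmooth),
       nKernel = as.integer(nKernel), stepExponent = stepExponent,
       anneal = anneal, nIS = as.integer(nIS), seed = as.integer(seed),
       rwInit = rwInit, targetAccept = targetAccept)
}

# Flattened fitting structures shared by the SAEM loop, the EBE optimizer
# and the likelihood estimator. BLQ observations are excluded from the
# likelihood (their count is reported).
.prepareFit <- function(data, model) {
  r <- data@records
  ids <- unique(r$ID)
  covdf <- data@covariates[match(ids, data@covariates$id), , drop = FALSE]
  obs <- r[r$EVID == 0 & r$BLQ == 0 & !is.na(r$DV), ]
  nBLQ <- sum(r$EVID == 0 & (r$BLQ == 1 | is.na(r$DV)))
  dose <- r[r$EVID == 1, ]
  subjOf <- function(id) match(id, ids)
  obsSubj <- subjOf(obs$ID)
  pairs <- .makePairs(obsSubj, obs$TIME, subjOf(dose$ID), dose$TIME, dose$AMT)
  if (any(tabulate(obsSubj, length(ids)) == 0))
    warning("subject(s) without quantifiable observations contribute only ",
            "their prior", call. = FALSE)
  list(ids = ids, n = length(ids), covdf = covdf,
       y = obs$DV, obsSubj = obsSubj, obsTime = obs$TIME,
       nObs = nrow(obs), pairs = pairs, nBLQ = nBLQ)
}

# Design array B (n x P x nBeta): intercept per structural parameter plus
# one column per covariate link. Returns the array, coefficient names and
# the index of each parameter's intercept.
.designArray <- function(model, covdf) {
  sn <- .structNames(model@nComp)
  P <- length(sn)
  n <- nrow(covdf)
  links <- model@covariates
  nBeta <- P + length(links)
  B <- array(0, c(n, P, nBeta))
  for (p in seq_len(P)) B[, p, p] <- 1
  betaNames <- paste0("log_theta_", sn)
  for (l in seq_along(links)) {
    lk <- links[[l]]
    x <- vapply(seq_len(n),
                function(i) .linkValue(lk, covdf[i, , drop = FALSE]),
                numeric(1))
    B[, match(lk$param, sn), P + l] <- x
    betaNames <- c(betaNames, paste0("beta_", lk$cov, "_", lk$param))
  }
  list(B = B, betaNames = betaNames, interceptIdx = seq_len(P), nBeta = nBeta)
}

# NCA-style starting values: Vc from dose/Cmax, CL from a crude
# trapezoid-plus-tail AUC, distribution parameters from those.
.initTheta <- function(prep, nComp) {
  n <- prep$n
  vcs <- cls <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    sel <- prep$obsSubj == i
    tt <- prep$obsTime[sel]; yy <- prep$y[sel]
    if (!length(yy)) next
    pr <- prep$pairs[prep$pairs[, "subj"] == i, , drop = FALSE]
    d1 <- pr[which.min(pr[, "dt"]), "amt"]
    vcs[i] <- d1 / max(yy)
    o <- order(tt); tt <- tt[o]; yy <- yy[o]
    auc <- sum(diff(tt) * (head(yy, -1) + tail(yy, -1)) / 2)
    m <- length(yy)
    lz <- if (m >= 2 && yy[m] > 0 && yy[m - 1] > yy[m])
      log(yy[m - 1] / yy[m]) / (tt[m] - tt[m - 1]) else 0.2
    lz <- max(lz, 0.02)
    auc <- auc + yy[m] / lz
    cls[i] <- sum(pr[, "amt"]) / auc
  }
  cl <- median(cls, na.rm = TRUE); vc <- median(vcs, na.rm = TRUE)
  th <- c(cl = cl, vc = vc)
  if (nComp >= 2) th <- c(th, q = cl, vp = vc)
  if (nComp >= 3) th <- c(th, q2 = cl / 2, vp2 = 2 * vc)
  th
}

# Observation log-likelihood per subject for a phi matrix.
.llObs <- function(phi, prep, nComp, a, b) {
  f <- .concBatch(exp(phi), nComp, prep$pairs, prep$nObs)
  sig <- pmax(a + b * f, 1e-10)
  ll <- -log(sig) - 0.5 * ((prep$y - f) / sig)^2
  ll[!is.finite(ll)] <- -Inf  # overflowing parameter proposals
  out <- numeric(nrow(phi))
  agg <- rowsum(ll, prep$obsSubj)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

.priorQuad <- function(phi, Mu, U) {
  # U = chol(Omega); returns the quadratic form per subject
  z <- forwardsolve(t(U), t(phi - Mu))
  colSums(z^2)
}

#' Fit a population PK model by SAEM
#'
#' Maximum-likelihood estimation of the nonlinear mixed-effects model by
#' stochastic approximation EM, followed by empirical Bayes estimation,
#' importance-sampling evaluation of the marginal log-likelihood, BIC and
#' eta shrinkage. The run is fully reproducible from `control$seed`.
#'
#' @param data A [PKEventData-class]. Records below the limit of
#'   quantification are excluded from the likelihood (count logged).
#' @param model A [PopPKModel-class] giving the structure (compartments,
#'   covariate links, error components): nonzero `errA`/`errB` select the
#'   additive/proportional error components to estimate.
#' @param control [saemControl()] settings.
#' @param autoInit If `TRUE` (default) starting typical values come from
#'   model-free concentration heuristics; if `FALSE`, from `model@theta`.
#' @param computeLL Evaluate the importance-sampling log-likelihood and
#'   BIC (default `TRUE`).
#' @return A [PKFit-class] object.
#' @examples
#' \donttest{
#' d <- cohortDesign(n = 30)
#' dat <- simulateStudy(d, cefazolinFinalModel(), seed = 1)
#' fit <- saemFit(dat, cefazolinFinalModel(),
#'                saemControl(nBurn = 60, nSmooth = 40, nKernel = 2))
#' fit
#' }
#' @export
saemFit <- function(data, model, control = saemControl(), autoInit = TRUE,
                    computeLL = TRUE) {
  stopifnot(is(data, "PKEventData"), is(model, "PopPKModel"))
  set.seed(control$seed)
  nComp <- model@nComp
  sn <- .structNames(nComp)
  P <- length(sn)
  prep <- .prepareFit(data, model)
  n <- prep$n
  des <- .designArray(model, prep$covdf)

  estA <- model@errA > 0
  estB <- model@errB > 0
  a <- if (estA) max(model@errA, 0.5) else 0
  b <- if (estB) 0.2 else 0

  theta0 <- if (autoInit) .initTheta(prep, nComp) else model@theta
  beta <- numeric(des$nBeta)
  beta[des$interceptIdx] <- log(theta0)
  for (l in seq_along(model@covariates))
    beta[P + l] <- model@covariates[[l]]$coef
  names(beta) <- des$betaNames

  omega2 <- rep(0.3^2, P)
  corr <- 0
  estCorr <- P >= 2

  muOf <- function(beta) {
    Mu <- matrix(0, n, P)
    for (p in seq_len(P))
      Mu[, p] <- des$B[, p, , drop = TRUE] %*% beta
    Mu
  }
  Mu <- muOf(beta)
  phi <- Mu

  Omega <- .omegaMatrix(sqrt(omega2), corr)
  U <- .safeChol(Omega)
  llY <- .llObs(phi, prep, nComp, a, b)

  # stochastic-approximation state
  sPhi <- phi
  sPhiPhi <- array(0, c(n, P, P))
  for (p in seq_len(P)) for (q in seq_len(P))
    sPhiPhi[, p, q] <- phi[, p] * phi[, q]
  sErr <- sum(((prep$y - 0) / 1)^2)  # overwritten on first iteration
  sF <- rep(0, prep$nObs); sR2 <- rep(0, prep$nObs)
  firstStat <- TRUE

  rw <- rep(control$rwInit, P)
  K <- control$nBurn + control$nSmooth
  traceNames <- c(des$betaNames, paste0("omega_", sn),
                  if (estCorr) "corr_cl_vc", if (estA) "err_a",
                  if (estB) "err_b")
  trace <- matrix(NA_real_, K, length(traceNames),
                  dimnames = list(NULL, traceNames))

  for (k in seq_len(K)) {
    burn <- k <= control$nBurn
    gamma <- if (burn) 1 else (k - control$nBurn)^(-control$stepExponent)

    accRW <- numeric(P)
    for (tr in seq_len(control$nKernel)) {
      # kernel 1: independent proposal from the conditional prior
      phiP <- Mu + matrix(rnorm(n * P), n, P) %*% U
      llP <- .llObs(phiP, prep, nComp, a, b)
      acc <- log(runif(n)) < llP - llY
      phi[acc, ] <- phiP[acc, ]
      llY[acc] <- llP[acc]
      # kernel 2: componentwise random walk
      quad <- .priorQuad(phi, Mu, U)
      for (p in seq_len(P)) {
        phiP <- phi
        phiP[, p] <- phiP[, p] + rw[p] * rnorm(n)
        llP <- .llObs(phiP, prep, nComp, a, b)
        quadP <- .priorQuad(phiP, Mu, U)
        acc <- log(runif(n)) < (llP - 0.5 * quadP) - (llY - 0.5 * quad)
        phi[acc, ] <- phiP[acc, ]
        llY[acc] <- llP[acc]
        quad[acc] <- quadP[acc]
        accRW[p] <- accRW[p] + mean(acc)
      }
    }
    if (burn) {
      rate <- accRW / control$nKernel
      rw <- pmin(pmax(rw * exp(0.4 * (rate - control$targetAccept)),
                      0.01), 2)
    }

    # stochastic approximation of sufficient statistics
    g <- if (firstStat) 1 else gamma
    firstStat <- FALSE
    sPhi <- sPhi + g * (phi - sPhi)
    for (p in seq_len(P)) for (q in seq_len(P))
      sPhiPhi[, p, q] <- sPhiPhi[, p, q] + g * (phi[, p] * phi[, q] -
                                                sPhiPhi[, p, q])
    f <- .concBatch(exp(phi), nComp, prep$pairs, prep$nObs)
    res2 <- (prep$y - f)^2
    if (estB && !estA)
      sErr <- sErr + g * (sum(res2 / pmax(f, 1e-10)^2) - sErr)
    else if (estA && !estB)
      sErr <- sErr + g * (sum(res2) - sErr)
    else {
      sF <- sF + g * (f - sF)
      sR2 <- sR2 + g * (res2 - sR2)
    }

    # M-step: GLS for beta given Omega
    W <- chol2inv(U)
    A <- matrix(0, des$nBeta, des$nBeta)
    rhs <- numeric(des$nBeta)
    for (i in seq_len(n)) {
      Bi <- matrix(des$B[i, , ], P, des$nBeta)
      WB <- W %*% Bi
      A <- A + crossprod(Bi, WB)
      rhs <- rhs + crossprod(WB, sPhi[i, ])
    }
    beta <- drop(solve(A, rhs))
    Mu <- muOf(beta)

    # Omega from approximated second moments, projected to the block
    # structure (diagonal + CL-Vc term)
    Om <- matrix(0, P, P)
    for (p in seq_len(P)) for (q in seq_len(P))
      Om[p, q] <- mean(sPhiPhi[, p, q] - sPhi[, p] * Mu[, q] -
                       Mu[, p] * sPhi[, q] + Mu[, p] * Mu[, q])
    d2 <- pmax(diag(Om), 1e-10)
    if (burn) d2 <- pmax(d2, control$anneal * omega2)
    omega2 <- d2
    if (estCorr) {
      corr <- Om[1, 2] / sqrt(Om[1, 1] * Om[2, 2])
      corr <- min(max(corr, -0.98), 0.98)
    }
    Omega <- .omegaMatrix(sqrt(omega2), corr)
    U <- .safeChol(Omega)

    # error model
    if (estB && !estA) {
      b2 <- sErr / prep$nObs
      if (burn) b2 <- max(b2, control$anneal * b^2)
      b <- sqrt(b2)
    } else if (estA && !estB) {
      a2 <- sErr / prep$nObs
      if (burn) a2 <- max(a2, control$anneal * a^2)
      a <- sqrt(a2)
    } else {
      nll <- function(lp) {
        s <- exp(lp[1]) + exp(lp[2]) * sF
        sum(log(s) + 0.5 * sR2 / s^2)
      }
      op <- optim(c(log(max(a, 1e-3)), log(max(b, 1e-3))), nll,
                  method = "Nelder-Mead")
      aN <- exp(op$par[1]); bN <- exp(op$par[2])
      if (burn) {
        aN <- sqrt(max(aN^2, control$anneal * a^2))
        bN <- sqrt(max(bN^2, control$anneal * b^2))
      }
      a <- aN; b <- bN
    }

    # likelihood terms change with the new population parameters
    llY <- .llObs(phi, prep, nComp, a, b)
    trace[k, ] <- c(beta, sqrt(omega2), if (estCorr) corr,
                    if (estA) a, if (estB) b)
  }

  theta <- setNames(exp(beta[des$interceptIdx]), sn)
  links <- model@covariates
  for (l in seq_along(links)) links[[l]]$coef <- unname(beta[P + l])
  fitModel <- popPKModel(nComp, theta, covariates = links,
                         omega = setNames(sqrt(omega2), sn), corr = corr,
                         errA = a, errB = b)
  nParams <- des$nBeta + P + (if (estCorr) 1 else 0) + estA + estB

  msgs <- character(0)
  if (prep$nBLQ > 0)
    msgs <- sprintf("%d observation(s) below LLOQ excluded from the likelihood",
                    prep$nBLQ)

  fit <- new("PKFit", model = fitModel, data = data,
             logLik = NA_real_, logLikSE = NA_real_, bic = NA_real_,
             nParams = nParams, ebes = matrix(0, 0, 0),
             shrinkage = setNames(numeric(0), character(0)),
             rse = setNames(rep(NA_real_, length(traceNames)), traceNames),
             trace = trace, control = control, converged = TRUE,
             messages = msgs)
  fit@ebes <- empiricalBayes(fit)
  fit@shrinkage <- .shrinkageFromEbes(fit@ebes, fitModel@omega)
  if (computeLL) {
    ll <- computeLogLik(fit, nSamples = control$nIS,
                        seed = control$seed + 7L)
    fit@logLik <- ll$logLik
    fit@logLikSE <- ll$se
    fit@bic <- bic(ll$logLik, nParams, n)
  }
  fit
}
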