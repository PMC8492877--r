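# Marginal likelihood, empirical Bayes estimates, shrinkage, BIC and
# standard errors.

#' Bayesian information criterion
#'
#' `-2 logL + k log(N)` with `N` the number of subjects (the mixed-model
#' convention: subjects, not observations, are the independent sampling
#' units).
#'
#' @param logLik Maximised (estimated) log-likelihood.
#' @param nParams Number of estimated parameters `k`.
#' @param nSubjects Number of subjects `N`.
#' @return The BIC (lower is better).
#' @examples
#' bic(-50, 3, 100)  # 113.8155
#' @export
bic <- function(logLik, nParams, nSubjects) {
  stopifnot(nParams >= 0, nSubjects >= 1)
  -2 * logLik + nParams * log(nSubjects)
}

# Joint negative log density of (y_i, eta) for one subject, on the free
# eta coordinates (components with omega ~ 0 are pinned at zero).
.makeSubjectObjective <- function(prep, model, i, free = NULL) {
  nComp <- model@nComp
  P <- length(model@omega)
  sel <- prep$obsSubj == i
  y <- prep$y[sel]
  pr <- prep$pairs[prep$pairs[, "subj"] == i, , drop = FALSE]
  pr[, "obs"] <- match(pr[, "obs"], which(sel))
  pr[, "subj"] <- 1
  mu <- .muMatrix(model, prep$covdf[i, , drop = FALSE])
  if (is.null(free)) free <- model@omega > 1e-6
  nFree <- sum(free)
  if (nFree > 0) {
    Om <- .omegaMatrix(model@omega[free], if (sum(free[1:2]) == 2)
      model@corr else 0)
    Winv <- chol2inv(.safeChol(Om))
    ldet <- as.numeric(determinant(Om, logarithm = TRUE)$modulus)
  } else {
    Winv <- matrix(0, 0, 0); ldet <- 0
  }
  a <- model@errA; b <- model@errB
  nObsI <- length(y)
  list(
    free = free, nFree = nFree, mu = drop(mu), Winv = Winv,
    # -log p(y | eta) for a free-coordinate eta vector
    nllY = function(etaFree) {
      eta <- numeric(P); eta[free] <- etaFree
      f <- .concBatch(matrix(exp(drop(mu) + eta), 1), nComp, pr, nObsI)
      sig <- pmax(a + b * f, 1e-10)
      sum(log(sig) + 0.5 * ((y - f) / sig)^2) + nObsI * log(2 * pi) / 2
    },
    # -log p(eta)
    nllEta = function(etaFree) {
      if (!nFree) return(0)
      0.5 * drop(etaFree %*% Winv %*% etaFree) +
        0.5 * (ldet + nFree * log(2 * pi))
    },
    # vectorised log p(y | eta) over rows of an M x nFree matrix: each
    # draw is treated as a pseudo-subject of the batch evaluator
    llYBatch = function(etaFreeMat) {
      M <- nrow(etaFreeMat)
      eta <- matrix(0, M, P)
      eta[, free] <- etaFreeMat
      phi <- matrix(drop(mu), M, P, byrow = TRUE) + eta
      rep0 <- seq_len(M) - 1L
      prRep <- cbind(obs = rep(pr[, "obs"], M) + rep(rep0 * nObsI,
                                                     each = nrow(pr)),
                     dt = rep(pr[, "dt"], M), amt = rep(pr[, "amt"], M),
                     subj = rep(seq_len(M), each = nrow(pr)))
      f <- .concBatch(exp(phi), nComp, prRep, M * nObsI)
      sig <- pmax(a + b * f, 1e-10)
      yRep <- rep(y, M)
      ll <- -log(sig) - 0.5 * ((yRep - f) / sig)^2
      ll[!is.finite(ll)] <- -Inf  # overflowing eta draws
      as.numeric(rowsum(ll, rep(seq_len(M), each = nObsI))) -
        nObsI * log(2 * pi) / 2
    },
    llEtaBatch = function(etaFreeMat) {
      q <- rowSums((etaFreeMat %*% Winv) * etaFreeMat)
      -0.5 * q - 0.5 * (ldet + nFree * log(2 * pi))
    })
}

#' Empirical Bayes estimates of the random effects
#'
#' Per-subject posterior modes of eta given the data and the population
#' estimates, by gradient-based maximisation of the joint density starting
#' at eta = 0. Components whose omega is (numerically) zero are pinned at
#' their prior mode zero; an optimizer failure also returns zero for that
#' subject (flagged via attribute `"failed"`).
#'
#' @param fit A [PKFit-class] (or pass `data` and `model` explicitly).
#' @param data,model Optional explicit [PKEventData-class] /
#'   [PopPKModel-class] overriding the fit's.
#' @return `n x P` matrix of eta modes, columns named per parameter.
#' @export
empiricalBayes <- function(fit = NULL, data = NULL, model = NULL) {
  if (is.null(data)) data <- fit@data
  if (is.null(model)) model <- fit@model
  prep <- .prepareFit(data, model)
  sn <- .structNames(model@nComp)
  P <- length(sn)
  ebes <- matrix(0, prep$n, P, dimnames = list(prep$ids, sn))
  failed <- logical(prep$n)
  for (i in seq_len(prep$n)) {
    ob <- .makeSubjectObjective(prep, model, i)
    if (ob$nFree == 0) next
    res <- tryCatch(
      nlminb(rep(0, ob$nFree),
             function(e) ob$nllY(e) + ob$nllEta(e)),
      error = function(e) NULL)
    if (is.null(res)) { failed[i] <- TRUE; next }
    ebes[i, ob$free] <- res$par
  }
  attr(ebes, "failed") <- failed
  ebes
}

.shrinkageFromEbes <- function(ebes, omega) {
  out <- rep(NA_real_, length(omega))
  names(out) <- names(omega)
  for (p in seq_along(omega)) {
    if (omega[p] <= 1e-6) next  # undefined for a zero omega
    out[p] <- 100 * (1 - sd(ebes[, p]) / omega[p])
  }
  out
}

#' Eta shrinkage
#'
#' `100 * (1 - SD(EBE) / omega)` per parameter; `NA` where omega is zero
#' (shrinkage is undefined). Values near 100% mean the individual data
#' carry no information about that random effect.
#'
#' @param ebes Matrix of empirical Bayes eta modes (subjects x
#'   parameters).
#' @param omega Named population SDs.
#' @return Named shrinkage percentages.
#' @examples
#' shrinkagePct(matrix(0, 5, 1, dimnames = list(NULL, "cl")), c(cl = 0.3))
#' @export
shrinkagePct <- function(ebes, omega) {
  stopifnot(nrow(ebes) >= 2)
  .shrinkageFromEbes(ebes, omega)
}

#' Importance-sampling marginal log-likelihood
#'
#' Integrates the random effects out of the joint density by importance
#' sampling, with a multivariate-t proposal (5 df) centred at each
#' subject's empirical Bayes mode and scaled by the local curvature of the
#' joint density; subjects whose curvature is degenerate fall back to the
#' population prior as proposal. Reports the estimate and its Monte-Carlo
#' standard error.
#'
#' @param fit A [PKFit-class].
#' @param nSamples Importance samples per subject.
#' @param seed Integer seed.
#' @param data,model Optional overrides of the fit's data and model.
#' @return List with `logLik`, `se` (MC standard error) and `perSubject`.
#' @export
computeLogLik <- function(fit = NULL, nSamples = 5000, seed = 1,
                          data = NULL, model = NULL) {
  if (is.null(data)) data <- fit@data
  if (is.null(model)) model <- fit@model
  prep <- .prepareFit(data, model)
  ebes <- if (!is.null(fit) && nrow(fit@ebes) == prep$n) fit@ebes
          else empiricalBayes(data = data, model = model)
  set.seed(seed)
  prop <- .isProposals(prep, model, ebes)
  draws <- .isDraws(prop, nSamples)
  r <- .isEvaluate(prep, model, prop, draws)
  list(logLik = r$logLik, se = r$se, perSubject = r$perSubject)
}

# Proposal construction: mode + curvature per subject (shared by
# computeLogLik and the standard-error machinery, which needs a proposal
# frozen across parameter perturbations).
.isProposals <- function(prep, model, ebes) {
  lapply(seq_len(prep$n), function(i) {
    ob <- .makeSubjectObjective(prep, model, i)
    if (ob$nFree == 0) return(list(ob = ob, none = TRUE))
    m <- ebes[i, ob$free]
    nll <- function(e) ob$nllY(e) + ob$nllEta(e)
    H <- .fdHessian(nll, m, h = 1e-3)
    Sig <- tryCatch(solve(H), error = function(e) NULL)
    ok <- !is.null(Sig) && all(is.finite(Sig)) &&
      all(eigen(Sig, symmetric = TRUE, only.values = TRUE)$values > 0)
    if (!ok) {
      warning("degenerate proposal curvature for subject ", i,
              ": falling back to the prior proposal", call. = FALSE)
      Sig <- .omegaMatrix(model@omega[ob$free],
                          if (sum(ob$free[1:2]) == 2) model@corr else 0)
      m <- rep(0, ob$nFree)
    }
    list(ob = ob, none = FALSE, m = m, L = chol(Sig * 1.2))
  })
}

.isDraws <- function(prop, nSamples) {
  df <- 5
  lapply(prop, function(pr) {
    if (pr$none) return(NULL)
    k <- length(pr$m)
    z <- matrix(rnorm(nSamples * k), nSamples, k)
    w <- sqrt(df / stats::rchisq(nSamples, df))
    list(z = z, w = w, df = df)
  })
}

.isEvaluate <- function(prep, model, prop, draws) {
  perSubject <- se2 <- numeric(prep$n)
  for (i in seq_len(prep$n)) {
    pr <- prop[[i]]
    # densities come from the model being evaluated; the proposal (mode,
    # scale, draws) stays frozen so the log-likelihood is smooth in the
    # model parameters
    ob <- .makeSubjectObjective(prep, model, i, free = pr$ob$free)
    if (pr$none) {  # no random effects: direct density
      perSubject[i] <- -ob$nllY(numeric(0))
      next
    }
    d <- draws[[i]]
    k <- length(pr$m)
    eta <- sweep((d$z * d$w) %*% pr$L, 2, pr$m, "+")
    # multivariate-t log density of the proposal
    Linv <- backsolve(pr$L, diag(k))
    u <- (eta - matrix(pr$m, nrow(eta), k, byrow = TRUE)) %*% Linv
    q2 <- rowSums(u^2)
    ldetL <- sum(log(diag(pr$L)))
    logq <- lgamma((d$df + k) / 2) - lgamma(d$df / 2) -
      k / 2 * log(d$df * pi) - ldetL -
      (d$df + k) / 2 * log1p(q2 / d$df)
    logp <- ob$llYBatch(eta) + ob$llEtaBatch(eta)
    lw <- logp - logq
    lw[!is.finite(lw)] <- -Inf
    m <- max(lw)
    if (!is.finite(m)) { perSubject[i] <- -Inf; next }
    wexp <- exp(lw - m)
    perSubject[i] <- m + log(mean(wexp))
    se2[i] <- var(wexp) / (length(wexp) * mean(wexp)^2)
  }
  list(logLik = sum(perSubject), se = sqrt(sum(se2)),
       perSubject = perSubject)
}

# Central finite-difference Hessian (the target functions are smooth and,
# under common random numbers, deterministic).
.fdHessian <- function(f, x, h = 1e-3) {
  k <- length(x)
  H <- matrix(0, k, k)
  hh <- pmax(abs(x), 0.1) * h
  f0 <- f(x)
  for (i in seq_len(k)) {
    ei <- numeric(k); ei[i] <- hh[i]
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / hh[i]^2
    if (i < k) for (j in seq((i + 1), k)) {
      ej <- numeric(k); ej[j] <- hh[j]
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) +
           f(x - ei - ej)) / (4 * hh[i] * hh[j])
    }
  }
  H
}

#' Relative standard errors of the population estimates
#'
#' Standard errors from the observed Fisher information, computed as the
#' finite-difference Hessian of the importance-sampling log-likelihood
#' under common random numbers (the proposal and its draws are frozen at
#' the fitted model, making the likelihood surface smooth in the
#' parameters). Scale parameters are differentiated on the log scale, so
#' their relative standard errors are reported directly in percent.
#'
#' @param fit A [PKFit-class].
#' @param nSamples Importance samples per subject.
#' @param seed Integer seed.
#' @return The fit with its `rse` slot filled (named percentages).
#' @export
fitStandardErrors <- function(fit, nSamples = 1000, seed = 1) {
  model <- fit@model
  data <- fit@data
  prep <- .prepareFit(data, model)
  sn <- .structNames(model@nComp)
  P <- length(sn)
  estA <- model@errA > 0; estB <- model@errB > 0
  estCorr <- P >= 2

  set.seed(seed)
  prop <- .isProposals(prep, model, fit@ebes)
  draws <- .isDraws(prop, nSamples)

  links <- model@covariates
  x0 <- c(log(model@theta),
          vapply(links, function(l) l$coef, numeric(1)),
          log(pmax(model@omega, 1e-4)),
          if (estCorr) atanh(min(max(model@corr, -0.98), 0.98)),
          if (estA) log(model@errA),
          if (estB) log(model@errB))
  labs <- c(paste0("log_theta_", sn),
            vapply(links, function(l) paste0("beta_", l$cov, "_", l$param),
                   character(1)),
            paste0("omega_", sn),
            if (estCorr) "corr_cl_vc", if (estA) "err_a", if (estB) "err_b")
  rebuild <- function(x) {
    th <- setNames(exp(x[seq_len(P)]), sn)
    lk <- links
    for (l in seq_along(lk)) lk[[l]]$coef <- x[P + l]
    off <- P + length(lk)
    om <- setNames(exp(x[off + seq_len(P)]), sn)
    off <- off + P
    co <- if (estCorr) tanh(x[off + 1]) else 0
    off <- off + estCorr
    aa <- if (estA) exp(x[off + 1]) else 0
    off <- off + estA
    bb <- if (estB) exp(x[off + 1]) else 0
    popPKModel(model@nComp, th, covariates = lk, omega = om, corr = co,
               errA = aa, errB = bb)
  }
  nll <- function(x)
    -.isEvaluate(prep, rebuild(x), prop, draws)$logLik
  H <- .fdHessian(nll, x0, h = 5e-3)
  V <- tryCatch(solve(H), error = function(e) matrix(NA_real_, length(x0),
                                                     length(x0)))
  se <- sqrt(pmax(diag(V), 0))
  rse <- 100 * se
  # coefficients and the correlation are not log-scale: convert to
  # relative error against the estimate
  for (l in seq_along(links)) {
    idx <- P + l
    rse[idx] <- 100 * se[idx] / abs(x0[idx])
  }
  if (estCorr) {
    idx <- P + length(links) + P + 1
    seCorr <- se[idx] * (1 - model@corr^2)  # delta method through tanh
    rse[idx] <- 100 * seCorr / abs(model@corr)
  }
  fit@rse <- setNames(rse, labs)
  fit
}
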