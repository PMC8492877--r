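# Individual-parameter covariate map, residual error model and
# random-effect sampling.

# Covariate value lookup for a link given a one-row covariate record.
.linkValue <- function(lk, cov) {
  x <- cov[[lk$cov]]
  if (is.null(x) || is.na(x))
    stop(sprintf("covariate '%s' missing", lk$cov), call. = FALSE)
  if (lk$type == "power") {
    if (x <= 0)
      stop(sprintf("covariate '%s' must be positive", lk$cov), call. = FALSE)
    log(x / lk$center)
  } else {
    as.numeric(x %in% c("F", "female", "Female", 1))
  }
}

# Log-scale typical values mu_i (n x P) for all subjects of a covariate
# table under a model's covariate links.
.muMatrix <- function(model, covdf) {
  sn <- .structNames(model@nComp)
  n <- nrow(covdf)
  mu <- matrix(rep(log(model@theta), each = n), n, length(sn),
               dimnames = list(NULL, sn))
  for (lk in model@covariates) {
    cf <- if (is.null(lk$coef)) 0 else lk$coef
    x <- vapply(seq_len(n), function(i) .linkValue(lk, covdf[i, , drop = FALSE]),
                numeric(1))
    mu[, lk$param] <- mu[, lk$param] + cf * x
  }
  mu
}

#' Map fixed effects, covariates and random effects to individual parameters
#'
#' Applies the power covariate model on clearance,
#' `CL_i = theta_cl * (CrCL_i / 80)^theta_crcl * exp(eta_cl)`, and the
#' log-normal random effects `param_i = typical * exp(eta)` for the
#' remaining structural parameters (no covariates on Vc, Q, Vp in the final
#' model, though any link carried by `model` is honoured).
#'
#' @param model A [PopPKModel-class].
#' @param eta Named (or positionally ordered) numeric vector of log-scale
#'   random effects, one per structural parameter; defaults to all zero.
#' @param covariates One-row data.frame (or named list) with the covariate
#'   columns referenced by the model's links, e.g. `crcl_ckdepi`.
#' @return A [PKParameters-class] object.
#' @examples
#' m <- cefazolinFinalModel()
#' individualParameters(m, covariates = list(crcl_ckdepi = 80))  # typical
#' @export
individualParameters <- function(model, eta = NULL, covariates = list()) {
  stopifnot(is(model, "PopPKModel"))
  sn <- .structNames(model@nComp)
  if (is.null(eta)) eta <- setNames(rep(0, length(sn)), sn)
  if (!is.null(names(eta))) eta <- eta[sn]
  covdf <- as.data.frame(covariates, stringsAsFactors = FALSE)
  if (nrow(covdf) == 0) covdf <- data.frame(.dummy = 1)
  mu <- .muMatrix(model, covdf[1, , drop = FALSE])
  psi <- exp(drop(mu) + as.numeric(eta))
  qi <- if (model@nComp > 1L) seq(3L, length(sn), by = 2L) else integer(0)
  pkParameters(cl = psi[1], vc = psi[2], q = psi[qi], vp = psi[qi + 1L])
}

#' Residual error model
#'
#' Returns the observed concentration `f + (a + b * f) * epsilon`, the
#' combined additive/proportional error model; the final cefazolin model
#' uses `a = 0`, `b = 0.12` (12% proportional error).
#'
#' @param f Predicted concentration(s), mg/L, non-negative.
#' @param epsilon Standard-normal deviate(s), recycled against `f`.
#' @param a Additive error component (mg/L).
#' @param b Proportional error component (fraction).
#' @return Observed concentration(s) in mg/L.
#' @examples
#' observeConc(100, epsilon = 1, b = 0.12)  # 112
#' @export
observeConc <- function(f, epsilon, a = 0, b = 0.12) {
  if (any(f < 0)) stop("predicted concentrations must be non-negative",
                       call. = FALSE)
  if (a < 0 || b < 0 || (a == 0 && b == 0))
    stop("invalid residual error specification", call. = FALSE)
  f + (a + b * f) * epsilon
}

#' Sample random-effect vectors
#'
#' Draws multivariate-normal log-scale random effects with the model's
#' block structure: independent components except for the CL-Vc
#' correlation.
#'
#' @param model A [PopPKModel-class] (its `omega` and `corr` are used), or
#'   a named numeric vector of SDs with attribute/argument `corr`.
#' @param n Number of subjects to draw.
#' @param seed Optional integer seed for reproducibility.
#' @param corr CL-Vc correlation when `model` is a plain SD vector.
#' @return `n` x P matrix of eta draws (columns named per parameter).
#' @examples
#' sampleEtas(cefazolinFinalModel(), n = 5, seed = 1)
#' @export
sampleEtas <- function(model, n, seed = NULL, corr = 0) {
  if (is(model, "PopPKModel")) {
    omega <- model@omega; corr <- model@corr
  } else omega <- model
  if (any(omega < 0)) stop("omega SDs must be non-negative", call. = FALSE)
  if (abs(corr) > 1)
    stop("random-effect covariance is not positive semi-definite", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  P <- length(omega)
  if (all(omega == 0))
    return(matrix(0, n, P, dimnames = list(NULL, names(omega))))
  S <- .omegaMatrix(omega, corr)
  U <- .safeChol(S)
  eta <- matrix(rnorm(n * P), n, P) %*% U
  # components with omega exactly 0 must be exactly 0, not chol-jittered
  eta[, omega == 0] <- 0
  colnames(eta) <- names(omega)
  eta
}
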