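# Structural model comparison and forward-stepwise covariate selection,
# both ranked by BIC (subject-count convention).

#' BIC reduction between two models
#'
#' Bookkeeping helper for selection reports: the drop in BIC from a
#' reference model to a candidate (positive when the candidate is
#' better).
#'
#' @param bicReference,bicCandidate The two BIC values.
#' @return `bicReference - bicCandidate`.
#' @examples
#' deltaBic(4279.77, 4211.26)  # 68.51
#' @export
deltaBic <- function(bicReference, bicCandidate) bicReference - bicCandidate

#' Relative reduction in a variability estimate
#'
#' Percentage drop of a random-effect SD after covariate inclusion,
#' rounded to integer percent, e.g. from 39 to 32 gives 18%.
#'
#' @param omegaBefore,omegaAfter SDs (any common scale) before and after.
#' @return Integer percentage reduction.
#' @examples
#' omegaReductionPct(39, 32)  # 18
#' @export
omegaReductionPct <- function(omegaBefore, omegaAfter) {
  stopifnot(omegaBefore > 0)
  round(100 * (1 - omegaAfter / omegaBefore))
}

#' Compare 1-, 2- and 3-compartment structural models
#'
#' Fits each candidate compartment count with shared SAEM settings and the
#' passed error structure, then ranks by BIC. Non-convergent candidates
#' are kept in the trace with an explicit flag, never silently dropped.
#'
#' @param data A [PKEventData-class].
#' @param control Shared [saemControl()] settings; each candidate gets a
#'   distinct deterministic seed derived from `control$seed`.
#' @param nComps Candidate compartment counts (default `1:3`).
#' @param errB,errA Residual error components to estimate (nonzero =
#'   estimated), default proportional-only.
#' @return List with `trace` (data.frame: nComp, logLik, nParams, BIC,
#'   converged, selected), `best` (selected compartment count) and `fits`.
#' @export
compareStructural <- function(data, control = saemControl(), nComps = 1:3,
                              errA = 0, errB = 0.12) {
  fits <- vector("list", length(nComps))
  rows <- vector("list", length(nComps))
  for (j in seq_along(nComps)) {
    nc <- nComps[j]
    theta <- c(cl = 3, vc = 5, q = 8, vp = 5, q2 = 2, vp2 = 8)[
      seq_len(2 * nc)]
    names(theta) <- .structNames(nc)
    m <- popPKModel(nc, theta, errA = errA, errB = if (errB > 0) errB else 0)
    ctl <- control
    ctl$seed <- control$seed + 1000L * j
    fit <- tryCatch(saemFit(data, m, ctl), error = function(e) e)
    if (inherits(fit, "error")) {
      warning(sprintf("%d-compartment fit failed: %s", nc,
                      conditionMessage(fit)), call. = FALSE)
      rows[[j]] <- data.frame(nComp = nc, logLik = NA_real_,
                              nParams = NA_real_, BIC = Inf,
                              converged = FALSE)
      next
    }
    ok <- is.finite(fit@logLik)
    if (!ok)
      warning(sprintf("%d-compartment likelihood is degenerate", nc),
              call. = FALSE)
    fits[[j]] <- fit
    rows[[j]] <- data.frame(nComp = nc, logLik = fit@logLik,
                            nParams = fit@nParams,
                            BIC = if (ok) fit@bic else Inf,
                            converged = fit@converged && ok)
  }
  trace <- do.call(rbind, rows)
  best <- which.min(trace$BIC)
  trace$selected <- seq_len(nrow(trace)) == best
  list(trace = trace, best = trace$nComp[best], fits = fits)
}

#' Forward-stepwise covariate selection by BIC
#'
#' Starting from a covariate-free base model, refits one candidate link at
#' a time, accepts the candidate giving the largest BIC decrease, and
#' repeats until no candidate decreases the BIC. Each accepted step also
#' records the drop in the affected parameter's omega. A candidate whose
#' fit fails is skipped with a warning.
#'
#' @param data A [PKEventData-class].
#' @param candidates List of [candidateCovariate()] links to test.
#' @param baseModel Base [PopPKModel-class] (default: covariate-free
#'   2-compartment, proportional error).
#' @param control Shared [saemControl()]; candidate fits get distinct
#'   deterministic seeds.
#' @param maxSteps Maximum accepted steps (default: all candidates).
#' @return List with `trace` (data.frame, one row per evaluated model:
#'   step, model label, BIC, deltaBIC vs the running base, omega of the
#'   affected parameter, accepted flag), `model` (the selected
#'   [PopPKModel-class]), `fit` (its [PKFit-class]) and `selected`
#'   (labels of accepted links, in acceptance order).
#' @export
forwardStepwise <- function(data, candidates,
                            baseModel = popPKModel(
                              2, c(cl = 3, vc = 5, q = 8, vp = 5),
                              errB = 0.12),
                            control = saemControl(), maxSteps = Inf) {
  lab <- function(lk) paste0(lk$cov, "->", lk$param)
  baseFit <- saemFit(data, baseModel, control)
  if (!baseFit@converged) stop("base fit did not converge", call. = FALSE)
  trace <- data.frame(step = 0L, model = "base", BIC = baseFit@bic,
                      deltaBIC = 0, omega = NA_real_, accepted = TRUE,
                      stringsAsFactors = FALSE)
  current <- baseFit
  remaining <- candidates
  step <- 0L
  fitSeq <- 0L
  while (length(remaining) > 0 && step < maxSteps) {
    step <- step + 1L
    bics <- rep(Inf, length(remaining))
    fits <- vector("list", length(remaining))
    for (j in seq_along(remaining)) {
      lk <- remaining[[j]]
      m <- current@model
      m@covariates <- c(m@covariates, list(lk))
      ctl <- control
      fitSeq <- fitSeq + 1L
      ctl$seed <- control$seed + 100L * fitSeq
      fit <- tryCatch(saemFit(data, m, ctl), error = function(e) e)
      if (inherits(fit, "error") || !fit@converged) {
        warning(sprintf("candidate %s skipped: %s", lab(lk),
                        if (inherits(fit, "error"))
                          conditionMessage(fit) else "no convergence"),
                call. = FALSE)
        trace <- rbind(trace, data.frame(
          step = step, model = lab(lk), BIC = NA_real_, deltaBIC = NA_real_,
          omega = NA_real_, accepted = FALSE))
        next
      }
      fits[[j]] <- fit
      bics[j] <- fit@bic
      trace <- rbind(trace, data.frame(
        step = step, model = lab(lk), BIC = fit@bic,
        deltaBIC = deltaBic(current@bic, fit@bic),
        omega = unname(fit@model@omega[lk$param]), accepted = FALSE))
    }
    best <- which.min(bics)
    if (!length(best) || bics[best] >= current@bic) break
    trace$accepted[nrow(trace) - length(remaining) + best] <- TRUE
    current <- fits[[best]]
    remaining <- remaining[-best]
  }
  accepted <- trace$model[trace$accepted & trace$step > 0]
  list(trace = trace, model = current@model, fit = current,
       selected = accepted)
}
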