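#' @import methods
#' @importFrom stats approx coef cor cov dnorm lm median nlminb optim pnorm
#'   qnorm quantile rbinom rnorm runif sd setNames var
#' @importFrom utils head tail
NULL

# Ordered structural-parameter names for an n-compartment mammillary model.
.structNames <- function(nComp) {
  switch(nComp,
    c("cl", "vc"),
    c("cl", "vc", "q", "vp"),
    c("cl", "vc", "q", "vp", "q2", "vp2"),
    stop("compartment count must be 1, 2 or 3", call. = FALSE)
  )
}

#' Individual structural pharmacokinetic parameters
#'
#' Holds one subject's disposition parameters for a mammillary compartment
#' model with bolus input: elimination clearance `cl` (L/h), central volume
#' `vc` (L), and one intercompartmental clearance / peripheral volume pair
#' per peripheral compartment (`q` in L/h, `vp` in L).
#'
#' @slot cl Elimination clearance (L/h).
#' @slot vc Central volume of distribution (L).
#' @slot q Intercompartmental clearances (L/h), length `nComp - 1`.
#' @slot vp Peripheral volumes (L), length `nComp - 1`.
#' @slot nComp Number of compartments (1, 2 or 3).
#' @export
setClass("PKParameters",
  representation(cl = "numeric", vc = "numeric", q = "numeric",
                 vp = "numeric", nComp = "integer"),
  validity = function(object) {
    if (!(object@nComp %in% 1:3)) return("nComp must be 1, 2 or 3")
    if (length(object@q) != object@nComp - 1L ||
        length(object@vp) != object@nComp - 1L)
      return("q and vp must each have nComp - 1 entries")
    vals <- c(object@cl, object@vc, object@q, object@vp)
    if (any(!is.finite(vals)) || any(vals <= 0))
      return("all PK parameters must be positive and finite")
    TRUE
  })

#' Construct a PKParameters object
#'
#' @param cl Elimination clearance (L/h).
#' @param vc Central volume (L).
#' @param q Intercompartmental clearance(s) (L/h); one value per peripheral
#'   compartment.
#' @param vp Peripheral volume(s) (L); same length as `q`.
#' @return A [PKParameters-class] object.
#' @examples
#' pkParameters(cl = 2.86, vc = 5.2, q = 10.9, vp = 4.56)
#' @export
pkParameters <- function(cl, vc, q = numeric(0), vp = numeric(0)) {
  new("PKParameters", cl = as.numeric(cl), vc = as.numeric(vc),
      q = as.numeric(q), vp = as.numeric(vp),
      nComp = as.integer(length(q) + 1L))
}

setMethod("show", "PKParameters", function(object) {
  cat(sprintf("PKParameters: %d-compartment IV bolus\n", object@nComp))
  cat(sprintf("  CL = %.4g L/h, Vc = %.4g L\n", object@cl, object@vc))
  if (object@nComp > 1)
    for (j in seq_along(object@q))
      cat(sprintf("  Q%d = %.4g L/h, Vp%d = %.4g L\n",
                  j, object@q[j], j, object@vp[j]))
})

#' Population pharmacokinetic model specification
#'
#' Fixed effects (typical structural parameters), covariate links on those
#' parameters, log-normal between-subject variability with an optional
#' CL-Vc correlation, and a combined additive/proportional residual error
#' model `sd = a + b * f`.
#'
#' @slot nComp Number of compartments (1-3).
#' @slot theta Named typical values, names as in [pkParameters()] but flat
#'   (`cl, vc, q, vp, q2, vp2` as applicable).
#' @slot covariates List of covariate links (see [candidateCovariate()]);
#'   each carries its estimated/assumed coefficient in `$coef`.
#' @slot omega Named log-scale standard deviations of the random effects,
#'   one per structural parameter.
#' @slot corr Correlation between the CL and Vc random effects; all other
#'   off-diagonals are fixed at zero.
#' @slot errA Additive residual component (mg/L).
#' @slot errB Proportional residual component (fraction).
#' @export
setClass("PopPKModel",
  representation(nComp = "integer", theta = "numeric", covariates = "list",
                 omega = "numeric", corr = "numeric",
                 errA = "numeric", errB = "numeric"),
  validity = function(object) {
    sn <- .structNames(object@nComp)
    if (!identical(names(object@theta), sn))
      return(sprintf("theta must be named %s", paste(sn, collapse = ", ")))
    if (any(object@theta <= 0)) return("typical values must be positive")
    if (!identical(names(object@omega), sn))
      return("omega must carry one SD per structural parameter")
    if (any(object@omega < 0)) return("omega SDs must be non-negative")
    if (abs(object@corr) > 1) return("CL-Vc correlation must lie in [-1, 1]")
    if (object@errA < 0 || object@errB < 0)
      return("error components must be non-negative")
    if (object@errA == 0 && object@errB == 0)
      return("error components cannot both be zero")
    for (lk in object@covariates) {
      if (!all(c("cov", "param", "type") %in% names(lk)))
        return("each covariate link needs cov, param and type fields")
      if (!lk$param %in% sn)
        return(sprintf("covariate target '%s' is not a model parameter", lk$param))
      if (lk$type == "power" && (is.null(lk$center) || lk$center <= 0))
        return("power links need a positive centering constant")
    }
    TRUE
  })

#' Construct a population PK model
#'
#' @param nComp Number of compartments (1, 2 or 3).
#' @param theta Named numeric vector of typical values (`cl`, `vc`, plus
#'   `q`, `vp` and `q2`, `vp2` as required by `nComp`).
#' @param covariates List of covariate links, e.g.
#'   `list(candidateCovariate("crcl_ckdepi", "cl", center = 80, coef = 0.79))`.
#' @param omega Named log-scale random-effect SDs (defaults to all zero).
#' @param corr CL-Vc random-effect correlation (default 0).
#' @param errA,errB Additive (mg/L) and proportional residual error
#'   components.
#' @return A [PopPKModel-class] object.
#' @examples
#' cefazolinFinalModel()
#' @export
popPKModel <- function(nComp, theta, covariates = list(),
                       omega = NULL, corr = 0, errA = 0, errB = 0.1) {
  nComp <- as.integer(nComp)
  sn <- .structNames(nComp)
  theta <- theta[sn]
  if (is.null(omega)) omega <- setNames(rep(0, length(sn)), sn)
  omega <- omega[sn]
  names(omega) <- sn
  new("PopPKModel", nComp = nComp, theta = theta, covariates = covariates,
      omega = omega, corr = as.numeric(corr),
      errA = as.numeric(errA), errB = as.numeric(errB))
}

#' The published final cefazolin model
#'
#' Convenience constructor for the final 2-compartment covariate model of
#' cefazolin in hip arthroplasty: CL (L/h) = 2.86 x (CrCL/80)^0.79, Vc =
#' 5.2 L, Q = 10.9 L/h, Vp = 4.56 L, log-scale random-effect SDs
#' 0.32/0.57/0.66/0.10 with a 0.83 CL-Vc correlation, and a 12%
#' proportional residual error. CrCL is the CKD-EPI estimate.
#'
#' @param covariate Logical; if `FALSE`, returns the covariate-free variant
#'   (model 1 of the report: CL 2.87 L/h, Vc 4.97, Q 10.5, Vp 4.73, SDs
#'   0.39/0.59/0.60/0.15, correlation 0.71).
#' @return A [PopPKModel-class] object.
#' @export
cefazolinFinalModel <- function(covariate = TRUE) {
  if (covariate) {
    popPKModel(2,
      theta = c(cl = 2.86, vc = 5.2, q = 10.9, vp = 4.56),
      covariates = list(candidateCovariate("crcl_ckdepi", "cl",
                                           center = 80, coef = 0.79)),
      omega = c(cl = 0.32, vc = 0.57, q = 0.66, vp = 0.10),
      corr = 0.83, errA = 0, errB = 0.12)
  } else {
    popPKModel(2,
      theta = c(cl = 2.87, vc = 4.97, q = 10.5, vp = 4.73),
      omega = c(cl = 0.39, vc = 0.59, q = 0.60, vp = 0.15),
      corr = 0.71, errA = 0, errB = 0.12)
  }
}

setMethod("show", "PopPKModel", function(object) {
  cat(sprintf("PopPKModel: %d compartments\n", object@nComp))
  cat("  theta:", paste(sprintf("%s=%.4g", names(object@theta), object@theta),
                        collapse = ", "), "\n")
  for (lk in object@covariates)
    cat(sprintf("  link : %s on %s (%s%s), coef=%.4g\n", lk$cov, lk$param,
                lk$type,
                if (lk$type == "power") sprintf(", center=%g", lk$center) else "",
                if (is.null(lk$coef)) NA_real_ else lk$coef))
  cat("  omega:", paste(sprintf("%s=%.3g", names(object@omega), object@omega),
                        collapse = ", "),
      sprintf("(corr CL-Vc %.3g)\n", object@corr))
  cat(sprintf("  error: sd = %.3g + %.3g * f\n", object@errA, object@errB))
})

#' Longitudinal dosing/observation dataset
#'
#' Event records in the NONMEM convention (`ID`, `TIME`, `EVID`, `AMT`,
#' `DV`, `MDV`, `BLQ`) together with one row of time-constant covariates
#' per subject.
#'
#' @slot records data.frame of dose (`EVID = 1`) and observation
#'   (`EVID = 0`) rows.
#' @slot covariates data.frame keyed by `id`, one row per subject.
#' @slot lloq Lower limit of quantification (mg/L) used to set `BLQ`.
#' @slot seed Seed recorded when the dataset was simulated (NA for read
#'   data).
#' @export
setClass("PKEventData",
  representation(records = "data.frame", covariates = "data.frame",
                 lloq = "numeric", seed = "numeric"),
  validity = function(object) {
    r <- object@records
    need <- c("ID", "TIME", "EVID", "AMT", "DV", "MDV", "BLQ")
    if (!all(need %in% names(r)))
      return(paste("records must contain columns:", paste(need, collapse = " ")))
    if (any(r$TIME < 0)) return("event times must be non-negative")
    if (any(r$EVID == 1 & !is.na(r$DV)))
      return("dose records must not carry an observed concentration")
    if (any(r$EVID == 0 & !is.na(r$AMT)))
      return("observation records must not carry a dose amount")
    if (any(r$EVID == 1 & (is.na(r$AMT) | r$AMT <= 0)))
      return("dose amounts must be positive")
    for (id in unique(r$ID)) {
      ri <- r[r$ID == id, ]
      if (is.unsorted(ri$TIME)) return(sprintf("times not sorted for subject %s", id))
      if (!any(ri$EVID == 1)) return(sprintf("subject %s has no dose record", id))
      if (!any(ri$EVID == 0)) return(sprintf("subject %s has no observation", id))
    }
    if (!"id" %in% names(object@covariates))
      return("covariates must carry an 'id' column")
    if (!all(unique(r$ID) %in% object@covariates$id))
      return("every subject needs a covariate row")
    TRUE
  })

#' Construct an event dataset
#'
#' @param records data.frame with NONMEM-convention columns `ID`, `TIME`,
#'   `EVID`, `AMT`, `DV`, `MDV`; `BLQ` is derived from `lloq` if absent.
#' @param covariates Per-subject covariate data.frame with an `id` column.
#' @param lloq Lower limit of quantification (mg/L).
#' @param seed Optional seed provenance.
#' @return A [PKEventData-class] object.
#' @export
eventDataset <- function(records, covariates, lloq = 5, seed = NA_real_) {
  records <- as.data.frame(records)
  if (is.null(records$BLQ))
    records$BLQ <- as.integer(records$EVID == 0 & !is.na(records$DV) &
                              records$DV < lloq)
  if (is.null(records$MDV)) records$MDV <- as.integer(records$EVID != 0)
  records <- records[order(records$ID, records$TIME, -records$EVID), ]
  rownames(records) <- NULL
  new("PKEventData", records = records,
      covariates = as.data.frame(covariates),
      lloq = as.numeric(lloq), seed = as.numeric(seed))
}

setMethod("show", "PKEventData", function(object) {
  r <- object@records
  cat(sprintf("PKEventData: %d subjects, %d dose and %d observation records",
              length(unique(r$ID)), sum(r$EVID == 1), sum(r$EVID == 0)),
      sprintf("(%d below LLOQ %.3g mg/L)\n", sum(r$BLQ == 1), object@lloq))
})

#' Population model fit
#'
#' Result of [saemFit()]: the estimated model, the likelihood and BIC, the
#' empirical Bayes estimates, shrinkage, optional relative standard errors,
#' and the full parameter iteration trace.
#'
#' @slot model Estimated [PopPKModel-class].
#' @slot data The fitted [PKEventData-class].
#' @slot logLik Importance-sampling log-likelihood estimate.
#' @slot logLikSE Monte-Carlo standard error of `logLik`.
#' @slot bic Bayesian information criterion (subject-count convention).
#' @slot nParams Number of estimated parameters entering the BIC penalty.
#' @slot ebes Matrix of per-subject empirical Bayes eta modes.
#' @slot shrinkage Named per-parameter eta shrinkage (%).
#' @slot rse Named relative standard errors (%), NA unless computed.
#' @slot trace Iteration-by-parameter SAEM trace.
#' @slot control SAEM settings used.
#' @slot converged Logical convergence flag.
#' @slot messages Character log (e.g. BLQ exclusion counts).
#' @export
setClass("PKFit",
  representation(model = "PopPKModel", data = "PKEventData",
                 logLik = "numeric", logLikSE = "numeric", bic = "numeric",
                 nParams = "numeric", ebes = "matrix", shrinkage = "numeric",
                 rse = "numeric", trace = "matrix", control = "list",
                 converged = "logical", messages = "character"))

setMethod("show", "PKFit", function(object) {
  cat("SAEM population PK fit\n")
  show(object@model)
  cat(sprintf("  logLik %.2f (MC SE %.3f), BIC %.2f (k = %d, N = %d)\n",
              object@logLik, object@logLikSE, object@bic,
              as.integer(object@nParams),
              length(unique(object@data@records$ID))))
  if (length(object@shrinkage))
    cat("  shrinkage (%):",
        paste(sprintf("%s=%.1f", names(object@shrinkage), object@shrinkage),
              collapse = ", "), "\n")
})

#' @describeIn PKFit Number of compartments of a fitted or specified model.
#' @param object A `PKFit` or `PopPKModel`.
#' @export
setGeneric("nCompartments", function(object) standardGeneric("nCompartments"))
setMethod("nCompartments", "PopPKModel", function(object) object@nComp)
setMethod("nCompartments", "PKFit", function(object) object@model@nComp)

#' Accessors for model and fit components
#'
#' `fixedEffects()` returns typical values plus covariate coefficients,
#' `omegaSd()` the log-scale random-effect SDs (with the CL-Vc correlation
#' as attribute `"corr"`), `residualError()` the `c(a, b)` error
#' components, `shrinkage()` the per-parameter eta shrinkage, and
#' `eventRecords()` / `subjectCovariates()` the underlying tables.
#'
#' @param object A [PopPKModel-class], [PKFit-class] or
#'   [PKEventData-class] as appropriate.
#' @return Named numeric vectors (or data.frames for the table accessors).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("fixedEffects", function(object) standardGeneric("fixedEffects"))
setMethod("fixedEffects", "PopPKModel", function(object) {
  out <- object@theta
  for (lk in object@covariates)
    out[paste0("beta_", lk$cov, "_", lk$param)] <-
      if (is.null(lk$coef)) NA_real_ else lk$coef
  out
})
setMethod("fixedEffects", "PKFit", function(object) fixedEffects(object@model))

#' @rdname accessors
#' @export
setGeneric("omegaSd", function(object) standardGeneric("omegaSd"))
setMethod("omegaSd", "PopPKModel", function(object) {
  out <- object@omega
  attr(out, "corr") <- object@corr
  out
})
setMethod("omegaSd", "PKFit", function(object) omegaSd(object@model))

#' @rdname accessors
#' @export
setGeneric("residualError", function(object) standardGeneric("residualError"))
setMethod("residualError", "PopPKModel",
          function(object) c(a = object@errA, b = object@errB))
setMethod("residualError", "PKFit",
          function(object) residualError(object@model))

#' @rdname accessors
#' @export
etaShrinkage <- function(object) {
  stopifnot(is(object, "PKFit"))
  object@shrinkage
}

#' @rdname accessors
#' @export
eventRecords <- function(object) {
  stopifnot(is(object, "PKEventData"))
  object@records
}

#' @rdname accessors
#' @export
subjectCovariates <- function(object) {
  stopifnot(is(object, "PKEventData"))
  object@covariates
}
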