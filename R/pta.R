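# Monte-Carlo exposure simulation: concentration-time profiles by
# covariate profile, probability of target attainment, time above
# threshold, toxicity exceedance and regimen comparison.

#' Total-concentration efficacy threshold
#'
#' Converts a free-drug MIC target into a total-plasma threshold given the
#' unbound fraction: `mic / fu`. Cefazolin is ~80% protein bound
#' (`fu = 0.2`), so the 4 mg/L MIC maps to 20 mg/L total.
#'
#' @param mic Minimum inhibitory concentration (mg/L, free drug).
#' @param fu Unbound fraction, in (0, 1].
#' @return Total-concentration threshold (mg/L).
#' @examples
#' efficacyThreshold(4, 0.2)  # 20
#' @export
efficacyThreshold <- function(mic, fu) {
  if (any(fu <= 0) || any(fu > 1))
    stop("unbound fraction must lie in (0, 1]", call. = FALSE)
  mic / fu
}

#' Define a simulation scenario
#'
#' A covariate profile (at minimum the CrCL feeding the clearance model),
#' a bolus schedule, the efficacy and toxicity thresholds, and the
#' evaluation grid.
#'
#' @param covariates Named list/one-row data.frame of covariates (e.g.
#'   `list(crcl_ckdepi = 90)`).
#' @param doses data.frame with `time` (h) and `amount` (mg).
#' @param efficacyThreshold Total-concentration efficacy target (mg/L).
#' @param toxicityThreshold Neurotoxicity cutoff (mg/L).
#' @param evalTimes Times (h) at which PTA is reported; 2.01 h is the
#'   study's mean injection-to-skin-closure time, 4 h the recommended
#'   redosing horizon.
#' @param grid Profile time grid (h); must span `evalTimes`.
#' @return A list of class `regimenScenario`.
#' @export
regimenScenario <- function(covariates = list(crcl_ckdepi = 90),
                            doses = data.frame(time = 0, amount = 2000),
                            efficacyThreshold = 20,
                            toxicityThreshold = 360,
                            evalTimes = c(2.01, 4),
                            grid = seq(0, 8, by = 0.01)) {
  stopifnot(efficacyThreshold > 0, toxicityThreshold > 0)
  grid <- sort(unique(c(grid, evalTimes)))
  if (any(evalTimes < min(grid)) || any(evalTimes > max(grid)))
    stop("evaluation times must lie within the grid span", call. = FALSE)
  structure(list(covariates = covariates, doses = doses,
                 efficacyThreshold = efficacyThreshold,
                 toxicityThreshold = toxicityThreshold,
                 evalTimes = evalTimes, grid = grid),
            class = "regimenScenario")
}

#' Simulate a virtual population under a scenario
#'
#' Draws random effects from the model's between-subject distribution
#' (including the CL-Vc correlation), maps them to individual parameters
#' through the covariate model at the scenario's profile, and evaluates
#' noise-free concentration curves on the grid. Residual (assay) error is
#' excluded by default: exposure, not measurement, is the target.
#'
#' @param model A [PopPKModel-class].
#' @param scenario A [regimenScenario()].
#' @param n Number of simulated subjects.
#' @param seed Integer seed.
#' @param includeResidual If `TRUE`, adds residual error draws.
#' @return `n x length(grid)` concentration matrix with the grid as
#'   `"times"` attribute.
#' @examples
#' m <- cefazolinFinalModel()
#' cm <- simulatePopulation(m, regimenScenario(), n = 100, seed = 1)
#' @export
simulatePopulation <- function(model, scenario, n, seed = NULL,
                               includeResidual = FALSE) {
  stopifnot(is(model, "PopPKModel"), inherits(scenario, "regimenScenario"),
            n >= 1)
  if (!is.null(seed)) set.seed(seed)
  eta <- sampleEtas(model, n)
  covdf <- as.data.frame(scenario$covariates, stringsAsFactors = FALSE)
  mu <- .muMatrix(model, covdf[rep(1, n), , drop = FALSE])
  psi <- exp(mu + eta)
  tg <- scenario$grid
  nt <- length(tg)
  d <- scenario$doses
  # one shared grid: pair every (subject, grid point) with every dose
  pairs <- do.call(rbind, lapply(seq_len(nrow(d)), function(k) {
    w <- which(tg >= d$time[k])
    if (!length(w)) return(NULL)
    cbind(obs = rep(w, n) + rep((seq_len(n) - 1) * nt, each = length(w)),
          dt = rep(tg[w] - d$time[k], n), amt = d$amount[k],
          subj = rep(seq_len(n), each = length(w)))
  }))
  conc <- matrix(.concBatch(psi, model@nComp, pairs, n * nt), n, nt,
                 byrow = TRUE)
  if (includeResidual)
    conc <- conc + (model@errA + model@errB * conc) *
      matrix(rnorm(n * nt), n, nt)
  attr(conc, "times") <- tg
  conc
}

#' Probability of target attainment
#'
#' Fraction (%) of simulated subjects at or above the efficacy threshold
#' at each evaluation time, plus the median and 5th/95th percentile
#' profile curves.
#'
#' @param concMatrix Matrix from [simulatePopulation()] (grid in its
#'   `"times"` attribute).
#' @param threshold Efficacy threshold (mg/L).
#' @param times Evaluation times (must lie on the grid).
#' @return List of class `ptaResult`: `pta` (data.frame time/pta%),
#'   `profiles` (median and 90% interval curves), `threshold`, `n`.
#' @export
pta <- function(concMatrix, threshold, times) {
  tg <- attr(concMatrix, "times")
  idx <- match(times, tg)
  if (any(is.na(idx))) stop("evaluation times must lie on the grid",
                            call. = FALSE)
  ptaPct <- vapply(idx, function(j) 100 * mean(concMatrix[, j] >= threshold),
                   numeric(1))
  qs <- apply(concMatrix, 2, quantile, probs = c(0.05, 0.5, 0.95))
  structure(list(
    pta = data.frame(time = times, pta = ptaPct),
    profiles = data.frame(time = tg, p05 = qs[1, ], p50 = qs[2, ],
                          p95 = qs[3, ]),
    threshold = threshold, n = nrow(concMatrix)), class = "ptaResult")
}

#' Toxicity-threshold exceedance
#'
#' Pointwise fraction of subjects above the neurotoxicity cutoff
#' (360 mg/L by default) along the grid, and each subject's total
#' duration above the cutoff (crossing points located by linear
#' interpolation between grid nodes).
#'
#' @param concMatrix Matrix from [simulatePopulation()].
#' @param cutoff Toxicity cutoff (mg/L).
#' @return List: `fractionAbove` (data.frame time/fraction),
#'   `durationAbove` (per-subject hours above cutoff), `cutoff`.
#' @export
toxicityExceedance <- function(concMatrix, cutoff = 360) {
  tg <- attr(concMatrix, "times")
  frac <- colMeans(concMatrix >= cutoff)
  dur <- apply(concMatrix, 1, .timeAbove, tg = tg, thr = cutoff)
  list(fractionAbove = data.frame(time = tg, fraction = frac),
       durationAbove = dur, cutoff = cutoff)
}

# Duration above a threshold for one piecewise-linear curve.
.timeAbove <- function(y, tg, thr) {
  above <- y >= thr
  if (!any(above)) return(0)
  tot <- 0
  for (k in seq_len(length(tg) - 1)) {
    y1 <- y[k]; y2 <- y[k + 1]; dt <- tg[k + 1] - tg[k]
    if (above[k] && above[k + 1]) tot <- tot + dt
    else if (above[k] != above[k + 1]) {
      frac <- (thr - y1) / (y2 - y1)
      tot <- tot + if (above[k]) frac * dt else (1 - frac) * dt
    }
  }
  tot
}

#' Compare two dosing regimens for a set of covariate profiles
#'
#' For each profile (e.g. the study's obese patients with BMI > 35 and
#' TBW > 100 kg) the individual-typical (eta = 0) curves are computed
#' under both regimens, with the time each stays above the efficacy
#' threshold and the duration above the toxicity cutoff.
#'
#' @param model A [PopPKModel-class].
#' @param profiles data.frame of covariate profiles, one row per subject.
#' @param regimenA,regimenB Dose data.frames (`time`, `amount`).
#' @param efficacy Efficacy threshold (mg/L).
#' @param toxicity Toxicity cutoff (mg/L).
#' @param grid Time grid (h).
#' @return List: `curves` (long data.frame: profile, regimen, time, conc)
#'   and `summary` (per profile x regimen: timeAboveEfficacy,
#'   durationAboveToxicity).
#' @export
compareRegimens <- function(model, profiles,
                            regimenA = data.frame(time = c(0, 4),
                                                  amount = c(4000, 2000)),
                            regimenB = data.frame(time = c(0, 4),
                                                  amount = c(2000, 1000)),
                            efficacy = 20, toxicity = 360,
                            grid = seq(0, 8, by = 0.01)) {
  profiles <- as.data.frame(profiles)
  curves <- list(); summ <- list()
  for (i in seq_len(nrow(profiles))) {
    p <- individualParameters(model,
                              covariates = profiles[i, , drop = FALSE])
    for (reg in c("A", "B")) {
      d <- if (reg == "A") regimenA else regimenB
      cc <- concentrationProfile(p, d, grid)
      curves[[length(curves) + 1]] <-
        data.frame(profile = i, regimen = reg, time = grid, conc = cc)
      summ[[length(summ) + 1]] <- data.frame(
        profile = i, regimen = reg,
        timeAboveEfficacy = .timeAbove(cc, grid, efficacy),
        durationAboveToxicity = .timeAbove(cc, grid, toxicity))
    }
  }
  list(curves = do.call(rbind, curves), summary = do.call(rbind, summ))
}
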