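# Model evaluation: prediction-corrected VPC, normalized prediction
# distribution errors, and goodness-of-fit tables.

# Population predictions (eta = 0) at the observed design.
.predPop <- function(prep, model) {
  psi <- exp(.muMatrix(model, prep$covdf))
  .concBatch(psi, model@nComp, prep$pairs, prep$nObs)
}

# Simulate replicate observation vectors at the observed design.
# Returns an nSim x nObs matrix (with residual error unless noiseFree).
.simAtDesign <- function(prep, model, nSim, noiseFree = FALSE) {
  Mu <- .muMatrix(model, prep$covdf)
  out <- matrix(NA_real_, nSim, prep$nObs)
  for (s in seq_len(nSim)) {
    eta <- sampleEtas(model, prep$n)
    f <- .concBatch(exp(Mu + eta), model@nComp, prep$pairs, prep$nObs)
    out[s, ] <- if (noiseFree) f else
      f + (model@errA + model@errB * f) * rnorm(prep$nObs)
  }
  out
}

#' Prediction-corrected visual predictive check
#'
#' Observations and simulated replicates are rescaled by the ratio of the
#' bin-median population prediction to each record's own population
#' prediction (Bergstrand prediction correction), removing dose and
#' covariate heterogeneity. Within quantile-based time bins, the 5th, 50th
#' and 95th percentiles of the corrected observations are compared against
#' 90% confidence bands of the same percentiles across simulated
#' replicates.
#'
#' @param data A [PKEventData-class].
#' @param model A [PopPKModel-class] (typically a fit's `@model`).
#' @param nSim Number of simulated replicates (default 1000).
#' @param bins Number of quantile-based time bins (default 6).
#' @param seed Integer seed.
#' @param predictionCorrected Set `FALSE` for a plain VPC.
#' @return A list of class `vpcResult`: `bins` (per-bin data.frame with
#'   edges, n, observed percentiles and simulated 90% bands), `obs`
#'   (per-record corrected observations) and settings.
#' @export
pcVpc <- function(data, model, nSim = 1000, bins = 6, seed = 1,
                  predictionCorrected = TRUE) {
  stopifnot(nSim >= 100)
  prep <- .prepareFit(data, model)
  set.seed(seed)
  pred <- .predPop(prep, model)
  keep <- pred > 0
  if (any(!keep))
    warning(sum(!keep), " record(s) with zero population prediction excluded",
            call. = FALSE)
  tt <- prep$obsTime[keep]
  if (length(unique(tt)) <= bins) {
    # nominal-time design: one bin per distinct sampling time, so the
    # correction is exactly the identity when PRED is constant per time
    binOf <- factor(tt)
  } else {
    edges <- unique(quantile(tt, probs = seq(0, 1, length.out = bins + 1)))
    binOf <- cut(tt, edges, include.lowest = TRUE)  # empty bins merge via unique
  }
  medPred <- tapply(pred[keep], binOf, median)
  fac <- if (predictionCorrected)
    as.numeric(medPred[as.integer(binOf)]) / pred[keep] else rep(1, sum(keep))
  pcObs <- prep$y[keep] * fac
  probs <- c(0.05, 0.5, 0.95)
  obsPct <- t(vapply(levels(binOf), function(b)
    quantile(pcObs[binOf == b], probs), numeric(3)))
  sims <- .simAtDesign(prep, model, nSim)[, keep, drop = FALSE]
  simPct <- array(NA_real_, c(nSim, nlevels(binOf), 3))
  for (s in seq_len(nSim)) {
    pcs <- sims[s, ] * fac
    simPct[s, , ] <- t(vapply(levels(binOf), function(b)
      quantile(pcs[binOf == b], probs), numeric(3)))
  }
  lo <- apply(simPct, c(2, 3), quantile, probs = 0.05)
  hi <- apply(simPct, c(2, 3), quantile, probs = 0.95)
  md <- apply(simPct, c(2, 3), median)
  binDf <- data.frame(
    bin = levels(binOf),
    tMid = vapply(levels(binOf), function(b) median(tt[binOf == b]),
                  numeric(1)),
    n = as.integer(table(binOf)),
    obs05 = obsPct[, 1], obs50 = obsPct[, 2], obs95 = obsPct[, 3],
    sim05lo = lo[, 1], sim05hi = hi[, 1], sim05md = md[, 1],
    sim50lo = lo[, 2], sim50hi = hi[, 2], sim50md = md[, 2],
    sim95lo = lo[, 3], sim95hi = hi[, 3], sim95md = md[, 3],
    row.names = NULL)
  structure(list(bins = binDf,
                 obs = data.frame(time = tt, pcObs = pcObs, bin = binOf),
                 nSim = nSim, predictionCorrected = predictionCorrected),
            class = "vpcResult")
}

#' Normalized prediction distribution errors
#'
#' For each subject the observed vector is decorrelated with the mean and
#' covariance of `nSim` simulated replicates (Cholesky), the decorrelated
#' observations are ranked within the decorrelated simulations (midpoint
#' convention for ties), and the ranks are mapped through the standard
#' normal quantile. Under the true model the NPDE are approximately
#' standard normal and uncorrelated.
#'
#' @inheritParams pcVpc
#' @param nSim Number of simulated replicates (at least 500).
#' @return data.frame with one row per (non-BLQ) observation: `ID`,
#'   `TIME`, `PRED` and `npde`.
#' @export
npde <- function(data, model, nSim = 1000, seed = 1) {
  stopifnot(nSim >= 500)
  prep <- .prepareFit(data, model)
  set.seed(seed)
  sims <- .simAtDesign(prep, model, nSim)
  pred <- .predPop(prep, model)
  out <- numeric(prep$nObs)
  for (i in seq_len(prep$n)) {
    sel <- which(prep$obsSubj == i)
    S <- sims[, sel, drop = FALSE]
    y <- prep$y[sel]
    E <- colMeans(S)
    V <- cov(S)
    if (length(sel) > 1) {
      if (rcond(V) < 1e-10) {
        warning("singular simulated covariance: ridge-regularized",
                call. = FALSE)
        V <- V + diag(1e-8 * mean(diag(V)), length(sel))
      }
      L <- t(chol(V))
      yStar <- forwardsolve(L, y - E)
      sStar <- t(forwardsolve(L, t(S) - E))
    } else {
      yStar <- (y - E) / sqrt(V[1, 1])
      sStar <- (S - E) / sqrt(V[1, 1])
    }
    pde <- vapply(seq_along(sel), function(j)
      (sum(sStar[, j] < yStar[j]) + 0.5 * sum(sStar[, j] == yStar[j])) /
        nSim, numeric(1))
    pde <- pmin(pmax(pde, 1 / (2 * nSim)), 1 - 1 / (2 * nSim))
    out[sel] <- qnorm(pde)
  }
  data.frame(ID = prep$ids[prep$obsSubj], TIME = prep$obsTime,
             PRED = pred, npde = out)
}

#' Goodness-of-fit table
#'
#' One row per quantifiable observation with the observed value, the
#' population prediction (eta = 0, each subject's own covariates), the
#' individual prediction (empirical Bayes etas) and the NPDE.
#'
#' @param fit A [PKFit-class].
#' @param nSim Simulated replicates used for the NPDE column.
#' @param seed Integer seed for the NPDE simulation.
#' @return data.frame with `ID`, `TIME`, `OBS`, `PRED`, `IPRED`, `NPDE`.
#' @export
gofTable <- function(fit, nSim = 1000, seed = 1) {
  model <- fit@model
  prep <- .prepareFit(fit@data, model)
  pred <- .predPop(prep, model)
  ebes <- if (nrow(fit@ebes) == prep$n) fit@ebes
          else empiricalBayes(fit)
  Mu <- .muMatrix(model, prep$covdf)
  ipred <- .concBatch(exp(Mu + ebes), model@nComp, prep$pairs, prep$nObs)
  nd <- npde(fit@data, model, nSim = nSim, seed = seed)
  data.frame(ID = prep$ids[prep$obsSubj], TIME = prep$obsTime,
             OBS = prep$y, PRED = pred, IPRED = ipred, NPDE = nd$npde)
}

#' Diagnostic plots
#'
#' `plotVpc()` draws the prediction-corrected VPC (observed percentiles
#' over simulated bands), `plotGof()` observed-vs-predicted panels, and
#' `plotNpde()` NPDE against time and predictions.
#'
#' @param x A `vpcResult` (for `plotVpc`) or [gofTable()] data.frame.
#' @return A ggplot object.
#' @export
plotVpc <- function(x) {
  stopifnot(inherits(x, "vpcResult"))
  b <- x$bins
  ggplot2::ggplot(b, ggplot2::aes(x = tMid)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = sim05lo, ymax = sim05hi),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = sim95lo, ymax = sim95hi),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = sim50lo, ymax = sim50hi),
                         fill = "orange", alpha = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = obs50)) +
    ggplot2::geom_line(ggplot2::aes(y = obs05), linetype = 2) +
    ggplot2::geom_line(ggplot2::aes(y = obs95), linetype = 2) +
    ggplot2::geom_point(data = x$obs,
                        ggplot2::aes(x = time, y = pcObs), alpha = 0.25) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Time after first bolus (h)",
                  y = "Prediction-corrected concentration (mg/L)")
}

#' @rdname plotVpc
#' @export
plotGof <- function(x) {
  df <- rbind(data.frame(pred = x$PRED, obs = x$OBS, panel = "PRED"),
              data.frame(pred = x$IPRED, obs = x$OBS, panel = "IPRED"))
  ggplot2::ggplot(df, ggplot2::aes(x = pred, y = obs)) +
    ggplot2::geom_point(alpha = 0.4, colour = "steelblue") +
    ggplot2::geom_abline(slope = 1, intercept = 0) +
    ggplot2::facet_wrap(~panel) +
    ggplot2::labs(x = "Predicted concentration (mg/L)",
                  y = "Observed concentration (mg/L)")
}

#' @rdname plotVpc
#' @export
plotNpde <- function(x) {
  df <- rbind(data.frame(xv = x$TIME, npde = x$NPDE, panel = "vs time"),
              data.frame(xv = x$PRED, npde = x$NPDE, panel = "vs PRED"))
  ggplot2::ggplot(df, ggplot2::aes(x = xv, y = npde)) +
    ggplot2::geom_point(alpha = 0.4, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::facet_wrap(~panel, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "NPDE")
}
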