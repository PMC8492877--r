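# Closed-form mammillary compartment kinetics for IV bolus input.
#
# The unit-bolus central concentration of an n-compartment mammillary model
# is a sum of n exponentials, C(t) = (1/Vc) * sum_j c_j exp(-lambda_j t),
# with decay rates lambda the eigenvalues of the micro-rate matrix and
# coefficients from partial fractions. Multiple doses superpose linearly.

# psi: matrix (n x P) of natural-scale parameters, columns per .structNames.
# Returns list(lambda, coef): n x nComp matrices with sum(coef) = 1 rowwise.
.dispositionTerms <- function(psi, nComp) {
  cl <- psi[, 1L]; vc <- psi[, 2L]
  k10 <- cl / vc
  if (nComp == 1L)
    return(list(lambda = cbind(k10), coef = cbind(rep(1, length(k10)))))
  k12 <- psi[, 3L] / vc
  k21 <- psi[, 3L] / psi[, 4L]
  if (nComp == 2L) {
    s <- k10 + k12 + k21
    root <- sqrt(pmax(s * s - 4 * k10 * k21, 0))
    al <- (s + root) / 2
    be <- (s - root) / 2
    d <- al - be
    return(list(lambda = cbind(al, be),
                coef = cbind((al - k21) / d, (k21 - be) / d)))
  }
  k13 <- psi[, 5L] / vc
  k31 <- psi[, 5L] / psi[, 6L]
  # cubic lambda^3 - a2 lambda^2 + a1 lambda - a0 = 0, all roots real > 0
  a2 <- k10 + k12 + k13 + k21 + k31
  a1 <- k10 * k21 + k10 * k31 + k12 * k31 + k13 * k21 + k21 * k31
  a0 <- k10 * k21 * k31
  p <- a1 - a2 * a2 / 3
  qq <- -2 * a2^3 / 27 + a2 * a1 / 3 - a0
  m <- 2 * sqrt(pmax(-p / 3, 1e-300))
  arg <- pmin(pmax(3 * qq / (p * m), -1), 1)
  th <- acos(arg) / 3
  l1 <- m * cos(th) + a2 / 3
  l2 <- m * cos(th - 2 * pi / 3) + a2 / 3
  l3 <- m * cos(th - 4 * pi / 3) + a2 / 3
  lam <- cbind(l1, l2, l3)
  cf <- matrix(0, nrow(lam), 3L)
  for (j in 1:3) {
    oth <- setdiff(1:3, j)
    cf[, j] <- (k21 - lam[, j]) * (k31 - lam[, j]) /
      ((lam[, oth[1]] - lam[, j]) * (lam[, oth[2]] - lam[, j]))
  }
  list(lambda = lam, coef = cf)
}

# Flattened observation-by-dose pairing used by the vectorised evaluator.
# obsSubj: subject index per observation row; dose vectors per subject.
.makePairs <- function(obsSubj, obsTime, doseSubj, doseTime, doseAmt) {
  idx <- lapply(seq_along(doseSubj), function(d) {
    w <- which(obsSubj == doseSubj[d] & obsTime >= doseTime[d])
    if (!length(w)) return(NULL)
    cbind(obs = w, dt = obsTime[w] - doseTime[d], amt = doseAmt[d],
          subj = doseSubj[d])
  })
  m <- do.call(rbind, idx)
  if (is.null(m)) m <- matrix(numeric(0), 0, 4,
                              dimnames = list(NULL, c("obs", "dt", "amt", "subj")))
  m
}

# Vectorised concentrations at paired (observation, dose) offsets.
# psi rows are indexed by pair 'subj'. Returns vector of length nObs.
.concBatch <- function(psi, nComp, pairs, nObs) {
  out <- numeric(nObs)
  if (!nrow(pairs)) return(out)
  dt <- .dispositionTerms(psi, nComp)
  s <- pairs[, "subj"]
  contrib <- rowSums(dt$coef[s, , drop = FALSE] *
                     exp(-dt$lambda[s, , drop = FALSE] * pairs[, "dt"])) *
    pairs[, "amt"] / psi[s, 2L]
  agg <- rowsum(contrib, group = pairs[, "obs"])
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

#' Concentration-time profile of a bolus regimen
#'
#' Evaluates the analytic sum-of-exponentials solution of the 1-, 2- or
#' 3-compartment mammillary model with instantaneous IV bolus input,
#' superposing all doses administered at or before each requested time.
#'
#' @param params A [PKParameters-class] object.
#' @param doses data.frame with columns `time` (h, non-decreasing) and
#'   `amount` (mg, positive), one row per bolus.
#' @param times Numeric vector of evaluation times (h, non-negative).
#' @return Numeric vector of central concentrations (mg/L).
#' @examples
#' p <- pkParameters(cl = 2.86, vc = 5.2, q = 10.9, vp = 4.56)
#' concentrationProfile(p, data.frame(time = 0, amount = 2000),
#'                      times = c(0, 1, 4, 8))
#' @export
concentrationProfile <- function(params, doses, times) {
  stopifnot(is(params, "PKParameters"))
  if (any(times < 0)) stop("evaluation times must be non-negative", call. = FALSE)
  if (is.null(doses) || nrow(as.data.frame(doses)) == 0)
    return(numeric(length(times)))
  doses <- as.data.frame(doses)
  if (!all(c("time", "amount") %in% names(doses)))
    stop("doses need 'time' and 'amount' columns", call. = FALSE)
  if (any(doses$amount <= 0)) stop("dose amounts must be positive", call. = FALSE)
  if (is.unsorted(doses$time)) stop("dose times must be non-decreasing", call. = FALSE)
  psi <- matrix(c(params@cl, params@vc, rbind(params@q, params@vp)), nrow = 1)
  pairs <- .makePairs(rep(1L, length(times)), times,
                      rep(1L, nrow(doses)), doses$time, doses$amount)
  .concBatch(psi, params@nComp, pairs, length(times))
}

# Compartment amounts via a plain eigendecomposition of the micro-rate
# matrix; used for mass-balance checks (independent of the trig/quadratic
# closed forms above).
.compartmentAmounts <- function(params, dose, t) {
  n <- params@nComp
  vc <- params@vc
  k10 <- params@cl / vc
  K <- matrix(0, n, n)
  K[1, 1] <- -k10
  if (n > 1) for (j in seq_len(n - 1)) {
    kin <- params@q[j] / vc
    kout <- params@q[j] / params@vp[j]
    K[1, 1] <- K[1, 1] - kin
    K[1, j + 1] <- kout
    K[j + 1, 1] <- kin
    K[j + 1, j + 1] <- -kout
  }
  e <- eigen(K)
  V <- e$vectors
  a0 <- c(dose, rep(0, n - 1))
  sapply(t, function(tt) Re(V %*% (exp(e$values * tt) * solve(V, a0))))
}
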