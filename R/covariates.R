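# Renal-function and body-size covariate formulas.

MGDL_PER_UMOLL <- 1 / 88.4  # serum creatinine unit conversion

.scrToMgdl <- function(scr, unit = c("umol/L", "mg/dL")) {
  unit <- match.arg(unit)
  if (any(scr <= 0)) stop("serum creatinine must be positive", call. = FALSE)
  if (unit == "umol/L") scr * MGDL_PER_UMOLL else scr
}

.isFemale <- function(sex) {
  tolower(as.character(sex)) %in% c("f", "female", "1")
}

#' Cockcroft-Gault creatinine clearance
#'
#' `CrCL = (140 - age) * TBW / (0.814 * SCr[umol/L])`, multiplied by 0.85
#' for females. Serum creatinine may be given in umol/L (default) or mg/dL.
#'
#' @param age Age in years.
#' @param sex `"M"`/`"F"` (or `"male"`/`"female"`).
#' @param tbw Total body weight (kg).
#' @param scr Serum creatinine.
#' @param scrUnit `"umol/L"` (default) or `"mg/dL"`.
#' @return Creatinine clearance in mL/min.
#' @examples
#' crclCockcroftGault(age = 70, sex = "M", tbw = 76, scr = 88.4)  # ~73.9
#' @export
crclCockcroftGault <- function(age, sex, tbw, scr, scrUnit = "umol/L") {
  if (any(is.na(age)) || any(is.na(tbw)) || any(is.na(scr)))
    stop("age, tbw and scr are all required", call. = FALSE)
  scrU <- .scrToMgdl(scr, scrUnit) * 88.4
  out <- (140 - age) * tbw / (0.814 * scrU)
  out <- out * ifelse(.isFemale(sex), 0.85, 1)
  if (any(out <= 0)) {
    warning("age at or beyond 140 years gives a degenerate clearance",
            call. = FALSE)
    out <- pmax(out, 0)
  }
  out
}

#' CKD-EPI estimated creatinine clearance (2009 creatinine equation)
#'
#' `141 * min(SCr/k, 1)^alpha * max(SCr/k, 1)^-1.209 * 0.993^age`, times
#' 1.018 for females, with `k = 0.7` (F) / `0.9` (M) and `alpha = -0.329`
#' (F) / `-0.411` (M); SCr in mg/dL internally.
#'
#' @inheritParams crclCockcroftGault
#' @return Estimated clearance in mL/min/1.73 m2.
#' @examples
#' crclCkdEpi(age = 60, sex = "F", scr = 0.7, scrUnit = "mg/dL")  # ~94
#' @export
crclCkdEpi <- function(age, sex, scr, scrUnit = "umol/L") {
  if (any(is.na(age)) || any(is.na(scr)))
    stop("age and scr are required", call. = FALSE)
  s <- .scrToMgdl(scr, scrUnit)
  fem <- .isFemale(sex)
  kappa <- ifelse(fem, 0.7, 0.9)
  alpha <- ifelse(fem, -0.329, -0.411)
  r <- s / kappa
  141 * pmin(r, 1)^alpha * pmax(r, 1)^(-1.209) * 0.993^age *
    ifelse(fem, 1.018, 1)
}

#' Lean body weight (Janmahasatian 2005)
#'
#' Males: `9270 * TBW / (6680 + 216 * BMI)`; females:
#' `9270 * TBW / (8780 + 244 * BMI)`.
#'
#' @inheritParams crclCockcroftGault
#' @param bmi Body mass index (kg/m2).
#' @return Lean body weight (kg).
#' @examples
#' leanBodyWeight(sex = "M", tbw = 76, bmi = 25)  # ~58.3
#' @export
leanBodyWeight <- function(sex, tbw, bmi) {
  if (any(bmi <= 0)) stop("bmi must be positive", call. = FALSE)
  fem <- .isFemale(sex)
  9270 * tbw / ifelse(fem, 8780 + 244 * bmi, 6680 + 216 * bmi)
}

#' Declare a candidate covariate link
#'
#' Continuous covariates enter as power functions centred on a reference
#' value, `param_i = typical * (x_i / center)^coef`; sex enters as a
#' multiplicative factor `exp(coef)` for females.
#'
#' @param cov Covariate column name (`age`, `tbw`, `bmi`, `lbw`,
#'   `crcl_cg`, `crcl_ckdepi`, `sex`).
#' @param param Target structural parameter (`cl`, `vc`, `q`, `vp`).
#' @param center Positive centering constant for power links (80 for CrCL
#'   in the final model; a cohort median otherwise). Ignored for `sex`.
#' @param coef Initial/assumed coefficient (0 when the link is to be
#'   estimated).
#' @return A covariate-link list consumed by [popPKModel()] and
#'   [forwardStepwise()].
#' @export
candidateCovariate <- function(cov, param = "cl", center = NULL, coef = 0) {
  type <- if (identical(cov, "sex")) "factor" else "power"
  if (type == "power") {
    if (is.null(center) || center <= 0)
      stop("power links need a positive centering constant", call. = FALSE)
  } else center <- NA_real_
  list(cov = cov, param = param, type = type, center = center, coef = coef)
}
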