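# Virtual-cohort generator emulating the hip-arthroplasty study design:
# ~100 adults, 2000 mg cefazolin bolus at anaesthesia induction (4000 mg
# when BMI > 35 and TBW > 100), redosing at 4 h for long surgeries, and a
# five-point sampling schedule (3 min, 20 min, end of surgery, 3 h, 8 h).

#' Cohort design settings
#'
#' Distributional settings of the virtual cohort. Defaults reproduce the
#' study's baseline table: mean age 67 (24-91), mean TBW 76 kg (48-123),
#' 49% female, ~29% obese (BMI > 30), CKD-EPI clearance mean ~83 (17-129)
#' induced by back-calculation from drawn serum creatinine, surgery
#' duration mean 1.16 h (0.49-2.48) and injection-to-incision delay mean
#' 0.85 h (0.18-2.23).
#'
#' @param n Number of subjects.
#' @param ageMean,ageSd,ageRange Truncated-normal age distribution (years).
#' @param pFemale Proportion of females.
#' @param tbwMean,tbwSd,tbwRange Truncated-normal total body weight (kg).
#' @param tbwHeightCorr Correlation between weight and height (keeps the
#'   BMI tail realistic while preserving the weight spread).
#' @param heightMean Named (`M`, `F`) mean heights (m).
#' @param heightSd,heightRange Height spread and truncation (m).
#' @param scrMeanlog Named (`M`, `F`) log-means of serum creatinine
#'   (umol/L, log-normal).
#' @param scrSdlog Log-SD of serum creatinine.
#' @param crclRange Admissible CKD-EPI range (mL/min/1.73 m2); creatinine
#'   is redrawn for subjects falling outside.
#' @param durationMean,durationSd,durationRange Surgery duration (h).
#' @param delayMean,delaySd,delayRange Injection-to-incision delay (h).
#' @param lloq Assay lower limit of quantification (mg/L).
#' @return A list of class `cohortDesign`.
#' @export
cohortDesign <- function(n = 100,
                         ageMean = 68.5, ageSd = 13.5, ageRange = c(24, 91),
                         pFemale = 0.49,
                         tbwMean = 75.5, tbwSd = 16, tbwRange = c(48, 123),
                         tbwHeightCorr = 0.5,
                         heightMean = c(M = 1.74, F = 1.62),
                         heightSd = 0.07, heightRange = c(1.45, 2.00),
                         scrMeanlog = c(M = log(80), F = log(63)),
                         scrSdlog = 0.27,
                         crclRange = c(17, 129),
                         durationMean = 1.11, durationSd = 0.42,
                         durationRange = c(0.49, 2.48),
                         delayMean = 0.80, delaySd = 0.42,
                         delayRange = c(0.18, 2.23),
                         lloq = 5) {
  d <- as.list(environment())
  if (d$n < 1) stop("n must be at least 1", call. = FALSE)
  if (d$lloq < 0) stop("lloq must be non-negative", call. = FALSE)
  stopifnot(ageRange[1] < ageRange[2], tbwRange[1] < tbwRange[2])
  class(d) <- "cohortDesign"
  d
}

#' Generate a virtual cohort
#'
#' Draws subject covariates and surgery times from a [cohortDesign()].
#' Marginals are truncated normals (log-normal for creatinine); BMI is
#' induced from drawn weight and height, and the CKD-EPI clearance from
#' creatinine, age and sex, so that all renal covariates stay mutually
#' consistent. Creatinine is redrawn (up to 50 rounds) for subjects whose
#' clearance falls outside the admissible range.
#'
#' @param design A [cohortDesign()] list.
#' @param seed Optional integer seed.
#' @return data.frame with one row per subject: `id`, `age`, `sex`,
#'   `tbw`, `height`, `bmi`, `lbw`, `scr` (umol/L), `crcl_cg`,
#'   `crcl_ckdepi`, `delay`, `duration`.
#' @examples
#' head(generateCohort(cohortDesign(n = 20), seed = 1))
#' @export
generateCohort <- function(design = cohortDesign(), seed = NULL) {
  stopifnot(inherits(design, "cohortDesign"))
  if (!is.null(seed)) set.seed(seed)
  n <- design$n
  sex <- ifelse(runif(n) < design$pFemale, "F", "M")
  age <- .rtruncnorm(n, design$ageMean, design$ageSd,
                     design$ageRange[1], design$ageRange[2])
  height <- .rtruncnorm(n, design$heightMean[sex], design$heightSd,
                        design$heightRange[1], design$heightRange[2])
  rho <- design$tbwHeightCorr
  tbw <- .rtruncnorm(n,
                     design$tbwMean + rho * design$tbwSd / design$heightSd *
                       (height - design$heightMean[sex]),
                     sqrt(1 - rho^2) * design$tbwSd,
                     design$tbwRange[1], design$tbwRange[2])
  bmi <- tbw / height^2
  scr <- exp(rnorm(n, design$scrMeanlog[sex], design$scrSdlog))
  crcl <- crclCkdEpi(age, sex, scr)
  for (round in 1:50) {
    bad <- crcl < design$crclRange[1] | crcl > design$crclRange[2]
    if (!any(bad)) break
    scr[bad] <- exp(rnorm(sum(bad), design$scrMeanlog[sex[bad]],
                          design$scrSdlog))
    crcl[bad] <- crclCkdEpi(age[bad], sex[bad], scr[bad])
  }
  data.frame(
    id = seq_len(n), age = age, sex = sex, tbw = tbw, height = height,
    bmi = bmi, lbw = leanBodyWeight(sex, tbw, bmi), scr = scr,
    crcl_cg = crclCockcroftGault(age, sex, tbw, scr),
    crcl_ckdepi = crcl,
    delay = .rtruncnorm(n, design$delayMean, design$delaySd,
                        design$delayRange[1], design$delayRange[2]),
    duration = .rtruncnorm(n, design$durationMean, design$durationSd,
                           design$durationRange[1], design$durationRange[2]),
    stringsAsFactors = FALSE)
}

#' Protocol dosing rule
#'
#' 2000 mg at induction (t = 0), doubled to 4000 mg when BMI > 35 kg/m2
#' AND TBW > 100 kg; when surgery extends past 4 h after injection, a
#' redose of half the initial dose (1000 or 2000 mg) is given at exactly
#' 4 h.
#'
#' @param bmi Body mass index (kg/m2).
#' @param tbw Total body weight (kg).
#' @param surgeryEnd End of surgery, hours after the cefazolin injection.
#' @return data.frame with columns `time` (h) and `amount` (mg).
#' @examples
#' protocolDoses(bmi = 27, tbw = 80, surgeryEnd = 4.5)
#' @export
protocolDoses <- function(bmi, tbw, surgeryEnd) {
  if (surgeryEnd <= 0) stop("surgery must end after the injection", call. = FALSE)
  initial <- if (bmi > 35 && tbw > 100) 4000 else 2000
  doses <- data.frame(time = 0, amount = initial)
  if (surgeryEnd > 4)
    doses <- rbind(doses, data.frame(time = 4, amount = initial / 2))
  doses
}

#' Blood-sampling schedule
#'
#' Samples at 3 min (0.05 h) and 20 min (1/3 h) after the bolus, at the
#' end of surgery, and at 3 h and 8 h after the bolus; coincident times
#' are deduplicated.
#'
#' @param delay Injection-to-incision delay (h).
#' @param duration Surgery duration from incision (h).
#' @return Sorted vector of unique sampling times (h post-bolus).
#' @examples
#' samplingTimes(delay = 0.85, duration = 1.16)  # 0.05 0.333 2.01 3 8
#' @export
samplingTimes <- function(delay, duration) {
  if (duration <= 0) stop("surgery must end after incision", call. = FALSE)
  sort(unique(c(0.05, 1 / 3, delay + duration, 3, 8)))
}

#' Simulate an observed dataset from a cohort and model
#'
#' Runs the population model forward: draws one eta vector per subject,
#' derives individual parameters through the covariate map, evaluates the
#' closed-form profile at the protocol sampling times, applies the
#' residual error model, truncates negative observations at zero (logged)
#' and flags records below the limit of quantification.
#'
#' @param cohort Covariate data.frame from [generateCohort()].
#' @param model Generating [PopPKModel-class].
#' @param design The [cohortDesign()] (used for the LLOQ).
#' @param seed Optional integer seed.
#' @return A [PKEventData-class] dataset in the NONMEM convention.
#' @examples
#' d <- cohortDesign(n = 5)
#' simulateDataset(generateCohort(d, seed = 1), cefazolinFinalModel(), d,
#'                 seed = 2)
#' @export
simulateDataset <- function(cohort, model, design = cohortDesign(),
                            seed = NULL) {
  stopifnot(is(model, "PopPKModel"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(cohort)
  eta <- sampleEtas(model, n)
  mu <- .muMatrix(model, cohort)
  psi <- exp(mu + eta)
  recs <- vector("list", n)
  nTrunc <- 0L
  for (i in seq_len(n)) {
    doses <- protocolDoses(cohort$bmi[i], cohort$tbw[i],
                           cohort$delay[i] + cohort$duration[i])
    tt <- samplingTimes(cohort$delay[i], cohort$duration[i])
    pairs <- .makePairs(rep(1L, length(tt)), tt,
                        rep(1L, nrow(doses)), doses$time, doses$amount)
    f <- .concBatch(psi[i, , drop = FALSE], model@nComp, pairs, length(tt))
    dv <- observeConc(f, rnorm(length(tt)), a = model@errA, b = model@errB)
    if (any(dv < 0)) { nTrunc <- nTrunc + sum(dv < 0); dv <- pmax(dv, 0) }
    sid <- if (!is.null(cohort$id)) cohort$id[i] else i
    recs[[i]] <- rbind(
      data.frame(ID = sid, TIME = doses$time, EVID = 1L, AMT = doses$amount,
                 DV = NA_real_, MDV = 1L),
      data.frame(ID = sid, TIME = tt, EVID = 0L, AMT = NA_real_, DV = dv,
                 MDV = 0L))
  }
  if (nTrunc > 0)
    message(nTrunc, " simulated concentration(s) were negative after ",
            "residual noise and were truncated at 0")
  eventDataset(do.call(rbind, recs), cohort, lloq = design$lloq,
               seed = if (is.null(seed)) NA_real_ else seed)
}

#' One-call study simulation
#'
#' Convenience wrapper: [generateCohort()] then [simulateDataset()],
#' deriving the two stage seeds from one master seed.
#'
#' @inheritParams simulateDataset
#' @param design A [cohortDesign()].
#' @param seed Master seed.
#' @return A [PKEventData-class].
#' @export
simulateStudy <- function(design = cohortDesign(),
                          model = cefazolinFinalModel(), seed = 1) {
  cohort <- generateCohort(design, seed = seed)
  simulateDataset(cohort, model, design, seed = seed + 1e6)
}
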