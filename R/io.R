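# Dataset I/O in the NONMEM column convention and the YAML-configured
# pipeline runner.

.requiredCols <- c("ID", "TIME", "EVID", "AMT", "DV", "MDV")

#' Write an event dataset to CSV
#'
#' NONMEM-convention columns (`ID`, `TIME`, `EVID`, `AMT`, `DV`, `MDV`,
#' `BLQ`) followed by the per-subject covariates repeated on each row.
#' Numeric values are written with full precision so that
#' [readDataset()] is an exact inverse.
#'
#' @param data A [PKEventData-class].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeDataset <- function(data, path) {
  stopifnot(is(data, "PKEventData"))
  r <- data@records
  cov <- data@covariates[match(r$ID, data@covariates$id), , drop = FALSE]
  cov$id <- NULL
  out <- cbind(r, cov)
  num <- vapply(out, is.numeric, logical(1))
  for (cn in names(out)[num])
    out[[cn]] <- ifelse(is.na(out[[cn]]), "", sprintf("%.17g", out[[cn]]))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read an event dataset from CSV
#'
#' Validates the NONMEM-convention schema on read: required columns,
#' non-decreasing times within subject, no concentration on dose rows, no
#' amount on observation rows, at least one dose and one observation per
#' subject. Violations raise an error naming the offending row. Row and
#' subject counts are reported via `message()`.
#'
#' @param path CSV path written by [writeDataset()] or hand-assembled in
#'   the same convention.
#' @param lloq Lower limit of quantification used to (re)derive `BLQ` if
#'   that column is absent.
#' @return A [PKEventData-class].
#' @export
readDataset <- function(path, lloq = 5) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.requiredCols, names(raw))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- which(raw$EVID == 1 & !is.na(raw$DV))
  if (length(bad))
    stop("row ", bad[1], ": dose record carries an observed concentration",
         call. = FALSE)
  bad <- which(raw$EVID == 0 & !is.na(raw$AMT))
  if (length(bad))
    stop("row ", bad[1], ": observation record carries a dose amount",
         call. = FALSE)
  for (id in unique(raw$ID)) {
    w <- which(raw$ID == id)
    if (is.unsorted(raw$TIME[w]))
      stop("row ", w[which(diff(raw$TIME[w]) < 0)[1] + 1],
           ": times not non-decreasing within subject ", id, call. = FALSE)
  }
  recCols <- intersect(c(.requiredCols, "BLQ"), names(raw))
  covCols <- setdiff(names(raw), recCols)
  cov <- raw[!duplicated(raw$ID), c("ID", covCols), drop = FALSE]
  names(cov)[1] <- "id"
  rownames(cov) <- NULL
  ds <- eventDataset(raw[, recCols, drop = FALSE], cov, lloq = lloq)
  message(sprintf("read %d rows: %d subjects, %d observation rows",
                  nrow(raw), length(unique(raw$ID)),
                  sum(raw$EVID == 0)))
  ds
}

# ---- pipeline -------------------------------------------------------------

.configKeys <- c("data", "design", "model", "saem", "diagnostics",
                 "scenarios", "stages", "outdir", "seed")

.defaultConfig <- function() {
  list(design = list(n = 100), model = list(compartments = 2),
       saem = list(), diagnostics = list(nSim = 500, bins = 6),
       scenarios = list(list(crcl = 90, dose = 2000)),
       stages = c("simulate", "structural", "select", "fit", "diagnose",
                  "scenarios"),
       outdir = "cefapk-run", seed = 1)
}

.modelFromConfig <- function(mc) {
  nc <- if (is.null(mc$compartments)) 2L else as.integer(mc$compartments)
  theta <- c(cl = 3, vc = 5, q = 8, vp = 5, q2 = 2, vp2 = 8)[seq_len(2 * nc)]
  names(theta) <- .structNames(nc)
  links <- list()
  if (isTRUE(mc$crclOnCl))
    links <- list(candidateCovariate("crcl_ckdepi", "cl", center = 80))
  popPKModel(nc, theta, covariates = links,
             errA = if (is.null(mc$errA)) 0 else mc$errA,
             errB = if (is.null(mc$errB)) 0.12 else mc$errB)
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes the enabled stages in order -- simulate (or load), structural
#' comparison, covariate selection, final fit, diagnostics, scenario
#' simulations -- writing CSV tables, a JSON manifest (config hash, seed,
#' stage timings) and stage completion markers into the output directory.
#' A failing stage stops the downstream stages. With `resume = TRUE`,
#' stages whose completion marker exists are skipped.
#'
#' @param config Path to a YAML file or a configuration list. Recognised
#'   keys: `data` (CSV path) or `design` (cohort settings; use
#'   `subjects` for the cohort size in YAML, where a bare `n` key parses
#'   as a boolean), `model`
#'   (`compartments`, `crclOnCl`, `errA`, `errB`), `saem` (passed to
#'   [saemControl()]), `diagnostics` (`nSim`, `bins`), `scenarios` (list
#'   of `crcl`/`dose` entries), `stages`, `outdir`, `seed`. Unknown keys
#'   are rejected.
#' @param resume Skip stages with existing completion markers.
#' @return Invisibly, the manifest list.
#' @export
runPipeline <- function(config, resume = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  unknown <- setdiff(names(config), .configKeys)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(config$design))
    # YAML 1.1 reads a bare key "n" as boolean; accept "subjects" too
    names(config$design)[names(config$design) %in%
                           c("subjects", "FALSE")] <- "n"
  cfg <- utils::modifyList(.defaultConfig(), config)
  if (!is.null(cfg$data) && !is.null(config$design))
    stop("configure exactly one data source ('data' or 'design')",
         call. = FALSE)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed)
  manifest <- list(package = "cefapk",
                   version = as.character(utils::packageVersion("cefapk")),
                   seed = seed, configHash = .contentHash(cfg),
                   timings = list())
  logFile <- file.path(cfg$outdir, "run.log")
  logLine <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    cat(msg, "\n", sep = "")
    cat(msg, "\n", sep = "", file = logFile, append = TRUE)
  }
  marker <- function(stage) file.path(cfg$outdir, paste0(".", stage, ".done"))
  runStage <- function(stage, fun) {
    if (!(stage %in% cfg$stages)) return(invisible(NULL))
    if (resume && file.exists(marker(stage))) {
      logLine("stage %s: marker present, skipped", stage)
      return(invisible(NULL))
    }
    t0 <- Sys.time()
    fun()
    manifest$timings[[stage]] <<-
      round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)
    file.create(marker(stage))
    logLine("stage %s done (%.1fs)", stage, manifest$timings[[stage]])
  }

  env <- new.env()
  runStage("simulate", function() {
    if (!is.null(cfg$data)) {
      env$data <- readDataset(cfg$data)
    } else {
      design <- do.call(cohortDesign, cfg$design)
      env$data <- simulateStudy(design, cefazolinFinalModel(), seed = seed)
      writeDataset(env$data, file.path(cfg$outdir, "dataset.csv"))
    }
  })
  if (is.null(env$data)) {
    if (!is.null(cfg$data)) env$data <- readDataset(cfg$data)
    else stop("no dataset available; enable the simulate stage or give 'data'",
              call. = FALSE)
  }
  ctl <- do.call(saemControl, c(cfg$saem, list(seed = seed)))

  runStage("structural", function() {
    cs <- compareStructural(env$data, ctl)
    utils::write.csv(cs$trace, file.path(cfg$outdir, "structural.csv"),
                     row.names = FALSE)
    env$nComp <- cs$best
  })
  runStage("select", function() {
    cands <- list(
      candidateCovariate("crcl_ckdepi", "cl", center = 80),
      candidateCovariate("age", "cl", center = 67),
      candidateCovariate("tbw", "cl", center = 76),
      candidateCovariate("lbw", "cl", center = 55),
      candidateCovariate("tbw", "vc", center = 76))
    fs <- forwardStepwise(env$data, cands, control = ctl)
    utils::write.csv(fs$trace, file.path(cfg$outdir, "selection.csv"),
                     row.names = FALSE)
    env$model <- fs$model
    env$fit <- fs$fit
  })
  runStage("fit", function() {
    if (is.null(env$model)) env$model <- .modelFromConfig(cfg$model)
    env$fit <- saemFit(env$data, env$model, ctl)
    est <- data.frame(parameter = c(names(fixedEffects(env$fit)),
                                    paste0("omega_", names(omegaSd(env$fit))),
                                    "corr_cl_vc", "err_a", "err_b",
                                    "logLik", "BIC"),
                      estimate = c(fixedEffects(env$fit),
                                   as.numeric(omegaSd(env$fit)),
                                   env$fit@model@corr,
                                   residualError(env$fit),
                                   env$fit@logLik, env$fit@bic))
    utils::write.csv(est, file.path(cfg$outdir, "estimates.csv"),
                     row.names = FALSE)
  })
  runStage("diagnose", function() {
    if (is.null(env$fit)) stop("diagnostics need a fit stage", call. = FALSE)
    v <- pcVpc(env$data, env$fit@model, nSim = cfg$diagnostics$nSim,
               bins = cfg$diagnostics$bins, seed = seed)
    utils::write.csv(v$bins, file.path(cfg$outdir, "vpc.csv"),
                     row.names = FALSE)
    g <- gofTable(env$fit, nSim = max(cfg$diagnostics$nSim, 500),
                  seed = seed)
    utils::write.csv(g, file.path(cfg$outdir, "gof.csv"), row.names = FALSE)
  })
  runStage("scenarios", function() {
    model <- if (!is.null(env$fit)) env$fit@model else cefazolinFinalModel()
    rows <- lapply(cfg$scenarios, function(sc) {
      s <- regimenScenario(covariates = list(crcl_ckdepi = sc$crcl),
                           doses = data.frame(time = 0, amount = sc$dose),
                           grid = seq(0, 8, by = 0.1))
      cm <- simulatePopulation(model, s, n = 10000, seed = seed)
      p <- pta(cm, s$efficacyThreshold, s$evalTimes)
      data.frame(crcl = sc$crcl, dose = sc$dose,
                 time = p$pta$time, pta = p$pta$pta)
    })
    utils::write.csv(do.call(rbind, rows),
                     file.path(cfg$outdir, "pta.csv"), row.names = FALSE)
  })

  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
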