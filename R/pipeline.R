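## End-to-end workflows: the BOLD/MION sensitivity simulation and the
## synthetic GLM -> RSA pipeline, each driven by a single config whose
## fully resolved form is written beside the outputs.

sensitivityDefaults <- function() list(
  seed = 1L,
  irf = list(dt = 0.1, duration = 60, peakRatio = 1.8, smoothWidth = 1.0,
             boldN = 3, boldTau = 1.2, boldDelay = 0,
             mionMeanLag = 6, mionSdLag = 4.5),
  design = list(switchEvery = 2, totalDuration = 480, tr = 2),
  sweep = list(ratios = seq(1.8, 1.0, by = -0.1), fMax = 0.25, padTo = 120),
  noiseSd = 1)

glmRsaDefaults <- function() list(
  seed = NULL,
  synth = list(nRuns = 10, nConditions = 48, nVoxels = 60,
               censorRate = 0.163, motionRate = 0.03,
               noiseSd = 1, lengthScale = 2,
               categorySd = 0.15, exemplarSd = 0.15,
               baseline = 100, driftPerRun = 0),
  glm = list(hrfMeanLag = 3, hrfSdLag = 1.5, hrfDt = 0.1,
             driftOrder = 1, tr = 2),
  rsa = list(nFolds = 50, shrinkage = 0.1))

## merge a user config into the defaults, rejecting unknown keys
resolveConfig <- function(config, defaults, path = "config") {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
      else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopIfNot(is.list(config), paste0(path, " must be a list"))
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste(paste0(path, "$", unknown), collapse = ", "), call. = FALSE)
  for (k in names(config)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(config[[k]]))
      resolveConfig(config[[k]], defaults[[k]], paste0(path, "$", k))
    else config[[k]]
  }
  defaults
}

logStage <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
}

writeResolved <- function(cfg, outDir) {
  jsonlite::write_json(
    c(cfg, list(package_version = as.character(
        utils::packageVersion("rersim")))),
    file.path(outDir, "config.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
}

#' Run the BOLD/MION sensitivity simulation
#'
#' Builds the impulse-response models and their smooth-onset variants,
#' convolves the alternating fast-switch design into contrast time
#' courses under each model, computes effect energies, analytic
#' contrast standard errors at equal additive noise, periodograms, the
#' full-spectrum dominance test and the peak-ratio sweep. The
#' deterministic report is written as JSON, the spectra as CSV, and the
#' fully resolved config beside them.
#'
#' @param config list (possibly partial) or path to a YAML/JSON file;
#'   unknown keys are rejected. See \code{rersim:::sensitivityDefaults()}
#'   for the tree of recognized keys.
#' @param outDir output directory (created if needed); NULL writes
#'   nothing.
#' @param verbose log one line per stage.
#' @return the report, invisibly: a list with irfs, effect energies,
#'   contrast SEs, dominance and sweep results.
#' @export
runSensitivity <- function(config = list(), outDir = NULL, verbose = FALSE) {
  cfg <- resolveConfig(config, sensitivityDefaults())
  ic <- cfg$irf
  bold <- boldBoynton(dt = ic$dt, duration = ic$duration, n = ic$boldN,
                      tau = ic$boldTau, delay = ic$boldDelay)
  mionRaw <- mionModel(dt = ic$dt, duration = ic$duration,
                       peakRatio = ic$peakRatio,
                       meanLag = ic$mionMeanLag, sdLag = ic$mionSdLag)
  mion <- spliceSmoothOnset(mionRaw, bold)
  boldS <- smoothOnsetVariant(bold, ic$smoothWidth)
  mionS <- smoothOnsetVariant(mion, ic$smoothWidth)
  logStage(verbose, "irfs: bold peak %.2f s, mion peak %.2f s (ratio %.2f)",
           peakTime(bold), peakTime(mion), ic$peakRatio)

  dc <- cfg$design
  sched <- alternatingDesign(dc$switchEvery, dc$totalDuration, dc$tr)
  regBold <- convolveSchedule(sched, boldS, "contrast")
  regMion <- convolveSchedule(sched, mionS, "contrast")
  logStage(verbose, "design: %d events, %d volumes",
           nrow(events(sched)), nVolumes(sched))

  energy <- c(bold = effectEnergy(regBold), mion = effectEnergy(regMion))
  seOf <- function(reg) {
    X <- cbind(contrast = values(reg), intercept = 1)
    contrastSE(X, c(1, 0), cfg$noiseSd)
  }
  se <- c(bold = seOf(regBold), mion = seOf(regMion))
  logStage(verbose, "effect energy bold %.3f mion %.3f; SE bold %.4f mion %.4f",
           energy[["bold"]], energy[["mion"]], se[["bold"]], se[["mion"]])

  sw <- cfg$sweep
  dom <- fullSpectrumDominance(mionS, boldS, fMax = sw$fMax, padTo = sw$padTo)
  builder <- function(r) smoothOnsetPair(
    peakRatio = r, smoothWidth = ic$smoothWidth, dt = ic$dt,
    duration = ic$duration,
    boldArgs = list(n = ic$boldN, tau = ic$boldTau, delay = ic$boldDelay),
    mionArgs = list(meanLag = ic$mionMeanLag, sdLag = ic$mionSdLag))
  sweep <- peakRatioSweep(ratios = sw$ratios, fMax = sw$fMax,
                          builder = builder, padTo = sw$padTo)
  logStage(verbose, "sweep: threshold ratio %s",
           format(sweep$threshold))

  report <- list(
    design = sprintf("alternating switch %gs, TR %gs, %gs run",
                     dc$switchEvery, dc$tr, dc$totalDuration),
    peak_ratio = ic$peakRatio,
    effect_energy = as.list(energy),
    contrast_se = as.list(se),
    dominance = list(dominant = dom$dominant,
                     min_margin = min(dom$margins),
                     first_fail_freq = dom$firstFailFreq),
    threshold_ratio = sweep$threshold,
    sweep = sweep$perRatio)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(outDir, "sensitivity_report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         dataframe = "rows", na = "null")
    writeSpectrum(periodogram(boldS, padTo = sw$padTo),
                  file.path(outDir, "spectrum_bold.csv"))
    writeSpectrum(periodogram(mionS, padTo = sw$padTo),
                  file.path(outDir, "spectrum_mion.csv"))
    writeSpectrum(periodogram(regBold), file.path(outDir,
                                                  "spectrum_contrast_bold.csv"))
    writeResolved(cfg, outDir)
  }
  invisible(report)
}

#' Analyze a (synthetic) session: censoring, per-run GLMs, crossnobis RDM
#'
#' Applies the fixation and motion censoring rules to each run, fits
#' per-run GLMs, extracts condition beta patterns and residuals, and
#' computes the split-half crossnobis RDM. When the dataset was built
#' with zero noise the residual-based covariance is singular, so the
#' identity whitener is used instead.
#'
#' @param dataset a [SyntheticROIDataset-class].
#' @param hrf an [ImpulseResponse-class].
#' @param driftOrder polynomial drift order for the design.
#' @param nFolds,shrinkage passed to [splitHalfRDM()].
#' @param seed integer seed for the fold assignment.
#' @param identityWhitener force the identity noise covariance.
#' @param verbose log one line per stage.
#' @return list with rdm ([RDM-class]) and qc (list of censored /
#'   outlier fractions and per-run dof).
#' @export
analyzeSession <- function(dataset, hrf = gammaHRF(), driftOrder = 1,
                           nFolds = 50, shrinkage = 0.1, seed,
                           identityWhitener = FALSE, verbose = FALSE) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  runs <- sessionRuns(dataset)
  betaList <- list()
  resList <- list()
  dofs <- numeric(length(runs))
  nCens <- 0L
  nMot <- 0L
  nVols <- 0L
  for (r in seq_along(runs)) {
    run <- runs[[r]]
    tr <- trTime(run$schedule)
    fix <- censorBrokenFixation(run$eye, tr)
    mot <- flagMotionOutliers(run$motion)
    nCens <- nCens + sum(!keptVolumes(fix))
    nMot <- nMot + sum(!keptVolumes(mot))
    nVols <- nVols + nVolumes(run$schedule)
    des <- buildDesignMatrix(run$schedule, hrf, censor = fix, motion = mot,
                             driftOrder = driftOrder)
    fit <- fitGLM(des, run$data)
    interest <- des$labels$name[des$labels$type == "interest"]
    betaList[[r]] <- betas(fit)[interest, , drop = FALSE]
    resList[[r]] <- glmResiduals(fit)
    dofs[r] <- dofResidual(fit)
    logStage(verbose, "run %d: %d censored, %d motion, dof %d", r,
             sum(!keptVolumes(fix)), sum(!keptVolumes(mot)), dofs[r])
  }
  patterns <- patternEstimates(betaList)
  rdm <- splitHalfRDM(patterns, residuals = resList, nFolds = nFolds,
                      seed = seed, shrinkage = shrinkage,
                      noiseCov = if (identityWhitener) "identity" else NULL)
  qc <- list(censored_fraction = nCens / nVols,
             motion_fraction = nMot / nVols,
             dof_per_run = dofs,
             n_runs = length(runs), n_volumes = nVols)
  list(rdm = rdm, qc = qc)
}

#' Run the synthetic GLM -> RSA workflow
#'
#' Generates a synthetic session from the config, applies the
#' censoring rules, fits per-run GLMs, computes the split-half
#' crossnobis RDM, and writes the RDM (CSV + JSON sidecar), a QC
#' summary (censored and motion-outlier fractions, per-run degrees of
#' freedom) and the resolved config. With \code{synth$noiseSd = 0} the
#' identity whitener replaces the residual covariance (which would be
#' singular) and the RDM reduces to planted squared Euclidean
#' distances.
#'
#' @param config list or YAML/JSON path; \code{seed} is required.
#'   Unknown keys are rejected. See \code{rersim:::glmRsaDefaults()}.
#' @param outDir output directory; NULL writes nothing.
#' @param verbose log one line per stage.
#' @return invisibly, a list with dataset, rdm and qc.
#' @export
runGlmRsa <- function(config = list(), outDir = NULL, verbose = FALSE) {
  cfg <- resolveConfig(config, glmRsaDefaults())
  if (is.null(cfg$seed)) stop("config$seed is required", call. = FALSE)
  sc <- cfg$synth
  gc <- cfg$glm
  hrf <- gammaHRF(meanLag = gc$hrfMeanLag, sdLag = gc$hrfSdLag,
                  dt = gc$hrfDt)
  dataset <- generateSession(
    nRuns = sc$nRuns, nConditions = sc$nConditions, nVoxels = sc$nVoxels,
    patternSpec = list(nCategories = 4, categorySd = sc$categorySd,
                       exemplarSd = sc$exemplarSd),
    noiseSpec = list(sd = sc$noiseSd, lengthScale = sc$lengthScale),
    censorRate = sc$censorRate, motionRate = sc$motionRate,
    hrf = hrf, tr = gc$tr, baseline = sc$baseline,
    driftPerRun = sc$driftPerRun, seed = deriveSeed(cfg$seed, 1L))
  logStage(verbose, "generated %d runs x %d voxels", sc$nRuns, sc$nVoxels)
  res <- analyzeSession(dataset, hrf = hrf, driftOrder = gc$driftOrder,
                        nFolds = cfg$rsa$nFolds,
                        shrinkage = cfg$rsa$shrinkage,
                        seed = deriveSeed(cfg$seed, 2L),
                        identityWhitener = sc$noiseSd == 0,
                        verbose = verbose)
  if (all(vapply(res$qc$dof_per_run, function(d) d <= 0, logical(1))))
    stop("all runs censored: no usable volumes remain", call. = FALSE)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeRDM(res$rdm, file.path(outDir, "rdm.csv"))
    jsonlite::write_json(res$qc, file.path(outDir, "qc.json"),
                         auto_unbox = TRUE, digits = NA)
    writeResolved(cfg, outDir)
  }
  invisible(list(dataset = dataset, rdm = res$rdm, qc = res$qc))
}
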