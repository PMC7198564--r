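## Seeded synthetic ROI data: voxel time series with planted condition
## patterns, eye-position traces and head-motion series whose planted
## artefact flags are exactly what the censoring operations recover.

#' Synthetic eye-position trace
#'
#' Generates a 20 Hz-style gaze trace consistent with a planted set of
#' broken-fixation volumes: kept volumes have every sample well inside
#' the fixation window, while each broken volume has strictly more than
#' half of its samples outside, so [censorBrokenFixation()] reproduces
#' the planted flags exactly (zero false positives or negatives).
#'
#' @param schedule an [EventSchedule-class] (defines volume count and TR).
#' @param brokenVolumes integer volume indices planted as broken.
#' @param sampleRate eye samples per second.
#' @param windowHalfWidth fixation window half-width in degrees.
#' @param seed integer seed.
#' @return an [EyeTrace-class].
#' @export
generateEyeTrace <- function(schedule, brokenVolumes = integer(),
                             sampleRate = 20, windowHalfWidth = 5, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  nv <- nVolumes(schedule)
  spv <- as.integer(round(sampleRate * trTime(schedule)))
  stopIfNot(all(brokenVolumes >= 1 & brokenVolumes <= nv),
            "brokenVolumes must be valid volume indices")
  n <- nv * spv
  w <- windowHalfWidth
  withSeed(seed, {
    ## fixational jitter well inside the window
    x <- stats::runif(n, -0.6 * w, 0.6 * w)
    y <- stats::runif(n, -0.6 * w, 0.6 * w)
    minOut <- floor(spv / 2) + 1L  # strictly more than half
    for (v in brokenVolumes) {
      nOut <- sample(minOut:spv, 1L)
      idx <- (v - 1L) * spv + sample.int(spv, nOut)
      excursion <- stats::runif(nOut, 1.2 * w, 2.5 * w) *
        sample(c(-1, 1), nOut, replace = TRUE)
      vertical <- stats::runif(nOut) < 0.5
      x[idx[!vertical]] <- excursion[!vertical]
      y[idx[vertical]] <- excursion[vertical]
    }
    eyeTrace(x, y, sampleRate = sampleRate, windowHalfWidth = w)
  })
}

#' Synthetic head-motion variance series
#'
#' Generates a per-volume motion-variance series whose outliers are
#' exactly the planted volumes under the mean + 2 SD rule of
#' [flagMotionOutliers()]. The baseline is uniform around
#' \code{baseLevel} (a bounded distribution can never stray two of its
#' own standard deviations above its mean, so baseline volumes are
#' never flagged); planted spikes sit at \code{spikeScale} times the
#' baseline. The result is validated post hoc against the flagging
#' rule; if the spikes are too small relative to their own inflation of
#' the series moments, an error asks for a larger \code{spikeScale}.
#'
#' @param nVolumes number of volumes.
#' @param outlierVolumes integer volume indices planted as outliers.
#' @param baseLevel baseline motion variance level.
#' @param spikeScale multiple of \code{baseLevel} for planted spikes.
#' @param seed integer seed.
#' @return numeric vector of length \code{nVolumes}.
#' @export
generateMotionSeries <- function(nVolumes, outlierVolumes = integer(),
                                 baseLevel = 1, spikeScale = 10, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  stopIfNot(all(outlierVolumes >= 1 & outlierVolumes <= nVolumes),
            "outlierVolumes must be valid volume indices")
  series <- withSeed(seed, {
    s <- stats::runif(nVolumes, 0.9 * baseLevel, 1.1 * baseLevel)
    s[outlierVolumes] <- baseLevel * spikeScale *
      stats::runif(length(outlierVolumes), 0.95, 1.05)
    s
  })
  ## repair pass: in small samples a baseline draw can exceed the
  ## empirical mean + 2 SD; pull such values back to the base level so
  ## the planted outlier set is exact by construction
  for (i in 1:50) {
    thr <- mean(series) + 2 * stats::sd(series)
    fp <- setdiff(which(series > thr), outlierVolumes)
    if (!length(fp)) break
    series[fp] <- baseLevel
  }
  got <- which(!keptVolumes(flagMotionOutliers(series)))
  if (!identical(got, as.integer(sort(outlierVolumes))))
    stop("planted spikes do not all exceed mean + 2 SD of the series; ",
         "use a larger spikeScale or fewer outliers", call. = FALSE)
  series
}

## spatially correlated voxel noise: cov_ij = sd^2 exp(-|i-j| / length)
spatialNoiseCov <- function(nVoxels, sd, lengthScale) {
  idx <- seq_len(nVoxels)
  sd^2 * exp(-abs(outer(idx, idx, `-`)) / lengthScale)
}

#' Generate a synthetic multi-run ROI session
#'
#' Builds per-run rapid event-related schedules, plants condition
#' patterns with category structure (categories x exemplars, e.g. 4 x 12
#' for a 48-image set), convolves them with the HRF, and adds baseline,
#' optional linear drift and spatially correlated Gaussian noise.
#' Broken-fixation volumes and motion spikes are planted at the given
#' rates, with eye traces and motion series constructed so the
#' censoring operations recover the planted flags exactly. The returned
#' truth (patterns, identity-whitened squared-Euclidean RDM, flags,
#' noise covariance, seed) supports parameter-recovery tests.
#'
#' @param nRuns runs per session (default 10).
#' @param nConditions stimulus conditions per run (default 48).
#' @param nVoxels voxels in the ROI (default 60).
#' @param patternSpec list: nCategories, categorySd (SD of shared
#'   category pattern components), exemplarSd (SD of per-image
#'   components), all in raw signal units per unit regressor.
#' @param noiseSpec list: sd (volume-to-volume noise SD), lengthScale
#'   (spatial correlation length in voxel index units); sd = 0 gives
#'   noiseless data.
#' @param censorRate expected fraction of broken-fixation volumes.
#' @param motionRate expected fraction of motion-outlier volumes.
#' @param hrf an [ImpulseResponse-class] (default macaque [gammaHRF()]).
#' @param tr volume repetition time in seconds.
#' @param baseline mean baseline signal added to every voxel.
#' @param driftPerRun linear drift amplitude over one run (0 = none).
#' @param scheduleArgs extra arguments for [rapidERSchedule()].
#' @param seed integer top-level seed; per-run substreams are derived
#'   from it.
#' @return a [SyntheticROIDataset-class].
#' @export
generateSession <- function(nRuns = 10, nConditions = 48, nVoxels = 60,
                            patternSpec = list(nCategories = 4,
                                               categorySd = 0.15,
                                               exemplarSd = 0.15),
                            noiseSpec = list(sd = 1, lengthScale = 2),
                            censorRate = 0.163, motionRate = 0.03,
                            hrf = gammaHRF(), tr = 2, baseline = 100,
                            driftPerRun = 0, scheduleArgs = list(),
                            seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  stopIfNot(censorRate >= 0 && censorRate < 1, "censorRate must be in [0, 1)")
  stopIfNot(motionRate >= 0 && motionRate < 1, "motionRate must be in [0, 1)")
  if (nVoxels < 2) stop("n_voxels >= 2 required for covariance structure",
                        call. = FALSE)
  nCat <- patternSpec$nCategories
  stopIfNot(nConditions %% nCat == 0,
            "nConditions must be a multiple of nCategories")

  ## planted patterns: shared category component + exemplar component
  patterns <- withSeed(deriveSeed(seed, 1L), {
    catPat <- matrix(stats::rnorm(nCat * nVoxels, sd = patternSpec$categorySd),
                     nCat, nVoxels)
    cat <- rep(seq_len(nCat), each = nConditions / nCat)
    catPat[cat, , drop = FALSE] +
      matrix(stats::rnorm(nConditions * nVoxels,
                          sd = patternSpec$exemplarSd),
             nConditions, nVoxels)
  })
  rownames(patterns) <- paste0("cond_", seq_len(nConditions) - 1L)

  noiseCov <- spatialNoiseCov(nVoxels, noiseSpec$sd, noiseSpec$lengthScale)
  cholNoise <- if (noiseSpec$sd > 0) chol(noiseCov) else NULL

  runs <- vector("list", nRuns)
  brokenVolumes <- vector("list", nRuns)
  motionVolumes <- vector("list", nRuns)
  for (r in seq_len(nRuns)) {
    runSeed <- deriveSeed(seed, 10L * r)
    schedule <- do.call(rapidERSchedule,
                        c(list(nStimuli = nConditions, tr = tr,
                               seed = runSeed), scheduleArgs))
    nv <- nVolumes(schedule)
    des <- buildDesignMatrix(schedule, hrf, driftOrder = -1)
    signal <- des$X %*% patterns[colnames(des$X), , drop = FALSE]
    flags <- withSeed(deriveSeed(seed, 10L * r + 1L), {
      list(broken = which(stats::runif(nv) < censorRate),
           motion = which(stats::runif(nv) < motionRate))
    })
    noise <- if (is.null(cholNoise)) 0 else
      withSeed(deriveSeed(seed, 10L * r + 2L),
               matrix(stats::rnorm(nv * nVoxels), nv, nVoxels) %*% cholNoise)
    drift <- if (driftPerRun != 0)
      driftPerRun * (seq_len(nv) - 1) / (nv - 1) else 0
    Y <- baseline + signal + noise + drift
    eye <- generateEyeTrace(schedule, flags$broken,
                            sampleRate = 20, windowHalfWidth = 5,
                            seed = deriveSeed(seed, 10L * r + 3L))
    motion <- generateMotionSeries(nv, flags$motion,
                                   seed = deriveSeed(seed, 10L * r + 4L))
    runs[[r]] <- list(data = Y, schedule = schedule, eye = eye,
                      motion = motion)
    brokenVolumes[[r]] <- as.integer(flags$broken)
    motionVolumes[[r]] <- as.integer(flags$motion)
  }

  ## planted RDM: squared Euclidean distance under the identity whitener
  rdm <- as.matrix(stats::dist(patterns))^2
  truth <- list(patterns = patterns, rdm = rdm,
                brokenVolumes = brokenVolumes,
                motionVolumes = motionVolumes,
                noiseCov = noiseCov, driftPerRun = driftPerRun,
                censorRate = censorRate, motionRate = motionRate,
                seed = as.integer(seed))
  new("SyntheticROIDataset", runs = runs, truth = truth)
}
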