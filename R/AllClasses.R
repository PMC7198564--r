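#' @import methods
NULL

#' Sampled hemodynamic impulse response
#'
#' An \code{ImpulseResponse} holds a hemodynamic impulse-response function
#' (IRF) sampled on a regular time grid starting at t = 0. The sign
#' convention throughout the package is magnitude-only: the physical MION
#' signal decrease is represented as a positive response, so all model
#' constructors return non-negative samples.
#'
#' @slot name character label for the model.
#' @slot dt grid spacing in seconds.
#' @slot samples numeric vector of amplitudes, one per grid point.
#'
#' @seealso [boldBoynton()], [mionModel()], [gammaHRF()],
#'   [spliceSmoothOnset()], [smoothOnsetVariant()]
#' @export
setClass("ImpulseResponse",
  representation(name = "character", dt = "numeric", samples = "numeric"))

setValidity("ImpulseResponse", function(object) {
  msg <- character()
  if (length(object@dt) != 1L || !is.finite(object@dt) || object@dt <= 0)
    msg <- c(msg, "dt must be a single positive number")
  if (length(object@samples) < 2L)
    msg <- c(msg, "at least 2 samples are required")
  if (!all(is.finite(object@samples)))
    msg <- c(msg, "samples must be finite")
  if (length(msg)) msg else TRUE
})

newImpulseResponse <- function(name, dt, samples) {
  new("ImpulseResponse", name = name, dt = dt, samples = as.numeric(samples))
}

#' Timed stimulus schedule for one fMRI run
#'
#' Events are rows of (onset, duration, condition) in seconds; condition
#' -1 denotes a null (blank) trial. The total duration is always an
#' integer multiple of the volume TR (schedules are padded with trailing
#' blank when built).
#'
#' @slot events data.frame with columns onset, duration, condition.
#' @slot tr volume repetition time in seconds.
#' @slot totalDuration run length in seconds.
#'
#' @seealso [alternatingDesign()], [rapidERSchedule()], [blockSchedule()]
#' @export
setClass("EventSchedule",
  representation(events = "data.frame", tr = "numeric",
                 totalDuration = "numeric"))

setValidity("EventSchedule", function(object) {
  ev <- object@events
  msg <- character()
  if (!all(c("onset", "duration", "condition") %in% names(ev)))
    return("events needs columns onset, duration, condition")
  if (length(object@tr) != 1L || object@tr <= 0)
    msg <- c(msg, "tr must be a single positive number")
  if (nrow(ev)) {
    if (is.unsorted(ev$onset))
      msg <- c(msg, "events must be sorted by onset")
    if (any(ev$onset < -1e-9))
      msg <- c(msg, "onsets must be non-negative")
    if (any(ev$onset + ev$duration > object@totalDuration + 1e-9))
      msg <- c(msg, "events must end within totalDuration")
    stim <- ev[ev$condition >= 0, , drop = FALSE]
    if (nrow(stim) > 1L) {
      ends <- stim$onset + stim$duration
      if (any(stim$onset[-1L] < ends[-nrow(stim)] - 1e-9))
        msg <- c(msg, "stimulus events must not overlap")
    }
  }
  if (!isMultiple(object@totalDuration, object@tr))
    msg <- c(msg, "totalDuration must be an integer multiple of tr")
  if (length(msg)) msg else TRUE
})

newEventSchedule <- function(events, tr, totalDuration) {
  ev <- events[order(events$onset), , drop = FALSE]
  rownames(ev) <- NULL
  new("EventSchedule", events = ev, tr = tr, totalDuration = totalDuration)
}

#' Volume-sampled regressor
#'
#' One amplitude per acquired volume, obtained by convolving a stimulus
#' boxcar (or a two-condition contrast boxcar) with an impulse response
#' and sampling at the end of each TR.
#'
#' @slot values numeric, one value per volume.
#' @slot tr volume repetition time in seconds.
#' @slot condition character description (condition label or contrast).
#'
#' @seealso [convolveSchedule()]
#' @export
setClass("SampledRegressor",
  representation(values = "numeric", tr = "numeric", condition = "character"))

setValidity("SampledRegressor", function(object) {
  if (!all(is.finite(object@values))) "values must be finite" else TRUE
})

#' One-sided power spectrum
#'
#' Discrete-Fourier power per frequency bin from 0 to Nyquist, under the
#' convention that the sum of power over all bins equals the sum of
#' squared samples of the source signal (Parseval).
#'
#' @slot freqs frequencies in Hz, strictly increasing from 0.
#' @slot power non-negative power per bin.
#' @slot df bin width in Hz.
#'
#' @seealso [periodogram()]
#' @export
setClass("PowerSpectrum",
  representation(freqs = "numeric", power = "numeric", df = "numeric"))

setValidity("PowerSpectrum", function(object) {
  msg <- character()
  if (length(object@freqs) != length(object@power))
    msg <- c(msg, "freqs and power must have equal length")
  if (length(object@freqs) && (object@freqs[1L] != 0 ||
      is.unsorted(object@freqs, strictly = TRUE)))
    msg <- c(msg, "freqs must strictly increase from 0")
  if (any(object@power < -1e-12))
    msg <- c(msg, "power must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Gaze-position trace for one run
#'
#' Horizontal and vertical eye position in degrees of visual angle,
#' sampled at a fixed rate, relative to the fixation cue at (0, 0).
#' The fixation window is the square of half-width
#' \code{windowHalfWidth} degrees around the cue.
#'
#' @slot sampleRate samples per second (Hz).
#' @slot x,y gaze position sequences in degrees.
#' @slot windowHalfWidth half-width of the fixation window in degrees.
#'
#' @seealso [censorBrokenFixation()], [generateEyeTrace()]
#' @export
setClass("EyeTrace",
  representation(sampleRate = "numeric", x = "numeric", y = "numeric",
                 windowHalfWidth = "numeric"))

setValidity("EyeTrace", function(object) {
  msg <- character()
  if (object@sampleRate <= 0) msg <- c(msg, "sampleRate must be positive")
  if (length(object@x) != length(object@y))
    msg <- c(msg, "x and y must have equal length")
  if (object@windowHalfWidth <= 0)
    msg <- c(msg, "windowHalfWidth must be positive")
  if (length(msg)) msg else TRUE
})

#' Per-volume censoring mask
#'
#' Keep/exclude flag per volume plus the reason for exclusion
#' ("fixation" or "motion"; "none" for kept volumes).
#'
#' @slot keep logical, TRUE for volumes retained.
#' @slot reason character, one of "none", "fixation", "motion".
#'
#' @seealso [censorBrokenFixation()], [flagMotionOutliers()]
#' @export
setClass("CensorMask",
  representation(keep = "logical", reason = "character"))

setValidity("CensorMask", function(object) {
  msg <- character()
  if (length(object@keep) != length(object@reason))
    msg <- c(msg, "keep and reason must have equal length")
  if (!all(object@reason %in% c("none", "fixation", "motion")))
    msg <- c(msg, "reason must be one of none, fixation, motion")
  if (any(object@keep & object@reason != "none"))
    msg <- c(msg, "kept volumes must have reason 'none'")
  if (length(msg)) msg else TRUE
})

newCensorMask <- function(keep, reason) new("CensorMask", keep = keep, reason = reason)

#' Ordinary-least-squares fit of one run
#'
#' Per-voxel parameter estimates and derived statistics from a single
#' run's GLM. Rows of \code{betas}/\code{se}/\code{tstat}/\code{zstat}
#' are regressors (all-zero design columns yield NA rows), columns are
#' voxels. \code{residuals} is the volumes x voxels residual matrix.
#'
#' @slot betas,se,tstat,zstat regressors x voxels matrices.
#' @slot residuals volumes x voxels matrix.
#' @slot dof residual degrees of freedom (volumes minus design rank).
#' @slot nVolumes number of volumes fitted.
#' @slot labels data.frame describing design columns (name, type).
#'
#' @seealso [fitGLM()], [buildDesignMatrix()]
#' @export
setClass("GLMFit",
  representation(betas = "matrix", se = "matrix", tstat = "matrix",
                 zstat = "matrix", residuals = "matrix", dof = "numeric",
                 nVolumes = "numeric", labels = "data.frame"))

setValidity("GLMFit", function(object) {
  msg <- character()
  if (object@dof <= 0) msg <- c(msg, "dof must be positive")
  ok <- is.finite(object@se) & object@se > 0 & is.finite(object@betas)
  if (any(abs(object@tstat[ok] - object@betas[ok] / object@se[ok]) > 1e-8))
    msg <- c(msg, "tstat must equal betas / se where se > 0")
  if (length(msg)) msg else TRUE
})

#' Regularized noise covariance
#'
#' Voxel x voxel covariance estimated from GLM residuals as
#' \eqn{\Sigma = (1/T) R^\top R}, optionally blended toward its own
#' diagonal by a shrinkage weight so that the matrix is invertible even
#' when voxels outnumber residual degrees of freedom.
#'
#' @slot sigma voxel x voxel covariance matrix.
#' @slot source character note on which residuals produced it.
#' @slot shrinkage shrinkage weight in [0, 1].
#'
#' @seealso [noiseCovariance()], [crossnobis()]
#' @export
setClass("NoiseCov",
  representation(sigma = "matrix", source = "character",
                 shrinkage = "numeric"))

setValidity("NoiseCov", function(object) {
  msg <- character()
  s <- object@sigma
  if (nrow(s) != ncol(s) || max(abs(s - t(s))) > 1e-8)
    msg <- c(msg, "sigma must be square symmetric")
  if (object@shrinkage < 0 || object@shrinkage > 1)
    msg <- c(msg, "shrinkage must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Per-run multivoxel pattern estimates
#'
#' Beta patterns (condition x voxel) for each run of a session, with a
#' per-run availability flag: after trial censoring a condition may have
#' no modelled event in a run, in which case its pattern is unusable.
#'
#' @slot betas list of condition x voxel matrices, one per run.
#' @slot runIds character run identifiers.
#' @slot available conditions x runs logical matrix.
#'
#' @seealso [patternEstimates()], [splitHalfRDM()]
#' @export
setClass("PatternEstimates",
  representation(betas = "list", runIds = "character", available = "matrix"))

setValidity("PatternEstimates", function(object) {
  msg <- character()
  if (length(object@betas) != length(object@runIds))
    msg <- c(msg, "one beta matrix per run id is required")
  if (length(object@betas) > 1L) {
    d <- vapply(object@betas, dim, integer(2))
    if (any(d[1, ] != d[1, 1]) || any(d[2, ] != d[2, 1]))
      msg <- c(msg, "all runs must share conditions and voxels")
  }
  if (length(msg)) msg else TRUE
})

#' Representational dissimilarity matrix
#'
#' Symmetric condition x condition matrix of cross-validated squared
#' Mahalanobis (crossnobis) distances. The diagonal is identically zero
#' by construction; off-diagonal entries may be negative because the
#' cross-validated estimator is unbiased. Entries that could not be
#' estimated in any fold are NA.
#'
#' @slot values condition x condition numeric matrix.
#' @slot conditions character condition labels.
#' @slot nFolds number of cross-validation folds averaged.
#' @slot provenance list of metadata (seed, shrinkage, sessions, ...).
#'
#' @seealso [splitHalfRDM()], [averageRDMs()]
#' @export
setClass("RDM",
  representation(values = "matrix", conditions = "character",
                 nFolds = "numeric", provenance = "list"))

setValidity("RDM", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v)) msg <- c(msg, "values must be square")
  if (nrow(v) != length(object@conditions))
    msg <- c(msg, "one label per condition is required")
  if (any(abs(diag(v)) > 1e-12, na.rm = TRUE))
    msg <- c(msg, "diagonal must be zero")
  d <- v - t(v)
  if (any(abs(d) > 1e-8, na.rm = TRUE))
    msg <- c(msg, "values must be symmetric")
  if (length(msg)) msg else TRUE
})

#' Synthetic ROI dataset with planted ground truth
#'
#' A multi-run session of synthetic ROI voxel time series along with the
#' truth used to generate it: planted condition patterns, the planted
#' (identity-whitened) RDM, planted censor/outlier flags, the noise
#' covariance, and the generator seed. The planted flags are exactly the
#' volumes the censoring operations will exclude -- generator and
#' analyzer are mutually consistent by construction.
#'
#' @slot runs list; each element has data (volumes x voxels matrix),
#'   schedule (EventSchedule), eye (EyeTrace), motion (numeric).
#' @slot truth list with elements patterns, rdm, brokenVolumes,
#'   motionVolumes, noiseCov, drift, seed.
#'
#' @seealso [generateSession()]
#' @export
setClass("SyntheticROIDataset",
  representation(runs = "list", truth = "list"))

setValidity("SyntheticROIDataset", function(object) {
  for (r in object@runs) {
    sched <- r$schedule
    if (nrow(r$data) != round(sched@totalDuration / sched@tr))
      return("each run's volume count must equal totalDuration / tr")
  }
  TRUE
})
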