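#' Accessors for rersim classes
#'
#' Small accessor generics used across the package instead of direct
#' slot access.
#'
#' @param object an object of the documented class.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))
#' @rdname accessors
#' @export
setGeneric("timeStep", function(object) standardGeneric("timeStep"))
#' @rdname accessors
#' @export
setGeneric("peakAmplitude", function(object) standardGeneric("peakAmplitude"))
#' @rdname accessors
#' @export
setGeneric("peakTime", function(object) standardGeneric("peakTime"))
#' @rdname accessors
#' @export
setGeneric("irfTimes", function(object) standardGeneric("irfTimes"))
#' @rdname accessors
#' @export
setGeneric("events", function(object) standardGeneric("events"))
#' @rdname accessors
#' @export
setGeneric("trTime", function(object) standardGeneric("trTime"))
#' @rdname accessors
#' @export
setGeneric("totalDuration", function(object) standardGeneric("totalDuration"))
#' @rdname accessors
#' @export
setGeneric("nVolumes", function(object) standardGeneric("nVolumes"))
#' @rdname accessors
#' @export
setGeneric("values", function(object) standardGeneric("values"))
#' @rdname accessors
#' @export
setGeneric("keptVolumes", function(object) standardGeneric("keptVolumes"))
#' @rdname accessors
#' @export
setGeneric("censorReasons", function(object) standardGeneric("censorReasons"))
#' @rdname accessors
#' @export
setGeneric("betas", function(object) standardGeneric("betas"))
#' @rdname accessors
#' @export
setGeneric("stdErrors", function(object) standardGeneric("stdErrors"))
#' @rdname accessors
#' @export
setGeneric("tStats", function(object) standardGeneric("tStats"))
#' @rdname accessors
#' @export
setGeneric("zStats", function(object) standardGeneric("zStats"))
#' @rdname accessors
#' @export
setGeneric("glmResiduals", function(object) standardGeneric("glmResiduals"))
#' @rdname accessors
#' @export
setGeneric("dofResidual", function(object) standardGeneric("dofResidual"))
#' @rdname accessors
#' @export
setGeneric("designLabels", function(object) standardGeneric("designLabels"))
#' @rdname accessors
#' @export
setGeneric("covMatrix", function(object) standardGeneric("covMatrix"))
#' @rdname accessors
#' @export
setGeneric("conditions", function(object) standardGeneric("conditions"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("sessionRuns", function(object) standardGeneric("sessionRuns"))
#' @rdname accessors
#' @export
setGeneric("plantedTruth", function(object) standardGeneric("plantedTruth"))

## ---- ImpulseResponse ----

#' @rdname accessors
setMethod("samples", "ImpulseResponse", function(object) object@samples)
#' @rdname accessors
setMethod("timeStep", "ImpulseResponse", function(object) object@dt)
#' @rdname accessors
setMethod("irfTimes", "ImpulseResponse",
  function(object) (seq_along(object@samples) - 1L) * object@dt)
#' @rdname accessors
setMethod("peakAmplitude", "ImpulseResponse",
  function(object) max(object@samples))
## ties broken by earliest index
#' @rdname accessors
setMethod("peakTime", "ImpulseResponse",
  function(object) (which.max(object@samples) - 1L) * object@dt)

setMethod("show", "ImpulseResponse", function(object) {
  cat(sprintf(
    "ImpulseResponse '%s': %d samples, dt = %g s, peak %.4g at %.2f s\n",
    object@name, length(object@samples), object@dt,
    peakAmplitude(object), peakTime(object)))
})

## ---- EventSchedule ----

#' @rdname accessors
setMethod("events", "EventSchedule", function(object) object@events)
#' @rdname accessors
setMethod("trTime", "EventSchedule", function(object) object@tr)
#' @rdname accessors
setMethod("totalDuration", "EventSchedule", function(object) object@totalDuration)
#' @rdname accessors
setMethod("nVolumes", "EventSchedule",
  function(object) as.integer(round(object@totalDuration / object@tr)))

setMethod("show", "EventSchedule", function(object) {
  ev <- object@events
  nStim <- sum(ev$condition >= 0)
  nNull <- sum(ev$condition < 0)
  cat(sprintf(
    "EventSchedule: %d stimulus + %d null events, %g s (%d volumes at TR %g s)\n",
    nStim, nNull, object@totalDuration, nVolumes(object), object@tr))
})

## ---- SampledRegressor ----

#' @rdname accessors
setMethod("values", "SampledRegressor", function(object) object@values)
#' @rdname accessors
setMethod("trTime", "SampledRegressor", function(object) object@tr)
#' @rdname accessors
setMethod("nVolumes", "SampledRegressor", function(object) length(object@values))

setMethod("show", "SampledRegressor", function(object) {
  cat(sprintf("SampledRegressor '%s': %d volumes at TR %g s\n",
              object@condition, length(object@values), object@tr))
})

## ---- PowerSpectrum ----

#' @rdname accessors
setMethod("values", "PowerSpectrum", function(object) object@power)

#' Frequencies of a power spectrum
#' @param object a PowerSpectrum.
#' @return numeric vector of frequencies in Hz.
#' @export
frequencies <- function(object) object@freqs

setMethod("show", "PowerSpectrum", function(object) {
  cat(sprintf("PowerSpectrum: %d bins, df = %.4g Hz, Nyquist = %.4g Hz\n",
              length(object@freqs), object@df, max(object@freqs)))
})

## ---- CensorMask ----

#' @rdname accessors
setMethod("keptVolumes", "CensorMask", function(object) object@keep)
#' @rdname accessors
setMethod("censorReasons", "CensorMask", function(object) object@reason)
#' @rdname accessors
setMethod("nVolumes", "CensorMask", function(object) length(object@keep))

setMethod("show", "CensorMask", function(object) {
  tab <- table(factor(object@reason[!object@keep],
                      levels = c("fixation", "motion")))
  cat(sprintf("CensorMask: %d/%d volumes excluded (fixation %d, motion %d)\n",
              sum(!object@keep), length(object@keep),
              tab[["fixation"]], tab[["motion"]]))
})

## ---- GLMFit ----

#' @rdname accessors
setMethod("betas", "GLMFit", function(object) object@betas)
#' @rdname accessors
setMethod("stdErrors", "GLMFit", function(object) object@se)
#' @rdname accessors
setMethod("tStats", "GLMFit", function(object) object@tstat)
#' @rdname accessors
setMethod("zStats", "GLMFit", function(object) object@zstat)
#' @rdname accessors
setMethod("glmResiduals", "GLMFit", function(object) object@residuals)
#' @rdname accessors
setMethod("dofResidual", "GLMFit", function(object) object@dof)
#' @rdname accessors
setMethod("nVolumes", "GLMFit", function(object) object@nVolumes)
#' @rdname accessors
setMethod("designLabels", "GLMFit", function(object) object@labels)

setMethod("show", "GLMFit", function(object) {
  cat(sprintf("GLMFit: %d regressors x %d voxels, T = %d, dof = %d\n",
              nrow(object@betas), ncol(object@betas),
              as.integer(object@nVolumes), as.integer(object@dof)))
})

## ---- NoiseCov ----

#' @rdname accessors
setMethod("covMatrix", "NoiseCov", function(object) object@sigma)

setMethod("show", "NoiseCov", function(object) {
  cat(sprintf("NoiseCov: %d x %d (%s), shrinkage %.2f\n",
              nrow(object@sigma), ncol(object@sigma), object@source,
              object@shrinkage))
})

## ---- PatternEstimates ----

#' @rdname accessors
setMethod("conditions", "PatternEstimates",
  function(object) rownames(object@betas[[1L]]))

setMethod("show", "PatternEstimates", function(object) {
  cat(sprintf(
    "PatternEstimates: %d runs, %d conditions x %d voxels (%.0f%% available)\n",
    length(object@betas), nrow(object@betas[[1L]]), ncol(object@betas[[1L]]),
    100 * mean(object@available)))
})

## ---- RDM ----

#' @rdname accessors
setMethod("values", "RDM", function(object) object@values)
#' @rdname accessors
setMethod("conditions", "RDM", function(object) object@conditions)
#' @rdname accessors
setMethod("provenance", "RDM", function(object) object@provenance)

setMethod("show", "RDM", function(object) {
  off <- object@values[upper.tri(object@values)]
  cat(sprintf(
    "RDM: %d conditions, %d folds; off-diagonal mean %.4g (%d NA)\n",
    length(object@conditions), as.integer(object@nFolds),
    mean(off, na.rm = TRUE), sum(is.na(off))))
})

## ---- SyntheticROIDataset ----

#' @rdname accessors
setMethod("sessionRuns", "SyntheticROIDataset", function(object) object@runs)
#' @rdname accessors
setMethod("plantedTruth", "SyntheticROIDataset", function(object) object@truth)

setMethod("show", "SyntheticROIDataset", function(object) {
  r1 <- object@runs[[1L]]
  cat(sprintf(
    "SyntheticROIDataset: %d runs of %d volumes x %d voxels (seed %d)\n",
    length(object@runs), nrow(r1$data), ncol(r1$data),
    object@truth$seed))
})
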