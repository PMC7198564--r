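## Per-run GLM estimation with behaviour-based trial censoring: broken
## fixation detection from eye traces, motion-outlier flagging, design
## construction with nuisance columns, OLS, t-to-z conversion, percent
## signal change and spherical ROI geometry.

#' Build an eye trace
#'
#' @param x,y gaze positions in degrees relative to the fixation cue.
#' @param sampleRate samples per second (default 20 Hz).
#' @param windowHalfWidth fixation window half-width in degrees
#'   (default 5, i.e. the +/- 5 degree box).
#' @return an [EyeTrace-class].
#' @export
eyeTrace <- function(x, y, sampleRate = 20, windowHalfWidth = 5) {
  new("EyeTrace", sampleRate = sampleRate, x = as.numeric(x),
      y = as.numeric(y), windowHalfWidth = windowHalfWidth)
}

#' Censor volumes with broken fixation
#'
#' A volume is excluded when the subject looked outside the fixation
#' window for strictly more than half of that volume's eye samples. At
#' 20 Hz and TR 2 s each volume spans 40 samples, so exclusion requires
#' more than 20 samples (i.e. more than 1 s) outside the +/- 5 degree
#' box; exactly half keeps the volume.
#'
#' @param trace an [EyeTrace-class].
#' @param tr volume repetition time in seconds.
#' @return a [CensorMask-class] with reason "fixation" for exclusions.
#' @export
censorBrokenFixation <- function(trace, tr = 2) {
  spv <- trace@sampleRate * tr
  stopIfNot(isMultiple(spv, 1), "sampleRate * tr must be an integer")
  spv <- as.integer(round(spv))
  n <- length(trace@x)
  if (n < spv)
    stop("eye trace shorter than one volume", call. = FALSE)
  stopIfNot(n %% spv == 0L,
            "eye trace must cover an integer number of volumes")
  w <- trace@windowHalfWidth
  outside <- abs(trace@x) > w | abs(trace@y) > w
  nOut <- colSums(matrix(outside, nrow = spv))
  keep <- !(nOut > spv / 2)
  newCensorMask(keep, ifelse(keep, "none", "fixation"))
}

#' Flag head-motion outlier volumes
#'
#' A volume is flagged when its motion variance exceeds the mean plus
#' two standard deviations of the whole series (strict inequality; a
#' constant series flags nothing).
#'
#' @param motionVariance numeric per-volume head-motion variance.
#' @return a [CensorMask-class] with reason "motion" for flags.
#' @export
flagMotionOutliers <- function(motionVariance) {
  stopIfNot(length(motionVariance) >= 3L, "need at least 3 volumes")
  stopIfNot(all(is.finite(motionVariance)), "motion series must be finite")
  thr <- mean(motionVariance) + 2 * stats::sd(motionVariance)
  keep <- !(motionVariance > thr)
  newCensorMask(keep, ifelse(keep, "none", "motion"))
}

#' Build a GLM design matrix
#'
#' One HRF-convolved column per stimulus condition, with the boxcar of
#' any event zeroed when one of the volumes it spans is
#' fixation-censored (the trial is "not modelled"); one one-hot
#' nuisance column per motion-flagged volume; and polynomial drift
#' columns of order 0..driftOrder (order 0 is the intercept). A
#' condition whose every event is censored yields an all-zero column,
#' flagged in the labels and excluded from invertibility requirements.
#'
#' @param schedule an [EventSchedule-class].
#' @param hrf an [ImpulseResponse-class] whose dt divides the TR.
#' @param censor optional fixation [CensorMask-class].
#' @param motion optional motion [CensorMask-class].
#' @param driftOrder polynomial drift order (default 1: intercept +
#'   linear trend); negative for no drift columns.
#' @return list with \code{X} (volumes x columns matrix) and
#'   \code{labels} data.frame (name, type in interest/nuisance/drift,
#'   allZero flag).
#' @export
buildDesignMatrix <- function(schedule, hrf, censor = NULL, motion = NULL,
                              driftOrder = 1) {
  nv <- nVolumes(schedule)
  tr <- trTime(schedule)
  if (!is.null(censor))
    stopIfNot(nVolumes(censor) == nv, "censor mask must match volume count")
  if (!is.null(motion))
    stopIfNot(nVolumes(motion) == nv, "motion mask must match volume count")
  ev <- events(schedule)
  condLabs <- sort(unique(ev$condition[ev$condition >= 0]))

  ## an event is censored when any volume overlapping it is excluded
  eventCensored <- rep(FALSE, nrow(ev))
  if (!is.null(censor)) {
    bad <- which(!keptVolumes(censor))
    for (v in bad) {
      t0 <- (v - 1) * tr
      t1 <- v * tr
      hit <- ev$onset < t1 - 1e-9 & (ev$onset + ev$duration) > t0 + 1e-9
      eventCensored <- eventCensored | hit
    }
  }

  cols <- list()
  for (k in condLabs) {
    keepEv <- ev$condition == k & !eventCensored
    sub <- ev[keepEv, , drop = FALSE]
    if (nrow(sub) == 0L) {
      cols[[paste0("cond_", k)]] <- numeric(nv)
    } else {
      s <- newEventSchedule(sub, tr, totalDuration(schedule))
      cols[[paste0("cond_", k)]] <- values(convolveSchedule(s, hrf, k))
    }
  }
  labels <- data.frame(name = names(cols), type = "interest",
                       allZero = vapply(cols, function(x) all(x == 0),
                                        logical(1)))
  if (!is.null(motion)) {
    for (v in which(!keptVolumes(motion))) {
      nm <- paste0("motion_v", v)
      col <- numeric(nv)
      col[v] <- 1
      cols[[nm]] <- col
      labels <- rbind(labels, data.frame(name = nm, type = "nuisance",
                                         allZero = FALSE))
    }
  }
  if (driftOrder >= 0) {
    tt <- seq_len(nv)
    for (d in 0:driftOrder) {
      nm <- paste0("drift_", d)
      col <- if (d == 0) rep(1, nv) else scale(tt^d)[, 1L]
      cols[[nm]] <- col
      labels <- rbind(labels, data.frame(name = nm, type = "drift",
                                         allZero = FALSE))
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  rownames(labels) <- NULL
  list(X = X, labels = labels)
}

#' Fit a per-run GLM by ordinary least squares
#'
#' Per-voxel OLS on a volumes x voxels data matrix. All-zero design
#' columns (fully censored conditions) are dropped from the fit and
#' reported as NA rows. Standard errors derive from the residual
#' variance after the complete model is fit; t = beta / se; z is the
#' tail-matched standard-normal equivalent of t.
#'
#' @param design either the list returned by [buildDesignMatrix()] or a
#'   plain design matrix.
#' @param data volumes x voxels numeric matrix (a single voxel may be a
#'   vector).
#' @return a [GLMFit-class].
#' @export
fitGLM <- function(design, data) {
  if (is.list(design) && !is.null(design$X)) {
    X <- design$X
    labels <- design$labels
  } else {
    X <- as.matrix(design)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    labels <- data.frame(name = colnames(X), type = "interest",
                         allZero = apply(X == 0, 2, all))
  }
  Y <- as.matrix(data)
  stopIfNot(all(is.finite(Y)), "data must be finite")
  stopIfNot(nrow(Y) == nrow(X), "data and design must agree on volumes")
  zero <- apply(X == 0, 2, all)
  Xf <- X[, !zero, drop = FALSE]
  stopIfNot(nrow(Xf) > ncol(Xf), "need more volumes than regressors")
  qrX <- qr(Xf)
  if (qrX$rank < ncol(Xf)) {
    bad <- colnames(Xf)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("singular design after dropping all-zero columns; offending: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  nT <- nrow(Xf)
  dof <- nT - qrX$rank
  beta <- qr.coef(qrX, Y)
  res <- Y - Xf %*% beta
  sigma2 <- colSums(res^2) / dof
  xtxInv <- chol2inv(qr.R(qrX))
  piv <- qrX$pivot
  xtxInv[piv, piv] <- xtxInv
  seScale <- sqrt(diag(xtxInv))
  se <- outer(seScale, sqrt(sigma2))
  tstat <- ifelse(se > 0, beta / se, NA_real_)
  z <- tToZ(tstat, dof)

  full <- function(m) {
    out <- matrix(NA_real_, nrow = ncol(X), ncol = ncol(Y),
                  dimnames = list(colnames(X), colnames(Y)))
    out[!zero, ] <- m
    out
  }
  new("GLMFit", betas = full(beta), se = full(se), tstat = full(tstat),
      zstat = full(z), residuals = res, dof = dof, nVolumes = nT,
      labels = labels)
}

#' Convert a t statistic to a z statistic
#'
#' Two-sided, sign-preserving tail matching: the returned z has the
#' same upper-tail probability under the standard normal as |t| has
#' under the t distribution with \code{dof} degrees of freedom, with
#' t's sign restored. Computed in log-tail space so |t| up to 40 maps
#' to a finite z.
#'
#' @param t t statistic(s); vectors and matrices are handled
#'   elementwise.
#' @param dof residual degrees of freedom (>= 1).
#' @return z statistic(s) with the shape of \code{t}.
#' @export
tToZ <- function(t, dof) {
  stopIfNot(all(dof >= 1), "dof must be >= 1")
  logp <- stats::pt(abs(t), df = dof, lower.tail = FALSE, log.p = TRUE)
  z <- sign(t) * stats::qnorm(logp, lower.tail = FALSE, log.p = TRUE)
  z[!is.finite(t) & !is.na(t)] <- NA_real_
  if (is.matrix(t)) dim(z) <- dim(t)
  z
}

#' Percent signal change from a beta estimate
#'
#' Featquery-style scaling: the beta is multiplied by the height of an
#' isolated single-event regressor (so the product is the peak signal
#' excursion one event produces) and expressed as a percentage of the
#' baseline mean signal.
#'
#' @param beta parameter estimate.
#' @param regressorHeight peak of an isolated single-event regressor.
#' @param baselineMean mean baseline signal (> 0).
#' @return percent signal change.
#' @export
percentSignalChange <- function(beta, regressorHeight, baselineMean) {
  if (any(baselineMean <= 0))
    stop("baselineMean must be positive", call. = FALSE)
  100 * beta * regressorHeight / baselineMean
}

#' Spherical ROI mask on a voxel grid
#'
#' All voxels whose centre lies within Euclidean distance
#' \code{radius} (inclusive) of the centre voxel's centre. On the
#' 1.5 mm grid a 2 mm radius keeps the centre plus its six face
#' neighbours (diagonals sit at 1.5 * sqrt(2) ~ 2.12 mm).
#'
#' @param center integer voxel index triple.
#' @param radius sphere radius in mm.
#' @param voxelSize isotropic voxel size in mm.
#' @return integer matrix, one voxel index triple per row.
#' @export
sphericalROIMask <- function(center = c(0L, 0L, 0L), radius, voxelSize = 1.5) {
  stopIfNot(radius >= 0, "radius must be non-negative")
  stopIfNot(voxelSize > 0, "voxelSize must be positive")
  r <- floor(radius / voxelSize + 1e-9)
  off <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  d <- voxelSize * sqrt(off$dx^2 + off$dy^2 + off$dz^2)
  sel <- off[d <= radius + 1e-9, , drop = FALSE]
  m <- cbind(center[1L] + sel$dx, center[2L] + sel$dy, center[3L] + sel$dz)
  colnames(m) <- c("x", "y", "z")
  m[order(m[, 1L], m[, 2L], m[, 3L]), , drop = FALSE]
}
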