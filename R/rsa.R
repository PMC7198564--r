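## Cross-validated Mahalanobis (crossnobis) distances: noise covariance
## from GLM residuals, split-half fold construction, RDM assembly and
## averaging.

#' Bundle per-run beta patterns
#'
#' @param betaList list of condition x voxel matrices, one per run, all
#'   sharing row (condition) and column (voxel) sets. Rows that are
#'   all-NA or all-zero are marked unavailable (the condition had no
#'   modelled event in that run).
#' @param runIds optional character run identifiers.
#' @return a [PatternEstimates-class].
#' @export
patternEstimates <- function(betaList, runIds = NULL) {
  stopIfNot(length(betaList) >= 1L, "at least one run is required")
  if (is.null(runIds)) runIds <- paste0("run", seq_along(betaList))
  if (is.null(rownames(betaList[[1L]])))
    betaList <- lapply(betaList, function(m) {
      rownames(m) <- paste0("cond_", seq_len(nrow(m)) - 1L); m
    })
  avail <- vapply(betaList, function(m) {
    apply(m, 1L, function(r) !all(is.na(r)) && !all(r[!is.na(r)] == 0))
  }, logical(nrow(betaList[[1L]])))
  avail <- matrix(avail, nrow = nrow(betaList[[1L]]),
                  dimnames = list(rownames(betaList[[1L]]), runIds))
  new("PatternEstimates", betas = betaList, runIds = runIds,
      available = avail)
}

#' Noise covariance from GLM residuals
#'
#' Estimates the voxel x voxel noise covariance as
#' \eqn{\Sigma = (1/T) R^\top R} from the T x P residual matrix, then
#' blends it with its own diagonal:
#' \eqn{(1-\lambda)\Sigma + \lambda\,\mathrm{diag}(\Sigma)}. Any
#' positive shrinkage guarantees invertibility when all voxels have
#' non-zero residual variance; shrinkage 0 reproduces the raw estimate.
#'
#' @param residuals T x P residual matrix (volumes x voxels).
#' @param shrinkage shrinkage weight in [0, 1] toward the diagonal.
#' @return a [NoiseCov-class].
#' @export
noiseCovariance <- function(residuals, shrinkage = 0.1) {
  R <- as.matrix(residuals)
  stopIfNot(all(is.finite(R)), "residuals must be finite")
  stopIfNot(nrow(R) >= 2L, "need at least 2 residual rows")
  stopIfNot(shrinkage >= 0 && shrinkage <= 1, "shrinkage must be in [0, 1]")
  S <- crossprod(R) / nrow(R)
  Sreg <- (1 - shrinkage) * S + shrinkage * diag(diag(S), nrow(S))
  new("NoiseCov", sigma = Sreg,
      source = sprintf("T=%d residual rows", nrow(R)),
      shrinkage = shrinkage)
}

#' Crossnobis bilinear form
#'
#' The cross-validated squared Mahalanobis distance contribution of one
#' fold: \deqn{(b_{k,A} - b_{j,A}) \Sigma_A^{-1} (b_{k,B} - b_{j,B})^\top}
#' where A is the training half (also supplying the noise covariance)
#' and B the test half. Because the two halves carry independent noise
#' the estimator is unbiased and may be negative.
#'
#' @param deltaA pattern difference vector from the training half.
#' @param deltaB pattern difference vector from the test half.
#' @param covA a [NoiseCov-class] or plain covariance matrix.
#' @return a single number (possibly negative).
#' @export
crossnobis <- function(deltaA, deltaB, covA) {
  S <- if (is(covA, "NoiseCov")) covMatrix(covA) else as.matrix(covA)
  stopIfNot(length(deltaA) == length(deltaB) && length(deltaA) == nrow(S),
            "delta vectors must match the covariance dimension")
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch))
    stop("singular noise covariance; consider shrinkage > 0", call. = FALSE)
  drop(crossprod(deltaA, chol2inv(ch) %*% deltaB))
}

## Crossnobis for every condition pair at once, from half-mean pattern
## matrices A and B (conditions x voxels; NA rows = unavailable).
## entry(k, j) = (a_k - a_j) Sigma^-1 (b_k - b_j)^T
##            = M[k,k] - M[k,j] - M[j,k] + M[j,j],  M = A Sigma^-1 B^T
crossnobisAllPairs <- function(A, B, sigma) {
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch))
    stop("singular noise covariance; consider shrinkage > 0", call. = FALSE)
  ok <- !apply(is.na(A), 1L, any) & !apply(is.na(B), 1L, any)
  A0 <- A; B0 <- B
  A0[!ok, ] <- 0; B0[!ok, ] <- 0
  M <- A0 %*% chol2inv(ch) %*% t(B0)
  d <- diag(M)
  D <- outer(d, d, `+`) - M - t(M)
  D[!ok, ] <- NA_real_
  D[, !ok] <- NA_real_
  diag(D) <- ifelse(ok, 0, NA_real_)
  D
}

#' Split-half crossnobis RDM
#'
#' Repeats \code{nFolds} seeded random splits of the runs into a
#' training half A and a test half B (dropping one random run when the
#' count is odd). Within each half, available per-condition betas are
#' averaged across runs; the noise covariance is estimated from the
#' training half's concatenated residuals; crossnobis values are
#' computed for every condition pair and averaged over folds. A pair is
#' skipped in a fold when either condition is unavailable in either
#' half; a pair available in no fold yields NA.
#'
#' @param patterns a [PatternEstimates-class].
#' @param residuals list of per-run T x P residual matrices (same order
#'   as the runs in \code{patterns}); may be NULL when \code{noiseCov}
#'   is supplied.
#' @param nFolds number of random split-half folds (default 50).
#' @param seed integer seed for the fold assignment; required.
#' @param shrinkage shrinkage passed to [noiseCovariance()].
#' @param noiseCov optional fixed whitener: "identity", a matrix, or a
#'   [NoiseCov-class]; overrides estimation from residuals.
#' @return an [RDM-class].
#' @export
splitHalfRDM <- function(patterns, residuals = NULL, nFolds = 50, seed,
                         shrinkage = 0.1, noiseCov = NULL) {
  if (missing(seed))
    stop("seed is required: fold assignment is random", call. = FALSE)
  nRuns <- length(patterns@betas)
  if (nRuns < 2L)
    stop("need at least 2 usable runs for split-half cross-validation",
         call. = FALSE)
  nCond <- nrow(patterns@betas[[1L]])
  nVox <- ncol(patterns@betas[[1L]])
  condLabs <- conditions(patterns)
  if (is.null(noiseCov))
    stopIfNot(is.list(residuals) && length(residuals) == nRuns,
              "one residual matrix per run is required")
  fixedSigma <- NULL
  if (!is.null(noiseCov)) {
    fixedSigma <- if (identical(noiseCov, "identity")) diag(nVox)
      else if (is(noiseCov, "NoiseCov")) covMatrix(noiseCov)
      else as.matrix(noiseCov)
  }

  halfMean <- function(runIdx) {
    acc <- matrix(0, nCond, nVox)
    cnt <- numeric(nCond)
    for (r in runIdx) {
      av <- patterns@available[, r]
      b <- patterns@betas[[r]]
      acc[av, ] <- acc[av, , drop = FALSE] + b[av, , drop = FALSE]
      cnt[av] <- cnt[av] + 1
    }
    out <- acc / cnt
    out[cnt == 0, ] <- NA_real_
    out
  }

  accSum <- matrix(0, nCond, nCond)
  cnt <- matrix(0L, nCond, nCond)
  folds <- withSeed(seed, {
    lapply(seq_len(nFolds), function(i) sample.int(nRuns))
  })
  half <- floor(nRuns / 2)
  for (perm in folds) {
    use <- perm[seq_len(2L * half)]  # odd run count: drop one random run
    idxA <- use[seq_len(half)]
    idxB <- use[half + seq_len(half)]
    A <- halfMean(idxA)
    B <- halfMean(idxB)
    sigma <- if (!is.null(fixedSigma)) fixedSigma else
      covMatrix(noiseCovariance(do.call(rbind, residuals[idxA]),
                                shrinkage = shrinkage))
    D <- crossnobisAllPairs(A, B, sigma)
    ok <- !is.na(D)
    accSum[ok] <- accSum[ok] + D[ok]
    cnt[ok] <- cnt[ok] + 1L
  }
  vals <- ifelse(cnt > 0, accSum / cnt, NA_real_)
  ## the estimator is not exactly symmetric per fold (Sigma from A only);
  ## symmetrize, preserving NA structure
  vals <- (vals + t(vals)) / 2
  dimnames(vals) <- list(condLabs, condLabs)
  new("RDM", values = vals, conditions = condLabs, nFolds = nFolds,
      provenance = list(seed = seed, shrinkage = shrinkage,
                        nRuns = nRuns,
                        whitener = if (is.null(fixedSigma)) "residuals"
                                   else "fixed"))
}

#' Average RDMs entrywise
#'
#' Entrywise mean across sessions or hemispheres, ignoring missing
#' values (an entry missing in some inputs is the mean of the others).
#'
#' @param rdms list of [RDM-class] objects with identical condition
#'   labels.
#' @param grouping character tag recorded in the provenance
#'   ("session" or "hemisphere").
#' @return an [RDM-class].
#' @export
averageRDMs <- function(rdms, grouping = "session") {
  stopIfNot(length(rdms) >= 1L, "at least one RDM is required")
  labs <- conditions(rdms[[1L]])
  for (r in rdms)
    if (!identical(conditions(r), labs))
      stop("condition labels differ across RDMs", call. = FALSE)
  arr <- vapply(rdms, values, matrix(0, length(labs), length(labs)))
  m <- apply(arr, c(1, 2), function(x) {
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  })
  dimnames(m) <- list(labs, labs)
  new("RDM", values = m, conditions = labs,
      nFolds = mean(vapply(rdms, function(r) r@nFolds, numeric(1))),
      provenance = list(grouping = grouping,
                        inputs = lapply(rdms, provenance)))
}

#' Write / read an RDM as CSV plus JSON sidecar
#'
#' The matrix serializes as a square CSV with condition labels as
#' header and first column; fold count, shrinkage and provenance go to
#' \code{<path>.json}.
#'
#' @param rdm an [RDM-class].
#' @param path CSV file path (sidecar written to \code{paste0(path, ".json")}).
#' @return readers return an [RDM-class]; writers \code{path} invisibly.
#' @export
writeRDM <- function(rdm, path) {
  utils::write.csv(as.data.frame(values(rdm)), path, row.names = TRUE)
  jsonlite::write_json(
    list(n_folds = rdm@nFolds, provenance = provenance(rdm)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname writeRDM
#' @export
readRDM <- function(path) {
  tab <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  m <- as.matrix(tab)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  new("RDM", values = m, conditions = rownames(m),
      nFolds = if (!is.null(meta$n_folds)) as.numeric(meta$n_folds) else NA_real_,
      provenance = if (!is.null(meta$provenance)) meta$provenance else list())
}
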