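## Frequency-domain and GLM-based sensitivity comparison of the two
## contrast mechanisms: periodograms, effect energy, analytic contrast
## standard errors, full-spectrum dominance and the peak-ratio sweep.

#' Periodogram with Parseval normalization
#'
#' One-sided discrete-Fourier power spectrum from 0 to the Nyquist
#' frequency 1/(2 dt). Power in the negative-frequency bins is folded
#' into the corresponding positive bins, so the sum of power over all
#' bins equals the sum of squared samples exactly (Parseval). Optional
#' zero-padding refines the frequency grid without changing total
#' power.
#'
#' @param signal numeric vector, or an [ImpulseResponse-class] /
#'   [SampledRegressor-class] (dt is then taken from the object).
#' @param dt sample spacing in seconds (ignored for S4 inputs).
#' @param padTo pad the signal with zeros up to this length in seconds
#'   (NULL: no padding).
#' @return a [PowerSpectrum-class].
#' @export
periodogram <- function(signal, dt = NULL, padTo = NULL) {
  if (is(signal, "ImpulseResponse")) {
    dt <- timeStep(signal); signal <- samples(signal)
  } else if (is(signal, "SampledRegressor")) {
    dt <- trTime(signal); signal <- values(signal)
  }
  stopIfNot(length(signal) >= 2L, "signal needs at least 2 samples")
  stopIfNot(!is.null(dt) && dt > 0, "dt must be a positive number")
  if (!is.null(padTo)) {
    nPad <- as.integer(round(padTo / dt))
    if (nPad > length(signal)) signal <- c(signal, numeric(nPad - length(signal)))
  }
  n <- length(signal)
  p <- Mod(stats::fft(signal))^2 / n
  nb <- floor(n / 2) + 1L
  ps <- p[seq_len(nb)]
  if (n %% 2L == 0L) {
    if (nb > 2L) ps[2:(nb - 1L)] <- ps[2:(nb - 1L)] + p[n:(nb + 1L)]
  } else {
    ps[2:nb] <- ps[2:nb] + p[n:(nb + 1L)]
  }
  df <- 1 / (n * dt)
  new("PowerSpectrum", freqs = (seq_len(nb) - 1L) * df, power = ps, df = df)
}

#' Effect energy of a regressor
#'
#' The sum of squared regressor values -- proportional to the GLM
#' detection power of the corresponding effect at fixed noise.
#'
#' @param regressor a [SampledRegressor-class] or numeric vector.
#' @return a single number, >= 0.
#' @export
effectEnergy <- function(regressor) {
  v <- if (is(regressor, "SampledRegressor")) values(regressor) else regressor
  stopIfNot(length(v) > 0, "regressor must be non-empty")
  sum(v^2)
}

#' Analytic standard error of a contrast estimate
#'
#' Under independent additive noise of standard deviation
#' \code{noiseSd}, the OLS contrast estimate c'beta has standard error
#' \deqn{\sigma \sqrt{c^\top (X^\top X)^{-1} c}.}
#'
#' @param X design matrix (volumes x regressors), full column rank.
#' @param contrast numeric weight vector, one weight per column.
#' @param noiseSd noise standard deviation.
#' @return the standard error (a positive number).
#' @export
contrastSE <- function(X, contrast, noiseSd = 1) {
  X <- as.matrix(X)
  stopIfNot(length(contrast) == ncol(X),
            "contrast length must equal the number of design columns")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    if (is.null(bad)) bad <- qrX$pivot[-seq_len(qrX$rank)]
    stop("singular design matrix; offending columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  xtxInv <- chol2inv(qr.R(qrX))
  ## undo the pivoting applied by qr()
  piv <- qrX$pivot
  xtxInv[piv, piv] <- xtxInv
  as.numeric(noiseSd * sqrt(drop(t(contrast) %*% xtxInv %*% contrast)))
}

#' Full-spectrum dominance of one impulse response over another
#'
#' Computes both periodograms on a common zero-padded grid and tests
#' whether \code{irfA}'s power is at least \code{irfB}'s at every
#' frequency bin in (0, fMax]. Ties count as dominance; the DC bin is
#' excluded because mean signal is not an effect of interest.
#'
#' @param irfA,irfB [ImpulseResponse-class] objects on the same dt grid.
#' @param fMax upper edge of the evaluated band in Hz (at most Nyquist).
#' @param padTo common zero-padded length in seconds.
#' @return a list with elements \code{dominant} (logical),
#'   \code{freqs} and \code{margins} (powerA - powerB per bin in the
#'   evaluated band), and \code{firstFailFreq} (NA when dominant).
#' @export
fullSpectrumDominance <- function(irfA, irfB, fMax = 0.25, padTo = 120) {
  if (abs(timeStep(irfA) - timeStep(irfB)) > 1e-12)
    stop("grid mismatch: both responses must share the same dt", call. = FALSE)
  dt <- timeStep(irfA)
  stopIfNot(fMax <= 1 / (2 * dt) + 1e-12, "fMax must not exceed Nyquist")
  n <- max(length(samples(irfA)), length(samples(irfB)),
           as.integer(round(padTo / dt)))
  pa <- periodogram(c(samples(irfA), numeric(n - length(samples(irfA)))), dt)
  pb <- periodogram(c(samples(irfB), numeric(n - length(samples(irfB)))), dt)
  f <- frequencies(pa)
  band <- f > 0 & f <= fMax + 1e-12
  margins <- values(pa)[band] - values(pb)[band]
  dominant <- all(margins >= 0)
  firstFail <- if (dominant) NA_real_ else f[band][which(margins < 0)[1L]]
  list(dominant = dominant, freqs = f[band], margins = margins,
       firstFailFreq = firstFail)
}

#' Default smooth-onset model pair
#'
#' Builds the conservative smooth-onset variants used in the dominance
#' analyses: the BOLD gamma model and the MION model whose sharp onset
#' is replaced by the BOLD rising limb, both then smoothed with the
#' same raised-cosine kernel.
#'
#' @param peakRatio MION peak amplitude relative to the BOLD peak of 1.
#' @param smoothWidth kernel width in seconds applied to both models.
#' @param dt grid spacing in seconds.
#' @param duration sampled length in seconds.
#' @param boldArgs,mionArgs extra arguments for [boldBoynton()] and
#'   [mionModel()].
#' @return list with elements \code{bold} and \code{mion}.
#' @export
smoothOnsetPair <- function(peakRatio = 1.8, smoothWidth = 1.0, dt = 0.1,
                            duration = 60, boldArgs = list(),
                            mionArgs = list()) {
  bold <- do.call(boldBoynton, c(list(dt = dt, duration = duration), boldArgs))
  mion <- do.call(mionModel, c(list(dt = dt, duration = duration,
                                    peakRatio = peakRatio), mionArgs))
  list(bold = smoothOnsetVariant(bold, smoothWidth),
       mion = smoothOnsetVariant(spliceSmoothOnset(mion, bold), smoothWidth))
}

#' Peak-ratio dominance sweep
#'
#' Rebuilds the MION model at each peak ratio in a decreasing sequence,
#' tests full-spectrum dominance against the matched-onset BOLD model,
#' and returns the smallest ratio for which dominance still holds.
#' Because power scales with the square of amplitude, dominance is
#' monotone in the ratio. If dominance already fails at the largest
#' ratio the threshold is NA (a "no dominance" sentinel, not an error).
#'
#' @param ratios strictly decreasing positive ratios to test.
#' @param fMax upper edge of the evaluated band in Hz.
#' @param smoothWidth onset-smoothing kernel width in seconds, applied
#'   identically to both models (ignored when \code{builder} is given).
#' @param builder optional function(ratio) returning
#'   \code{list(bold = , mion = )}; defaults to [smoothOnsetPair()].
#' @param padTo common zero-padded length in seconds.
#' @return a list with \code{threshold} (smallest dominant ratio, or NA),
#'   \code{perRatio} data.frame (ratio, dominant, minMargin,
#'   firstFailFreq), and \code{firstFailFreq} of the first non-dominant
#'   ratio (NA if all dominate).
#' @export
peakRatioSweep <- function(ratios = seq(1.8, 1.0, by = -0.1), fMax = 0.25,
                           smoothWidth = 1.0, builder = NULL, padTo = 120) {
  stopIfNot(length(ratios) >= 1L && all(ratios > 0),
            "ratios must be positive")
  stopIfNot(length(ratios) == 1L || all(diff(ratios) < 0),
            "ratios must be strictly decreasing")
  if (is.null(builder))
    builder <- function(r) smoothOnsetPair(peakRatio = r,
                                           smoothWidth = smoothWidth)
  rows <- lapply(ratios, function(r) {
    pair <- builder(r)
    d <- fullSpectrumDominance(pair$mion, pair$bold, fMax = fMax,
                               padTo = padTo)
    data.frame(ratio = r, dominant = d$dominant,
               minMargin = min(d$margins),
               firstFailFreq = d$firstFailFreq)
  })
  per <- do.call(rbind, rows)
  dom <- per$dominant
  threshold <- if (any(dom)) {
    ## smallest ratio whose entire prefix (all larger ratios) dominates
    lastDom <- if (all(dom)) length(dom) else which(!dom)[1L] - 1L
    if (lastDom >= 1L) per$ratio[lastDom] else NA_real_
  } else NA_real_
  firstFail <- if (any(!dom)) per$firstFailFreq[which(!dom)[1L]] else NA_real_
  list(threshold = threshold, perRatio = per, firstFailFreq = firstFail)
}

#' Write a power spectrum as CSV
#'
#' @param spectrum a [PowerSpectrum-class].
#' @param path file path.
#' @return \code{path} invisibly.
#' @export
writeSpectrum <- function(spectrum, path) {
  utils::write.csv(data.frame(freq_hz = frequencies(spectrum),
                              power = values(spectrum)),
                   path, row.names = FALSE)
  invisible(path)
}
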