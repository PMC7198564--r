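## Gamma-family impulse-response models for the two contrast mechanisms,
## plus the onset transforms used in the sensitivity simulations.

#' BOLD impulse response (Boynton gamma model)
#'
#' The classic gamma-family BOLD impulse response
#' \deqn{h(t) = ((t - delay)/\tau)^{n-1} e^{-(t - delay)/\tau}} for
#' t >= delay (0 before), rescaled so the peak amplitude is 1. The
#' analytic peak (mode) sits at \code{delay + (n - 1) tau}.
#'
#' @param dt grid spacing in seconds.
#' @param duration length of the sampled response in seconds (>= 20 s).
#' @param n integer shape parameter.
#' @param tau time constant in seconds.
#' @param delay pure delay in seconds.
#' @return an [ImpulseResponse-class] with unit peak.
#' @examples
#' b <- boldBoynton()
#' peakTime(b)  # 2.4 s for the defaults n = 3, tau = 1.2
#' @export
boldBoynton <- function(dt = 0.1, duration = 60, n = 3, tau = 1.2, delay = 0) {
  stopIfNot(dt > 0, "invalid parameter: dt must be positive")
  stopIfNot(tau > 0, "invalid parameter: tau must be positive")
  stopIfNot(n >= 1, "invalid parameter: n must be >= 1")
  stopIfNot(delay >= 0, "invalid parameter: delay must be non-negative")
  stopIfNot(duration >= 20, "invalid parameter: duration must be >= 20 s")
  peak <- delay + (n - 1) * tau
  if (duration <= peak)
    stop("truncation error: duration shorter than the response peak time",
         call. = FALSE)
  t <- seq(0, duration, by = dt)
  x <- pmax(t - delay, 0) / tau
  h <- x^(n - 1) * exp(-x)
  h[t < delay] <- 0
  newImpulseResponse("bold_boynton", dt, h / max(h))
}

#' MION impulse response
#'
#' A blood-volume-weighted (iron-oxide contrast agent) impulse response,
#' modelled as a gamma density with the given mean lag and standard
#' deviation and amplitude-scaled so its peak equals \code{peakRatio}
#' (relative to the BOLD peak of 1). The MION signal change is
#' physically negative; the magnitude-only convention used throughout
#' represents it as a positive response. Default shape (mean lag 6 s,
#' SD 4.5 s) peaks later and is wider (larger FWHM) than the default
#' BOLD model, with a heavier spectral tail; see the methods vignette
#' for the calibration of these defaults.
#'
#' @param dt grid spacing in seconds.
#' @param duration sampled length in seconds; must contain >= 99\% of
#'   the response mass (>= 40 s recommended).
#' @param peakRatio peak amplitude relative to the unit BOLD peak.
#' @param meanLag first moment of the gamma density in seconds.
#' @param sdLag standard deviation of the gamma density in seconds.
#' @return an [ImpulseResponse-class] with peak \code{peakRatio}.
#' @examples
#' m <- mionModel(peakRatio = 1.8)
#' peakAmplitude(m)  # 1.8
#' @export
mionModel <- function(dt = 0.1, duration = 60, peakRatio = 1.8,
                      meanLag = 6, sdLag = 4.5) {
  stopIfNot(dt > 0, "invalid parameter: dt must be positive")
  stopIfNot(peakRatio > 0, "invalid parameter: peakRatio must be positive")
  stopIfNot(meanLag > 0 && sdLag > 0,
            "invalid parameter: meanLag and sdLag must be positive")
  shape <- (meanLag / sdLag)^2
  scale <- sdLag^2 / meanLag
  if (stats::pgamma(duration, shape = shape, scale = scale) < 0.99)
    stop("truncation error: duration too short to contain 99% of the response",
         call. = FALSE)
  t <- seq(0, duration, by = dt)
  h <- stats::dgamma(t, shape = shape, scale = scale)
  newImpulseResponse("mion", dt, h / max(h) * peakRatio)
}

#' Macaque gamma hemodynamic response function
#'
#' Gamma-density HRF parameterized by its first moment (mean lag) and
#' standard deviation, with unit peak. The defaults (3 s mean lag,
#' 1.5 s SD) reflect the macaque BOLD HRF, which is faster than the
#' human one; they correspond to gamma shape
#' \eqn{k = (mean/sd)^2 = 4} and scale \eqn{\theta = sd^2/mean = 0.75}.
#'
#' @param meanLag mean lag in seconds.
#' @param sdLag standard deviation in seconds.
#' @param dt grid spacing in seconds.
#' @param duration sampled length in seconds; must be at least
#'   \code{meanLag + 4 sdLag}.
#' @return an [ImpulseResponse-class] with unit peak.
#' @export
gammaHRF <- function(meanLag = 3, sdLag = 1.5, dt = 0.1, duration = 30) {
  stopIfNot(meanLag > 0, "invalid parameter: meanLag must be positive")
  stopIfNot(sdLag > 0, "invalid parameter: sdLag must be positive")
  stopIfNot(dt > 0, "invalid parameter: dt must be positive")
  if (duration < meanLag + 4 * sdLag)
    stop("truncation error: duration must be >= meanLag + 4 * sdLag",
         call. = FALSE)
  shape <- (meanLag / sdLag)^2
  scale <- sdLag^2 / meanLag
  t <- seq(0, duration, by = dt)
  h <- stats::dgamma(t, shape = shape, scale = scale)
  newImpulseResponse("gamma_hrf", dt, h / max(h))
}

#' Replace a sharp onset with a smooth rising limb
#'
#' Splices the (normalized) rising limb of \code{onsetSource} onto
#' \code{mion}: for t earlier than the MION peak, the output follows the
#' onset source's rise, time-rescaled so its peak lands at the MION peak
#' time and amplitude-rescaled to the MION peak; from the peak onward
#' the output equals the input MION response. The construction is
#' continuous at the splice point and preserves the peak, and is
#' idempotent: splicing a spliced response again changes nothing.
#'
#' @param mion the response whose onset is replaced.
#' @param onsetSource the response providing the rising limb (same dt).
#' @return an [ImpulseResponse-class].
#' @export
spliceSmoothOnset <- function(mion, onsetSource) {
  if (abs(mion@dt - onsetSource@dt) > 1e-12)
    stop("grid mismatch: both responses must share the same dt", call. = FALSE)
  stopIfNot(peakAmplitude(onsetSource) > 0,
            "onsetSource must have positive peak amplitude")
  tpM <- peakTime(mion)
  tpO <- peakTime(onsetSource)
  stopIfNot(tpM > 0 && tpO > 0, "both responses must peak after t = 0")
  t <- irfTimes(mion)
  out <- samples(mion)
  rising <- t < tpM
  srcT <- t[rising] * (tpO / tpM)
  onsetNorm <- samples(onsetSource) / peakAmplitude(onsetSource)
  out[rising] <- stats::approx(irfTimes(onsetSource), onsetNorm,
                               xout = srcT, rule = 2)$y * peakAmplitude(mion)
  newImpulseResponse(paste0(mion@name, "_smooth_onset"), mion@dt, out)
}

#' Smooth-onset variant of an impulse response
#'
#' Convolves the response with a unit-sum raised-cosine (Hann) kernel of
#' total width \code{width} seconds, supported on [0, width] so the
#' smoothed response stays causal (zero at t = 0), then renormalizes the
#' peak back to the input's peak amplitude. Applied with the same width
#' to both contrast mechanisms when they are compared, this yields the
#' "even smoother onset" variants used in the frequency-domain analysis.
#'
#' @param irf input [ImpulseResponse-class].
#' @param width total kernel width in seconds; 0 is the identity.
#' @return an [ImpulseResponse-class] with the same peak amplitude.
#' @export
smoothOnsetVariant <- function(irf, width) {
  if (width < 0)
    stop("invalid parameter: width must be non-negative", call. = FALSE)
  if (width == 0) return(irf)
  dt <- irf@dt
  u <- seq(0, width, by = dt)
  k <- 0.5 * (1 - cos(2 * pi * u / width))
  if (sum(k) == 0) return(irf)  # width below the grid resolution
  k <- k / sum(k)
  h <- samples(irf)
  n <- length(h)
  ## causal FIR filter in the time domain: y[t] = sum_u k[u] h[t - u]
  ## (exact arithmetic, so h(0) = 0 stays exactly 0 after smoothing)
  hp <- c(numeric(length(k) - 1L), h)
  y <- stats::filter(hp, k, method = "convolution", sides = 1)
  y <- as.numeric(y[length(k) - 1L + seq_len(n)])
  y <- y / max(y) * peakAmplitude(irf)
  newImpulseResponse(paste0(irf@name, "_smoothed"), dt, y)
}

#' Write / read an impulse response as CSV
#'
#' Two-column CSV (time_s, amplitude) with a comment header carrying the
#' name, grid spacing and peak amplitude. The reader round-trips the
#' samples exactly (full-precision formatting).
#'
#' @param irf an [ImpulseResponse-class].
#' @param path file path.
#' @return \code{readIRF} returns an [ImpulseResponse-class];
#'   \code{writeIRF} returns \code{path} invisibly.
#' @export
writeIRF <- function(irf, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# name=%s, dt=%s, peak_ratio=%s", irf@name,
                     format(irf@dt, digits = 17),
                     format(peakAmplitude(irf), digits = 17)), con)
  writeLines("time_s,amplitude", con)
  writeLines(paste(format(irfTimes(irf), digits = 17, trim = TRUE),
                   format(samples(irf), digits = 17, trim = TRUE), sep = ","),
             con)
  invisible(path)
}

#' @rdname writeIRF
#' @export
readIRF <- function(path) {
  lines <- readLines(path)
  hdr <- lines[[1L]]
  stopIfNot(startsWith(hdr, "# name="), "not an IRF CSV: missing header")
  fields <- strsplit(sub("^# ", "", hdr), ", ")[[1L]]
  kv <- vapply(strsplit(fields, "="), `[`, character(1), 2)
  names(kv) <- vapply(strsplit(fields, "="), `[`, character(1), 1)
  tab <- utils::read.csv(text = lines[-1L])
  newImpulseResponse(kv[["name"]], as.numeric(kv[["dt"]]), tab$amplitude)
}
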