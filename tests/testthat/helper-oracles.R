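## Independent oracles and small fixture builders used across tests.

## full width at half maximum of a sampled response, by linear
## interpolation of the half-peak crossings
fwhm <- function(irf) {
  h <- samples(irf)
  t <- irfTimes(irf)
  half <- max(h) / 2
  above <- which(h >= half)
  i0 <- min(above)
  i1 <- max(above)
  left <- if (i0 == 1L) t[1L] else {
    t[i0 - 1L] + (half - h[i0 - 1L]) / (h[i0] - h[i0 - 1L]) * (t[i0] - t[i0 - 1L])
  }
  right <- if (i1 == length(h)) t[i1] else {
    t[i1] + (h[i1] - half) / (h[i1] - h[i1 + 1L]) * (t[i1 + 1L] - t[i1])
  }
  right - left
}

## discrete first moment and SD of a sampled response, treating the
## samples as a density on the time grid
discreteMoments <- function(irf) {
  h <- samples(irf)
  t <- irfTimes(irf)
  m <- sum(t * h) / sum(h)
  s <- sqrt(sum((t - m)^2 * h) / sum(h))
  c(mean = m, sd = s)
}

## brute-force one-sided DFT power by direct summation (oracle for
## periodogram); O(n^2), use on short signals only
bruteDFTPower <- function(x) {
  n <- length(x)
  nb <- floor(n / 2) + 1L
  p <- numeric(nb)
  for (k in seq_len(n) - 1L) {
    re <- sum(x * cos(-2 * pi * k * (seq_len(n) - 1L) / n))
    im <- sum(x * sin(-2 * pi * k * (seq_len(n) - 1L) / n))
    pk <- (re^2 + im^2) / n
    fold <- if (k < nb) k + 1L else n - k + 1L
    if (k < nb) p[fold] <- p[fold] + pk else p[fold] <- p[fold] + pk
  }
  p
}

## single-event regressor height for a given HRF and stimulus duration:
## peak of one isolated event convolved on the fine grid
singleEventHeight <- function(hrf, stimDuration = 0.5) {
  dt <- timeStep(hrf)
  box <- numeric(length(samples(hrf)))
  box[seq_len(max(1L, round(stimDuration / dt)))] <- 1
  max(stats::convolve(c(box, numeric(length(samples(hrf)))),
                      rev(samples(hrf)), type = "open"))
}

## an eye trace with an exact per-volume count of outside-window samples
traceWithOutside <- function(nOutPerVolume, spv = 40, w = 5,
                             sampleRate = 20) {
  x <- unlist(lapply(nOutPerVolume, function(k) {
    c(rep(2 * w, k), rep(0, spv - k))
  }))
  eyeTrace(x, numeric(length(x)), sampleRate = sampleRate,
           windowHalfWidth = w)
}
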