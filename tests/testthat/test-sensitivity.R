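test_that("periodogram satisfies Parseval, matches a direct DFT, and handles pure tones", {
  ## impulse: flat spectrum after folding (interior bins carry both
  ## complex-conjugate halves)
  p <- periodogram(c(1, numeric(15)), dt = 0.5)
  inner <- values(p)[2:(length(values(p)) - 1L)]
  expect_equal(inner, rep(inner[1L], length(inner)))
  ## pure sinusoid at an exact bin frequency: all power in that bin
  n <- 64
  x <- sin(2 * pi * 4 * (0:(n - 1)) / n)
  ps <- periodogram(x, dt = 1)
  expect_equal(which.max(values(ps)), 5L)  # bin at 4 cycles / record
  expect_lt(sum(values(ps)[-5L]), 1e-20)
  ## Parseval for arbitrary signals, with and without zero-padding
  set.seed(42)
  for (len in c(33, 64, 101)) {
    x <- rnorm(len)
    expect_equal(sum(values(periodogram(x, dt = 0.1))), sum(x^2),
                 tolerance = 1e-9)
    expect_equal(sum(values(periodogram(x, dt = 0.1, padTo = 30))),
                 sum(x^2), tolerance = 1e-9)
  }
  ## brute-force DFT oracle on a short signal
  x <- rnorm(17)
  expect_equal(values(periodogram(x, dt = 1)), bruteDFTPower(x),
               tolerance = 1e-10)
  expect_error(periodogram(numeric(1), dt = 1), "samples")
})

test_that("effect energy is a sum of squares", {
  expect_equal(effectEnergy(numeric(10)), 0)
  x <- c(1, -2, 3)
  expect_equal(effectEnergy(x), 14)
  expect_equal(effectEnergy(5 * x), 25 * effectEnergy(x))
})

test_that("analytic contrast SE matches orthonormal and scaling identities", {
  X <- qr.Q(qr(matrix(rnorm(200), 50, 4)))
  expect_equal(contrastSE(X, c(1, 0, 0, 0), 1), 1, tolerance = 1e-10)
  X2 <- matrix(rnorm(120), 40, 3)
  expect_equal(contrastSE(2 * X2, c(1, -1, 0)),
               contrastSE(X2, c(1, -1, 0)) / 2, tolerance = 1e-10)
  Xs <- cbind(a = 1:10, b = 2 * (1:10))
  expect_error(contrastSE(Xs, c(1, 0)), "b")
})

test_that("analytic contrast SE matches the Monte-Carlo OLS spread", {
  ## 10,000 white-noise draws; empirical SD of the contrast estimate
  ## should sit within 3% of noise_sd * sqrt(c' (X'X)^-1 c)
  set.seed(9)
  X <- cbind(1, rnorm(60), rnorm(60))
  cvec <- c(0, 1, -1)
  M <- solve(crossprod(X), t(X))
  est <- as.numeric(t(cvec) %*% M %*% matrix(rnorm(60 * 10000), 60))
  expect_equal(sd(est), contrastSE(X, cvec, 1), tolerance = 0.03)
})

test_that("full-spectrum dominance obeys its defining identities", {
  b <- boldBoynton()
  self <- fullSpectrumDominance(b, b)
  expect_true(self$dominant)
  expect_equal(self$margins, rep(0, length(self$margins)))
  ## doubling the amplitude quadruples power: margin = 3 x base power
  b2 <- rersim:::newImpulseResponse("b2", timeStep(b), 2 * samples(b))
  d <- fullSpectrumDominance(b2, b)
  pb <- periodogram(b, padTo = 120)
  band <- frequencies(pb) > 0 & frequencies(pb) <= 0.25 + 1e-12
  expect_true(d$dominant)
  expect_equal(d$margins, 3 * values(pb)[band], tolerance = 1e-9)
  ## invariance to common rescaling
  b3 <- rersim:::newImpulseResponse("b3", timeStep(b), 0.37 * samples(b))
  m <- mionModel()
  m3 <- rersim:::newImpulseResponse("m3", timeStep(m), 0.37 * samples(m))
  expect_identical(fullSpectrumDominance(m, b)$dominant,
                   fullSpectrumDominance(m3, b3)$dominant)
  expect_error(fullSpectrumDominance(b, boldBoynton(dt = 0.05)),
               "grid mismatch")
})

test_that("smooth-onset MION dominates smooth-onset BOLD at peak ratio 1.8", {
  pair <- smoothOnsetPair(peakRatio = 1.8, smoothWidth = 1.0)
  expect_true(fullSpectrumDominance(pair$mion, pair$bold,
                                    fMax = 0.25)$dominant)
})

test_that("the peak-ratio sweep is monotone and agrees with per-bin brute force", {
  sw <- peakRatioSweep(seq(1.8, 1.0, by = -0.1))
  dom <- sw$perRatio$dominant
  ## once dominance is lost it never returns at smaller ratios
  expect_true(all(diff(as.integer(dom)) <= 0))
  expect_true(!is.na(sw$threshold))
  ## single-ratio sweep at 1.0 agrees with an independent per-bin check
  sw1 <- peakRatioSweep(1.0)
  pair <- smoothOnsetPair(peakRatio = 1.0, smoothWidth = 1.0)
  pm <- periodogram(pair$mion, padTo = 120)
  pb <- periodogram(pair$bold, padTo = 120)
  band <- frequencies(pm) > 0 & frequencies(pm) <= 0.25 + 1e-12
  brute <- all(values(pm)[band] >= values(pb)[band])
  expect_identical(sw1$perRatio$dominant, brute)
  if (!brute) expect_true(is.na(sw1$threshold))
  ## sweep failing at the largest ratio reports the sentinel, not an error
  nosweep <- peakRatioSweep(0.01)
  expect_true(is.na(nosweep$threshold))
  expect_false(is.na(nosweep$firstFailFreq))
})
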