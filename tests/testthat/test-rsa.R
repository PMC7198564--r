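test_that("noise covariance follows (1/T) R'R with diagonal shrinkage", {
  expect_equal(covMatrix(noiseCovariance(matrix(c(1, -1), 2, 1),
                                         shrinkage = 0)),
               matrix(1, 1, 1))
  ## Monte-Carlo: white unit-variance residuals
  set.seed(3)
  R <- matrix(rnorm(10000 * 5), 10000, 5)
  S <- covMatrix(noiseCovariance(R, shrinkage = 0))
  expect_true(all(abs(diag(S) - 1) < 0.05))
  expect_true(all(abs(S[upper.tri(S)]) < 0.05))
  ## shrinkage 1 returns exactly the diagonal target
  S1 <- covMatrix(noiseCovariance(R[1:20, ], shrinkage = 1))
  expect_identical(S1, diag(diag(crossprod(R[1:20, ]) / 20), 5))
})

test_that("crossnobis bilinear form matches hand-computed cases", {
  expect_equal(crossnobis(c(1, 2), c(1, 2), diag(2)), 5)
  expect_equal(crossnobis(c(2, 0), c(2, 0), 4 * diag(2)), 1)
  ## symmetric under exchanging the two conditions (both deltas flip)
  S <- crossprod(matrix(rnorm(9), 3)) + diag(3)
  dA <- rnorm(3); dB <- rnorm(3)
  expect_equal(crossnobis(-dA, -dB, S), crossnobis(dA, dB, S))
  expect_error(crossnobis(c(1, 0), c(1, 0), matrix(0, 2, 2)), "singular")
})

test_that("crossnobis is unbiased: zero mean for identical true patterns", {
  ## independent noise in the two halves; product has expectation 0
  set.seed(11)
  n <- 10000; P <- 4
  dA <- matrix(rnorm(n * P), n, P)
  dB <- matrix(rnorm(n * P), n, P)
  vals <- rowSums(dA * dB)               # identity whitener
  se <- sd(vals) / sqrt(n)
  expect_lt(abs(mean(vals)), 3 * se)
})

test_that("split-half RDM reproduces planted distances exactly without noise", {
  set.seed(4)
  truePat <- matrix(rnorm(6 * 5), 6, 5,
                    dimnames = list(paste0("cond_", 0:5), NULL))
  runs <- lapply(1:4, function(i) truePat)     # identical patterns per run
  pat <- patternEstimates(runs)
  rdm <- splitHalfRDM(pat, nFolds = 10, seed = 1, noiseCov = "identity")
  expect_equal(values(rdm), as.matrix(dist(truePat))^2,
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diag(values(rdm)) == 0))
  expect_equal(rdm@nFolds, 10)
  expect_identical(values(rdm), t(values(rdm)))
})

test_that("split-half folds are seeded, reproducible, and need two runs", {
  pat <- patternEstimates(lapply(1:5, function(i)
    matrix(rnorm(12), 4, 3, dimnames = list(paste0("cond_", 0:3), NULL))))
  res <- lapply(1:5, function(i) matrix(rnorm(60), 20, 3))
  r1 <- splitHalfRDM(pat, res, nFolds = 20, seed = 9)
  r2 <- splitHalfRDM(pat, res, nFolds = 20, seed = 9)
  expect_identical(values(r1), values(r2))
  r3 <- splitHalfRDM(pat, res, nFolds = 20, seed = 10)
  expect_false(identical(values(r1), values(r3)))
  expect_error(splitHalfRDM(pat, res, nFolds = 5), "seed")
  one <- patternEstimates(list(matrix(rnorm(12), 4, 3)))
  expect_error(splitHalfRDM(one, res[1], nFolds = 5, seed = 1), "2 usable")
})

test_that("conditions missing from every run give NA entries, others are kept", {
  base <- matrix(rnorm(12), 4, 3, dimnames = list(paste0("cond_", 0:3), NULL))
  runs <- lapply(1:4, function(i) {
    m <- base
    m[2, ] <- NA_real_                    # condition 1 never available
    m
  })
  pat <- patternEstimates(runs)
  expect_true(all(!pat@available[2, ]))
  rdm <- splitHalfRDM(pat, nFolds = 8, seed = 2, noiseCov = "identity")
  v <- values(rdm)
  expect_true(all(is.na(v[2, -2])))
  expect_true(all(!is.na(v[-2, -2])))
})

test_that("fold-averaged crossnobis recovers the planted whitened distance", {
  ## two conditions with true squared (whitened) distance d, matched
  ## noise; the session-averaged estimate is unbiased
  set.seed(21)
  P <- 5
  delta <- rep(1, P)                      # true squared distance = 5
  d <- sum(delta^2)
  nSessions <- 200
  est <- vapply(seq_len(nSessions), function(s) {
    runs <- lapply(1:4, function(i) {
      m <- rbind(cond_0 = numeric(P), cond_1 = delta) +
        matrix(rnorm(2 * P, sd = 1), 2, P)
      m
    })
    pat <- patternEstimates(runs)
    values(splitHalfRDM(pat, nFolds = 5, seed = s,
                        noiseCov = "identity"))[1, 2]
  }, numeric(1))
  se <- sd(est) / sqrt(nSessions)
  expect_lt(abs(mean(est) - d), 3 * se)
})

test_that("larger planted separations yield larger expected RDM entries", {
  set.seed(31)
  meanEntry <- vapply(c(0.5, 1.5), function(a) {
    est <- vapply(1:40, function(s) {
      runs <- lapply(1:4, function(i)
        rbind(cond_0 = numeric(4), cond_1 = rep(a, 4)) +
          matrix(rnorm(8), 2, 4))
      pat <- patternEstimates(runs)
      values(splitHalfRDM(pat, nFolds = 5, seed = s,
                          noiseCov = "identity"))[1, 2]
    }, numeric(1))
    mean(est)
  }, numeric(1))
  expect_gt(meanEntry[2], meanEntry[1])
})

test_that("RDM averaging is entrywise with the stated missing policy", {
  m <- matrix(c(0, 2, 2, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  r <- new("RDM", values = m, conditions = c("a", "b"), nFolds = 5,
           provenance = list())
  expect_equal(values(averageRDMs(list(r))), m)
  rn <- new("RDM", values = -m, conditions = c("a", "b"), nFolds = 5,
            provenance = list())
  expect_equal(values(averageRDMs(list(r, rn))), 0 * m)
  mNA <- m; mNA[1, 2] <- mNA[2, 1] <- NA_real_
  rNA <- new("RDM", values = mNA, conditions = c("a", "b"), nFolds = 5,
             provenance = list())
  avg <- averageRDMs(list(r, r, rNA))
  expect_equal(avg@values[1, 2], 2)       # mean of the two present values
  rBad <- new("RDM", values = m, conditions = c("x", "b"), nFolds = 5,
              provenance = list())
  expect_error(averageRDMs(list(r, rBad)), "labels")
})

test_that("RDMs round-trip through CSV plus JSON sidecar", {
  pat <- patternEstimates(lapply(1:4, function(i)
    matrix(rnorm(12), 4, 3, dimnames = list(paste0("cond_", 0:3), NULL))))
  rdm <- splitHalfRDM(pat, nFolds = 6, seed = 3, noiseCov = "identity")
  path <- tempfile(fileext = ".csv")
  writeRDM(rdm, path)
  back <- readRDM(path)
  expect_equal(values(back), values(rdm), tolerance = 1e-12)
  expect_equal(back@nFolds, 6)
})
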