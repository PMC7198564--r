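test_that("broken-fixation censoring applies the strict more-than-half rule", {
  ## 40 samples per volume at 20 Hz, TR 2 s
  tr <- traceWithOutside(c(0L, 21L, 20L, 40L))
  m <- censorBrokenFixation(tr, tr = 2)
  expect_equal(keptVolumes(m), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(censorReasons(m), c("none", "fixation", "none", "fixation"))
  expect_error(censorBrokenFixation(traceWithOutside(integer(0)), tr = 2),
               "shorter")
})

test_that("motion outlier rule flags strictly above mean + 2 SD", {
  expect_equal(sum(!keptVolumes(flagMotionOutliers(rep(1, 50)))), 0)
  x <- c(rep(1, 100), 10)
  m <- flagMotionOutliers(x)
  thr <- mean(x) + 2 * sd(x)       # ~2.88, direct computation
  expect_lt(thr, 10)
  expect_equal(which(!keptVolumes(m)), 101L)
  expect_identical(which(!keptVolumes(m)), which(x > thr))
})

test_that("design matrix has one column per image plus nuisance and drift", {
  hrf <- gammaHRF()
  s <- rapidERSchedule(seed = 3)
  d <- buildDesignMatrix(s, hrf, driftOrder = -1)
  expect_equal(ncol(d$X), 48)
  expect_true(all(d$labels$type == "interest"))
  ## motion flags become one-hot nuisance columns
  keep <- rep(TRUE, nVolumes(s)); keep[c(10, 50)] <- FALSE
  mot <- rersim:::newCensorMask(keep, ifelse(keep, "none", "motion"))
  d2 <- buildDesignMatrix(s, hrf, motion = mot, driftOrder = 0)
  mcols <- d2$X[, d2$labels$type == "nuisance", drop = FALSE]
  expect_equal(ncol(mcols), 2)
  expect_equal(colSums(mcols), c(motion_v10 = 1, motion_v50 = 1))
  ## censoring a condition's only event zeroes (and flags) its column
  ev <- events(s)
  v <- ceiling((ev$onset[ev$condition == 5][1L] + 0.01) / 2)
  keepF <- rep(TRUE, nVolumes(s)); keepF[v] <- FALSE
  fix <- rersim:::newCensorMask(keepF, ifelse(keepF, "none", "fixation"))
  d3 <- buildDesignMatrix(s, hrf, censor = fix, driftOrder = -1)
  expect_true(all(d3$X[, "cond_5"] == 0))
  expect_true(d3$labels$allZero[d3$labels$name == "cond_5"])
})

test_that("fixation and motion masks combine commutatively", {
  keepA <- rep(TRUE, 10); keepA[3] <- FALSE
  keepB <- rep(TRUE, 10); keepB[7] <- FALSE
  expect_identical(keepA & keepB, keepB & keepA)
  hrf <- gammaHRF()
  s <- alternatingDesign(2, 40, 2)
  fix <- rersim:::newCensorMask(rep(c(TRUE, FALSE), c(18, 2)),
                                rep(c("none", "fixation"), c(18, 2)))
  mot <- rersim:::newCensorMask(rep(c(FALSE, TRUE), c(1, 19)),
                                rep(c("motion", "none"), c(1, 19)))
  d1 <- buildDesignMatrix(s, hrf, censor = fix, motion = mot)
  d2 <- buildDesignMatrix(s, hrf, motion = mot, censor = fix)
  expect_identical(d1$X, d2$X)
})

test_that("OLS recovers exact betas at zero noise with orthogonal residuals", {
  set.seed(1)
  X <- cbind(intercept = 1, a = rnorm(40), b = rnorm(40))
  B <- matrix(c(2, -1, 0.5, 1, 0, 3), 3, 2)
  Y <- X %*% B
  fit <- fitGLM(X, Y + rnorm(80, sd = 0))  # noiseless
  expect_equal(unname(betas(fit)), unname(B), tolerance = 1e-8)
  expect_equal(dofResidual(fit), 40 - qr(X)$rank)
  Yn <- Y + matrix(rnorm(80), 40, 2)
  fitn <- fitGLM(X, Yn)
  expect_lt(max(abs(crossprod(X, glmResiduals(fitn)))), 1e-6)
  expect_error(fitGLM(cbind(1, 1:10, 2 * (1:10)), rnorm(10)), "singular")
})

test_that("analytic beta SE matches the empirical spread over noise draws", {
  set.seed(7)
  X <- cbind(1, scale(1:30), rnorm(30))
  M <- solve(crossprod(X), t(X))
  draws <- M %*% matrix(rnorm(30 * 1000), 30)    # beta for 1000 draws
  empSD <- apply(draws, 1L, sd)
  fit <- fitGLM(X, X %*% c(1, 2, 3) + rnorm(30))
  ## SE is per-voxel; compare the design-geometry factor at sigma = 1
  seUnit <- stdErrors(fit)[, 1L] / sqrt(sum(glmResiduals(fit)[, 1L]^2) /
                                          dofResidual(fit))
  expect_equal(unname(empSD), unname(seUnit), tolerance = 0.05)
})

test_that("t-to-z conversion preserves tails, sign and monotonicity", {
  expect_equal(tToZ(0, 10), 0)
  expect_equal(tToZ(1.7, 1e6), 1.7, tolerance = 1e-3)
  ## independent quadrature oracle for t = 2, dof = 10
  tailP <- integrate(function(x) dt(x, df = 10), 2, Inf,
                     rel.tol = 1e-12)$value
  expect_equal(tToZ(2, 10), qnorm(1 - tailP), tolerance = 1e-8)
  expect_equal(tToZ(-2, 10), -tToZ(2, 10))
  ts <- seq(-5, 5, by = 0.25)
  expect_true(all(diff(tToZ(ts, 8)) > 0))
  expect_true(is.finite(tToZ(40, 20)))   # log-tail arithmetic
  expect_error(tToZ(1, 0.5), "dof")
})

test_that("percent signal change scales as stated and survives data rescaling", {
  expect_equal(percentSignalChange(0, 4, 100), 0)
  expect_equal(percentSignalChange(2, 4, 100),
               2 * percentSignalChange(1, 4, 100))
  expect_equal(percentSignalChange(1, 4, 200),
               percentSignalChange(1, 4, 100) / 2)
  expect_error(percentSignalChange(1, 4, 0), "baseline")
  ## invariance: rescaling the raw data rescales beta and baseline alike
  set.seed(2)
  X <- cbind(1, rnorm(30))
  y <- 100 + X[, 2] * 3 + rnorm(30)
  f1 <- fitGLM(X, y)
  f2 <- fitGLM(X, 5 * y)
  h <- 0.8
  expect_equal(percentSignalChange(betas(f1)[2, 1], h, mean(y)),
               percentSignalChange(betas(f2)[2, 1], h, mean(5 * y)),
               tolerance = 1e-10)
})

test_that("spherical ROI masks match brute-force enumeration", {
  expect_equal(nrow(sphericalROIMask(c(0, 0, 0), 0, 1.5)), 1)
  ## 2 mm on the 1.5 mm grid: centre + 6 face neighbours only
  m2 <- sphericalROIMask(c(0, 0, 0), 2, 1.5)
  expect_equal(nrow(m2), 7)
  expect_true(all(rowSums(abs(m2)) <= 1))
  ## 5 mm sphere: independent enumeration over the bounding cube
  r <- 5; vs <- 1.5
  g <- expand.grid(x = -4:4, y = -4:4, z = -4:4)
  brute <- sum(vs * sqrt(g$x^2 + g$y^2 + g$z^2) <= r + 1e-9)
  expect_equal(nrow(sphericalROIMask(c(0, 0, 0), r, vs)), brute)
})
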