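test_that("synthetic eye traces reproduce planted broken-fixation flags exactly", {
  sched <- rapidERSchedule(seed = 1)
  clean <- generateEyeTrace(sched, integer(), seed = 5)
  expect_true(all(keptVolumes(censorBrokenFixation(clean, 2))))
  ## 20 Hz x TR 2 s = 40 samples per volume
  expect_equal(length(clean@x) / nVolumes(sched), 40)
  for (s in c(2, 7, 19)) {
    broken <- withr::with_seed(s, sort(sample.int(117, 20)))
    tr <- generateEyeTrace(sched, broken, seed = s)
    got <- which(!keptVolumes(censorBrokenFixation(tr, 2)))
    expect_identical(got, as.integer(broken))
  }
})

test_that("synthetic motion series reproduce planted outliers exactly", {
  m0 <- generateMotionSeries(100, integer(), seed = 1)
  expect_equal(sum(!keptVolumes(flagMotionOutliers(m0))), 0)
  for (s in c(3, 8)) {
    planted <- withr::with_seed(s, sort(sample.int(200, 6)))
    m <- generateMotionSeries(200, planted, seed = s)
    expect_identical(which(!keptVolumes(flagMotionOutliers(m))),
                     as.integer(planted))
  }
  ## spikes indistinguishable from baseline are refused
  expect_error(generateMotionSeries(50, c(5, 10), spikeScale = 1.01,
                                    seed = 2), "spikeScale")
})

test_that("planted artefact rates land near their targets over many volumes", {
  ## 16.3% broken fixation over >= 2000 volumes: binomial 99% band
  ds <- generateSession(nRuns = 18, nConditions = 48, nVoxels = 3,
                        noiseSpec = list(sd = 0.5, lengthScale = 2),
                        censorRate = 0.163, motionRate = 0.03, seed = 13)
  tru <- plantedTruth(ds)
  nv <- sum(vapply(sessionRuns(ds), function(r) nrow(r$data), numeric(1)))
  expect_gte(nv, 2000)
  frac <- length(unlist(tru$brokenVolumes)) / nv
  band <- qbinom(c(0.005, 0.995), nv, 0.163) / nv
  expect_gte(frac, band[1])
  expect_lte(frac, band[2])
  ## ~3% motion outliers over >= 3000 volumes
  ds2 <- generateSession(nRuns = 26, nConditions = 48, nVoxels = 3,
                         noiseSpec = list(sd = 0.5, lengthScale = 2),
                         censorRate = 0, motionRate = 0.03, seed = 14)
  nv2 <- sum(vapply(sessionRuns(ds2), function(r) nrow(r$data), numeric(1)))
  expect_gte(nv2, 3000)
  frac2 <- length(unlist(plantedTruth(ds2)$motionVolumes)) / nv2
  band2 <- qbinom(c(0.005, 0.995), nv2, 0.03) / nv2
  expect_gte(frac2, band2[1])
  expect_lte(frac2, band2[2])
})

test_that("generation is bit-reproducible under a fixed seed", {
  a <- generateSession(nRuns = 2, nConditions = 8, nVoxels = 5,
                       scheduleArgs = list(nNull = 4), seed = 5)
  b <- generateSession(nRuns = 2, nConditions = 8, nVoxels = 5,
                       scheduleArgs = list(nNull = 4), seed = 5)
  expect_identical(sessionRuns(a)[[1L]]$data, sessionRuns(b)[[1L]]$data)
  expect_identical(plantedTruth(a), plantedTruth(b))
  c <- generateSession(nRuns = 2, nConditions = 8, nVoxels = 5,
                       scheduleArgs = list(nNull = 4), seed = 6)
  expect_false(identical(sessionRuns(a)[[1L]]$data,
                         sessionRuns(c)[[1L]]$data))
})

test_that("noiseless data give exact beta recovery and the planted RDM", {
  ds <- generateSession(nRuns = 4, nConditions = 12, nVoxels = 8,
                        noiseSpec = list(sd = 0, lengthScale = 2),
                        censorRate = 0, motionRate = 0, seed = 8)
  hrf <- gammaHRF()
  run <- sessionRuns(ds)[[1L]]
  des <- buildDesignMatrix(run$schedule, hrf)
  fit <- fitGLM(des, run$data)
  interest <- des$labels$name[des$labels$type == "interest"]
  expect_equal(unname(betas(fit)[interest, ]),
               unname(plantedTruth(ds)$patterns), tolerance = 1e-8)
  res <- analyzeSession(ds, hrf = hrf, nFolds = 10, seed = 1,
                        identityWhitener = TRUE)
  expect_equal(unname(values(res$rdm)), unname(plantedTruth(ds)$rdm),
               tolerance = 1e-6)
})

test_that("planted censor flags match the analyzer output on every run", {
  ds <- generateSession(nRuns = 3, nConditions = 8, nVoxels = 4,
                        censorRate = 0.15, motionRate = 0.04,
                        scheduleArgs = list(nNull = 4), seed = 17)
  tru <- plantedTruth(ds)
  for (r in seq_along(sessionRuns(ds))) {
    run <- sessionRuns(ds)[[r]]
    expect_identical(which(!keptVolumes(censorBrokenFixation(run$eye, 2))),
                     tru$brokenVolumes[[r]])
    expect_identical(which(!keptVolumes(flagMotionOutliers(run$motion))),
                     tru$motionVolumes[[r]])
  }
})

test_that("betas track planted patterns at unit peak-to-noise SNR", {
  ## single-event response peak ~ 1 x noise SD; median correlation over
  ## seeds between estimated and planted betas should be strong
  hrf <- gammaHRF()
  height <- singleEventHeight(hrf, 0.5)
  patSd <- 1 / height / sqrt(2)   # categorySd^2 + exemplarSd^2 = (1/height)^2
  rs <- vapply(1:5, function(s) {
    ds <- generateSession(nRuns = 10, nConditions = 12, nVoxels = 12,
                          patternSpec = list(nCategories = 4,
                                             categorySd = patSd,
                                             exemplarSd = patSd),
                          noiseSpec = list(sd = 1, lengthScale = 2),
                          censorRate = 0, motionRate = 0,
                          scheduleArgs = list(nNull = 8), seed = 100 + s)
    est <- 0
    for (run in sessionRuns(ds)) {
      des <- buildDesignMatrix(run$schedule, hrf)
      fit <- fitGLM(des, run$data)
      interest <- des$labels$name[des$labels$type == "interest"]
      est <- est + betas(fit)[interest, ]
    }
    cor(as.vector(est), as.vector(plantedTruth(ds)$patterns))
  }, numeric(1))
  expect_gt(median(rs), 0.7)
})
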