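test_that("standard-electrode calibration round-trips to 3 uA", {
  expect_gt(calParams@thetaThresh, 0)
  thr <- findThreshold(standardTrain(), calParams, s = 0.43)
  expect_equal(thr$threshold_uA, 3, tolerance = 0.01)
  expect_true(thr$bracketOk)
  # calibration is stable under temporal-grid refinement
  pFine <- calibrateThetaThresh(temporalParams())
  resFine <- simulateTemporal(standardTrain(3, dt = 0.005), temporalParams())
  expect_equal(0.43 * resFine$maxR2, calParams@thetaThresh,
               tolerance = 0.01)
})

test_that("thresholds scale inversely with sensitivity and fall with pw and frequency", {
  tmpl <- pulseTrain(1, 0.25, 50, 0.5)
  t1 <- findThreshold(tmpl, calParams, s = 0.43, tol = 1e-6)$threshold_uA
  t2 <- findThreshold(tmpl, calParams, s = 0.86, tol = 1e-6)$threshold_uA
  expect_equal(t1 / t2, 2, tolerance = 1e-4)
  sd <- runStrengthDuration(calParams, pwGrid = c(0.1, 0.3, 0.6, 1))
  expect_true(all(diff(sd$threshold_uA) < 0))
  sf <- runStrengthDuration(calParams, fGrid = c(20, 50, 120, 240))
  expect_true(all(diff(sf$threshold_uA) < 0))
  # unreachable threshold returns the not-found sentinel
  nf <- findThreshold(tmpl, calParams, s = 1e-12, maxAmp = 10)
  expect_true(is.na(nf$threshold_uA))
})

test_that("strength-duration curves from electrodes differing in s superimpose after scaling", {
  pws <- c(0.15, 0.3, 0.6)
  a <- runStrengthDuration(calParams, pwGrid = pws, s = 0.43, tol = 1e-8)
  b <- runStrengthDuration(calParams, pwGrid = pws, s = 1.7, tol = 1e-8)
  r <- a$threshold_uA / b$threshold_uA
  expect_lt(max(abs(r / mean(r) - 1)), 1e-6)
})

test_that("sensitivity fitting recovers known scales", {
  fx <- makeFixtures(seed = 3)
  fit <- fitSensitivity(fx$thresholdTable, calParams)
  expect_equal(fit$s, fx$trueS, tolerance = 0.01)
  expect_lt(fit$rmse, 1e-4)
  # self-fit at the calibration scale
  tab43 <- fx$thresholdTable
  tab43$threshold_uA <- tab43$threshold_uA * fx$trueS / 0.43
  expect_equal(fitSensitivity(tab43, calParams)$s, 0.43, tolerance = 0.01)
  # log-space agrees on noiseless data
  expect_equal(fitSensitivity(fx$thresholdTable, calParams, "log")$s,
               fx$trueS, tolerance = 0.01)
  bad <- fx$thresholdTable; bad$threshold_uA[1] <- -1
  expect_error(fitSensitivity(bad, calParams), "positive")
})

test_that("brightness ratings are bounded, monotone and frequency-sensitive", {
  expect_equal(predictBrightness(pulseTrain(0, 0.25, 50, 0.5), calParams), 0)
  amps <- c(10, 100, 1e3, 1e4, 1e6)
  b <- vapply(amps, function(a)
    predictBrightness(pulseTrain(a, 0.25, 50, 0.5), calParams), numeric(1))
  expect_true(all(diff(b) > 0))
  expect_true(all(b >= 0 & b <= 10))
  expect_equal(b[5], 10, tolerance = 1e-6)   # saturation at the scale top
  # rating increases with frequency at fixed amplitude
  b50 <- predictBrightness(pulseTrain(500, 0.25, 50, 0.5), calParams)
  b100 <- predictBrightness(pulseTrain(500, 0.25, 100, 0.5), calParams)
  expect_gt(b100, b50)
  # brightness stable under temporal resampling
  bFine <- predictBrightness(pulseTrain(500, 0.25, 50, 0.5, dt = 0.005),
                             calParams)
  expect_equal(bFine, b50, tolerance = 0.01)
})

test_that("amplitude affects phosphene size more than frequency", {
  base <- runSizeExperiments(5, radEs = 0.25, ampFactors = 2,
                             params = calParams, seed = 6)
  A0 <- base$amp_uA[1]
  ampUp <- runSizeExperiments(5, radEs = 0.25, amps = 2 * A0,
                              params = calParams, seed = 6)
  f100 <- pulseTrain(3, 0.25, 100, 0.5)
  fUp <- runSizeExperiments(5, radEs = 0.25, amps = A0,
                            params = calParams, seed = 6, train = f100)
  expect_gt(ampUp$meanDiameter_deg, base$meanDiameter_deg)
  expect_gt(ampUp$meanDiameter_deg / base$meanDiameter_deg,
            fUp$meanDiameter_deg / base$meanDiameter_deg)
})

test_that("spatial thresholds use the percept peak", {
  sh <- testSheet(ecc = 3)
  el <- electrode("e", eccCortexX(3), 0, 0.25, s = 1)
  thr <- findThreshold(standardTrain(), calParams, electrode = el,
                       sheet = sh, maxAmp = 1e6, tol = 1e-4)
  expect_false(is.na(thr$threshold_uA))
  # doubling s halves the spatial threshold too
  el2 <- electrode("e2", el@x, 0, 0.25, s = 2)
  thr2 <- findThreshold(standardTrain(), calParams, electrode = el2,
                        sheet = sh, maxAmp = 1e6, tol = 1e-4)
  expect_equal(thr$threshold_uA / thr2$threshold_uA, 2, tolerance = 1e-2)
})
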