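test_that("the calibration curve has the stated asymptotes and midpoint", {
  cal <- calibrationFit(K = 15, tauMax = 2.5)
  expect_equal(predictLifetime(cal, 0), 0.914)
  expect_equal(predictLifetime(cal, 15), (2.5 + 0.914) / 2)
  # hand arithmetic: (2.5 - 0.914) * 0.75 + 0.914
  expect_equal(predictLifetime(cal, 45), 2.1035)
  expect_error(predictLifetime(cal, -1), ">= 0")
  # strictly increasing, bounded in [floor, tauMax)
  tau <- predictLifetime(cal, seq(0, 500, by = 0.5))
  expect_true(all(diff(tau) > 0))
  expect_true(all(tau >= 0.914 & tau < 2.5))
})

test_that("backcalculation inverts the curve exactly", {
  cal <- calibrationFit(K = 12, tauMax = 2.4)
  expect_equal(backcalculatePO2(cal, 0.914), 0)
  expect_equal(backcalculatePO2(cal, 0.5), 0)   # below the floor -> 0
  expect_equal(backcalculatePO2(cal, (2.4 + 0.914) / 2), 12)
  expect_true(is.na(backcalculatePO2(cal, 2.4)))  # saturated
  for (x in c(0.1, 1, 10, 100))
    expect_lt(abs(backcalculatePO2(cal, predictLifetime(cal, x)) - x), 1e-9)
})

test_that("calibration fitting recovers exact model points", {
  truth <- calibrationFit(K = 15, tauMax = 2.5)
  p <- c(0, 5, 10, 20, 40, 80, 120, 160)
  pts <- data.frame(imposedPO2 = p, tau = predictLifetime(truth, p))
  fit <- fitCalibration(pts)
  expect_true(fit@converged)
  expect_lt(abs(fit@K / 15 - 1), 1e-6)
  expect_lt(abs(fit@tauMax / 2.5 - 1), 1e-6)
  expect_identical(fit@tauFloor, 0.914)
  expect_lt(fit@rss, 1e-12)
})

test_that("calibration fitting rejects degenerate inputs", {
  expect_error(fitCalibration(data.frame(imposedPO2 = c(0, 160),
                                         tau = c(0.92, 2.4))),
               "at least 3")
  expect_error(fitCalibration(data.frame(imposedPO2 = c(10, 10, 10),
                                         tau = c(1.5, 1.5, 1.5))),
               "distinct")
})

test_that("calibration recovery is robust to lifetime noise", {
  truth <- calibrationFit(K = 15, tauMax = 2.5)
  p <- c(0, 5, 10, 20, 40, 80, 120, 160)
  mu <- predictLifetime(truth, p)
  errs <- withr::with_seed(101L, vapply(1:25, function(i) {
    pts <- data.frame(imposedPO2 = p, tau = mu + stats::rnorm(8, 0, 0.02))
    fit <- fitCalibration(pts)
    c(abs(fit@K / 15 - 1), abs(fit@tauMax / 2.5 - 1))
  }, c(1, 1)))
  expect_lt(stats::median(errs[1L, ]), 0.10)
  expect_lt(stats::median(errs[2L, ]), 0.02)
})

test_that("oxygen maps recover the imposed rotenone level", {
  spec <- sceneSpec(imageHeight = 48L, imageWidth = 48L, mitoCount = 8L,
                    mitoRadiusRange = c(2, 4), seed = 31L)
  ser <- generateCalibrationSeries(spec, 40)
  fit <- fitImage(ser[[1L]]$image)
  truthCal <- calibrationFit(spec$truthK, spec$truthTauMax)
  om <- po2Map(fit, truthCal)
  v <- po2Values(om)[fitMask(om)]
  expect_lt(abs(stats::median(v) / 40 - 1), 0.05)
  expect_identical(om@condition, "rotenone")
})

test_that("an all-floor image maps to zero oxygen everywhere", {
  fit <- constantFitImage(tau1 = 0.914, tau2 = 0.914, a1 = 1)
  cal <- calibrationFit(K = 15, tauMax = 2.5)
  om <- po2Map(fit, cal)
  expect_true(all(po2Values(om)[fitMask(om)] == 0))
})

test_that("saturated pixels are masked out of the oxygen map", {
  fit <- constantFitImage(nr = 2L, nc = 2L, tau1 = 2.0, tau2 = 3.0, a1 = 0.5)
  # tauMean = 2.5 = tauMax -> every pixel saturates
  cal <- calibrationFit(K = 15, tauMax = 2.5)
  om <- po2Map(fit, cal)
  expect_true(all(om@saturated))
  expect_false(any(fitMask(om)))
  emptyFit <- constantFitImage(mask = matrix(FALSE, 4L, 4L))
  expect_error(po2Map(emptyFit, cal), "no valid pixels")
})

test_that("mixture images give a bimodal oxygen distribution", {
  spec <- sceneSpec(imageHeight = 64L, imageWidth = 64L, mitoCount = 14L,
                    mitoRadiusRange = c(2, 4), seed = 37L)
  sim <- generateDecayImage(spec)
  fit <- fitImage(sim$image)
  om <- po2Map(fit, calibrationFit(spec$truthK, spec$truthTauMax))
  v <- po2Values(om)[fitMask(om)]
  # substantial mass near both mixture modes (10 and 60 mmHg)
  expect_gt(mean(abs(v - 10) < 10), 0.15)
  expect_gt(mean(abs(v - 60) < 25), 0.15)
  expect_lt(mean(v > 35 & v < 40), 0.2)
})
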