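dtDefault <- 12.5 / 256

test_that("amplitude-weighted lifetime follows the defining formula", {
  expect_equal(amplitudeWeightedLifetime(0.5, 0.5, 1.0, 3.0), 2.0)
  expect_equal(amplitudeWeightedLifetime(1.0, 0.0, 1.8, 7.3), 1.8)
  expect_equal(amplitudeWeightedLifetime(0.25, 0.75, 0.4, 2.0), 1.6)
  # unnormalized amplitudes are normalized by their sum
  expect_equal(amplitudeWeightedLifetime(2, 2, 1.0, 3.0), 2.0)
  expect_error(amplitudeWeightedLifetime(0, 0, 1, 2), "positive")
  expect_error(amplitudeWeightedLifetime(0.5, 0.5, -1, 2), "positive")
})

test_that("noiseless forward-model curves are recovered almost exactly", {
  cases <- list(c(0.5, 2.5, 0.6), c(0.3, 1.8, 0.2), c(0.9, 3.5, 0.75))
  for (cs in cases) {
    y <- 1e6 * decayChannelProbs(256, 12.5, cs[1], cs[2], cs[3])
    f <- fitPixelDecay(y, dtDefault)
    expect_true(f$valid)
    expect_lt(abs(f$tau1 / cs[1] - 1), 1e-3)
    expect_lt(abs(f$tau2 / cs[2] - 1), 1e-3)
    expect_lt(abs(f$a1 - cs[3]), 1e-3)
  }
})

test_that("single-exponential data yield the right mean lifetime", {
  y <- 1e6 * decayChannelProbs(256, 12.5, 1.8, 1.8, 1.0)
  f <- fitPixelDecay(y, dtDefault)
  expect_true(f$valid)
  expect_lt(abs(f$tauMean / 1.8 - 1), 0.01)
  # degenerate pairs collapse to a1 = 1 with tau1 = tau2
  if (f$collapsed) {
    expect_equal(f$a1, 1)
    expect_equal(f$tau1, f$tau2)
  }
})

test_that("empty and invalid histograms are handled as specified", {
  z <- fitPixelDecay(rep(0, 256), dtDefault, minPhotons = 0)
  expect_false(z$valid)
  expect_true(is.na(z$tauMean))
  few <- fitPixelDecay(c(50, rep(0, 255)), dtDefault, minPhotons = 100)
  expect_false(few$valid)
  expect_identical(few$photons, 50)
  expect_error(fitPixelDecay(c(-1, rep(1, 255)), dtDefault), "negative")
  expect_error(fitPixelDecay(rep(1, 4), dtDefault), "8 channels")
  expect_error(fitPixelDecay(rep(1, 256), 0), "positive")
})

test_that("fitter matches a dense grid search on a noiseless curve", {
  truthPar <- c(0.5, 2.5, 0.6)
  y <- 1e5 * decayChannelProbs(256, 12.5, truthPar[1], truthPar[2],
                               truthPar[3])
  N <- sum(y)
  w <- 1 / pmax(y, 1)
  # independent grid search over (tau1, tau2, a1) with N fixed
  g1 <- seq(0.35, 0.65, by = 0.025)
  g2 <- seq(2.2, 2.8, by = 0.025)
  g3 <- seq(0.45, 0.75, by = 0.025)
  best <- c(NA, NA, NA); bestCost <- Inf
  for (t1 in g1) for (t2 in g2) for (a in g3) {
    m <- N * decayChannelProbs(256, 12.5, t1, t2, a)
    cst <- sum(w * (y - m)^2)
    if (cst < bestCost) { bestCost <- cst; best <- c(t1, t2, a) }
  }
  f <- fitPixelDecay(y, dtDefault, objective = "neyman")
  expect_lt(abs(f$tau1 - best[1]), 0.025)
  expect_lt(abs(f$tau2 - best[2]), 0.025)
  expect_lt(abs(f$a1 - best[3]), 0.025)
  # and the optimizer must do at least as well as the grid
  mFit <- f$photons * decayChannelProbs(256, 12.5, f$tau1, f$tau2, f$a1)
  expect_lte(sum(w * (y - mFit)^2), bestCost + 1e-9)
})

test_that("whole-image fits satisfy the normalization and ordering invariants", {
  sim <- generateDecayImage(smallScene(seed = 13L))
  fit <- fitImage(sim$image)
  m <- fitMask(fit)
  expect_true(any(m))
  expect_true(all(abs(fit@a1[m] + fit@a2[m] - 1) < 1e-9))
  expect_true(all(fit@tau1[m] <= fit@tau2[m] + 1e-12))
  expect_true(all(is.na(tauMean(fit)[!m])))
  expect_true(methods::validObject(fit))
})

test_that("tau_mean recovery error shrinks as the photon budget grows", {
  rmse <- vapply(c(500, 5000, 50000), function(budget) {
    sim <- generateDecayImage(
      sceneSpec(imageHeight = 32L, imageWidth = 32L, mitoCount = 5L,
                mitoRadiusRange = c(2, 4), mitoPhotonBudget = budget,
                seed = 17L))
    fit <- fitImage(sim$image, minPhotons = 50)
    tm <- tauMean(sim$truth)
    m <- fitMask(fit) & !is.na(tm)
    sqrt(mean((tauMean(fit)[m] - tm[m])^2))
  }, 1)
  expect_true(all(diff(rmse) < 0))
})

test_that("spatial binning pools photons and reduces variance", {
  spec <- sceneSpec(imageHeight = 32L, imageWidth = 32L, mitoCount = 1L,
                    mitoRadiusRange = c(8, 8), mitoPhotonBudget = 500,
                    backgroundPhotonRate = 0,
                    po2Mixture = data.frame(weight = 1, mean = 40, sd = 0),
                    seed = 19L)
  sim <- generateDecayImage(spec)
  tm <- tauMean(sim$truth)
  inner <- !is.na(tm)
  f1 <- fitImage(sim$image, minPhotons = 100, spatialBinning = 1L)
  f3 <- fitImage(sim$image, minPhotons = 100, spatialBinning = 3L)
  core <- inner & fitMask(f1) & fitMask(f3)
  # interior-only comparison (binning mixes background at the rim)
  er <- cbind(tauMean(f1)[core], tauMean(f3)[core]) - tm[core]
  expect_lt(stats::sd(er[, 2L]), stats::sd(er[, 1L]))
  expect_lt(abs(mean(er[, 2L])), 0.05)
  expect_error(fitImage(sim$image, spatialBinning = 2L), "odd")
  expect_error(fitImage(sim$image, spatialBinning = 65L), "extent")
})

test_that("a min-photon threshold above all pixels empties the mask", {
  sim <- generateDecayImage(smallScene(seed = 23L))
  fit <- fitImage(sim$image, minPhotons = 1e9)
  expect_false(any(fitMask(fit)))
})

test_that("amplitude-fraction maps are complementary percentages", {
  sim <- generateDecayImage(smallScene(seed = 29L))
  fit <- fitImage(sim$image)
  short <- boundFractionMap(fit, "short")
  long <- boundFractionMap(fit, "long")
  m <- fitMask(fit)
  expect_true(all(abs(short[m] + long[m] - 100) < 1e-9))
  expect_true(all(is.na(short[!m])))
  # mean long ("bound") fraction tracks the generator truth within 2 points
  expect_lt(abs(mean(long[m]) - 75), 2)
})

test_that("constant-parameter fit images give constant fraction maps", {
  fit <- constantFitImage(a1 = 0.3)
  expect_true(all(boundFractionMap(fit, "short") == 30))
  expect_true(all(boundFractionMap(fit, "long") == 70))
})
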