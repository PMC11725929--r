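test_that("scene spec validation rejects inconsistent parameters", {
  expect_s3_class(smallScene(), "SceneSpec")
  expect_error(smallScene(po2Mixture = data.frame(weight = c(0.5, 0.4),
                                                  mean = c(10, 60),
                                                  sd = c(3, 10))),
               "sum to 1")
  expect_error(smallScene(shortLifetime = 3), "shortLifetime")
  expect_error(smallScene(shortFraction = 1), "shortFraction")
  expect_error(smallScene(nChannels = 1), "nChannels")
})

test_that("decay image generation is deterministic and photon-conserving", {
  spec <- smallScene(seed = 7L)
  s1 <- generateDecayImage(spec)
  s2 <- generateDecayImage(spec)
  expect_identical(counts(s1$image), counts(s2$image))
  expect_identical(perMitoPO2(s1$truth), perMitoPO2(s2$truth))
  # photon count per pixel is exactly the channel sum
  tot <- apply(counts(s1$image), c(1, 2), sum)
  expect_identical(sum(tot), sum(counts(s1$image)))
  # different seed gives a different realisation
  s3 <- generateDecayImage(smallScene(seed = 8L))
  expect_false(identical(counts(s1$image), counts(s3$image)))
})

test_that("zero background puts every photon inside the mitochondrial mask", {
  spec <- sceneSpec(imageHeight = 32L, imageWidth = 32L, mitoCount = 1L,
                    mitoRadiusRange = c(3, 5), backgroundPhotonRate = 0,
                    seed = 5L)
  sim <- generateDecayImage(spec)
  tot <- apply(counts(sim$image), c(1, 2), sum)
  expect_true(all(tot[labelImage(sim$truth) == 0L] == 0))
  expect_gt(sum(tot[labelImage(sim$truth) > 0L]), 0)
})

test_that("mitochondrial photon budget matches the Poisson mean", {
  spec <- sceneSpec(imageHeight = 64L, imageWidth = 64L, mitoCount = 12L,
                    mitoRadiusRange = c(3, 5), mitoPhotonBudget = 5000,
                    backgroundPhotonRate = 0, seed = 2L)
  sim <- generateDecayImage(spec)
  tot <- apply(counts(sim$image), c(1, 2), sum)
  inside <- tot[labelImage(sim$truth) > 0L]
  expect_gte(length(inside), 500L)
  se <- sqrt(5000 / length(inside))  # Poisson mean = variance
  expect_lt(abs(mean(inside) - 5000), 3 * se)
})

test_that("ground truth is self-consistent with the calibration law", {
  spec <- smallScene(seed = 9L)
  sim <- generateDecayImage(spec)
  truthCal <- calibrationFit(spec$truthK, spec$truthTauMax, spec$tauFloor)
  po2 <- perMitoPO2(sim$truth)
  lab <- labelImage(sim$truth)
  tm <- tauMean(sim$truth)
  for (m in unique(lab[lab > 0])) {
    tauM <- tm[lab == m][1L]
    expect_lt(abs(backcalculatePO2(truthCal, tauM) - po2[[as.character(m)]]),
              1e-9)
  }
  # amplitude-weighted consistency enforced by the class validity
  expect_true(methods::validObject(sim$truth))
})

test_that("mitochondria placement fails explicitly when space runs out", {
  expect_error(
    generateDecayImage(sceneSpec(imageHeight = 16L, imageWidth = 16L,
                                 mitoCount = 50L, mitoRadiusRange = c(3, 4),
                                 seed = 1L)),
    "non-overlapping")
})

test_that("calibration series pins every mitochondrion at the imposed level", {
  spec <- smallScene(seed = 3L)
  expect_error(generateCalibrationSeries(spec, numeric(0)), "at least one")
  expect_error(generateCalibrationSeries(spec, c(-5, 10)), ">= 0")
  ser <- generateCalibrationSeries(spec, c(0, 40, 160))
  expect_length(ser, 3L)
  # at pO2 = 0 the true mean lifetime is exactly the deoxygenated limit
  tm0 <- tauMean(ser[[1L]]$truth)
  expect_equal(unique(tm0[!is.na(tm0)]), spec$tauFloor, tolerance = 1e-12)
  expect_true(all(ser[[2L]]$truth@perMitoPO2 == 40))
  # true mean lifetime increases monotonically with imposed pO2
  means <- vapply(ser, function(s) mean(tauMean(s$truth), na.rm = TRUE), 1)
  expect_true(all(diff(means) > 0))
  expect_equal(vapply(ser, function(s) condition(s$image), ""),
               rep("rotenone", 3L))
})

test_that("Ct tables follow the dilution-corrected log arithmetic", {
  ab <- data.frame(sample = c("a", "b", "c"),
                   target = "t", role = "IP",
                   abundance = c(4, 4, 64))
  spec <- ctSpec(ab, replicateSd = 0, seed = 1L)
  tab <- generateCtTable(spec)
  # equal abundance and dilution -> identical Ct
  expect_equal(tab$ct1[1L], tab$ct1[2L])
  expect_equal(tab$ct1, tab$ct2)
  # abundance ratio 16 at efficiency 2 -> Ct difference 4
  expect_equal(tab$ct1[1L] - tab$ct1[3L], 4)
  # deterministic under a fixed seed, with noise
  spec2 <- ctSpec(ab, replicateSd = 0.3, seed = 42L)
  expect_identical(generateCtTable(spec2), generateCtTable(spec2))
  expect_error(ctSpec(transform(ab, abundance = c(1, 0, 2))), "positive")
  expect_error(ctSpec(ab, efficiency = 2.5), "efficiency")
})

test_that("read generator covers the circle uniformly without peaks", {
  reads <- generateReads(16299, 50000, 75, seed = 4L)
  expect_identical(reads, generateReads(16299, 50000, 75, seed = 4L))
  # chi-square GOF against the uniform multinomial over 100 bins
  bins <- cut(((reads$start - 1) %% 16299), breaks = 100)
  gof <- suppressWarnings(stats::chisq.test(table(bins)))
  expect_gt(gof$p.value, 0.01)
  expect_true(all(reads$end - reads$start == 74))
})

test_that("peak enrichment concentrates reads as specified", {
  pk <- data.frame(center = 8000, width = 400, fold = 20)
  reads <- generateReads(16299, 20000, 75, peaks = pk, seed = 6L)
  sig <- binnedRPKM(reads, 16299, 20)
  peakBins <- which(abs((seq_along(sig@values) - 0.5) * 20 - 8000) <= 200)
  bg <- mean(sig@values[-peakBins])
  expect_gt(mean(sig@values[peakBins]), 5 * bg)
  expect_error(generateReads(16299, 100, 75,
                             peaks = data.frame(center = 1, width = 10,
                                                fold = 0.5)),
               "fold")
  expect_error(generateReads(50, 10, 75), "genomeLength")
})
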