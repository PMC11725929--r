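test_that("lifetime histograms are normalized and refinement-consistent", {
  sim <- generateDecayImage(smallScene(seed = 41L))
  fit <- fitImage(sim$image)
  h <- lifetimeHistogram(fit, binWidth = 0.1)
  expect_equal(sum(h@frequencies), 1)
  expect_true(all(diff(h@binEdges) > 0))
  # halving the bin width re-aggregates exactly to the coarse histogram
  hf <- lifetimeHistogram(fit, binWidth = 0.05)
  coarse <- findInterval(hf@binEdges[-length(hf@binEdges)] + 1e-12,
                         h@binEdges)
  agg <- vapply(seq_along(h@frequencies), function(i)
    sum(hf@frequencies[coarse == i]), 1)
  expect_equal(agg, h@frequencies, tolerance = 1e-12)
})

test_that("a constant-lifetime image occupies a single histogram bin", {
  fit <- constantFitImage(tau1 = 2, tau2 = 2, a1 = 1)
  h <- lifetimeHistogram(fit, binWidth = 0.05)
  expect_equal(max(h@frequencies), 1)
  expect_equal(sum(h@frequencies > 0), 1L)
  empty <- constantFitImage(mask = matrix(FALSE, 4L, 4L))
  expect_error(lifetimeHistogram(empty), "no valid pixels")
})

test_that("label restriction selects only mitochondrial pixels", {
  sim <- generateDecayImage(smallScene(seed = 43L))
  fit <- fitImage(sim$image, minPhotons = 0)
  h <- lifetimeHistogram(fit, restrictTo = labelImage(sim$truth))
  expect_lte(h@nPixels, sum(labelImage(sim$truth) > 0))
})

test_that("subpopulation fractions partition the valid pixels", {
  om <- makeOxygenMap(matrix(c(rep(5, 6), rep(35, 4), rep(70, 6)), 4, 4))
  sp <- subpopulationFractions(om, 30, 40)
  expect_equal(sp@highOCR, 6 / 16)
  expect_equal(sp@mid, 4 / 16)
  expect_equal(sp@lowOCR, 6 / 16)
  expect_equal(sp@highOCR + sp@mid + sp@lowOCR, 1)
  # all pixels at zero oxygen -> all high-OCR
  spZero <- subpopulationFractions(makeOxygenMap(0), 30, 40)
  expect_equal(spZero@highOCR, 1)
  # thresholds outside the data range -> everything intermediate
  spMid <- subpopulationFractions(makeOxygenMap(35), 1, 1000)
  expect_equal(spMid@mid, 1)
  expect_error(subpopulationFractions(om, 40, 30), "smaller")
})

test_that("fractions ignore pixel order and masked pixels", {
  v <- c(rep(5, 5), rep(35, 3), rep(70, 8))
  om1 <- makeOxygenMap(matrix(v, 4, 4))
  om2 <- makeOxygenMap(matrix(rev(v), 4, 4))
  s1 <- subpopulationFractions(om1, 30, 40)
  s2 <- subpopulationFractions(om2, 30, 40)
  expect_equal(s1@highOCR, s2@highOCR)
  # append masked pixels: fractions unchanged
  big <- matrix(NA_real_, 5, 4)
  big[1:4, ] <- matrix(v, 4, 4)
  s3 <- subpopulationFractions(makeOxygenMap(big), 30, 40)
  expect_equal(s3@highOCR, s1@highOCR)
  expect_equal(s3@lowOCR, s1@lowOCR)
})

test_that("reference thresholds are pooled quantiles of valid pixels", {
  om <- makeOxygenMap(matrix(1:16, 4, 4))
  thr <- referenceThresholds(om)
  expect_equal(thr, unname(stats::quantile(1:16, c(0.25, 0.75))))
  thr2 <- referenceThresholds(list(om, om))
  expect_equal(thr, thr2)
})

test_that("FLIRR is the bound-NAD(P)H over bound-FAD amplitude ratio", {
  nadh <- constantFitImage(a1 = 0.6)   # a2 (bound) = 40%
  fad <- constantFitImage(a1 = 0.2)    # a1 (free-> bound flavin) = 20%
  rm <- flirrMap(nadh, fad)
  expect_true(all(rm@flirr[rm@mask] == 2))
  # zero FAD a1 pixels are masked, not infinite
  fad0 <- constantFitImage(a1 = 0)
  rm0 <- flirrMap(nadh, fad0)
  expect_false(any(rm0@mask))
  expect_true(all(is.na(rm0@flirr)))
  expect_error(flirrMap(nadh, constantFitImage(nr = 3L)), "dimensions")
})

test_that("FLIRR recovers a simulated truth ratio within 5%", {
  # noisy amplitude fields around a2n = 45%, a1f = 30% -> ratio 1.5
  withr::with_seed(47L, {
    n <- 40L
    a2n <- matrix(pmin(pmax(stats::rnorm(n * n, 0.45, 0.03), 0.05), 0.95),
                  n, n)
    a1f <- matrix(pmin(pmax(stats::rnorm(n * n, 0.30, 0.02), 0.05), 0.95),
                  n, n)
    mk <- function(a1) {
      f <- constantFitImage(nr = n, nc = n, a1 = 0.5)
      f@a1 <- a1; f@a2 <- 1 - a1
      f
    }
    rm <- flirrMap(mk(1 - a2n), mk(a1f))
    expect_lt(abs(stats::median(rm@flirr[rm@mask]) / 1.5 - 1), 0.05)
  })
})

test_that("Mann-Whitney matches exact enumeration on small samples", {
  res <- mannWhitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p.value, 0.1)
  expect_identical(res$method, "exact")
  expect_equal(res$p.value, enumMannWhitneyP(c(1, 2, 3), c(4, 5, 6)))
  # a second configuration against the enumeration oracle
  a <- c(1.2, 3.4, 2.2, 5.1); b <- c(2.8, 4.6, 6.3)
  expect_equal(mannWhitney(a, b)$p.value, enumMannWhitneyP(a, b))
  expect_error(mannWhitney(numeric(0), 1), "non-empty")
})

test_that("identical groups are not declared different", {
  res <- mannWhitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gte(res$p.value, 0.99)
})

test_that("exact and normal-approximation p agree at moderate n", {
  withr::with_seed(53L, {
    for (i in 1:5) {
      a <- stats::rnorm(6)
      b <- stats::rnorm(6)
      pExact <- mannWhitney(a, b)$p.value
      pNorm <- stats::wilcox.test(a, b, exact = FALSE,
                                  correct = TRUE)$p.value
      expect_lt(abs(pExact - pNorm), 0.02)
    }
  })
})

test_that("Welch t tests behave on the canonical cases", {
  g <- data.frame(condition = rep(c("A", "B"), each = 4L),
                  value = c(1, 2, 3, 4, 1, 2, 3, 4))
  res <- unpairedTTests(g)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  expect_error(unpairedTTests(g, pairs = list(c("A", "Z"))), "unknown")
  # a 3-SD shift at n = 20 is detected overwhelmingly
  withr::with_seed(59L, {
    g2 <- data.frame(condition = rep(c("A", "B"), each = 20L),
                     value = c(stats::rnorm(20), stats::rnorm(20, 3)))
    expect_lt(unpairedTTests(g2)$p, 0.001)
  })
  # Holm adjustment is available behind the flag
  g3 <- rbind(g, data.frame(condition = "C", value = c(9, 10, 11, 12)))
  resH <- unpairedTTests(g3, adjust = "holm")
  expect_equal(nrow(resH), 3L)
  expect_true(all(resH$p.adj >= resH$p))
})

test_that("pseudocolor rendering is warm-at-low-oxygen and deterministic", {
  om <- makeOxygenMap(matrix(c(0, 100, 50, 25), 2, 2))
  f1 <- file.path(tempdir(), "po2_a.png")
  f2 <- file.path(tempdir(), "po2_b.png")
  meta <- renderPseudocolor(om, f1, limits = c(0, 100))
  renderPseudocolor(om, f2, limits = c(0, 100))
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  img <- png::readPNG(f1)
  # warmth = red minus blue: 0 mmHg pixel (1,1) warmer than 100 mmHg (2,1)
  warmth <- img[, , 1] - img[, , 3]
  expect_gt(warmth[1, 1], warmth[2, 1])
  expect_gt(img[2, 1, 3], img[1, 1, 3])  # high oxygen is bluer
  expect_equal(meta$limits, c(0, 100))
  # constant maps render a single hue
  fc <- file.path(tempdir(), "po2_c.png")
  renderPseudocolor(makeOxygenMap(20), fc)
  imgc <- png::readPNG(fc)
  for (ch in 1:3)
    expect_length(unique(as.vector(imgc[, , ch])), 1L)
  empty <- constantFitImage(mask = matrix(FALSE, 4L, 4L))
  expect_error(renderPseudocolor(empty, tempfile()), "empty mask")
})
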