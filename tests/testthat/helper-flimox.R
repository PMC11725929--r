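# shared fixtures, built in code

# a small scene that fits quickly
smallScene <- function(seed = 1L, ...) {
  sceneSpec(imageHeight = 32L, imageWidth = 32L, mitoCount = 4L,
            mitoRadiusRange = c(2, 4), seed = seed, ...)
}

# FitImage with constant parameters on an all-valid mask
constantFitImage <- function(nr = 4L, nc = 4L, tau1 = 0.5, tau2 = 2.5,
                             a1 = 0.3, mask = NULL, condition = "test") {
  if (is.null(mask)) mask <- matrix(TRUE, nr, nc)
  m <- function(v) {
    x <- matrix(v, nr, nc)
    x[!mask] <- NA_real_
    x
  }
  methods::new("FitImage",
    tau1 = m(tau1), tau2 = m(tau2), a1 = m(a1), a2 = m(1 - a1),
    tauMean = m(a1 * tau1 + (1 - a1) * tau2),
    chi2 = m(1), photons = matrix(1000, nr, nc), mask = mask,
    chi2Flagged = matrix(FALSE, nr, nc),
    metadata = list(condition = condition, timeWindow = 12.5))
}

# OxygenMap with given pO2 values (matrix or scalar)
makeOxygenMap <- function(po2, mask = NULL, condition = "test") {
  if (!is.matrix(po2)) po2 <- matrix(po2, 4L, 4L)
  if (is.null(mask)) mask <- !is.na(po2)
  po2[!mask] <- NA_real_
  methods::new("OxygenMap", po2 = po2, mask = mask,
               saturated = matrix(FALSE, nrow(po2), ncol(po2)),
               condition = condition)
}

# independent two-sided exact Mann-Whitney p by full enumeration of
# labelings (oracle; never calls the implementation under test)
enumMannWhitneyP <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  uStat <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  obs <- uStat(a, b)
  mu <- na * (n - na) / 2
  combos <- utils::combn(n, na)
  us <- apply(combos, 2L, function(idx)
    uStat(pooled[idx], pooled[-idx]))
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}
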