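#' Discretized biexponential channel fractions
#'
#' Expected fraction of detected photons in each TCSPC channel under the
#' window-truncated biexponential decay
#' \eqn{a_1 e^{-t/\tau_1} + (1-a_1) e^{-t/\tau_2}} with a delta-function
#' instrument response. Channel probabilities are the exact integrals of the
#' normalized decay over each channel bin, truncated at the window (no
#' incomplete-decay wraparound).
#'
#' @param nChannels number of channels.
#' @param timeWindow TCSPC window in ns.
#' @param tau1,tau2 component lifetimes in ns.
#' @param a1 amplitude fraction of the \code{tau1} component, in \code{[0, 1]}.
#' @param offset fixed time offset in ns (default 0).
#' @return numeric vector of length \code{nChannels} summing to 1.
#' @export
decayChannelProbs <- function(nChannels, timeWindow, tau1, tau2, a1,
                              offset = 0) {
  .decayChannelProbsCpp(as.integer(nChannels), timeWindow / nChannels,
                        tau1, tau2, a1, offset)
}

#' Amplitude-weighted mean lifetime
#'
#' \eqn{\tau_{mean} = (a_1\tau_1 + a_2\tau_2)/(a_1 + a_2)}: the per-pixel
#' average lifetime generated by amplitude weighting of the biexponential
#' components.
#'
#' @param a1,a2 amplitude fractions (need not be normalized; their sum must
#'   be positive).
#' @param tau1,tau2 component lifetimes in ns (positive).
#' @return mean lifetime in ns.
#' @examples
#' amplitudeWeightedLifetime(0.5, 0.5, 1, 3)  # 2 ns
#' @export
amplitudeWeightedLifetime <- function(a1, a2, tau1, tau2) {
  if (any(a1 + a2 <= 0)) stop("a1 + a2 must be positive")
  if (any(tau1 <= 0) || any(tau2 <= 0)) stop("lifetimes must be positive")
  (a1 * tau1 + a2 * tau2) / (a1 + a2)
}

#' Fit a single pixel's decay histogram
#'
#' Nonlinear least-squares fit of the biexponential model
#' \eqn{N (a_1 e^{-t/\tau_1} + (1-a_1) e^{-t/\tau_2})} over channel-bin
#' integrals. The default \code{"poisson"} objective uses Poisson weights
#' refreshed from the model curve at every iteration (iteratively
#' reweighted least squares, equivalent to Fisher scoring for the Poisson
#' likelihood), which is essentially unbiased down to the photon counts
#' typical of a FLIM pixel; \code{"neyman"} uses the classic fixed
#' observed-count weights \code{1/max(count, 1)}, which are simpler but
#' bias lifetimes downward when many tail channels hold only a few photons.
#' Lifetimes are bounded to \code{[0.01 ns, timeWindow]} and ordered
#' \eqn{\tau_1 \le \tau_2} after convergence; a near-degenerate pair
#' (within 1\%) is collapsed to a single exponential reported with
#' \eqn{a_1 = 1}. The reduced chi-squared is the conventional
#' observed-count-weighted residual sum of squares over (channels - 4).
#'
#' @param histogram numeric vector of non-negative channel counts
#'   (length >= 8).
#' @param channelWidth channel width in ns.
#' @param minPhotons pixels with fewer total photons are marked invalid
#'   rather than fitted (default 100).
#' @param offset fixed time offset in ns (default 0).
#' @param objective \code{"poisson"} (default) or \code{"neyman"}, see
#'   Details.
#' @return a list with elements \code{tau1}, \code{tau2}, \code{a1},
#'   \code{a2}, \code{tauMean}, \code{chi2Reduced}, \code{photons},
#'   \code{valid}, \code{collapsed}.
#' @seealso [fitImage()] for whole-image fitting.
#' @export
fitPixelDecay <- function(histogram, channelWidth, minPhotons = 100,
                          offset = 0,
                          objective = c("poisson", "neyman")) {
  objective <- match.arg(objective)
  if (length(histogram) < 8L)
    stop("'histogram' must have at least 8 channels")
  if (channelWidth <= 0) stop("'channelWidth' must be positive")
  if (any(histogram < 0)) stop("negative photon counts are not allowed")
  photons <- sum(histogram)
  if (photons < minPhotons) {
    return(list(tau1 = NA_real_, tau2 = NA_real_, a1 = NA_real_,
                a2 = NA_real_, tauMean = NA_real_, chi2Reduced = NA_real_,
                photons = photons, valid = FALSE, collapsed = FALSE))
  }
  f <- .fitDecayCpp(matrix(as.numeric(histogram), ncol = 1L), channelWidth,
                    offset, 60L, 0.01,
                    if (objective == "neyman") 1L else 0L)
  valid <- is.finite(f[1L, 1L]) && f[6L, 1L] > 0
  list(tau1 = f[1L, 1L], tau2 = f[2L, 1L], a1 = f[3L, 1L],
       a2 = 1 - f[3L, 1L],
       tauMean = if (valid)
         amplitudeWeightedLifetime(f[3L, 1L], 1 - f[3L, 1L],
                                   f[1L, 1L], f[2L, 1L]) else NA_real_,
       chi2Reduced = f[5L, 1L], photons = photons, valid = valid,
       collapsed = f[8L, 1L] > 0)
}

#' Fit the biexponential decay model to every pixel of a TCSPC image
#'
#' Optionally pools photons over a k x k pixel neighborhood (sliding window,
#' as FLIM analysis software does to raise per-pixel photon counts) before
#' fitting each pixel with [fitPixelDecay()]'s model. Pixels with fewer than
#' \code{minPhotons} pooled photons, or whose optimisation fails, are masked.
#' Pixels whose reduced chi-squared exceeds \code{chi2Gate} are flagged in
#' \code{chi2Flagged} but retained in the mask by default.
#'
#' @param image a [TCSPCImage-class].
#' @param minPhotons minimum pooled photon count per pixel (default 100).
#' @param spatialBinning odd neighborhood width k (default 1 = no pooling).
#' @param offset fixed time offset in ns (default 0).
#' @param chi2Gate reduced chi-squared quality gate (default 5; flag only).
#' @param excludeFlagged drop chi-squared-flagged pixels from the mask
#'   (default \code{FALSE}).
#' @param objective fit objective, see [fitPixelDecay()].
#' @return a [FitImage-class].
#' @export
fitImage <- function(image, minPhotons = 100, spatialBinning = 1L,
                     offset = 0, chi2Gate = 5, excludeFlagged = FALSE,
                     objective = c("poisson", "neyman")) {
  objective <- match.arg(objective)
  stopifnot(methods::is(image, "TCSPCImage"))
  methods::validObject(image)
  d <- dim(image@counts)
  H <- d[1L]; W <- d[2L]; C <- d[3L]
  k <- as.integer(spatialBinning)
  if (k < 1L || k %% 2L == 0L)
    stop("'spatialBinning' must be an odd positive integer")
  if (k > min(H, W))
    stop("'spatialBinning' exceeds the image extent")
  cube <- image@counts
  if (k > 1L) {
    for (ch in seq_len(C)) cube[, , ch] <- boxSum2D(cube[, , ch], k)
  }
  M <- matrix(cube, H * W, C)  # pixel-major
  photons <- matrix(rowSums(M), H, W)
  validIn <- photons >= minPhotons

  emptyM <- function() matrix(NA_real_, H, W)
  tau1 <- emptyM(); tau2 <- emptyM(); a1 <- emptyM(); a2 <- emptyM()
  tm <- emptyM(); chi2 <- emptyM()
  mask <- matrix(FALSE, H, W)
  flagged <- matrix(FALSE, H, W)

  idx <- which(validIn)
  if (length(idx) > 0L) {
    f <- .fitDecayCpp(t(M[idx, , drop = FALSE]), image@timeWindow / C,
                      offset, 60L, 0.01,
                      if (objective == "neyman") 1L else 0L)
    ok <- is.finite(f[1L, ]) & f[6L, ] > 0
    mask[idx] <- ok
    oki <- idx[ok]
    tau1[oki] <- f[1L, ok]; tau2[oki] <- f[2L, ok]
    a1[oki] <- f[3L, ok]; a2[oki] <- 1 - f[3L, ok]
    tm[oki] <- a1[oki] * tau1[oki] + a2[oki] * tau2[oki]
    chi2[oki] <- f[5L, ok]
    flagged[oki] <- f[5L, ok] > chi2Gate
  }
  if (excludeFlagged) {
    drop <- mask & flagged
    mask[drop] <- FALSE
    tau1[drop] <- NA_real_; tau2[drop] <- NA_real_
    a1[drop] <- NA_real_; a2[drop] <- NA_real_
    tm[drop] <- NA_real_; chi2[drop] <- NA_real_
  }
  methods::new("FitImage",
    tau1 = tau1, tau2 = tau2, a1 = a1, a2 = a2, tauMean = tm,
    chi2 = chi2, photons = photons, mask = mask, chi2Flagged = flagged,
    metadata = list(condition = image@condition,
                    imposedPO2 = image@imposedPO2,
                    timeWindow = image@timeWindow,
                    spatialBinning = k, minPhotons = minPhotons,
                    chi2Gate = chi2Gate))
}

#' Amplitude-fraction ("free"/"bound") map in percent
#'
#' Returns the short-component amplitude fraction a1\% (the "free" species
#' for NAD(P)H) or the long-component a2\% (the "bound" species) as a masked
#' percentage image.
#'
#' @param fit a [FitImage-class].
#' @param component \code{"short"} (a1\%) or \code{"long"} (a2\%).
#' @return numeric matrix in percent, \code{NA} outside the fit mask.
#' @export
boundFractionMap <- function(fit, component = c("short", "long")) {
  stopifnot(methods::is(fit, "FitImage"))
  component <- match.arg(component)
  out <- if (component == "short") fit@a1 else fit@a2
  out[!fit@mask] <- NA_real_
  100 * out
}
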