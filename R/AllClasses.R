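#' @import methods
NULL

#' TCSPC image stack
#'
#' A time-correlated single photon counting (TCSPC) acquisition: a
#' \code{row x col x channel} array of non-negative photon counts, together
#' with the acquisition time window and condition metadata. The channel width
#' is \code{timeWindow / nChannels} nanoseconds.
#'
#' @slot counts numeric 3-D array (row x col x time channel) of photon counts.
#' @slot timeWindow length of the TCSPC window in ns (12.5 ns at 80 MHz).
#' @slot condition character condition label (e.g. \code{"WT"}, \code{"rotenone"}).
#' @slot imposedPO2 media-imposed oxygen partial pressure in mmHg, or \code{NA}
#'   when the condition is not a calibration reference.
#'
#' @seealso [tcspcImage()], [generateDecayImage()], [fitImage()]
#' @export
setClass("TCSPCImage",
  slots = c(
    counts = "array",
    timeWindow = "numeric",
    condition = "character",
    imposedPO2 = "numeric"
  )
)

setValidity("TCSPCImage", function(object) {
  msg <- NULL
  d <- dim(object@counts)
  if (length(d) != 3L)
    msg <- c(msg, "'counts' must be a 3-D array (row x col x channel)")
  else if (d[3L] < 2L)
    msg <- c(msg, "need at least 2 time channels")
  if (any(object@counts < 0) || any(!is.finite(object@counts)))
    msg <- c(msg, "photon counts must be finite and non-negative")
  if (length(object@timeWindow) != 1L || !is.finite(object@timeWindow) ||
      object@timeWindow <= 0)
    msg <- c(msg, "'timeWindow' must be a single positive number (ns)")
  if (length(object@imposedPO2) != 1L ||
      (!is.na(object@imposedPO2) && object@imposedPO2 < 0))
    msg <- c(msg, "'imposedPO2' must be NA or a single non-negative mmHg value")
  if (is.null(msg)) TRUE else msg
})

#' Ground truth accompanying a synthetic TCSPC image
#'
#' The hidden state of a simulated scene: the mitochondrion label image,
#' the oxygen partial pressure drawn for each mitochondrion, and the
#' per-pixel decay parameters the photons were sampled from.
#'
#' @slot labelImage integer matrix of mitochondrion labels (0 = background).
#' @slot perMitoPO2 named numeric vector, mmHg per label.
#' @slot tauMean numeric matrix of true amplitude-weighted mean lifetimes (ns),
#'   \code{NA} on background pixels.
#' @slot tau1,tau2,a1,a2 numeric matrices of the true biexponential
#'   parameters per pixel (\code{NA} on background).
#'
#' @export
setClass("FlimGroundTruth",
  slots = c(
    labelImage = "matrix",
    perMitoPO2 = "numeric",
    tauMean = "matrix",
    tau1 = "matrix",
    tau2 = "matrix",
    a1 = "matrix",
    a2 = "matrix"
  )
)

setValidity("FlimGroundTruth", function(object) {
  msg <- NULL
  labs <- sort(unique(object@labelImage[object@labelImage > 0]))
  if (!all(as.character(labs) %in% names(object@perMitoPO2)))
    msg <- c(msg, "every nonzero label needs an entry in 'perMitoPO2'")
  ok <- !is.na(object@tauMean)
  aw <- (object@a1 * object@tau1 + object@a2 * object@tau2)
  if (any(abs(object@tauMean[ok] - aw[ok]) > 1e-9))
    msg <- c(msg, "'tauMean' must equal a1*tau1 + a2*tau2 on every labelled pixel")
  if (is.null(msg)) TRUE else msg
})

#' Per-pixel biexponential fit results
#'
#' Output of [fitImage()]: per-pixel short/long lifetimes, amplitude
#' fractions, amplitude-weighted mean lifetime, reduced chi-squared, photon
#' counts, and the validity mask. Invalid pixels (too few photons or a failed
#' optimisation) carry \code{NA} lifetimes.
#'
#' @slot tau1,tau2 numeric matrices, short and long lifetimes (ns), tau1 <= tau2.
#' @slot a1,a2 numeric matrices, amplitude fractions (a1 + a2 = 1).
#' @slot tauMean numeric matrix, amplitude-weighted mean lifetime (ns).
#' @slot chi2 numeric matrix, reduced chi-squared of the weighted fit.
#' @slot photons numeric matrix of per-pixel photon counts (after any pooling).
#' @slot mask logical matrix of valid pixels.
#' @slot chi2Flagged logical matrix; \code{TRUE} where the reduced chi-squared
#'   exceeds the quality gate (flagged but retained by default).
#' @slot metadata list carried over from the source [TCSPCImage-class]
#'   (condition, imposedPO2, timeWindow, binning, minPhotons).
#'
#' @seealso [fitImage()], [boundFractionMap()], [po2Map()]
#' @export
setClass("FitImage",
  slots = c(
    tau1 = "matrix", tau2 = "matrix",
    a1 = "matrix", a2 = "matrix",
    tauMean = "matrix", chi2 = "matrix",
    photons = "matrix", mask = "matrix",
    chi2Flagged = "matrix",
    metadata = "list"
  )
)

setValidity("FitImage", function(object) {
  msg <- NULL
  dm <- dim(object@mask)
  for (s in c("tau1", "tau2", "a1", "a2", "tauMean", "chi2", "photons"))
    if (!identical(dim(slot(object, s)), dm))
      msg <- c(msg, sprintf("slot '%s' must match the mask dimensions", s))
  m <- object@mask
  if (any(is.na(m))) msg <- c(msg, "mask must not contain NA")
  else if (any(m)) {
    if (any(is.na(object@tauMean[m])))
      msg <- c(msg, "valid pixels must carry lifetimes")
    if (any(abs(object@a1[m] + object@a2[m] - 1) > 1e-9))
      msg <- c(msg, "a1 + a2 must equal 1 on valid pixels")
    if (any(object@tau1[m] > object@tau2[m] + 1e-12))
      msg <- c(msg, "tau1 <= tau2 must hold on valid pixels")
    if (any(!is.na(m) & !m & !is.na(object@tauMean)))
      msg <- c(msg, "invalid pixels must not carry lifetime values")
  }
  if (is.null(msg)) TRUE else msg
})

#' Hyperbolic lifetime--oxygen calibration
#'
#' Parameters of the myoglobin-FRET calibration curve
#' \deqn{\tau(pO_2) = (\tau_{max} - \tau_{floor}) \frac{pO_2}{K + pO_2} + \tau_{floor}}
#' fitted to full-image averaged lifetimes from the rotenone reference
#' condition. \code{tauFloor} is the deoxygenated asymptote, fixed at
#' 0.914 ns by default.
#'
#' @slot K affinity parameter (mmHg).
#' @slot tauMax lifetime at saturating oxygen (ns).
#' @slot tauFloor deoxygenated asymptote (ns), fixed constant 0.914.
#' @slot rss residual sum of squares of the fit.
#' @slot nPoints number of calibration points used.
#' @slot converged logical; \code{FALSE} flags a non-convergent fit.
#'
#' @seealso [fitCalibration()], [predictLifetime()], [backcalculatePO2()]
#' @export
setClass("CalibrationFit",
  slots = c(
    K = "numeric", tauMax = "numeric", tauFloor = "numeric",
    rss = "numeric", nPoints = "integer", converged = "logical"
  )
)

setValidity("CalibrationFit", function(object) {
  msg <- NULL
  if (object@K <= 0) msg <- c(msg, "'K' must be positive (mmHg)")
  if (object@tauFloor <= 0) msg <- c(msg, "'tauFloor' must be positive (ns)")
  if (object@tauMax <= object@tauFloor)
    msg <- c(msg, "'tauMax' must exceed 'tauFloor'")
  if (is.null(msg)) TRUE else msg
})

#' Per-pixel oxygen partial pressure map
#'
#' @slot po2 numeric matrix of pO2 in mmHg (\code{NA} outside the valid mask).
#' @slot mask logical matrix of valid pixels.
#' @slot saturated logical matrix; pixels whose lifetime reached or exceeded
#'   the calibration \code{tauMax}, where the inverted hyperbola diverges.
#'   Saturated pixels are excluded from the valid mask.
#' @slot condition character condition label.
#'
#' @seealso [po2Map()], [subpopulationFractions()]
#' @export
setClass("OxygenMap",
  slots = c(
    po2 = "matrix", mask = "matrix",
    saturated = "matrix", condition = "character"
  )
)

setValidity("OxygenMap", function(object) {
  msg <- NULL
  if (!identical(dim(object@po2), dim(object@mask)) ||
      !identical(dim(object@po2), dim(object@saturated)))
    msg <- c(msg, "po2, mask and saturated must share dimensions")
  m <- object@mask
  if (any(m & object@saturated))
    msg <- c(msg, "saturated pixels must be excluded from the valid mask")
  if (any(m) && any(is.na(object@po2[m]) | object@po2[m] < 0))
    msg <- c(msg, "pO2 must be defined and >= 0 on valid pixels")
  if (is.null(msg)) TRUE else msg
})

#' Normalized lifetime distribution histogram
#'
#' @slot binEdges strictly increasing bin edges (ns).
#' @slot frequencies per-bin fractions summing to 1.
#' @slot condition character condition label.
#' @slot nPixels number of pixels aggregated.
#'
#' @seealso [lifetimeHistogram()]
#' @export
setClass("LifetimeHistogram",
  slots = c(
    binEdges = "numeric", frequencies = "numeric",
    condition = "character", nPixels = "integer"
  )
)

setValidity("LifetimeHistogram", function(object) {
  msg <- NULL
  if (length(object@binEdges) != length(object@frequencies) + 1L)
    msg <- c(msg, "need one more bin edge than frequency")
  if (any(diff(object@binEdges) <= 0))
    msg <- c(msg, "bin edges must be strictly increasing")
  if (abs(sum(object@frequencies) - 1) > 1e-9)
    msg <- c(msg, "frequencies must sum to 1")
  if (is.null(msg)) TRUE else msg
})

#' High-/low-OCR mitochondrial subpopulation fractions
#'
#' Fractions of valid pixels below, between and above two pO2 thresholds.
#' Low local pO2 marks high oxygen consumption (high OCR) and vice versa.
#'
#' @slot highOCR fraction of pixels with pO2 <= low threshold.
#' @slot lowOCR fraction of pixels with pO2 >= high threshold.
#' @slot mid remaining fraction.
#' @slot thresholds numeric length-2 (low, high) in mmHg.
#' @slot condition character label.
#'
#' @seealso [subpopulationFractions()]
#' @export
setClass("SubpopulationSummary",
  slots = c(
    highOCR = "numeric", lowOCR = "numeric", mid = "numeric",
    thresholds = "numeric", condition = "character"
  )
)

setValidity("SubpopulationSummary", function(object) {
  msg <- NULL
  if (abs(object@highOCR + object@lowOCR + object@mid - 1) > 1e-9)
    msg <- c(msg, "fractions must sum to 1")
  if (length(object@thresholds) != 2L ||
      object@thresholds[1L] >= object@thresholds[2L])
    msg <- c(msg, "'thresholds' must be (low, high) with low < high")
  if (is.null(msg)) TRUE else msg
})

#' FLIM-based redox ratio (FLIRR) map
#'
#' Per-pixel ratio of the bound-NAD(P)H amplitude fraction to the bound-FAD
#' amplitude fraction (a2,NAD(P)H % / a1,FAD %), a proxy for the balance of
#' oxidative phosphorylation over glycolysis.
#'
#' @slot flirr numeric matrix of ratios (\code{NA} outside the mask).
#' @slot mask logical matrix of valid pixels.
#'
#' @seealso [flirrMap()]
#' @export
setClass("RedoxMap", slots = c(flirr = "matrix", mask = "matrix"))

setValidity("RedoxMap", function(object) {
  msg <- NULL
  if (!identical(dim(object@flirr), dim(object@mask)))
    msg <- c(msg, "flirr and mask must share dimensions")
  m <- object@mask
  if (any(m) && any(is.na(object@flirr[m]) | object@flirr[m] < 0))
    msg <- c(msg, "FLIRR must be defined and >= 0 on valid pixels")
  if (is.null(msg)) TRUE else msg
})

#' A qPCR record: one (sample, target, role) with replicate Ct values
#'
#' @slot sample sample label.
#' @slot target amplicon label.
#' @slot role one of \code{"IP"}, \code{"input"}, \code{"RNaseH-IP"},
#'   \code{"mtDNA"}, \code{"nuclear"}.
#' @slot dilution fold dilution applied before qPCR (>= 1).
#' @slot ct numeric vector of replicate threshold cycles.
#' @slot inputFraction fraction of material kept as input (default 0.02).
#'
#' @seealso [ctRecord()], [meanCt()], [dripEnrichment()]
#' @export
setClass("CtRecord",
  slots = c(
    sample = "character", target = "character", role = "character",
    dilution = "numeric", ct = "numeric", inputFraction = "numeric"
  )
)

setValidity("CtRecord", function(object) {
  msg <- NULL
  if (length(object@ct) < 1L) msg <- c(msg, "need at least one Ct replicate")
  if (any(!is.finite(object@ct) | object@ct <= 0))
    msg <- c(msg, "Ct values must be finite and positive")
  if (object@dilution < 1) msg <- c(msg, "'dilution' must be >= 1")
  if (object@inputFraction <= 0 || object@inputFraction > 1)
    msg <- c(msg, "'inputFraction' must be in (0, 1]")
  if (is.null(msg)) TRUE else msg
})

#' DRIP-qPCR enrichment result
#'
#' @slot sample,target labels carried from the IP record.
#' @slot ipOverInput dilution-corrected IP/input ratio (2^dCt method).
#' @slot rnasehNormalized ratio further normalized to the RNaseH-treated
#'   control, or \code{NA} before [rnasehNormalize()] is applied.
#' @slot dilutionCorrected,inputFractionCorrected logical provenance flags.
#'
#' @export
setClass("EnrichmentResult",
  slots = c(
    sample = "character", target = "character",
    ipOverInput = "numeric", rnasehNormalized = "numeric",
    dilutionCorrected = "logical", inputFractionCorrected = "logical"
  )
)

setValidity("EnrichmentResult", function(object) {
  msg <- NULL
  if (object@ipOverInput < 0) msg <- c(msg, "'ipOverInput' must be >= 0")
  if (!is.na(object@rnasehNormalized) && object@rnasehNormalized < 0)
    msg <- c(msg, "'rnasehNormalized' must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' Binned coverage signal on a circular genome
#'
#' Per-bin RPKM (reads per kilobase per million mapped reads) over a circular
#' reference, as produced by [binnedRPKM()], optionally smoothed
#' ([smoothSignal()]) or expressed as a ratio to a reference track
#' ([normalizeTracks()]).
#'
#' @slot genomeLength circular genome length in bp.
#' @slot binSize bin width in bp.
#' @slot values per-bin signal; RPKM, or a dimensionless ratio after
#'   normalization.
#' @slot totalReads total mapped reads behind the track.
#' @slot smoothed logical; has a sliding-window smoother been applied.
#' @slot units \code{"RPKM"} or \code{"ratio"}.
#' @slot normMode \code{NA}, \code{"input"} or \code{"rnaseh"}.
#'
#' @export
setClass("BinnedSignal",
  slots = c(
    genomeLength = "numeric", binSize = "numeric", values = "numeric",
    totalReads = "numeric", smoothed = "logical",
    units = "character", normMode = "character"
  )
)

setValidity("BinnedSignal", function(object) {
  msg <- NULL
  nb <- ceiling(object@genomeLength / object@binSize)
  if (length(object@values) != nb)
    msg <- c(msg, "number of bins must equal ceiling(genomeLength / binSize)")
  if (any(!is.finite(object@values) | object@values < 0))
    msg <- c(msg, "bin values must be finite and >= 0")
  if (object@totalReads <= 0) msg <- c(msg, "'totalReads' must be positive")
  if (is.null(msg)) TRUE else msg
})
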