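#' Specify a synthetic FLIM scene
#'
#' Bundles and validates every parameter of the synthetic TCSPC forward model:
#' acquisition geometry (256 channels over a 12.5 ns window, matching an
#' 80 MHz pulsed laser), scene composition (non-overlapping disk
#' "mitochondria"), the two-component oxygen mixture describing high-OCR
#' (low-pO2) and low-OCR (high-pO2) organelle subpopulations, and the
#' hyperbolic lifetime--oxygen law with its fixed 0.914 ns deoxygenated
#' asymptote.
#'
#' The probe's amplitude-weighted mean lifetime is tied to oxygen through
#' \eqn{\tau(pO_2) = (\tau_{max} - \tau_{floor})\,pO_2/(K + pO_2) + \tau_{floor}};
#' the long decay component is then solved from
#' \eqn{\tau_{mean} = a_1\tau_1 + (1-a_1)\tau_2} with the short component
#' \eqn{\tau_1} and its amplitude fraction \eqn{a_1} held fixed, so that the
#' simulated lifetime--oxygen relation is exactly the law the calibration
#' module fits.
#'
#' @param imageHeight,imageWidth image size in pixels.
#' @param nChannels number of TCSPC time channels (default 256).
#' @param timeWindow TCSPC window in ns (default 12.5).
#' @param mitoCount number of mitochondria to place.
#' @param mitoRadiusRange length-2 numeric, min/max disk radius in pixels.
#' @param backgroundPhotonRate mean background photons per pixel (uniform
#'   over channels).
#' @param mitoPhotonBudget mean photons per mitochondrial pixel.
#' @param po2Mixture data.frame with columns \code{weight}, \code{mean},
#'   \code{sd} (mmHg): the per-mitochondrion oxygen mixture. Defaults to a
#'   wild-type-like 60\% high-OCR (10 +/- 3 mmHg) / 40\% low-OCR
#'   (60 +/- 10 mmHg) mixture.
#' @param truthK,truthTauMax ground-truth calibration parameters (mmHg, ns).
#' @param tauFloor deoxygenated asymptote in ns, fixed constant 0.914.
#' @param shortLifetime short decay component \eqn{\tau_1} in ns.
#' @param shortFraction amplitude fraction \eqn{a_1} of the short component,
#'   in \code{[0, 1)}.
#' @param seed integer RNG seed; generators are pure functions of
#'   (spec, seed).
#' @return a validated list of class \code{"SceneSpec"}.
#' @examples
#' spec <- sceneSpec(imageHeight = 32, imageWidth = 32, mitoCount = 4,
#'                   seed = 1)
#' sim <- generateDecayImage(spec)
#' sim$image
#' @export
sceneSpec <- function(imageHeight = 256L, imageWidth = 256L,
                      nChannels = 256L, timeWindow = 12.5,
                      mitoCount = 40L, mitoRadiusRange = c(2, 5),
                      backgroundPhotonRate = 10,
                      mitoPhotonBudget = 5000,
                      po2Mixture = data.frame(weight = c(0.6, 0.4),
                                              mean = c(10, 60),
                                              sd = c(3, 10)),
                      truthK = 15, truthTauMax = 2.5, tauFloor = 0.914,
                      shortLifetime = 0.45, shortFraction = 0.25,
                      seed = 1L) {
  spec <- list(
    imageHeight = as.integer(imageHeight), imageWidth = as.integer(imageWidth),
    nChannels = as.integer(nChannels), timeWindow = timeWindow,
    mitoCount = as.integer(mitoCount), mitoRadiusRange = mitoRadiusRange,
    backgroundPhotonRate = backgroundPhotonRate,
    mitoPhotonBudget = mitoPhotonBudget,
    po2Mixture = po2Mixture,
    truthK = truthK, truthTauMax = truthTauMax, tauFloor = tauFloor,
    shortLifetime = shortLifetime, shortFraction = shortFraction,
    seed = as.integer(seed))
  validateSceneSpec(spec)
  class(spec) <- "SceneSpec"
  spec
}

validateSceneSpec <- function(spec) {
  with(spec, {
    if (imageHeight < 1L || imageWidth < 1L)
      stop("image dimensions must be positive")
    if (nChannels < 2L) stop("'nChannels' must be >= 2")
    if (timeWindow <= 0) stop("'timeWindow' must be positive (ns)")
    if (mitoCount < 1L) stop("'mitoCount' must be >= 1")
    if (length(mitoRadiusRange) != 2L || any(mitoRadiusRange <= 0) ||
        mitoRadiusRange[1L] > mitoRadiusRange[2L])
      stop("'mitoRadiusRange' must be an increasing positive pair")
    if (!all(c("weight", "mean", "sd") %in% names(po2Mixture)))
      stop("'po2Mixture' needs columns weight, mean, sd")
    if (abs(sum(po2Mixture$weight) - 1) > 1e-9)
      stop("mixture weights must sum to 1")
    if (any(po2Mixture$mean < 0) || any(po2Mixture$sd < 0))
      stop("mixture pO2 means and sds must be >= 0")
    if (backgroundPhotonRate < 0 || mitoPhotonBudget <= 0)
      stop("photon rates must be non-negative (budget positive)")
    if (truthK <= 0) stop("'truthK' must be positive")
    if (tauFloor <= 0 || truthTauMax <= tauFloor)
      stop("'truthTauMax' must exceed 'tauFloor' > 0")
    if (shortLifetime <= 0 || shortLifetime >= truthTauMax)
      stop("'shortLifetime' must lie in (0, truthTauMax)")
    if (shortFraction < 0 || shortFraction >= 1)
      stop("'shortFraction' must lie in [0, 1)")
    if (shortFraction > 0 && shortLifetime > tauFloor)
      stop("'shortLifetime' must not exceed 'tauFloor' so that the long ",
           "component stays the longer one at every pO2")
    tau2Top <- (truthTauMax - shortFraction * shortLifetime) /
      (1 - shortFraction)
    if (tau2Top >= timeWindow)
      stop("implied long lifetime exceeds the TCSPC window; reduce ",
           "'shortFraction' or 'truthTauMax'")
  })
  invisible(TRUE)
}

#' @export
print.SceneSpec <- function(x, ...) {
  cat(sprintf(
    "SceneSpec: %d x %d px, %d channels / %.3g ns, %d mitochondria\n",
    x$imageHeight, x$imageWidth, x$nChannels, x$timeWindow, x$mitoCount))
  cat(sprintf("  photons/px: %g (background %g); K = %g mmHg, tauMax = %g ns\n",
              x$mitoPhotonBudget, x$backgroundPhotonRate, x$truthK,
              x$truthTauMax))
  invisible(x)
}

# place non-overlapping disks; explicit failure after bounded retries
placeMitochondria <- function(H, W, n, radiusRange, maxTries = 200L * n) {
  centers <- matrix(NA_real_, n, 2L)
  radii <- numeric(n)
  placed <- 0L
  tries <- 0L
  while (placed < n) {
    tries <- tries + 1L
    if (tries > maxTries)
      stop("could not place ", n, " non-overlapping mitochondria in a ",
           H, " x ", W, " image after ", maxTries, " attempts")
    r <- stats::runif(1L, radiusRange[1L], radiusRange[2L])
    if (2 * r + 2 > min(H, W)) next
    ci <- stats::runif(1L, r + 1, H - r)
    cj <- stats::runif(1L, r + 1, W - r)
    if (placed > 0L) {
      d <- sqrt((centers[seq_len(placed), 1L] - ci)^2 +
                (centers[seq_len(placed), 2L] - cj)^2)
      if (any(d < radii[seq_len(placed)] + r + 1)) next
    }
    placed <- placed + 1L
    centers[placed, ] <- c(ci, cj)
    radii[placed] <- r
  }
  list(centers = centers, radii = radii)
}

#' Simulate a TCSPC decay image with known ground truth
#'
#' Forward model of the oxygen-sensing FLIM experiment: disk mitochondria are
#' placed without overlap, each draws its oxygen partial pressure from the
#' scene's two-component mixture, oxygen sets the amplitude-weighted mean
#' lifetime through the hyperbolic calibration law, and every mitochondrial
#' pixel's channel histogram is sampled with Poisson photon noise from the
#' window-truncated biexponential decay (delta-function instrument response).
#' Background pixels receive Poisson photons spread uniformly over channels.
#'
#' Photon noise is sampled as independent Poisson counts per channel with
#' means proportional to the discretized decay, which is distributionally
#' identical to drawing a Poisson pixel total and distributing it
#' multinomially over channels.
#'
#' @param spec a [sceneSpec()].
#' @param condition condition label stored in the image metadata.
#' @param imposedPO2 media-imposed pO2 (mmHg) for reference conditions,
#'   or \code{NA}.
#' @return a list with elements \code{image} ([TCSPCImage-class]) and
#'   \code{truth} ([FlimGroundTruth-class]).
#' @seealso [generateCalibrationSeries()], [fitImage()]
#' @export
generateDecayImage <- function(spec, condition = "synthetic",
                               imposedPO2 = NA_real_) {
  validateSceneSpec(spec)
  withr::with_seed(spec$seed, {
    H <- spec$imageHeight; W <- spec$imageWidth; C <- spec$nChannels
    dt <- spec$timeWindow / C
    geom <- placeMitochondria(H, W, spec$mitoCount, spec$mitoRadiusRange)

    label <- matrix(0L, H, W)
    rowIdx <- matrix(seq_len(H), H, W)
    colIdx <- matrix(seq_len(W), H, W, byrow = TRUE)
    for (m in seq_len(spec$mitoCount)) {
      inside <- (rowIdx - geom$centers[m, 1L])^2 +
        (colIdx - geom$centers[m, 2L])^2 <= geom$radii[m]^2
      label[inside] <- m
    }

    mix <- spec$po2Mixture
    comp <- sample.int(nrow(mix), spec$mitoCount, replace = TRUE,
                       prob = mix$weight)
    po2 <- pmax(0, stats::rnorm(spec$mitoCount, mix$mean[comp],
                                mix$sd[comp]))
    names(po2) <- as.character(seq_len(spec$mitoCount))

    tauMeanMito <- hyperbola(po2, spec$truthK, spec$truthTauMax,
                             spec$tauFloor)
    a1 <- spec$shortFraction
    tau1 <- spec$shortLifetime
    tau2Mito <- if (a1 > 0) (tauMeanMito - a1 * tau1) / (1 - a1)
                else tauMeanMito

    # counts as (pixels x channels) matrix for fast assignment
    M <- matrix(0, H * W, C)
    bgIdx <- which(label == 0L)
    if (spec$backgroundPhotonRate > 0 && length(bgIdx) > 0) {
      M[bgIdx, ] <- stats::rpois(length(bgIdx) * C,
                                 spec$backgroundPhotonRate / C)
    }
    for (m in seq_len(spec$mitoCount)) {
      pix <- which(label == m)
      if (length(pix) == 0L) next
      p <- .decayChannelProbsCpp(C, dt, tau1, tau2Mito[m],
                                 if (a1 > 0) a1 else 0, 0)
      lam <- p * spec$mitoPhotonBudget
      M[pix, ] <- matrix(stats::rpois(length(pix) * C, rep(lam, length(pix))),
                         nrow = length(pix), byrow = TRUE)
    }

    img <- methods::new("TCSPCImage",
      counts = array(M, dim = c(H, W, C)),
      timeWindow = spec$timeWindow,
      condition = condition,
      imposedPO2 = as.numeric(imposedPO2))

    naBg <- function(v) {
      out <- matrix(NA_real_, H, W)
      out[label > 0L] <- v[label[label > 0L]]
      out
    }
    truth <- methods::new("FlimGroundTruth",
      labelImage = label,
      perMitoPO2 = po2,
      tauMean = naBg(tauMeanMito),
      tau1 = naBg(rep(if (a1 > 0) tau1 else tau2Mito,
                      length.out = spec$mitoCount)),
      tau2 = naBg(tau2Mito),
      a1 = naBg(rep(a1, spec$mitoCount)),
      a2 = naBg(rep(1 - a1, spec$mitoCount)))
    list(image = img, truth = truth)
  })
}

#' Simulate a rotenone calibration series
#'
#' One decay image per imposed oxygen level. In the rotenone reference
#' condition mitochondria consume no oxygen, so intracellular pO2 equals the
#' media-imposed pO2: every mitochondrion's oxygen is set to the imposed
#' level exactly (the mixture is replaced by a point mass).
#'
#' @param spec a [sceneSpec()]; its mixture is ignored.
#' @param imposedPO2Levels numeric vector of imposed pO2 levels (mmHg, >= 0).
#' @return a list with one element per level, each a list of
#'   \code{imposedPO2}, \code{image}, \code{truth}.
#' @export
generateCalibrationSeries <- function(spec, imposedPO2Levels) {
  validateSceneSpec(spec)
  if (length(imposedPO2Levels) == 0L)
    stop("'imposedPO2Levels' must contain at least one level")
  if (any(imposedPO2Levels < 0))
    stop("imposed pO2 levels must be >= 0")
  lapply(seq_along(imposedPO2Levels), function(i) {
    lvl <- imposedPO2Levels[i]
    speci <- spec
    speci$po2Mixture <- data.frame(weight = 1, mean = lvl, sd = 0)
    speci$seed <- childSeed(spec$seed, i)
    sim <- generateDecayImage(speci, condition = "rotenone",
                              imposedPO2 = lvl)
    list(imposedPO2 = lvl, image = sim$image, truth = sim$truth)
  })
}

#' Specify a synthetic qPCR experiment
#'
#' @param abundance data.frame with columns \code{sample}, \code{target},
#'   \code{role} and \code{abundance} (true template abundance in arbitrary
#'   units, > 0).
#' @param dilution named numeric vector of fold dilutions per role
#'   (default IP 10x, input 100x, RNaseH-IP 10x).
#' @param replicateSd Gaussian technical noise on Ct, in cycles.
#' @param efficiency amplification factor per cycle, in (1, 2].
#' @param interceptCt instrument intercept: the Ct of one abundance unit
#'   loaded undiluted.
#' @param nReplicates technical replicates per record (default triplicates).
#' @param seed integer RNG seed.
#' @return a validated list of class \code{"CtSpec"}.
#' @export
ctSpec <- function(abundance,
                   dilution = c(IP = 10, input = 100, `RNaseH-IP` = 10),
                   replicateSd = 0.1, efficiency = 2, interceptCt = 30,
                   nReplicates = 3L, seed = 1L) {
  if (!all(c("sample", "target", "role", "abundance") %in% names(abundance)))
    stop("'abundance' needs columns sample, target, role, abundance")
  if (any(abundance$abundance <= 0))
    stop("abundances must be positive")
  if (!all(abundance$role %in% names(dilution)))
    stop("every role needs a dilution entry")
  if (any(dilution < 1)) stop("dilutions must be >= 1")
  if (replicateSd < 0) stop("'replicateSd' must be >= 0")
  if (efficiency <= 1 || efficiency > 2)
    stop("'efficiency' must lie in (1, 2]")
  if (nReplicates < 1L) stop("'nReplicates' must be >= 1")
  structure(list(abundance = abundance, dilution = dilution,
                 replicateSd = replicateSd, efficiency = efficiency,
                 interceptCt = interceptCt,
                 nReplicates = as.integer(nReplicates),
                 seed = as.integer(seed)),
            class = "CtSpec")
}

#' Simulate a qPCR Ct table
#'
#' Each record's expected threshold cycle is
#' \code{interceptCt - log_efficiency(abundance / dilution)}: a more diluted
#' template crosses the threshold later. Gaussian technical noise of sd
#' \code{replicateSd} cycles is added independently per replicate.
#'
#' @param spec a [ctSpec()].
#' @return data.frame with columns \code{sample}, \code{target}, \code{role},
#'   \code{dilution} and one \code{ct<i>} column per replicate.
#' @export
generateCtTable <- function(spec) {
  stopifnot(inherits(spec, "CtSpec"))
  withr::with_seed(spec$seed, {
    ab <- spec$abundance
    dil <- spec$dilution[ab$role]
    base <- spec$interceptCt -
      log(ab$abundance / dil, base = spec$efficiency)
    reps <- matrix(stats::rnorm(nrow(ab) * spec$nReplicates, 0,
                                spec$replicateSd),
                   nrow = nrow(ab))
    ct <- base + reps
    colnames(ct) <- paste0("ct", seq_len(spec$nReplicates))
    cbind(data.frame(sample = ab$sample, target = ab$target, role = ab$role,
                     dilution = as.numeric(dil)),
          as.data.frame(ct))
  })
}

#' Simulate a read-interval table on a circular genome
#'
#' Read start positions are drawn from a background-uniform density with
#' rectangular enriched peaks (per-base rate multiplied by \code{fold} inside
#' \code{center +/- width/2}, circular wrap handled). Intervals that run past
#' the origin keep \code{end > genomeLength}; downstream binning wraps them.
#'
#' @param genomeLength circular reference length in bp (mouse mitochondrial
#'   genome: 16,299 bp).
#' @param nReads number of reads.
#' @param readLength read length in bp.
#' @param peaks \code{NULL} for uniform background, or a data.frame with
#'   columns \code{center}, \code{width} (bp) and \code{fold} (>= 1).
#' @param seed integer RNG seed.
#' @return data.frame with columns \code{start}, \code{end} (1-based,
#'   inclusive; \code{end} may exceed \code{genomeLength} for wrapped reads)
#'   and \code{strand}.
#' @export
generateReads <- function(genomeLength, nReads, readLength = 75L,
                          peaks = NULL, seed = 1L) {
  if (genomeLength <= readLength || readLength <= 0)
    stop("need genomeLength > readLength > 0")
  if (nReads < 1L) stop("'nReads' must be >= 1")
  w <- rep(1, genomeLength)
  if (!is.null(peaks) && nrow(peaks) > 0) {
    if (!all(c("center", "width", "fold") %in% names(peaks)))
      stop("'peaks' needs columns center, width, fold")
    if (any(peaks$fold < 1))
      stop("peak fold enrichment must be >= 1")
    for (i in seq_len(nrow(peaks))) {
      half <- peaks$width[i] / 2
      pos <- ((round(peaks$center[i] - half):round(peaks$center[i] + half) -
                 1L) %% genomeLength) + 1L
      w[pos] <- pmax(w[pos], peaks$fold[i])
    }
  }
  readLength <- as.integer(readLength)
  withr::with_seed(as.integer(seed), {
    start <- sample.int(genomeLength, nReads, replace = TRUE, prob = w)
    strand <- sample(c("+", "-"), nReads, replace = TRUE)
    data.frame(start = start, end = start + readLength - 1L,
               strand = strand)
  })
}
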