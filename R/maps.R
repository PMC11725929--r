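#' Lifetime distribution histogram
#'
#' Normalized histogram of the amplitude-weighted mean lifetime over valid
#' (optionally label-restricted) pixels, the per-condition readout behind
#' lifetime-distribution panels. Bin edges are aligned to multiples of
#' \code{binWidth} so that halving the bin width re-aggregates exactly to
#' the coarser histogram.
#'
#' @param fitImage a [FitImage-class].
#' @param binWidth bin width in ns (default 0.05).
#' @param restrictTo optional label matrix (e.g. from
#'   [FlimGroundTruth-class]); only pixels with label > 0 are counted.
#' @return a [LifetimeHistogram-class].
#' @export
lifetimeHistogram <- function(fitImage, binWidth = 0.05, restrictTo = NULL) {
  stopifnot(methods::is(fitImage, "FitImage"), binWidth > 0)
  sel <- fitImage@mask
  if (!is.null(restrictTo)) {
    stopifnot(identical(dim(restrictTo), dim(sel)))
    sel <- sel & restrictTo > 0
  }
  v <- fitImage@tauMean[sel]
  if (length(v) == 0L)
    stop("no valid pixels selected for the lifetime histogram")
  lo <- binWidth * floor(min(v) / binWidth)
  hi <- binWidth * (floor(max(v) / binWidth) + 1L)
  edges <- seq(lo, hi, by = binWidth)
  cnt <- tabulate(findInterval(v, edges), nbins = length(edges) - 1L)
  cond <- fitImage@metadata$condition
  methods::new("LifetimeHistogram",
    binEdges = edges, frequencies = cnt / sum(cnt),
    condition = if (is.null(cond)) "unknown" else cond,
    nPixels = length(v))
}

#' Reference-anchored subpopulation thresholds
#'
#' Pooled quantiles of the valid pO2 values across one or more reference
#' (e.g. wild-type) oxygen maps, usable as scale-free low/high thresholds
#' for [subpopulationFractions()].
#'
#' @param maps a single [OxygenMap-class] or a list of them.
#' @param probs two quantile probabilities (default 25th and 75th).
#' @return numeric length-2 (low, high) in mmHg.
#' @export
referenceThresholds <- function(maps, probs = c(0.25, 0.75)) {
  if (methods::is(maps, "OxygenMap")) maps <- list(maps)
  v <- unlist(lapply(maps, function(m) m@po2[m@mask]))
  if (length(v) == 0L) stop("reference maps contain no valid pixels")
  stats::quantile(v, probs = probs, names = FALSE)
}

#' High-/low-OCR subpopulation fractions
#'
#' Classifies valid pixels of an oxygen map by local pO2: pixels at or below
#' \code{lowThresh} mmHg are the high-OCR (oxygen-depleting) subpopulation,
#' pixels at or above \code{highThresh} the low-OCR subpopulation, the rest
#' intermediate. The three fractions sum to 1 and are invariant to pixel
#' order and to masked pixels.
#'
#' @param oxygenMap an [OxygenMap-class].
#' @param lowThresh,highThresh thresholds in mmHg, \code{lowThresh <
#'   highThresh}.
#' @return a [SubpopulationSummary-class].
#' @export
subpopulationFractions <- function(oxygenMap, lowThresh, highThresh) {
  stopifnot(methods::is(oxygenMap, "OxygenMap"))
  if (lowThresh >= highThresh)
    stop("'lowThresh' must be smaller than 'highThresh'")
  v <- oxygenMap@po2[oxygenMap@mask]
  if (length(v) == 0L) stop("the oxygen map has no valid pixels")
  high <- mean(v <= lowThresh)
  low <- mean(v >= highThresh)
  methods::new("SubpopulationSummary",
    highOCR = high, lowOCR = low, mid = 1 - high - low,
    thresholds = c(lowThresh, highThresh),
    condition = oxygenMap@condition)
}

#' FLIM-based redox ratio (FLIRR) map
#'
#' Per-pixel ratio of the bound-NAD(P)H amplitude percentage (a2\% of the
#' NAD(P)H fit) to the bound-FAD amplitude percentage (a1\% of the FAD fit).
#' The two fit images must be co-registered (identical dimensions); pixels
#' where the FAD a1\% is zero are masked rather than mapped to infinity.
#'
#' @param nadhFit,fadFit [FitImage-class] objects from the NAD(P)H and FAD
#'   channels.
#' @return a [RedoxMap-class].
#' @export
flirrMap <- function(nadhFit, fadFit) {
  stopifnot(methods::is(nadhFit, "FitImage"), methods::is(fadFit, "FitImage"))
  if (!identical(dim(nadhFit@mask), dim(fadFit@mask)))
    stop("NAD(P)H and FAD fit images must have identical dimensions")
  bound <- 100 * nadhFit@a2
  fadFree <- 100 * fadFit@a1
  mask <- nadhFit@mask & fadFit@mask & !is.na(fadFree) & fadFree > 0
  flirr <- matrix(NA_real_, nrow(bound), ncol(bound))
  flirr[mask] <- bound[mask] / fadFree[mask]
  methods::new("RedoxMap", flirr = flirr, mask = mask)
}

#' Mann-Whitney rank test between two groups
#'
#' Two-sample Wilcoxon rank-sum (Mann-Whitney U) test, the group comparison
#' used for lifetime values between independent conditions. The p-value is
#' exact (full enumeration) when the combined sample size is at most 12 and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity correction is used.
#'
#' @param groupA,groupB numeric vectors (each non-empty).
#' @param alternative \code{"two.sided"} (default), \code{"less"} or
#'   \code{"greater"}.
#' @return list with \code{U} (the U statistic for \code{groupA}),
#'   \code{p.value}, and \code{method} (\code{"exact"} or
#'   \code{"normal-approx"}).
#' @examples
#' mannWhitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mannWhitney <- function(groupA, groupB,
                        alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(groupA) == 0L || length(groupB) == 0L)
    stop("both groups must be non-empty")
  ties <- anyDuplicated(c(groupA, groupB)) > 0L
  exact <- (length(groupA) + length(groupB) <= 12L) && !ties
  wt <- stats::wilcox.test(groupA, groupB, alternative = alternative,
                           exact = exact, correct = TRUE)
  list(U = unname(wt$statistic), p.value = wt$p.value,
       method = if (exact) "exact" else "normal-approx")
}

#' Multiple unpaired (Welch) t tests
#'
#' Welch two-sample t test for each requested pair of condition labels, with
#' no multiplicity correction by default (Holm available behind
#' \code{adjust}).
#'
#' @param groups data.frame with columns \code{condition} and \code{value}.
#' @param pairs list of length-2 character vectors of condition labels; by
#'   default all pairwise combinations.
#' @param adjust multiplicity adjustment passed to [stats::p.adjust()]
#'   (default \code{"none"}).
#' @return data.frame with columns \code{groupA}, \code{groupB}, \code{t},
#'   \code{df}, \code{p}, \code{p.adj}.
#' @export
unpairedTTests <- function(groups, pairs = NULL, adjust = "none") {
  stopifnot(all(c("condition", "value") %in% names(groups)))
  labs <- unique(groups$condition)
  if (is.null(pairs)) {
    if (length(labs) < 2L) stop("need at least two conditions")
    cmb <- utils::combn(labs, 2L)
    pairs <- lapply(seq_len(ncol(cmb)), function(i) cmb[, i])
  }
  res <- lapply(pairs, function(pr) {
    if (!all(pr %in% labs))
      stop("unknown condition label: ",
           paste(setdiff(pr, labs), collapse = ", "))
    a <- groups$value[groups$condition == pr[1L]]
    b <- groups$value[groups$condition == pr[2L]]
    if (length(a) < 2L || length(b) < 2L)
      stop("each condition needs at least 2 values")
    tt <- stats::t.test(a, b, var.equal = FALSE)
    data.frame(groupA = pr[1L], groupB = pr[2L],
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  })
  out <- do.call(rbind, res)
  out$p.adj <- stats::p.adjust(out$p, method = adjust)
  out
}

#' Render a pseudocolor map to a PNG file
#'
#' Writes an 8-bit color image with warm colors (orange/red) at low pO2 or
#' short lifetime -- the high-OCR end -- grading to cool blues at high pO2 /
#' long lifetime; masked pixels are black. The color limits are returned so
#' that images rendered with shared limits are directly comparable (and
#' byte-identical when regenerated).
#'
#' @param map an [OxygenMap-class] (renders pO2) or [FitImage-class]
#'   (renders the mean lifetime).
#' @param file output PNG path.
#' @param limits optional numeric length-2 color limits; default the range
#'   of valid values.
#' @param nColors palette resolution (default 256).
#' @return invisibly, a list with \code{file}, \code{limits} and
#'   \code{palette}.
#' @export
renderPseudocolor <- function(map, file, limits = NULL, nColors = 256L) {
  if (methods::is(map, "OxygenMap")) {
    vals <- map@po2; mask <- map@mask
  } else if (methods::is(map, "FitImage")) {
    vals <- map@tauMean; mask <- map@mask
  } else stop("'map' must be an OxygenMap or FitImage")
  if (!any(mask)) stop("cannot render a map with an empty mask")
  if (is.null(limits)) limits <- range(vals[mask])
  if (limits[2L] <= limits[1L]) limits[2L] <- limits[1L] + 1e-9
  pal <- grDevices::colorRampPalette(
    c("#7f0000", "#d7301f", "#fc8d59", "#fdcc8a", "#ffffcc",
      "#a8ddb5", "#7bccc4", "#43a2ca", "#0868ac", "#084081"))(nColors)
  sc <- (vals - limits[1L]) / (limits[2L] - limits[1L])
  sc[sc < 0] <- 0; sc[sc > 1] <- 1
  idx <- 1L + as.integer(round(sc * (nColors - 1L)))
  rgb <- grDevices::col2rgb(pal) / 255
  img <- array(0, dim = c(nrow(vals), ncol(vals), 3L))
  for (ch in 1:3) {
    plane <- matrix(0, nrow(vals), ncol(vals))
    plane[mask] <- rgb[ch, idx[mask]]
    img[, , ch] <- plane
  }
  png::writePNG(img, target = file)
  invisible(list(file = file, limits = limits, palette = pal))
}
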