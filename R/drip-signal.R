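#' Binned RPKM coverage on a circular genome
#'
#' Assigns each read to the bin containing its 5'-most genomic coordinate
#' (read start on the plus strand, read end on the minus strand), with
#' circular wrap-around, and converts bin counts to RPKM:
#' \deqn{RPKM = \frac{count}{(binSize/1000)\,(totalReads/10^6)}.}
#'
#' @param reads data.frame with columns \code{start}, \code{end} (1-based,
#'   inclusive; coordinates beyond \code{genomeLength} wrap) and
#'   \code{strand}.
#' @param genomeLength circular genome length in bp.
#' @param binSize bin width in bp (default 20).
#' @return a [BinnedSignal-class].
#' @examples
#' reads <- data.frame(start = rep(5, 10), end = rep(79, 10), strand = "+")
#' sig <- binnedRPKM(reads, genomeLength = 16299, binSize = 20)
#' # with 10^6 total reads, 10 reads in one 20 bp bin give 500 RPKM
#' @export
binnedRPKM <- function(reads, genomeLength, binSize = 20L) {
  if (!all(c("start", "end", "strand") %in% names(reads)))
    stop("'reads' needs columns start, end, strand")
  if (binSize < 1) stop("'binSize' must be >= 1")
  total <- nrow(reads)
  if (total == 0L) stop("cannot compute RPKM from zero reads")
  fivePrime <- ifelse(reads$strand == "-", reads$end, reads$start)
  pos <- ((fivePrime - 1L) %% genomeLength) + 1L
  nbins <- ceiling(genomeLength / binSize)
  bin <- (pos - 1L) %/% binSize + 1L
  cnt <- tabulate(bin, nbins = nbins)
  rpkm <- cnt / ((binSize / 1000) * (total / 1e6))
  methods::new("BinnedSignal",
    genomeLength = as.numeric(genomeLength), binSize = as.numeric(binSize),
    values = rpkm, totalReads = as.numeric(total),
    smoothed = FALSE, units = "RPKM", normMode = NA_character_)
}

#' Sliding-window smoothing of a binned circular signal
#'
#' Circular boxcar mean over the window covering
#' \code{ceiling(smoothLength / binSize)} bins, rounded up to an odd count
#' so the window is centered. On the circular genome the track mean is
#' preserved exactly.
#'
#' @param signal a [BinnedSignal-class].
#' @param smoothLength window length in bp (default 45, i.e. 3 bins of
#'   20 bp); must be at least one bin.
#' @return the smoothed [BinnedSignal-class].
#' @export
smoothSignal <- function(signal, smoothLength = 45) {
  stopifnot(methods::is(signal, "BinnedSignal"))
  if (smoothLength < signal@binSize)
    stop("'smoothLength' must be at least one bin")
  w <- ceiling(smoothLength / signal@binSize)
  if (w %% 2 == 0) w <- w + 1
  if (w > length(signal@values))
    stop("smoothing window exceeds the genome")
  sm <- as.numeric(stats::filter(signal@values, rep(1 / w, w),
                                 circular = TRUE))
  sm[sm < 0] <- 0  # guard tiny negative rounding
  signal@values <- sm
  signal@smoothed <- TRUE
  signal
}

#' Normalize an IP track against a reference track
#'
#' Per-bin ratio of the IP signal to a reference track (the input sample, or
#' the RNaseH-treated control), with a pseudocount added to the reference to
#' stabilise empty bins.
#'
#' @param ip [BinnedSignal-class] for the IP sample.
#' @param reference [BinnedSignal-class] with identical binning.
#' @param mode \code{"input"} or \code{"rnaseh"}; recorded in the result.
#' @param pseudocount added to the reference per bin (default 0.1 RPKM).
#' @return a ratio-valued [BinnedSignal-class].
#' @export
normalizeTracks <- function(ip, reference, mode = c("input", "rnaseh"),
                            pseudocount = 0.1) {
  stopifnot(methods::is(ip, "BinnedSignal"),
            methods::is(reference, "BinnedSignal"))
  mode <- match.arg(mode)
  if (ip@genomeLength != reference@genomeLength ||
      ip@binSize != reference@binSize ||
      length(ip@values) != length(reference@values))
    stop("'ip' and 'reference' must share genome length and binning")
  ip@values <- ip@values / (reference@values + pseudocount)
  ip@units <- "ratio"
  ip@normMode <- mode
  ip
}
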