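#' Construct a qPCR Ct record
#'
#' @param sample sample label.
#' @param target amplicon label.
#' @param role one of \code{"IP"}, \code{"input"}, \code{"RNaseH-IP"},
#'   \code{"mtDNA"}, \code{"nuclear"}.
#' @param ct numeric vector of replicate threshold cycles (typically
#'   triplicates).
#' @param dilution fold dilution applied before qPCR (IP samples 10x, input
#'   samples 100x in the reference protocol).
#' @param inputFraction fraction of sonicated material kept as input
#'   (default 0.02).
#' @return a [CtRecord-class].
#' @export
ctRecord <- function(sample, target, role, ct, dilution = 1,
                     inputFraction = 0.02) {
  methods::new("CtRecord", sample = sample, target = target, role = role,
               dilution = dilution, ct = as.numeric(ct),
               inputFraction = inputFraction)
}

#' Mean threshold cycle with replicate-outlier flagging
#'
#' Arithmetic mean of the replicate Ct values. Replicates deviating more
#' than \code{flagCycles} (default 1.0) cycles from the replicate median are
#' flagged -- attached as the \code{"flagged"} attribute -- but not dropped.
#'
#' @param record a [CtRecord-class].
#' @param flagCycles flagging threshold in cycles.
#' @return the mean Ct, with attribute \code{flagged} (logical per
#'   replicate).
#' @examples
#' meanCt(ctRecord("s", "t", "IP", c(24.0, 24.2, 24.1)))  # 24.1
#' @export
meanCt <- function(record, flagCycles = 1.0) {
  stopifnot(methods::is(record, "CtRecord"))
  methods::validObject(record)
  flagged <- abs(record@ct - stats::median(record@ct)) > flagCycles
  structure(mean(record@ct), flagged = flagged)
}

#' DRIP-qPCR enrichment by the 2^dCt method with dilution correction
#'
#' The undiluted template quantity behind a record is proportional to
#' \code{dilution * 2^(-Ct)} (a sample diluted d-fold crosses the threshold
#' log2(d) cycles later). Enrichment is the IP/input ratio of these
#' quantities:
#' \deqn{\frac{d_{IP}\,2^{-Ct_{IP}}}{d_{input}\,2^{-Ct_{input}}}.}
#' When \code{correctInputFraction} is \code{TRUE}, the input quantity is
#' additionally scaled up by \code{1/inputFraction} (the input aliquot
#' represents only e.g. 2\% of the material), shrinking the ratio by that
#' factor; the correction is off by default.
#'
#' @param ip [CtRecord-class] with role \code{"IP"} (or \code{"RNaseH-IP"}).
#' @param input [CtRecord-class] with role \code{"input"}, same target.
#' @param correctInputFraction apply the input-fraction correction
#'   (default \code{FALSE}).
#' @return an [EnrichmentResult-class].
#' @examples
#' ip <- ctRecord("WT", "nd1", "IP", c(28, 28, 28), dilution = 10)
#' inp <- ctRecord("WT", "nd1", "input", c(24, 24, 24), dilution = 100)
#' dripEnrichment(ip, inp)  # (10 * 2^-28) / (100 * 2^-24) = 0.00625
#' @export
dripEnrichment <- function(ip, input, correctInputFraction = FALSE) {
  stopifnot(methods::is(ip, "CtRecord"), methods::is(input, "CtRecord"))
  if (!ip@role %in% c("IP", "RNaseH-IP"))
    stop("'ip' must have role IP or RNaseH-IP, got '", ip@role, "'")
  if (input@role != "input")
    stop("'input' must have role input, got '", input@role, "'")
  if (ip@target != input@target)
    stop("target mismatch: '", ip@target, "' vs '", input@target, "'")
  ipQ <- ip@dilution * 2^(-as.numeric(meanCt(ip)))
  inQ <- input@dilution * 2^(-as.numeric(meanCt(input)))
  if (correctInputFraction) inQ <- inQ / input@inputFraction
  methods::new("EnrichmentResult",
    sample = ip@sample, target = ip@target,
    ipOverInput = ipQ / inQ, rnasehNormalized = NA_real_,
    dilutionCorrected = TRUE,
    inputFractionCorrected = correctInputFraction)
}

#' Normalize enrichment to the RNaseH-treated control
#'
#' Divides an IP/input enrichment by the IP/input enrichment of the
#' RNaseH1-treated (hybrid-depleted) control, yielding the hybrid-specific
#' enrichment.
#'
#' @param enr [EnrichmentResult-class] of the untreated sample.
#' @param enrRnaseh [EnrichmentResult-class] of the RNaseH-treated control,
#'   same target.
#' @return \code{enr} with the \code{rnasehNormalized} slot filled.
#' @export
rnasehNormalize <- function(enr, enrRnaseh) {
  stopifnot(methods::is(enr, "EnrichmentResult"),
            methods::is(enrRnaseh, "EnrichmentResult"))
  if (enr@target != enrRnaseh@target)
    stop("target mismatch: '", enr@target, "' vs '", enrRnaseh@target, "'")
  if (enrRnaseh@ipOverInput <= 0)
    stop("RNaseH control enrichment must be positive")
  enr@rnasehNormalized <- enr@ipOverInput / enrRnaseh@ipOverInput
  methods::validObject(enr)
  enr
}

#' Mitochondrial DNA copy number from paired qPCR
#'
#' Relative mtDNA copy number as the ratio of the mitochondrial amplicon
#' (nd4) to the single-copy nuclear control (mTert):
#' \code{efficiency^(Ct_nuclear - Ct_mito)}, i.e. 2^dCt under perfect
#' doubling.
#'
#' @param ctNd4 [CtRecord-class] for the mitochondrial amplicon.
#' @param ctMtert [CtRecord-class] for the nuclear control.
#' @param efficiency amplification factor per cycle, in (1, 2] (default 2).
#' @return the copy-number ratio.
#' @examples
#' nd4 <- ctRecord("L1", "nd4", "mtDNA", c(15, 15, 15))
#' tert <- ctRecord("L1", "mTert", "nuclear", c(22, 22, 22))
#' mtdnaCopyNumber(nd4, tert)  # 2^7 = 128
#' @export
mtdnaCopyNumber <- function(ctNd4, ctMtert, efficiency = 2) {
  stopifnot(methods::is(ctNd4, "CtRecord"), methods::is(ctMtert, "CtRecord"))
  if (efficiency <= 1 || efficiency > 2)
    stop("'efficiency' must lie in (1, 2]")
  efficiency^(as.numeric(meanCt(ctMtert)) - as.numeric(meanCt(ctNd4)))
}
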