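#' @name flimox-accessors
#' @title Accessors for flimox S4 classes
#'
#' @description Small accessor generics used across the package instead of
#' direct slot access.
#'
#' @param object a flimox S4 object.
#' @param x a flimox S4 object.
#' @return The slot content documented per method.
NULL

#' @rdname flimox-accessors
#' @export
setGeneric("counts", function(object) standardGeneric("counts"))

#' @rdname flimox-accessors
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))

#' @rdname flimox-accessors
#' @export
setGeneric("channelWidth", function(object) standardGeneric("channelWidth"))

#' @rdname flimox-accessors
#' @export
setGeneric("timeWindow", function(object) standardGeneric("timeWindow"))

#' @rdname flimox-accessors
#' @export
setGeneric("condition", function(object) standardGeneric("condition"))

#' @rdname flimox-accessors
#' @export
setGeneric("imposedPO2", function(object) standardGeneric("imposedPO2"))

#' @rdname flimox-accessors
#' @export
setGeneric("tauMean", function(object) standardGeneric("tauMean"))

#' @rdname flimox-accessors
#' @export
setGeneric("fitMask", function(object) standardGeneric("fitMask"))

#' @rdname flimox-accessors
#' @export
setGeneric("po2Values", function(object) standardGeneric("po2Values"))

#' @rdname flimox-accessors
#' @export
setGeneric("labelImage", function(object) standardGeneric("labelImage"))

#' @rdname flimox-accessors
#' @export
setGeneric("perMitoPO2", function(object) standardGeneric("perMitoPO2"))

#' @rdname flimox-accessors
#' @export
setMethod("counts", "TCSPCImage", function(object) object@counts)

#' @rdname flimox-accessors
#' @export
setMethod("nChannels", "TCSPCImage", function(object) dim(object@counts)[3L])

#' @rdname flimox-accessors
#' @export
setMethod("channelWidth", "TCSPCImage",
  function(object) object@timeWindow / dim(object@counts)[3L])

#' @rdname flimox-accessors
#' @export
setMethod("timeWindow", "TCSPCImage", function(object) object@timeWindow)

#' @rdname flimox-accessors
#' @export
setMethod("condition", "TCSPCImage", function(object) object@condition)

#' @rdname flimox-accessors
#' @export
setMethod("imposedPO2", "TCSPCImage", function(object) object@imposedPO2)

#' @rdname flimox-accessors
#' @export
setMethod("dim", "TCSPCImage", function(x) dim(x@counts))

#' @rdname flimox-accessors
#' @export
setMethod("tauMean", "FitImage", function(object) object@tauMean)

#' @rdname flimox-accessors
#' @export
setMethod("tauMean", "FlimGroundTruth", function(object) object@tauMean)

#' @rdname flimox-accessors
#' @export
setMethod("fitMask", "FitImage", function(object) object@mask)

#' @rdname flimox-accessors
#' @export
setMethod("fitMask", "OxygenMap", function(object) object@mask)

#' @rdname flimox-accessors
#' @export
setMethod("fitMask", "RedoxMap", function(object) object@mask)

#' @rdname flimox-accessors
#' @export
setMethod("po2Values", "OxygenMap", function(object) object@po2)

#' @rdname flimox-accessors
#' @export
setMethod("labelImage", "FlimGroundTruth", function(object) object@labelImage)

#' @rdname flimox-accessors
#' @export
setMethod("perMitoPO2", "FlimGroundTruth", function(object) object@perMitoPO2)

setMethod("show", "TCSPCImage", function(object) {
  d <- dim(object@counts)
  cat(sprintf("TCSPCImage: %d x %d pixels, %d channels over %.3g ns\n",
              d[1L], d[2L], d[3L], object@timeWindow))
  cat(sprintf("  condition: %s; imposed pO2: %s mmHg; total photons: %.4g\n",
              object@condition,
              ifelse(is.na(object@imposedPO2), "-",
                     format(object@imposedPO2)),
              sum(object@counts)))
})

setMethod("show", "FitImage", function(object) {
  d <- dim(object@mask)
  nv <- sum(object@mask)
  cat(sprintf("FitImage: %d x %d pixels, %d valid (%.1f%%)\n",
              d[1L], d[2L], nv, 100 * nv / prod(d)))
  if (nv > 0)
    cat(sprintf("  tau_mean on valid pixels: median %.3f ns [%.3f, %.3f]\n",
                stats::median(object@tauMean[object@mask]),
                min(object@tauMean[object@mask]),
                max(object@tauMean[object@mask])))
})

setMethod("show", "CalibrationFit", function(object) {
  cat(sprintf(
    "CalibrationFit: K = %.4g mmHg, tauMax = %.4g ns (floor %.3f ns)\n",
    object@K, object@tauMax, object@tauFloor))
  cat(sprintf("  %d points, rss = %.4g%s\n", object@nPoints, object@rss,
              if (object@converged) "" else " [non-convergent]"))
})

setMethod("show", "OxygenMap", function(object) {
  nv <- sum(object@mask)
  cat(sprintf("OxygenMap (%s): %d valid pixels, %d saturated\n",
              object@condition, nv, sum(object@saturated)))
  if (nv > 0)
    cat(sprintf("  pO2 median %.2f mmHg [%.2f, %.2f]\n",
                stats::median(object@po2[object@mask]),
                min(object@po2[object@mask]), max(object@po2[object@mask])))
})

setMethod("show", "SubpopulationSummary", function(object) {
  cat(sprintf(
    "SubpopulationSummary (%s): high-OCR %.3f, mid %.3f, low-OCR %.3f\n",
    object@condition, object@highOCR, object@mid, object@lowOCR))
  cat(sprintf("  thresholds: <= %.3g / >= %.3g mmHg\n",
              object@thresholds[1L], object@thresholds[2L]))
})

setMethod("show", "CtRecord", function(object) {
  cat(sprintf("CtRecord %s/%s [%s], dilution %gx: Ct = %s\n",
              object@sample, object@target, object@role, object@dilution,
              paste(format(object@ct, digits = 4), collapse = ", ")))
})

setMethod("show", "EnrichmentResult", function(object) {
  cat(sprintf("EnrichmentResult %s/%s: IP/input = %.4g%s\n",
              object@sample, object@target, object@ipOverInput,
              if (is.na(object@rnasehNormalized)) "" else
                sprintf(", RNaseH-normalized = %.4g",
                        object@rnasehNormalized)))
})

setMethod("show", "BinnedSignal", function(object) {
  cat(sprintf(
    "BinnedSignal: %d bins of %g bp on a %g bp circular genome (%s%s)\n",
    length(object@values), object@binSize, object@genomeLength,
    object@units, if (object@smoothed) ", smoothed" else ""))
})
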