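#' Construct a calibration object from known parameters
#'
#' Convenience constructor for a [CalibrationFit-class], e.g. to evaluate the
#' calibration model at ground-truth parameters.
#'
#' @param K affinity parameter in mmHg (> 0).
#' @param tauMax saturating lifetime in ns (> \code{tauFloor}).
#' @param tauFloor deoxygenated asymptote in ns (default 0.914).
#' @return a [CalibrationFit-class].
#' @export
calibrationFit <- function(K, tauMax, tauFloor = 0.914) {
  methods::new("CalibrationFit", K = K, tauMax = tauMax, tauFloor = tauFloor,
               rss = 0, nPoints = 0L, converged = TRUE)
}

#' Predict probe lifetime from oxygen partial pressure
#'
#' Evaluates the hyperbolic myoglobin-FRET calibration curve
#' \deqn{\tau(pO_2) = (\tau_{max} - \tau_{floor})\frac{pO_2}{K + pO_2} + \tau_{floor},}
#' strictly increasing in pO2 and bounded in
#' \eqn{[\tau_{floor}, \tau_{max})}. At zero oxygen it returns the
#' deoxygenated asymptote (0.914 ns with the default floor).
#'
#' @param calib a [CalibrationFit-class].
#' @param po2 oxygen partial pressure in mmHg (vectorized, >= 0).
#' @return predicted lifetime(s) in ns.
#' @seealso [backcalculatePO2()] for the exact inverse.
#' @export
predictLifetime <- function(calib, po2) {
  stopifnot(methods::is(calib, "CalibrationFit"))
  methods::validObject(calib)
  if (any(!is.finite(po2) | po2 < 0))
    stop("'po2' must be finite and >= 0 (mmHg)")
  hyperbola(po2, calib@K, calib@tauMax, calib@tauFloor)
}

#' Fit the lifetime--oxygen calibration curve
#'
#' Least-squares fit of the hyperbola to (imposed pO2, full-image averaged
#' lifetime) pairs from the rotenone reference condition, estimating the
#' affinity parameter K and the saturating lifetime tau_max with the
#' deoxygenated asymptote held fixed (0.914 ns by default). Initialisation:
#' tau_max from the largest observed lifetime, K from the pO2 level whose
#' lifetime is nearest the midpoint of the response.
#'
#' @param points data.frame with columns \code{imposedPO2} (mmHg) and
#'   \code{tau} (ns); at least 3 rows spanning at least 2 distinct pO2
#'   levels. Extra columns (\code{nPixels}, \code{condition}) are ignored.
#' @param tauFloor deoxygenated asymptote in ns; default the printed
#'   constant 0.914.
#' @return a [CalibrationFit-class]. A fit driven to the K > 0 boundary is
#'   flagged non-convergent rather than returned silently.
#' @examples
#' truth <- calibrationFit(K = 15, tauMax = 2.5)
#' pts <- data.frame(imposedPO2 = c(0, 5, 10, 20, 40, 80, 120, 160))
#' pts$tau <- predictLifetime(truth, pts$imposedPO2)
#' fitCalibration(pts)
#' @export
fitCalibration <- function(points, tauFloor = 0.914) {
  if (!all(c("imposedPO2", "tau") %in% names(points)))
    stop("'points' needs columns imposedPO2 and tau")
  if (nrow(points) < 3L)
    stop("need at least 3 calibration points")
  if (length(unique(points$imposedPO2)) < 2L)
    stop("calibration points must span at least 2 distinct pO2 levels")
  if (any(points$imposedPO2 < 0)) stop("imposed pO2 must be >= 0")
  if (any(points$tau <= 0)) stop("lifetimes must be positive")

  tauMax0 <- max(points$tau)
  if (tauMax0 <= tauFloor) tauMax0 <- tauFloor + 0.1
  mid <- (tauFloor + tauMax0) / 2
  K0 <- points$imposedPO2[which.min(abs(points$tau - mid))]
  if (K0 <= 0) K0 <- stats::median(points$imposedPO2[points$imposedPO2 > 0])

  df <- data.frame(p = points$imposedPO2, tau = points$tau)
  fit <- minpack.lm::nlsLM(
    tau ~ (tauMax - tauFloor) * (p / (K + p)) + tauFloor,
    data = df,
    start = list(tauMax = tauMax0, K = K0),
    lower = c(tauMax = tauFloor + 1e-9, K = 1e-9),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- stats::coef(fit)
  converged <- isTRUE(fit$convInfo$isConv) && est[["K"]] > 1e-6 &&
    est[["tauMax"]] > tauFloor + 1e-9
  methods::new("CalibrationFit",
    K = unname(est[["K"]]), tauMax = unname(est[["tauMax"]]),
    tauFloor = tauFloor,
    rss = sum(stats::resid(fit)^2), nPoints = nrow(points),
    converged = converged)
}

#' Invert the calibration curve: lifetime to oxygen partial pressure
#'
#' Rearranges the hyperbola to
#' \eqn{pO_2 = K (\tau - \tau_{floor}) / (\tau_{max} - \tau)}, the exact
#' inverse of [predictLifetime()] on \eqn{(\tau_{floor}, \tau_{max})}.
#' Lifetimes at or below the floor map to 0 mmHg; lifetimes at or above
#' tau_max are saturated (the rearranged formula diverges) and return
#' \code{NA} rather than an arbitrary large value.
#'
#' @param calib a [CalibrationFit-class].
#' @param tau lifetime(s) in ns (vectorized).
#' @return pO2 in mmHg; \code{NA} where saturated.
#' @export
backcalculatePO2 <- function(calib, tau) {
  stopifnot(methods::is(calib, "CalibrationFit"))
  methods::validObject(calib)
  out <- calib@K * (tau - calib@tauFloor) / (calib@tauMax - tau)
  out[tau <= calib@tauFloor] <- 0
  out[tau >= calib@tauMax] <- NA_real_
  out
}

#' Per-pixel oxygen map from a fitted image
#'
#' Applies [backcalculatePO2()] to the amplitude-weighted mean lifetime of
#' every valid pixel, fixing K and tau_max to the rotenone calibration.
#' Saturated pixels (lifetime >= tau_max) are recorded separately and
#' excluded from the valid mask.
#'
#' @param fitImage a [FitImage-class].
#' @param calib a [CalibrationFit-class].
#' @return an [OxygenMap-class].
#' @export
po2Map <- function(fitImage, calib) {
  stopifnot(methods::is(fitImage, "FitImage"),
            methods::is(calib, "CalibrationFit"))
  methods::validObject(calib)
  if (!any(fitImage@mask))
    stop("the fit image has no valid pixels to map")
  tau <- fitImage@tauMean
  saturated <- fitImage@mask & !is.na(tau) & tau >= calib@tauMax
  valid <- fitImage@mask & !saturated
  po2 <- matrix(NA_real_, nrow(tau), ncol(tau))
  po2[valid] <- backcalculatePO2(calib, tau[valid])
  cond <- fitImage@metadata$condition
  methods::new("OxygenMap",
    po2 = po2, mask = valid, saturated = saturated,
    condition = if (is.null(cond)) "unknown" else cond)
}
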