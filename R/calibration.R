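#' @include AllClasses.R AllGenerics.R registry.R
NULL

#' Fit an ordinary least-squares calibration line
#'
#' Fits \code{signal = slope * level + intercept} and records the tested
#' concentration span as the valid range.
#'
#' @param levels concentration levels (>= 3 distinct values).
#' @param signals measured signals, same length.
#' @param method,analyte,channel,unit metadata for the resulting curve.
#' @return A \linkS4class{CalibrationCurve} with \code{source = "fitted"}.
#' @examples
#' fitLinearCalibration(c(1, 2, 3), c(3, 5, 7), analyte = "heme")
#' @export
fitLinearCalibration <- function(levels, signals, method = "fitted",
                                 analyte = c("heme", "hemoglobin"),
                                 channel = "signal", unit = "uM") {
  analyte <- match.arg(analyte)
  if (length(levels) != length(signals))
    stop("levels and signals must have equal length")
  if (length(unique(levels)) < 3L)
    stop("at least 3 distinct calibration levels are required")
  if (stats::var(levels) == 0) stop("zero variance in levels")
  fit <- stats::lm.fit(cbind(1, levels), signals)
  slope <- unname(fit$coefficients[2])
  intercept <- unname(fit$coefficients[1])
  if (!is.finite(slope) || isTRUE(all.equal(slope, 0)))
    stop("degenerate calibration: fitted slope is zero")
  CalibrationCurve(method = method, analyte = analyte, channel = channel,
                   slope = slope, intercept = intercept,
                   validRange = range(levels), unit = unit)
}

# shared range-flagging: assay-side value vs the curve's valid range
.rangeFlags <- function(assaySide, validRange) {
  fl <- character()
  if (assaySide < validRange[1]) fl <- c(fl, "below_range")
  if (assaySide > validRange[2]) fl <- c(fl, "above_range")
  if (assaySide < 0) fl <- c(fl, "negative_estimate")
  fl
}

#' Invert a calibration curve
#'
#' Back-calculates the original-sample concentration
#' \code{c = DF * (signal - intercept) / slope}. Estimates outside the
#' curve's assay-side valid range are flagged (\code{below_range} /
#' \code{above_range}), never clamped; negative estimates are flagged
#' \code{negative_estimate} and reported as-is.
#'
#' @param curve a \linkS4class{CalibrationCurve}.
#' @param signal measured signal value.
#' @param dilutionFactor DF >= 1.
#' @return A \linkS4class{QuantResult}.
#' @examples
#' curve <- registryEntry(methodRegistry(), "direct_heme_a380")
#' concentration(applyCalibration(curve, 0.99))  # 40 uM
#' @export
applyCalibration <- function(curve, signal, dilutionFactor = 1) {
  stopifnot(is(curve, "CalibrationCurve"))
  if (dilutionFactor < 1) stop("dilutionFactor must be >= 1")
  if (curve@slope == 0) stop("calibration slope is zero")
  assaySide <- (signal - curve@intercept) / curve@slope
  QuantResult(analyte = curve@analyte,
              concentration = dilutionFactor * assaySide,
              method = curve@method, unit = curve@unit,
              flags = .rangeFlags(assaySide, curve@validRange))
}

#' Single-point recovery
#'
#' \code{100 * estimated / true} percent; defined only for positive truth.
#'
#' @param true true concentration (> 0).
#' @param estimated estimated concentration.
#' @return Recovery in percent.
#' @export
recovery <- function(true, estimated) {
  if (any(true <= 0)) stop("recovery is defined only for true > 0")
  100 * estimated / true
}

#' Mean recovery rate (MRR)
#'
#' Mean and sample (n-1) standard deviation of per-point recoveries; the
#' accuracy/linearity statistic used throughout. For a single pair the SD
#' is undefined and reported as 0 with an \code{sd_undefined} flag.
#'
#' @param true true concentrations (> 0).
#' @param estimated estimates, same length.
#' @return list with \code{mrr}, \code{sd}, \code{recoveries},
#'   \code{flags}.
#' @examples
#' meanRecovery(c(10, 10), c(9, 11))  # mrr 100, sd 14.14
#' @export
meanRecovery <- function(true, estimated) {
  if (length(true) == 0L) stop("empty input")
  if (length(true) != length(estimated))
    stop("true and estimated must have equal length")
  rec <- recovery(true, estimated)
  fl <- character()
  s <- if (length(rec) > 1L) stats::sd(rec) else {
    fl <- "sd_undefined"
    0
  }
  list(mrr = mean(rec), sd = s, recoveries = rec, flags = fl)
}

#' Linearity assessment by the 15 percent back-calculation rule
#'
#' Back-calculates each level through the curve, computes its recovery,
#' and returns the largest contiguous sub-range of levels whose recoveries
#' deviate from 100 percent by at most \code{tolerance}. A deviation
#' exactly equal to the tolerance passes. When runs tie in length, the one
#' at higher concentrations is returned; when no level passes, the range
#' is empty with a fail verdict.
#'
#' @param curve a \linkS4class{CalibrationCurve}.
#' @param levels tested concentration levels.
#' @param signals measured signals at those levels.
#' @param tolerance percent deviation allowed (default 15).
#' @return list with \code{linearRange} (numeric length 2, or length 0),
#'   \code{verdict} (TRUE when any level passes), \code{recoveries} and
#'   \code{pass} per level (in level order).
#' @export
linearityAssessment <- function(curve, levels, signals, tolerance = 15) {
  stopifnot(is(curve, "CalibrationCurve"))
  if (length(levels) != length(signals))
    stop("levels and signals must have equal length")
  ord <- order(levels)
  levels <- levels[ord]
  signals <- signals[ord]
  back <- (signals - curve@intercept) / curve@slope
  rec <- recovery(levels, back)
  pass <- abs(rec - 100) <= tolerance
  if (!any(pass))
    return(list(linearRange = numeric(), verdict = FALSE,
                recoveries = rec, pass = pass))
  runs <- rle(pass)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ok <- which(runs$values)
  best <- ok[which.max(runs$lengths[ok] + seq_along(runs$lengths)[ok] /
                       (length(runs$lengths) + 1))] # ties -> later run
  list(linearRange = c(levels[starts[best]], levels[ends[best]]),
       verdict = TRUE, recoveries = rec, pass = pass)
}

#' Limits of detection and quantification
#'
#' ICH-style closed forms: LOD = 3.3 sigma / |slope|,
#' LOQ = 10 sigma / |slope|.
#'
#' @param noiseSd blank/residual noise SD in signal units (>= 0).
#' @param slope calibration slope, signal per analyte unit (nonzero).
#' @return named numeric \code{c(lod, loq)} in analyte units.
#' @examples
#' lodLoq(0.01, 0.1)  # 0.33, 1.0
#' @export
lodLoq <- function(noiseSd, slope) {
  if (slope == 0) stop("slope must be nonzero")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  c(lod = 3.3 * noiseSd / abs(slope), loq = 10 * noiseSd / abs(slope))
}

#' Assemble a validation report
#'
#' Convenience bundling of \code{\link{meanRecovery}},
#' \code{\link{linearityAssessment}} and \code{\link{lodLoq}} for one
#' method: the pass verdict requires the MRR to deviate from 100 percent
#' by no more than the tolerance (boundary passes).
#'
#' @param true true concentrations.
#' @param estimated estimates.
#' @param tolerance linearity tolerance, percent.
#' @param linearRange optional, from \code{\link{linearityAssessment}}.
#' @param lod,loq optional detection limits.
#' @return A \linkS4class{ValidationReport}.
#' @export
validationReport <- function(true, estimated, tolerance = 15,
                             linearRange = numeric(), lod = NA_real_,
                             loq = NA_real_) {
  mr <- meanRecovery(true, estimated)
  new("ValidationReport", recoveries = mr$recoveries, mrr = mr$mrr,
      mrrSd = mr$sd, linearRange = linearRange, lod = lod, loq = loq,
      tolerance = tolerance,
      verdict = abs(mr$mrr - 100) <= tolerance, flags = mr$flags)
}
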