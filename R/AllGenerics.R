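#' @include AllClasses.R
NULL

#' Accessors
#'
#' Small accessor generics for the package's S4 classes; user code should
#' use these rather than reaching into slots.
#'
#' @param x an object of the documented class.
#' @param ... passed to methods.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("wavelengths", function(x, ...) standardGeneric("wavelengths"))

#' @rdname accessors
#' @export
setGeneric("absorbance", function(x, ...) standardGeneric("absorbance"))

#' @rdname accessors
#' @export
setGeneric("pathlength", function(x, ...) standardGeneric("pathlength"))

#' @rdname accessors
#' @export
setGeneric("dilutionFactor", function(x, ...)
  standardGeneric("dilutionFactor"))

#' @rdname accessors
#' @export
setGeneric("concentration", function(x, ...) standardGeneric("concentration"))

#' @rdname accessors
#' @export
setGeneric("flags", function(x, ...) standardGeneric("flags"))

#' @rdname accessors
#' @export
setGeneric("analyte", function(x, ...) standardGeneric("analyte"))

#' @rdname accessors
#' @export
setGeneric("curveSlope", function(x, ...) standardGeneric("curveSlope"))

#' @rdname accessors
#' @export
setGeneric("curveIntercept", function(x, ...)
  standardGeneric("curveIntercept"))

#' @rdname accessors
#' @export
setGeneric("validRange", function(x, ...) standardGeneric("validRange"))

#' @rdname accessors
#' @export
setGeneric("grade", function(x, ...) standardGeneric("grade"))

#' @rdname accessors
#' @export
setGeneric("isIcteric", function(x, ...) standardGeneric("isIcteric"))

#' @rdname accessors
#' @export
setGeneric("isLipemic", function(x, ...) standardGeneric("isLipemic"))

#' @rdname accessors
#' @export
setGeneric("isQuantifiable", function(x, ...)
  standardGeneric("isQuantifiable"))

#' @rdname accessors
#' @export
setGeneric("totalHeme", function(x, ...) standardGeneric("totalHeme"))

#' @rdname accessors
#' @export
setGeneric("readout", function(x, channel, ...) standardGeneric("readout"))

#' @rdname accessors
#' @export
setGeneric("panelSamples", function(x, ...) standardGeneric("panelSamples"))

#' @rdname accessors
#' @export
setGeneric("meanRecoveryRate", function(x, ...)
  standardGeneric("meanRecoveryRate"))

setMethod("wavelengths", "MeasuredSpectrum", function(x, ...) x@wavelengths)
setMethod("wavelengths", "ComponentLibrary", function(x, ...) x@wavelengths)
setMethod("absorbance", "MeasuredSpectrum", function(x, ...) x@absorbance)
setMethod("pathlength", "MeasuredSpectrum", function(x, ...) x@pathlength)
setMethod("dilutionFactor", "MeasuredSpectrum", function(x, ...)
  x@dilutionFactor)
setMethod("dilutionFactor", "AssayReadoutSet", function(x, ...)
  x@dilutionFactor)
setMethod("concentration", "QuantResult", function(x, ...) x@concentration)
setMethod("flags", "QuantResult", function(x, ...) x@flags)
setMethod("flags", "ValidationReport", function(x, ...) x@flags)
setMethod("analyte", "QuantResult", function(x, ...) x@analyte)
setMethod("analyte", "CalibrationCurve", function(x, ...) x@analyte)
setMethod("curveSlope", "CalibrationCurve", function(x, ...) x@slope)
setMethod("curveIntercept", "CalibrationCurve", function(x, ...) x@intercept)
setMethod("validRange", "CalibrationCurve", function(x, ...) x@validRange)
setMethod("grade", "SampleClassification", function(x, ...) x@grade)
setMethod("isIcteric", "SampleClassification", function(x, ...) x@icteric)
setMethod("isLipemic", "SampleClassification", function(x, ...) x@lipemic)
setMethod("isQuantifiable", "SampleClassification", function(x, ...)
  x@quantifiable)
setMethod("totalHeme", "SampleComposition", function(x, ...)
  4 * x@hb + x@labileHeme)
setMethod("readout", "AssayReadoutSet", function(x, channel, ...) {
  if (!all(channel %in% names(x@readouts)))
    stop("unknown readout channel: ",
         paste(setdiff(channel, names(x@readouts)), collapse = ", "))
  unname(x@readouts[channel])
})
setMethod("panelSamples", "PlasmaPanel", function(x, ...) x@samples)
setMethod("meanRecoveryRate", "ValidationReport", function(x, ...)
  c(mrr = x@mrr, sd = x@mrrSd))

setMethod("show", "MeasuredSpectrum", function(object) {
  cat(sprintf(
    "MeasuredSpectrum: %d points, %g-%g nm, path %g cm, DF %g, sigma %g AU\n",
    length(object@wavelengths), min(object@wavelengths),
    max(object@wavelengths), object@pathlength, object@dilutionFactor,
    object@noiseSigma))
})

setMethod("show", "SampleComposition", function(object) {
  cat(sprintf(
    paste0("SampleComposition: labile heme %.3g uM, Hb %.3g uM (tetramer),",
           " bilirubin %.3g uM, turbidity %.3g\n"),
    object@labileHeme, object@hb, object@bilirubin, object@turbidity))
  cat(sprintf("  total heme equivalents: %.3g uM\n", totalHeme(object)))
})

setMethod("show", "QuantResult", function(object) {
  fl <- if (length(object@flags)) paste(object@flags, collapse = ";")
        else "none"
  cat(sprintf("QuantResult [%s] %s: %.4g %s (flags: %s)\n",
              object@method, object@analyte, object@concentration,
              object@unit, fl))
})

setMethod("show", "CalibrationCurve", function(object) {
  cat(sprintf(
    "CalibrationCurve [%s/%s@%s]: signal = %.6g c %+.6g, range %g-%g %s (%s)\n",
    object@method, object@analyte, object@channel, object@slope,
    object@intercept, object@validRange[1], object@validRange[2],
    object@unit, object@source))
})

setMethod("show", "MethodRegistry", function(object) {
  cat(sprintf("MethodRegistry v%s: %d curves, %d constants\n",
              object@version, length(object@entries),
              length(object@constants)))
  for (e in object@entries) show(e)
})

setMethod("show", "ValidationReport", function(object) {
  rng <- if (length(object@linearRange) == 2L)
    sprintf("%g-%g", object@linearRange[1], object@linearRange[2])
  else "empty"
  cat(sprintf(
    "ValidationReport: MRR %.2f +/- %.2f %%, linear range %s, LOD %.3g, LOQ %.3g, %s\n",
    object@mrr, object@mrrSd, rng, object@lod, object@loq,
    if (isTRUE(object@verdict)) "PASS" else "FAIL"))
})

setMethod("show", "SampleClassification", function(object) {
  cat(sprintf(
    "SampleClassification: grade %s, icteric %s, lipemic %s, quantifiable %s\n",
    object@grade, object@icteric, object@lipemic, object@quantifiable))
})

setMethod("show", "PlasmaPanel", function(object) {
  states <- vapply(object@samples, `[[`, character(1), "state")
  cat(sprintf("PlasmaPanel: %d samples (seed %d, sigma %g AU)\n",
              length(object@samples), object@seed, object@noiseSigma))
  print(table(states))
})

#' Construct a ground-truth sample composition
#'
#' @param labileHeme labile heme, uM.
#' @param hb hemoglobin, tetramer uM.
#' @param bilirubin bilirubin, uM.
#' @param turbidity dimensionless turbidity index.
#' @param interactionCoeff coefficient of the opt-in hyperchromic
#'   heme--hemoglobin cross term at 405 nm (default 0, i.e. off).
#' @return A \linkS4class{SampleComposition}.
#' @examples
#' comp <- SampleComposition(labileHeme = 10, hb = 5)
#' totalHeme(comp)  # 30: 4 heme per tetramer plus the labile pool
#' @export
SampleComposition <- function(labileHeme = 0, hb = 0, bilirubin = 0,
                              turbidity = 0, interactionCoeff = 0) {
  new("SampleComposition", labileHeme = labileHeme, hb = hb,
      bilirubin = bilirubin, turbidity = turbidity,
      interactionCoeff = interactionCoeff)
}

#' Construct a calibration curve
#'
#' @param method method identifier string.
#' @param analyte "heme" or "hemoglobin".
#' @param channel signal channel name (e.g. "A380").
#' @param slope,intercept line coefficients (signal = slope*c + intercept).
#' @param validRange assay-side concentration bounds \code{c(lo, hi)}.
#' @param unit concentration unit.
#' @param source "fitted", "registry" or "synthetic".
#' @param note free-text provenance note.
#' @return A \linkS4class{CalibrationCurve}.
#' @export
CalibrationCurve <- function(method, analyte, channel, slope, intercept,
                             validRange, unit = "uM", source = "fitted",
                             note = "") {
  new("CalibrationCurve", method = method, analyte = analyte,
      channel = channel, slope = slope, intercept = intercept,
      validRange = validRange, unit = unit, source = source, note = note)
}

#' Construct a quantification result
#'
#' @param analyte analyte name.
#' @param concentration estimate on the original-sample scale.
#' @param method method identifier.
#' @param unit concentration unit.
#' @param flags character flag vector.
#' @return A \linkS4class{QuantResult}.
#' @export
QuantResult <- function(analyte, concentration, method, unit = "uM",
                        flags = character()) {
  new("QuantResult", analyte = analyte, concentration = concentration,
      method = method, unit = unit, flags = flags)
}
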