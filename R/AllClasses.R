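#' @import methods
NULL

.SPECIES <- c("labile_heme", "hemoglobin", "bilirubin", "turbidity")

#' ComponentSpectrum library
#'
#' Wavelength-resolved specific absorbances for the four spectral components
#' of a plasma sample: labile heme (broad Soret band near 380 nm),
#' oxyhemoglobin (Soret maximum in 405--415 nm plus Q bands), bilirubin
#' (band near 455 nm) and lipemic turbidity (broadband scattering baseline,
#' nonzero at 700 nm where the chromophores are dark). Chromophore columns
#' are in AU per uM per cm; the turbidity column is AU per unit turbidity
#' index per cm.
#'
#' @slot wavelengths numeric, nm grid (ascending).
#' @slot coefficients numeric matrix, one row per wavelength, one column per
#'   species (\code{labile_heme}, \code{hemoglobin}, \code{bilirubin},
#'   \code{turbidity}).
#' @slot referencePathlengths named numeric, the pathlengths (cm) at which
#'   the heme and hemoglobin amplitudes were calibrated against the published
#'   evaluation equations.
#' @exportClass ComponentLibrary
setClass("ComponentLibrary",
  representation(
    wavelengths = "numeric",
    coefficients = "matrix",
    referencePathlengths = "numeric"
  ),
  validity = function(object) {
    msg <- character()
    if (nrow(object@coefficients) != length(object@wavelengths))
      msg <- c(msg, "coefficient rows must match wavelength grid length")
    if (!identical(colnames(object@coefficients), .SPECIES))
      msg <- c(msg, sprintf("coefficient columns must be %s",
                            paste(.SPECIES, collapse = ", ")))
    if (any(object@coefficients < 0))
      msg <- c(msg, "specific absorbances must be non-negative")
    if (is.unsorted(object@wavelengths, strictly = TRUE))
      msg <- c(msg, "wavelengths must be strictly increasing")
    if (length(msg)) msg else TRUE
  }
)

#' Ground-truth composition of one simulated sample
#'
#' Concentrations are on the undiluted-sample scale. Hemoglobin is counted
#' per tetramer; total heme bookkeeping is
#' \code{4 * hb + labileHeme} (four heme groups per tetramer).
#'
#' @slot labileHeme numeric, uM, >= 0.
#' @slot hb numeric, tetramer uM, >= 0.
#' @slot bilirubin numeric, uM, >= 0.
#' @slot turbidity numeric, dimensionless turbidity index, >= 0.
#' @slot interactionCoeff numeric, dimensionless coefficient of the additive
#'   heme--hemoglobin hyperchromic cross term at 405 nm (default 0).
#' @exportClass SampleComposition
setClass("SampleComposition",
  representation(
    labileHeme = "numeric",
    hb = "numeric",
    bilirubin = "numeric",
    turbidity = "numeric",
    interactionCoeff = "numeric"
  ),
  prototype(labileHeme = 0, hb = 0, bilirubin = 0, turbidity = 0,
            interactionCoeff = 0),
  validity = function(object) {
    vals <- c(object@labileHeme, object@hb, object@bilirubin,
              object@turbidity)
    if (any(!is.finite(vals)) || any(vals < 0))
      return("concentrations and turbidity index must be finite and >= 0")
    if (length(object@interactionCoeff) != 1L ||
        !is.finite(object@interactionCoeff))
      return("interactionCoeff must be a finite scalar")
    TRUE
  }
)

#' A measured (or simulated) absorbance spectrum
#'
#' @slot wavelengths numeric, nm.
#' @slot absorbance numeric, AU, same length as the grid.
#' @slot pathlength numeric, cm, > 0.
#' @slot dilutionFactor numeric >= 1 (from the allowed power-of-two grid for
#'   simulated spectra).
#' @slot noiseSigma numeric, AU, >= 0.
#' @slot seed integer seed used for the noise draw (NA when noiseless or
#'   externally measured).
#' @exportClass MeasuredSpectrum
setClass("MeasuredSpectrum",
  representation(
    wavelengths = "numeric",
    absorbance = "numeric",
    pathlength = "numeric",
    dilutionFactor = "numeric",
    noiseSigma = "numeric",
    seed = "integer"
  ),
  prototype(pathlength = 0.29, dilutionFactor = 1, noiseSigma = 0,
            seed = NA_integer_),
  validity = function(object) {
    msg <- character()
    if (length(object@absorbance) != length(object@wavelengths))
      msg <- c(msg, "absorbance and wavelengths must have equal length")
    if (any(!is.finite(object@absorbance)))
      msg <- c(msg, "absorbance must be finite")
    if (object@pathlength <= 0)
      msg <- c(msg, "pathlength must be > 0")
    if (object@dilutionFactor < 1)
      msg <- c(msg, "dilutionFactor must be >= 1")
    if (object@noiseSigma < 0)
      msg <- c(msg, "noiseSigma must be >= 0")
    if (length(msg)) msg else TRUE
  }
)

#' Per-assay scalar read-outs for one sample
#'
#' Named channels generated by the documented forward model of each method
#' from a single \linkS4class{SampleComposition}:
#' \code{hak_A400}; \code{harboe_A380}, \code{harboe_A415},
#' \code{harboe_A450}; \code{pyridine_A556_reduced},
#' \code{pyridine_A556_oxidized}, \code{pyridine_A540_reduced},
#' \code{pyridine_A557_reduced}; \code{sls_A395}, \code{sls_A413};
#' \code{apohrp_apparent_heme_nM}; \code{direct_A380}, \code{direct_A405}.
#'
#' @slot readouts named numeric vector of channel values (AU, or nM for the
#'   apoHRP channel).
#' @slot dilutionFactor numeric >= 1, the dilution at which the channels were
#'   read.
#' @exportClass AssayReadoutSet
setClass("AssayReadoutSet",
  representation(readouts = "numeric", dilutionFactor = "numeric"),
  prototype(dilutionFactor = 1),
  validity = function(object) {
    if (is.null(names(object@readouts)) || anyNA(names(object@readouts)))
      return("readouts must be a named numeric vector")
    if (any(!is.finite(object@readouts)))
      return("readouts must be finite")
    if (object@dilutionFactor < 1)
      return("dilutionFactor must be >= 1")
    TRUE
  }
)

#' A linear calibration curve for one method--analyte channel
#'
#' Represents \code{signal = slope * concentration + intercept} over a
#' stated valid concentration range (assay side, i.e. after dilution).
#'
#' @slot method character method identifier.
#' @slot analyte "heme" or "hemoglobin".
#' @slot channel character, the signal channel (e.g. "A380").
#' @slot slope numeric, signal per concentration unit; must be nonzero.
#' @slot intercept numeric, signal units.
#' @slot validRange numeric length-2, assay-side concentration bounds.
#' @slot unit character concentration unit ("uM", "nM", "pmol").
#' @slot source "fitted" for curves estimated from data, "registry" for
#'   published constants, "synthetic" for simulator-defined stand-ins.
#' @slot note character free-text provenance/protocol note.
#' @exportClass CalibrationCurve
setClass("CalibrationCurve",
  representation(
    method = "character", analyte = "character", channel = "character",
    slope = "numeric", intercept = "numeric", validRange = "numeric",
    unit = "character", source = "character", note = "character"
  ),
  prototype(unit = "uM", source = "fitted", note = ""),
  validity = function(object) {
    msg <- character()
    if (!is.finite(object@slope) || object@slope == 0)
      msg <- c(msg, "slope must be finite and nonzero")
    if (length(object@validRange) != 2L ||
        !(object@validRange[1] < object@validRange[2]))
      msg <- c(msg, "validRange must be c(lo, hi) with lo < hi")
    if (!object@analyte %in% c("heme", "hemoglobin"))
      msg <- c(msg, "analyte must be 'heme' or 'hemoglobin'")
    if (length(msg)) msg else TRUE
  }
)

#' Read-only registry of published method constants
#'
#' Holds every fixed calibration curve and scalar constant used by the
#' quantifiers: direct UV/Vis curves, the pyridine linear curve and its
#' extinction-coefficient set, HPLC and ESI-MS curves, kit and Harboe
#' constants, apoHRP ranges and hemoglobin cross-reactivity, and reagent
#' strip bounds.
#'
#' @slot entries named list of \linkS4class{CalibrationCurve}.
#' @slot constants named list of scalar constants (extinction coefficients
#'   in mM^-1 cm^-1, equation factors, range bounds).
#' @slot version character registry version string.
#' @exportClass MethodRegistry
setClass("MethodRegistry",
  representation(entries = "list", constants = "list", version = "character"),
  validity = function(object) {
    ok <- vapply(object@entries, is, logical(1), class2 = "CalibrationCurve")
    if (!all(ok)) return("all entries must be CalibrationCurve objects")
    TRUE
  }
)

#' A single concentration estimate with range/flag metadata
#'
#' @slot analyte character.
#' @slot concentration numeric estimate on the original-sample scale.
#' @slot unit character ("uM" or "nM").
#' @slot method character method identifier.
#' @slot flags character vector, subset of \code{below_range},
#'   \code{above_range}, \code{negative_estimate}, \code{semiquantitative},
#'   \code{blank_offset}. Negative estimates are reported and flagged,
#'   never truncated.
#' @exportClass QuantResult
setClass("QuantResult",
  representation(
    analyte = "character", concentration = "numeric", unit = "character",
    method = "character", flags = "character"
  ),
  prototype(unit = "uM", flags = character()),
  validity = function(object) {
    allowed <- c("below_range", "above_range", "negative_estimate",
                 "semiquantitative", "blank_offset")
    if (!all(object@flags %in% allowed))
      return(sprintf("flags must be a subset of {%s}",
                     paste(allowed, collapse = ", ")))
    TRUE
  }
)

#' Validation statistics for one method
#'
#' @slot recoveries numeric, per-point recoveries in percent.
#' @slot mrr numeric, mean recovery rate in percent.
#' @slot mrrSd numeric, sample (n-1) standard deviation of recoveries, percent.
#' @slot linearRange numeric length-2 (or length-0 when no level passes).
#' @slot lod numeric, limit of detection (analyte units).
#' @slot loq numeric, limit of quantification (analyte units).
#' @slot tolerance numeric, the linearity tolerance in percent (default 15).
#' @slot verdict logical, pass/fail at the tolerance.
#' @slot flags character.
#' @exportClass ValidationReport
setClass("ValidationReport",
  representation(
    recoveries = "numeric", mrr = "numeric", mrrSd = "numeric",
    linearRange = "numeric", lod = "numeric", loq = "numeric",
    tolerance = "numeric", verdict = "logical", flags = "character"
  ),
  prototype(linearRange = numeric(), lod = NA_real_, loq = NA_real_,
            tolerance = 15, verdict = NA, flags = character())
)

#' Hemolysis/icterus/lipemia classification of a plasma sample
#'
#' Grade convention: \code{non-hemolytic} strictly below 5 uM hemoglobin,
#' \code{severe} strictly above 100 uM, \code{mild} otherwise (both
#' boundaries fall in \code{mild}). Lipemic samples are not quantifiable.
#'
#' @slot grade one of "non-hemolytic", "mild", "severe" (NA when not
#'   quantifiable).
#' @slot icteric logical.
#' @slot lipemic logical.
#' @slot quantifiable logical; FALSE whenever lipemic.
#' @exportClass SampleClassification
setClass("SampleClassification",
  representation(grade = "character", icteric = "logical",
                 lipemic = "logical", quantifiable = "logical"),
  validity = function(object) {
    if (isTRUE(object@lipemic) && isTRUE(object@quantifiable))
      return("lipemic samples must have quantifiable = FALSE")
    if (!is.na(object@grade) &&
        !object@grade %in% c("non-hemolytic", "mild", "severe"))
      return("grade must be non-hemolytic, mild or severe")
    TRUE
  }
)

#' A simulated plasma panel with retained ground truth
#'
#' @slot samples named list; each element has \code{id}, \code{state},
#'   \code{composition} (\linkS4class{SampleComposition}), \code{spectrum}
#'   (\linkS4class{MeasuredSpectrum}, undiluted), and \code{readouts}
#'   (\linkS4class{AssayReadoutSet}, undiluted).
#' @slot seed integer panel seed.
#' @slot noiseSigma numeric, AU.
#' @slot library the \linkS4class{ComponentLibrary} used.
#' @exportClass PlasmaPanel
setClass("PlasmaPanel",
  representation(samples = "list", seed = "integer", noiseSigma = "numeric",
                 library = "ComponentLibrary")
)

#' Run configuration
#'
#' Bundles every tunable of the simulate--quantify--report pipeline so a run
#' is reproducible from one object: the master seed, the noise level, well
#' pathlengths, the allowed dilution grid and the classification thresholds.
#'
#' @slot seed integer master seed; all randomness flows from it.
#' @slot noiseSigma numeric, AU.
#' @slot pathlengths named numeric, cm per well format (e.g.
#'   \code{c(well200uL = 0.58, well100uL = 0.29)}).
#' @slot dilutionGrid numeric, allowed dilution factors.
#' @slot linearityTolerance numeric, percent.
#' @slot lipemiaThreshold numeric, AU at 700 nm on the undiluted scale.
#' @slot gradeBounds numeric length-2, uM hemoglobin (non-hemolytic/mild and
#'   mild/severe boundaries).
#' @slot eq1Parse "printed" or "bracketed".
#' @exportClass RunConfig
setClass("RunConfig",
  representation(
    seed = "integer", noiseSigma = "numeric", pathlengths = "numeric",
    dilutionGrid = "numeric", linearityTolerance = "numeric",
    lipemiaThreshold = "numeric", gradeBounds = "numeric",
    eq1Parse = "character"
  ),
  validity = function(object) {
    msg <- character()
    if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
    if (any(object@pathlengths <= 0)) msg <- c(msg, "pathlengths must be > 0")
    if (any(object@dilutionGrid < 1)) msg <- c(msg, "dilution factors >= 1")
    if (object@linearityTolerance <= 0 || object@lipemiaThreshold <= 0)
      msg <- c(msg, "thresholds must be positive")
    if (length(object@gradeBounds) != 2L ||
        !(0 < object@gradeBounds[1] && object@gradeBounds[1] <
          object@gradeBounds[2]))
      msg <- c(msg, "gradeBounds must be 0 < lo < hi")
    if (!object@eq1Parse %in% c("printed", "bracketed"))
      msg <- c(msg, "eq1Parse must be 'printed' or 'bracketed'")
    if (length(msg)) msg else TRUE
  }
)
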