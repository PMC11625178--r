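#' @include AllClasses.R AllGenerics.R registry.R calibration.R
NULL

#' Direct UV/Vis quantification at the Soret maxima
#'
#' Inverts the registry direct calibration curve: heme at 380 nm
#' (y = 0.029 x - 0.170, valid 10--40 uM) or hemoglobin at 405 nm
#' (y = 0.158 x - 0.007, valid 1--7 uM).
#'
#' @param analyte "heme" or "hemoglobin".
#' @param signal absorbance, AU.
#' @param dilutionFactor DF >= 1.
#' @param registry the \linkS4class{MethodRegistry}.
#' @return A \linkS4class{QuantResult} in uM.
#' @examples
#' concentration(uvvisDirect("heme", 0.99))  # 40 uM
#' @export
uvvisDirect <- function(analyte = c("heme", "hemoglobin"), signal,
                        dilutionFactor = 1, registry = methodRegistry()) {
  analyte <- match.arg(analyte)
  if (!is.finite(signal)) stop("signal must be finite")
  id <- if (analyte == "heme") "direct_heme_a380" else "direct_hb_a405"
  applyCalibration(registryEntry(registry, id), signal, dilutionFactor)
}

#' Harboe polychromatic hemoglobin quantification
#'
#' Three-wavelength correction isolating the oxyhemoglobin Soret signal:
#' \code{c(Hb)[uM] = DF * 0.155 * (83.6 * (2 A415 - A380 - A450))}.
#' The assay-side valid range is 1.3--16.5 uM.
#'
#' @param a380,a415,a450 absorbances, AU (>= 0).
#' @param dilutionFactor DF >= 1.
#' @param registry the \linkS4class{MethodRegistry}.
#' @return A \linkS4class{QuantResult} (hemoglobin, uM, tetramer).
#' @examples
#' concentration(harboeHb(0, 1.0, 0))  # 25.916 uM
#' @export
harboeHb <- function(a380, a415, a450, dilutionFactor = 1,
                     registry = methodRegistry()) {
  if (any(c(a380, a415, a450) < 0)) stop("absorbances must be >= 0")
  if (dilutionFactor < 1) stop("dilutionFactor must be >= 1")
  k <- registry@constants
  assaySide <- k$harboe_f1 * (k$harboe_f2 * (2 * a415 - a380 - a450))
  rng <- validRange(registryEntry(registry, "harboe_hb"))
  QuantResult(analyte = "hemoglobin",
              concentration = dilutionFactor * assaySide,
              method = "harboe", unit = "uM",
              flags = .rangeFlags(assaySide, rng))
}

#' Pyridine hemochromogen heme quantification
#'
#' Converts reduced-state bis-pyridine complex absorbances to heme
#' equivalents under one of five evaluation conventions:
#' \describe{
#'   \item{reduced_556_heme}{\code{c = A556 / (34.1 * path)} mM, as uM.}
#'   \item{reduced_556_hb}{\code{c = A556 / (80.4 * path)} mM, hemoglobin
#'     tetramer uM (the coefficient is per tetramer).}
#'   \item{published_557}{\code{c = A557 / (34.7 * path)}, the earlier
#'     published convention (systematically under-recovers relative to the
#'     fitted curve).}
#'   \item{difference_557_540}{\code{c = (A557 - A540) / (23.98 * path)}.}
#'   \item{linear_fit}{inverse of the fitted linear heme curve
#'     y = 0.034 x - 0.161 (valid 7.5--37.5 uM).}
#' }
#'
#' @param readouts named numeric vector (or \linkS4class{AssayReadoutSet})
#'   with the pyridine channels \code{pyridine_A556_reduced},
#'   \code{pyridine_A557_reduced}, \code{pyridine_A540_reduced} as the mode
#'   requires.
#' @param mode evaluation convention, see above.
#' @param pathlength cuvette pathlength, cm (the published coefficients
#'   assume 1 cm).
#' @param dilutionFactor DF >= 1 (the 1:1 sample:reagent mixing of the
#'   protocol is part of the caller-supplied DF).
#' @param registry the \linkS4class{MethodRegistry}.
#' @return A \linkS4class{QuantResult} (heme equivalents uM, or hemoglobin
#'   tetramer uM for \code{reduced_556_hb}).
#' @examples
#' concentration(pyridineHemochromogen(
#'   c(pyridine_A556_reduced = 0.341), "reduced_556_heme"))  # 10 uM
#' @export
pyridineHemochromogen <- function(readouts,
    mode = c("reduced_556_heme", "reduced_556_hb", "published_557",
             "difference_557_540", "linear_fit"),
    pathlength = 1, dilutionFactor = 1, registry = methodRegistry()) {
  mode <- match.arg(mode)
  if (is(readouts, "AssayReadoutSet")) readouts <- readouts@readouts
  if (dilutionFactor < 1) stop("dilutionFactor must be >= 1")
  k <- registry@constants
  need <- switch(mode,
    reduced_556_heme = , reduced_556_hb = , linear_fit =
      "pyridine_A556_reduced",
    published_557 = "pyridine_A557_reduced",
    difference_557_540 = c("pyridine_A557_reduced", "pyridine_A540_reduced"))
  if (!all(need %in% names(readouts)))
    stop("missing pyridine channel(s) for mode ", mode, ": ",
         paste(setdiff(need, names(readouts)), collapse = ", "))
  df <- dilutionFactor
  rng <- validRange(registryEntry(registry, "pyridine_heme_linear"))
  analyte <- "heme"
  if (mode == "linear_fit") {
    res <- applyCalibration(registryEntry(registry, "pyridine_heme_linear"),
                            readouts[["pyridine_A556_reduced"]], df)
    return(QuantResult("heme", concentration(res),
                       "pyridine_hemochromogen", "uM", flags(res)))
  }
  a <- switch(mode,
    reduced_556_heme = readouts[["pyridine_A556_reduced"]],
    reduced_556_hb = readouts[["pyridine_A556_reduced"]],
    published_557 = readouts[["pyridine_A557_reduced"]],
    difference_557_540 = readouts[["pyridine_A557_reduced"]] -
      readouts[["pyridine_A540_reduced"]])
  eps <- switch(mode,
    reduced_556_heme = k$eps556_heme,
    reduced_556_hb = k$eps556_hb,
    published_557 = k$eps557,
    difference_557_540 = k$eps557_540)
  if (mode == "reduced_556_hb") {
    analyte <- "hemoglobin"
    rng <- c(1.3, 12.7) # published hemoglobin range for this assay
  }
  assaySide <- a / (eps * pathlength) * 1000 # mM -> uM
  QuantResult(analyte = analyte, concentration = df * assaySide,
              method = "pyridine_hemochromogen", unit = "uM",
              flags = .rangeFlags(assaySide, rng))
}

#' Modified SLS (surfactant) quantification
#'
#' Inverts a fitted surfactant-method curve: hemoglobin at 413 nm
#' (valid 0.5--6 uM) or heme at 395 nm (valid 10--45 uM).
#'
#' @param analyte "heme" or "hemoglobin"; must match the curve's analyte.
#' @param signal absorbance at 395 (heme) or 413 (hemoglobin) nm.
#' @param curve a \linkS4class{CalibrationCurve} for this method (fit it
#'   from standards, or use the registry stand-in).
#' @param dilutionFactor DF >= 1.
#' @param registry the \linkS4class{MethodRegistry} (range flags).
#' @return A \linkS4class{QuantResult} in uM.
#' @export
slsModified <- function(analyte = c("heme", "hemoglobin"), signal,
                        curve = NULL, dilutionFactor = 1,
                        registry = methodRegistry()) {
  analyte <- match.arg(analyte)
  id <- if (analyte == "heme") "sls_heme_a395" else "sls_hb_a413"
  if (is.null(curve)) curve <- registryEntry(registry, id)
  if (curve@analyte != analyte)
    stop("curve analyte (", curve@analyte, ") does not match ", analyte)
  res <- applyCalibration(curve, signal, dilutionFactor)
  # flag against the published range for this method even for fitted curves
  rng <- validRange(registryEntry(registry, id))
  assaySide <- concentration(res) / dilutionFactor
  QuantResult(analyte = analyte, concentration = concentration(res),
              method = "sls", unit = "uM",
              flags = .rangeFlags(assaySide, rng))
}

#' Total heme by the colorimetric kit at 400 nm
#'
#' Apparent total heme from the kit signal alone (no hemoglobin
#' correction): \code{c = DF * 25.64 * A400 + 4.85} uM, flagged against
#' the 8--32 uM assay-side range. Use
#' \code{\link{estimateLabileHeme}} for the hemoglobin-corrected labile
#' heme estimate.
#'
#' @param a400 absorbance at 400 nm (>= 0).
#' @param dilutionFactor DF >= 1.
#' @param registry the \linkS4class{MethodRegistry}.
#' @return A \linkS4class{QuantResult} (heme, uM).
#' @examples
#' concentration(hemeAssayKitTotal(1.0))  # 30.49 uM
#' @export
hemeAssayKitTotal <- function(a400, dilutionFactor = 1,
                              registry = methodRegistry()) {
  if (a400 < 0) stop("a400 must be >= 0")
  if (dilutionFactor < 1) stop("dilutionFactor must be >= 1")
  k <- registry@constants
  conc <- dilutionFactor * k$eq1_kit_slope * a400 + k$eq1_offset
  rng <- validRange(registryEntry(registry, "hak_heme"))
  QuantResult(analyte = "heme", concentration = conc,
              method = "heme_assay_kit", unit = "uM",
              flags = .rangeFlags(conc / dilutionFactor, rng))
}

#' Semiquantitative reagent-strip classification
#'
#' Peroxidase-activity test strips respond to both analytes:
#' \code{positive} when heme is within 10--1000 nM or hemoglobin within
#' 2.5--250 nM (closed bounds); \code{saturated} above either upper bound
#' (higher concentrations give the same maximal color);
#' \code{negative} otherwise. Always semiquantitative.
#'
#' @param cHeme heme, nM (>= 0).
#' @param cHb hemoglobin, nM (>= 0).
#' @param registry the \linkS4class{MethodRegistry}.
#' @return character bin in \{"negative", "positive", "saturated"\} with a
#'   \code{flags} attribute containing \code{semiquantitative}.
#' @examples
#' hemastixClassify(500, 0)   # positive
#' hemastixClassify(0, 2500)  # saturated
#' @export
hemastixClassify <- function(cHeme, cHb, registry = methodRegistry()) {
  if (cHeme < 0 || cHb < 0) stop("concentrations must be >= 0")
  hemeRng <- registryConstant(registry, "hemastix_heme_range")
  hbRng <- registryConstant(registry, "hemastix_hb_range")
  bin <- if (cHeme > hemeRng[2] || cHb > hbRng[2]) "saturated"
    else if ((cHeme >= hemeRng[1] && cHeme <= hemeRng[2]) ||
             (cHb >= hbRng[1] && cHb <= hbRng[2])) "positive"
    else "negative"
  structure(bin, flags = "semiquantitative")
}

#' apoHRP peroxidase-reconstitution heme quantification
#'
#' The assay reports heme as the nM-equivalent of reconstituted-peroxidase
#' activity; the mapping is the identity on that signal, with
#' substrate-specific valid-range flags (TMB 33.3--42.9 nM,
#' o-dianisidine 23.8--41.7 nM).
#'
#' @param apparentHemeSignal nM-equivalent signal (>= 0).
#' @param substrate "TMB" or "o-dianisidine".
#' @param registry the \linkS4class{MethodRegistry}.
#' @return A \linkS4class{QuantResult} (heme, nM).
#' @export
apoHrpQuantify <- function(apparentHemeSignal,
                           substrate = c("TMB", "o-dianisidine"),
                           registry = methodRegistry()) {
  substrate <- match.arg(substrate)
  if (apparentHemeSignal < 0) stop("signal must be >= 0")
  rng <- registryConstant(registry,
    if (substrate == "TMB") "apohrp_range_tmb"
    else "apohrp_range_odianisidine")
  QuantResult(analyte = "heme", concentration = apparentHemeSignal,
              method = paste0("apohrp_", tolower(sub("-", "", substrate))),
              unit = "nM", flags = .rangeFlags(apparentHemeSignal, rng))
}

#' Hemoglobin cross-reactivity of the apoHRP assay
#'
#' Apparent heme reported for a pure hemoglobin solution:
#' \code{3.629 * c(Hb) + 21.86} nM.
#'
#' @param cHbNm hemoglobin, nM (>= 0).
#' @param registry the \linkS4class{MethodRegistry}.
#' @return Apparent heme, nM.
#' @examples
#' apoHrpApparentHemeFromHb(10)  # 58.15 nM
#' @export
apoHrpApparentHemeFromHb <- function(cHbNm, registry = methodRegistry()) {
  if (any(cHbNm < 0)) stop("cHbNm must be >= 0")
  registryConstant(registry, "apohrp_hb_slope") * cHbNm +
    registryConstant(registry, "apohrp_hb_intercept")
}
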