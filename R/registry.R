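#' @include AllClasses.R AllGenerics.R
NULL

REGISTRY_VERSION <- "1.0"

#' The registry of published method constants
#'
#' Returns the read-only registry of every fixed calibration curve and
#' scalar constant used by the quantifiers. Curves are
#' \code{signal = slope * c + intercept} with assay-side valid ranges.
#'
#' Entries: \code{direct_heme_a380} (0.029, -0.170, 10--40 uM),
#' \code{direct_hb_a405} (0.158, -0.007, 1--7 uM),
#' \code{pyridine_heme_linear} (0.034, -0.161, 7.5--37.5 uM),
#' \code{hplc_hb} and \code{hplc_heme} and \code{esi_ms_heme}
#' (chromatographic/MS peak-response curves in pmol),
#' \code{hak_heme}/\code{hak_hb} (colorimetric kit at 400 nm),
#' \code{harboe_hb} (polychromatic correction, 1.3--16.5 uM),
#' \code{sls_hb_a413}/\code{sls_heme_a395} (surfactant method; slopes are
#' simulator-defined stand-ins because only ranges are published).
#'
#' Constants include the pyridine hemochromogen extinction coefficients
#' (\code{eps556_heme} = 34.1, \code{eps556_hb} = 80.4, \code{eps557} = 34.7,
#' \code{eps557_540} = 23.98 mM^-1 cm^-1), the Harboe factors (0.155, 83.6),
#' the combined-estimator constants (25.64, 2.59, 4.85), the apoHRP
#' hemoglobin cross-reactivity line (3.629, 21.86 nM) and substrate ranges,
#' and the reagent-strip detection bounds (heme 10--1000 nM, hemoglobin
#' 2.5--250 nM).
#'
#' @return A \linkS4class{MethodRegistry}.
#' @examples
#' reg <- methodRegistry()
#' registryEntry(reg, "direct_heme_a380")
#' registryConstant(reg, "eps557_540")
#' @export
methodRegistry <- local({
  cached <- NULL
  function() {
    if (!is.null(cached)) return(cached)
    cc <- CalibrationCurve
    entries <- list(
      direct_heme_a380 = cc("direct_uvvis", "heme", "A380", 0.029, -0.170,
        c(10, 40), "uM", "registry",
        "direct Soret-band quantification, 200 uL wells"),
      direct_hb_a405 = cc("direct_uvvis", "hemoglobin", "A405", 0.158,
        -0.007, c(1, 7), "uM", "registry",
        "direct Soret-band quantification, 200 uL wells"),
      pyridine_heme_linear = cc("pyridine_hemochromogen", "heme",
        "A556_reduced", 0.034, -0.161, c(7.5, 37.5), "uM", "registry",
        "linear heme calibration of the reduced bis-pyridine complex"),
      hplc_hb = cc("hplc", "hemoglobin", "AUC220", 35375434, -6495339,
        c(0.2, 2.4), "pmol", "registry",
        "C4 reversed-phase peak area at 220 nm; an equivalent molar range of 0.5-6 uM (~0.2-2.4 nmol) is also reported (rangeAlt)"),
      hplc_heme = cc("hplc", "heme", "AUC220", 2096511, -15660327,
        c(8, 18), "pmol", "registry",
        "C4 reversed-phase peak area at 220 nm; an equivalent ~8-18 nmol range is also reported (rangeAlt)"),
      esi_ms_heme = cc("esi_ms", "heme", "ion_intensity", 48564, 46751,
        c(0.8, 25), "pmol", "registry",
        "electrospray MS heme ion response"),
      hak_heme = cc("heme_assay_kit", "heme", "A400", 1 / 25.64,
        -4.85 / 25.64, c(8, 32), "uM", "registry",
        "colorimetric kit response at 400 nm, expressed from the combined-estimator constants"),
      hak_hb = cc("heme_assay_kit", "hemoglobin", "A400", 2.59 / 25.64,
        -4.85 / 25.64, c(0.5, 10), "uM", "registry",
        "hemoglobin cross-response of the kit at 400 nm"),
      harboe_hb = cc("harboe", "hemoglobin", "2*A415-A380-A450",
        1 / (0.155 * 83.6), 0, c(1.3, 16.5), "uM", "registry",
        "three-wavelength polychromatic correction, 100 uL wells"),
      sls_hb_a413 = cc("sls", "hemoglobin", "A413", 0.150, 0.005,
        c(0.5, 6), "uM", "synthetic",
        "surfactant chromophore at 413 nm; published range, simulator-defined slope"),
      sls_heme_a395 = cc("sls", "heme", "A395", 0.020, 0.010,
        c(10, 45), "uM", "synthetic",
        "surfactant chromophore at 395 nm; published range, simulator-defined slope")
    )
    constants <- list(
      eps556_heme = 34.1,     # mM^-1 cm^-1, reduced complex, per heme
      eps556_hb = 80.4,       # mM^-1 cm^-1, per hemoglobin tetramer
      eps557 = 34.7,          # mM^-1 cm^-1, earlier published convention
      eps557_540 = 23.98,     # mM^-1 cm^-1, reduced-state difference
      harboe_f1 = 0.155,
      harboe_f2 = 83.6,
      eq1_kit_slope = 25.64,  # uM per AU at 400 nm
      eq1_hb_coeff = 2.59,    # uM apparent heme per uM hemoglobin
      eq1_offset = 4.85,      # uM blank offset
      apohrp_hb_slope = 3.629,     # nM apparent heme per nM hemoglobin
      apohrp_hb_intercept = 21.86, # nM
      apohrp_range_tmb = c(33.3, 42.9),          # nM heme
      apohrp_range_odianisidine = c(23.8, 41.7), # nM heme
      hemastix_heme_range = c(10, 1000),  # nM
      hemastix_hb_range = c(2.5, 250)     # nM
    )
    cached <<- new("MethodRegistry", entries = entries,
                   constants = constants, version = REGISTRY_VERSION)
    cached
  }
})

#' Look up a registry calibration curve
#'
#' @param registry a \linkS4class{MethodRegistry}.
#' @param id entry name (see \code{\link{methodRegistry}}).
#' @return A \linkS4class{CalibrationCurve}.
#' @export
registryEntry <- function(registry, id) {
  stopifnot(is(registry, "MethodRegistry"))
  if (!id %in% names(registry@entries))
    stop("unknown registry entry: ", id)
  registry@entries[[id]]
}

#' Look up a registry scalar constant
#'
#' @param registry a \linkS4class{MethodRegistry}.
#' @param id constant name.
#' @return Numeric constant (possibly length 2 for range bounds).
#' @export
registryConstant <- function(registry, id) {
  stopifnot(is(registry, "MethodRegistry"))
  if (!id %in% names(registry@constants))
    stop("unknown registry constant: ", id)
  registry@constants[[id]]
}

#' Export the registry as JSON
#'
#' Serializes every curve and constant, with provenance notes and the
#' registry version, for archiving alongside pipeline outputs.
#'
#' @param registry a \linkS4class{MethodRegistry}.
#' @param path optional file path; when NULL the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
registryToJson <- function(registry = methodRegistry(), path = NULL) {
  entries <- lapply(registry@entries, function(e) list(
    method = e@method, analyte = e@analyte, channel = e@channel,
    slope = e@slope, intercept = e@intercept,
    valid_range = e@validRange, unit = e@unit, source = e@source,
    note = e@note))
  obj <- list(version = registry@version, entries = entries,
              constants = registry@constants)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
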