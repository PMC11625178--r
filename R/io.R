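#' @include AllClasses.R AllGenerics.R simulate.R pipeline.R
NULL

#' Construct a run configuration
#'
#' @param seed master seed; all randomness in a run flows from it.
#' @param noiseSigma plate-reader noise SD, AU.
#' @param pathlengths named pathlengths, cm per well format.
#' @param dilutionGrid allowed dilution factors.
#' @param linearityTolerance percent.
#' @param lipemiaThreshold AU at 700 nm, undiluted scale.
#' @param gradeBounds uM hemoglobin grade boundaries.
#' @param eq1Parse "printed" or "bracketed".
#' @return A \linkS4class{RunConfig}.
#' @export
runConfig <- function(seed = 1L, noiseSigma = 0.005,
                      pathlengths = c(well200uL = PATHLENGTH_200UL,
                                      well100uL = PATHLENGTH_100UL),
                      dilutionGrid = DILUTION_GRID,
                      linearityTolerance = 15, lipemiaThreshold = 0.3,
                      gradeBounds = c(5, 100), eq1Parse = "printed") {
  new("RunConfig", seed = as.integer(seed), noiseSigma = noiseSigma,
      pathlengths = pathlengths, dilutionGrid = dilutionGrid,
      linearityTolerance = linearityTolerance,
      lipemiaThreshold = lipemiaThreshold, gradeBounds = gradeBounds,
      eq1Parse = eq1Parse)
}

.configList <- function(cfg) list(
  seed = cfg@seed, noise_sigma = cfg@noiseSigma,
  pathlengths = as.list(cfg@pathlengths),
  dilution_grid = cfg@dilutionGrid,
  linearity_tolerance = cfg@linearityTolerance,
  lipemia_threshold = cfg@lipemiaThreshold,
  grade_bounds = cfg@gradeBounds, eq1_parse = cfg@eq1Parse)

#' Write / read a run configuration (YAML)
#'
#' The pair is a round trip: \code{readRunConfig(writeRunConfig(cfg, f))}
#' reproduces \code{cfg}.
#'
#' @param cfg a \linkS4class{RunConfig}.
#' @param path file path.
#' @return \code{writeRunConfig} returns \code{path} invisibly;
#'   \code{readRunConfig} returns a \linkS4class{RunConfig}.
#' @export
writeRunConfig <- function(cfg, path) {
  stopifnot(is(cfg, "RunConfig"))
  yaml::write_yaml(.configList(cfg), path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  x <- yaml::read_yaml(path)
  runConfig(seed = x$seed, noiseSigma = x$noise_sigma,
            pathlengths = unlist(x$pathlengths),
            dilutionGrid = as.numeric(x$dilution_grid),
            linearityTolerance = x$linearity_tolerance,
            lipemiaThreshold = x$lipemia_threshold,
            gradeBounds = as.numeric(x$grade_bounds),
            eq1Parse = x$eq1_parse)
}

#' Provenance fingerprint of a run configuration
#'
#' Polynomial rolling hash (mod 2^31 - 1) of the serialized
#' configuration, embedded in every output file for provenance. A
#' fingerprint, not a cryptographic hash.
#'
#' @param cfg a \linkS4class{RunConfig}.
#' @return 8-character hex string.
#' @export
configHash <- function(cfg) {
  s <- yaml::as.yaml(.configList(cfg))
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

.provenanceLine <- function(config) {
  cfg <- if (is.null(config)) runConfig() else config
  sprintf("# hemeQuant config_hash=%s registry_version=%s",
          configHash(cfg), REGISTRY_VERSION)
}

#' Write a plate CSV
#'
#' First column \code{wavelength_nm}, one column per sample id; a leading
#' \code{#} provenance comment embeds the config hash and registry
#' version. Comma-separated, dot decimal, UTF-8.
#'
#' @param x a \linkS4class{PlasmaPanel} or a named list of
#'   \linkS4class{MeasuredSpectrum} on a common grid.
#' @param path output file.
#' @param config optional \linkS4class{RunConfig} for provenance.
#' @return \code{path}, invisibly.
#' @export
writePlateCsv <- function(x, path, config = NULL) {
  spectra <- if (is(x, "PlasmaPanel"))
    lapply(x@samples, `[[`, "spectrum") else x
  if (length(spectra) == 0L) stop("no spectra to write")
  wl <- wavelengths(spectra[[1]])
  mat <- vapply(spectra, function(s) {
    if (!identical(wavelengths(s), wl))
      stop("all spectra must share one wavelength grid")
    absorbance(s)
  }, numeric(length(wl)))
  tab <- data.frame(wavelength_nm = wl, mat, check.names = FALSE)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(.provenanceLine(config), con)
  utils::write.csv(tab, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the sample sheet of a panel
#'
#' Columns: \code{sample_id, dilution_factor, pathlength_cm, state, seed}.
#'
#' @param panel a \linkS4class{PlasmaPanel}.
#' @param path output file.
#' @param config optional \linkS4class{RunConfig}.
#' @return \code{path}, invisibly.
#' @export
writeSampleSheet <- function(panel, path, config = NULL) {
  stopifnot(is(panel, "PlasmaPanel"))
  tab <- do.call(rbind, lapply(panel@samples, function(s) data.frame(
    sample_id = s$id, dilution_factor = dilutionFactor(s$spectrum),
    pathlength_cm = pathlength(s$spectrum), state = s$state,
    seed = s$spectrum@seed)))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(.provenanceLine(config), con)
  utils::write.csv(tab, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSampleSheet
#' @export
readSampleSheet <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write panel ground truth as CSV
#'
#' @param panel a \linkS4class{PlasmaPanel}.
#' @param path output file.
#' @param config optional \linkS4class{RunConfig}.
#' @return \code{path}, invisibly.
#' @export
writeGroundTruth <- function(panel, path, config = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(.provenanceLine(config), con)
  utils::write.csv(panelGroundTruth(panel), con, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a plate CSV
#'
#' Expects a header \code{wavelength_nm, <sample ids...>} (leading
#' \code{#} comment lines are skipped) and a numeric body with strictly
#' increasing wavelengths. When a sample sheet is given, per-sample
#' dilution factor and pathlength are joined in; a sheet naming an unknown
#' sample id is an error.
#'
#' @param path plate CSV path.
#' @param sampleSheet optional data.frame from
#'   \code{\link{readSampleSheet}}.
#' @return Named list of \linkS4class{MeasuredSpectrum}.
#' @export
readPlateCsv <- function(path, sampleSheet = NULL) {
  tab <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  if (names(tab)[1] != "wavelength_nm")
    stop("first column must be 'wavelength_nm'")
  if (!all(vapply(tab, is.numeric, logical(1))))
    stop("plate CSV body must be numeric")
  wl <- tab[[1]]
  if (is.unsorted(wl, strictly = TRUE))
    stop("wavelengths must be strictly increasing")
  ids <- names(tab)[-1]
  if (!is.null(sampleSheet)) {
    unknown <- setdiff(sampleSheet$sample_id, ids)
    if (length(unknown))
      stop("sample sheet names unknown sample id(s): ",
           paste(unknown, collapse = ", "))
  }
  out <- lapply(ids, function(id) {
    df <- 1; pl <- PATHLENGTH_100UL
    if (!is.null(sampleSheet) && id %in% sampleSheet$sample_id) {
      row <- sampleSheet[sampleSheet$sample_id == id, , drop = FALSE][1, ]
      if (!is.null(row$dilution_factor)) df <- row$dilution_factor
      if (!is.null(row$pathlength_cm)) pl <- row$pathlength_cm
    }
    new("MeasuredSpectrum", wavelengths = wl, absorbance = tab[[id]],
        pathlength = pl, dilutionFactor = df, noiseSigma = 0,
        seed = NA_integer_)
  })
  names(out) <- ids
  out
}

#' Write per-assay read-outs of a panel as CSV
#'
#' Long format: \code{sample_id, method, channel, signal,
#' dilution_factor}.
#'
#' @param panel a \linkS4class{PlasmaPanel}.
#' @param path output file.
#' @param config optional \linkS4class{RunConfig}.
#' @return \code{path}, invisibly.
#' @export
writeReadoutCsv <- function(panel, path, config = NULL) {
  stopifnot(is(panel, "PlasmaPanel"))
  rows <- do.call(rbind, lapply(panel@samples, function(s) {
    ro <- s$readouts@readouts
    method <- sub("_[^_]*$", "", names(ro))
    method[startsWith(names(ro), "apohrp")] <- "apohrp"
    data.frame(sample_id = s$id, method = method, channel = names(ro),
               signal = unname(ro),
               dilution_factor = dilutionFactor(s$readouts))
  }))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(.provenanceLine(config), con)
  utils::write.csv(rows, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeReadoutCsv
#' @export
readReadoutCsv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Batch quantification of a read-out table
#'
#' Applies the matching quantifier to each sample/method group of a
#' long-format read-out table (see \code{\link{writeReadoutCsv}}):
#' \code{direct} (A380 heme / A405 hemoglobin), \code{harboe} (the three
#' channels), \code{hak} (A400 apparent total heme), \code{sls}
#' (A395 heme / A413 hemoglobin), \code{pyridine} (linear-fit evaluation
#' of the reduced 556 nm channel), \code{apohrp} (nM identity with TMB
#' range flags).
#'
#' @param readouts data.frame from \code{\link{readReadoutCsv}}.
#' @param registry the \linkS4class{MethodRegistry}.
#' @return data.frame: sample_id, method, analyte, concentration, unit,
#'   flags (semicolon-joined).
#' @export
quantifyReadouts <- function(readouts, registry = methodRegistry()) {
  need <- c("sample_id", "method", "channel", "signal", "dilution_factor")
  if (!all(need %in% names(readouts)))
    stop("readout table must have columns: ", paste(need, collapse = ", "))
  out <- list()
  for (sid in unique(readouts$sample_id)) {
    sub <- readouts[readouts$sample_id == sid, , drop = FALSE]
    get1 <- function(ch) {
      i <- match(ch, sub$channel)
      if (is.na(i)) NA_real_ else sub$signal[i]
    }
    df1 <- function(ch) {
      i <- match(ch, sub$channel)
      if (is.na(i)) 1 else sub$dilution_factor[i]
    }
    res <- list()
    if (!is.na(get1("direct_A380")))
      res <- c(res, uvvisDirect("heme", get1("direct_A380"),
                                df1("direct_A380"), registry))
    if (!is.na(get1("direct_A405")))
      res <- c(res, uvvisDirect("hemoglobin", get1("direct_A405"),
                                df1("direct_A405"), registry))
    if (!anyNA(c(get1("harboe_A380"), get1("harboe_A415"),
                 get1("harboe_A450"))))
      res <- c(res, harboeHb(get1("harboe_A380"), get1("harboe_A415"),
                             get1("harboe_A450"), df1("harboe_A415"),
                             registry))
    if (!is.na(get1("hak_A400")))
      res <- c(res, hemeAssayKitTotal(max(0, get1("hak_A400")),
                                      df1("hak_A400"), registry))
    if (!is.na(get1("sls_A395")))
      res <- c(res, slsModified("heme", get1("sls_A395"),
                                dilutionFactor = df1("sls_A395"),
                                registry = registry))
    if (!is.na(get1("sls_A413")))
      res <- c(res, slsModified("hemoglobin", get1("sls_A413"),
                                dilutionFactor = df1("sls_A413"),
                                registry = registry))
    if (!is.na(get1("pyridine_A556_reduced")))
      res <- c(res, pyridineHemochromogen(
        c(pyridine_A556_reduced = get1("pyridine_A556_reduced")),
        "linear_fit", 1, df1("pyridine_A556_reduced"), registry))
    if (!is.na(get1("apohrp_apparent_heme_nM")))
      res <- c(res, apoHrpQuantify(max(0, get1("apohrp_apparent_heme_nM")),
                                   "TMB", registry))
    for (r in res)
      out[[length(out) + 1L]] <- data.frame(
        sample_id = sid, method = r@method, analyte = r@analyte,
        concentration = r@concentration, unit = r@unit,
        flags = paste(r@flags, collapse = ";"))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a panel report as TSV and JSON
#'
#' The TSV carries machine-readable flags as a semicolon-joined token
#' column plus a provenance comment line; the JSON sidecar embeds the
#' config hash and registry version.
#'
#' @param report data.frame from \code{\link{analyzePanel}} or
#'   \code{\link{reportFromFiles}}.
#' @param pathTsv,pathJson output paths (either may be NULL to skip).
#' @param config optional \linkS4class{RunConfig}.
#' @return Invisibly, a list of the written paths.
#' @export
writeReport <- function(report, pathTsv = NULL, pathJson = NULL,
                        config = NULL) {
  if (!is.null(pathTsv)) {
    con <- file(pathTsv, "w", encoding = "UTF-8")
    writeLines(.provenanceLine(config), con)
    utils::write.table(report, con, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    close(con)
  }
  if (!is.null(pathJson)) {
    cfg <- if (is.null(config)) runConfig() else config
    obj <- list(config_hash = configHash(cfg),
                registry_version = REGISTRY_VERSION,
                samples = report)
    jsonlite::write_json(obj, pathJson, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(list(tsv = pathTsv, json = pathJson))
}

#' Panel report from measured files
#'
#' The measured-data path of the pipeline: reads a plate CSV (spectra at
#' the sample-sheet dilution), the sample sheet, and a read-out CSV
#' carrying the kit 400 nm channel at its own dilution; quantifies
#' hemoglobin with the Harboe equation from the spectrum, classifies each
#' sample and estimates labile heme with the combined estimator.
#'
#' @param platePath,sheetPath,readoutPath input CSVs.
#' @param config a \linkS4class{RunConfig} (thresholds, parse mode).
#' @return A report data.frame as in \code{\link{analyzePanel}}.
#' @export
reportFromFiles <- function(platePath, sheetPath, readoutPath,
                            config = runConfig()) {
  sheet <- readSampleSheet(sheetPath)
  spectra <- readPlateCsv(platePath, sheet)
  readouts <- readReadoutCsv(readoutPath)
  registry <- methodRegistry()
  rows <- lapply(names(spectra), function(id) {
    sp <- spectra[[id]]
    wl <- wavelengths(sp)
    idx <- vapply(c(380, 415, 450), function(l) which.min(abs(wl - l)),
                  integer(1))
    a <- absorbance(sp)
    hb <- harboeHb(max(0, a[idx[1]]), max(0, a[idx[2]]), max(0, a[idx[3]]),
                   dilutionFactor(sp), registry)
    cls <- classifySample(sp, concentration(hb),
                          lipemiaThreshold = config@lipemiaThreshold,
                          gradeBounds = config@gradeBounds)
    sub <- readouts[readouts$sample_id == id &
                    readouts$channel == "hak_A400", , drop = FALSE]
    if (!isQuantifiable(cls) || nrow(sub) == 0L) {
      fl <- if (!isQuantifiable(cls)) "lipemic;not_quantifiable"
            else "missing_kit_channel"
      return(data.frame(sample_id = id,
        df_harboe = dilutionFactor(sp), df_hak = NA_real_,
        c_hb_uM = if (isQuantifiable(cls)) concentration(hb) else NA_real_,
        c_labile_heme_uM = NA_real_,
        grade = if (isQuantifiable(cls)) grade(cls) else NA_character_,
        icteric = isIcteric(cls), lipemic = isLipemic(cls),
        quantifiable = FALSE, flags = fl))
    }
    lab <- estimateLabileHeme(max(0, sub$signal[1]),
                              sub$dilution_factor[1],
                              max(0, concentration(hb)),
                              config@eq1Parse, registry)
    data.frame(sample_id = id, df_harboe = dilutionFactor(sp),
               df_hak = sub$dilution_factor[1],
               c_hb_uM = concentration(hb),
               c_labile_heme_uM = concentration(lab), grade = grade(cls),
               icteric = isIcteric(cls), lipemic = FALSE,
               quantifiable = TRUE,
               flags = paste(unique(c(flags(hb), flags(lab))),
                             collapse = ";"))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
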