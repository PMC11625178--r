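#' @include AllClasses.R AllGenerics.R componentLibrary.R registry.R
NULL

# evaluate under a seed without disturbing the caller's RNG stream;
# seed = NULL leaves the global stream untouched (and draws from it)
.withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# noiseless Beer-Lambert mixture on the library grid, assay-side (diluted)
.mixtureAbsorbance <- function(comp, library, pathlength, df) {
  co <- library@coefficients
  a <- pathlength / df * (
    co[, "labile_heme"] * comp@labileHeme +
    co[, "hemoglobin"] * comp@hb +
    co[, "bilirubin"] * comp@bilirubin +
    co[, "turbidity"] * comp@turbidity
  )
  if (comp@interactionCoeff != 0) {
    cross <- comp@interactionCoeff * (comp@hb / df) * (comp@labileHeme / df)
    a <- a + pathlength * cross * .gauss(library@wavelengths, 405, 20)
  }
  a
}

#' Simulate an absorbance spectrum
#'
#' Beer--Lambert forward model: the spectrum of a diluted sample is the
#' pathlength times the concentration-weighted sum of the component
#' spectra, divided by the dilution factor, plus the optional hyperchromic
#' heme--hemoglobin cross term at 405 nm and independent Gaussian noise per
#' wavelength. Deterministic given \code{seed}; an all-zero composition at
#' zero noise gives a flat zero spectrum.
#'
#' @param comp a \linkS4class{SampleComposition}.
#' @param library a \linkS4class{ComponentLibrary} (built on demand when
#'   NULL).
#' @param pathlength cm (> 0); default the 100 uL well format.
#' @param dilutionFactor >= 1.
#' @param sigma Gaussian noise standard deviation, AU (>= 0).
#' @param seed integer noise seed, or NULL to draw from the session RNG.
#' @return A \linkS4class{MeasuredSpectrum}.
#' @examples
#' sp <- simulateSpectrum(SampleComposition(hb = 5), sigma = 0)
#' max(absorbance(sp))
#' @export
simulateSpectrum <- function(comp, library = NULL,
                             pathlength = PATHLENGTH_100UL,
                             dilutionFactor = 1, sigma = 0, seed = NULL) {
  stopifnot(is(comp, "SampleComposition"))
  if (dilutionFactor < 1) stop("dilutionFactor must be >= 1")
  if (sigma < 0) stop("sigma must be >= 0")
  if (is.null(library)) library <- buildComponentLibrary()
  a <- .mixtureAbsorbance(comp, library, pathlength, dilutionFactor)
  if (sigma > 0)
    a <- a + .withSeed(seed, stats::rnorm(length(a), 0, sigma))
  new("MeasuredSpectrum", wavelengths = library@wavelengths, absorbance = a,
      pathlength = pathlength, dilutionFactor = dilutionFactor,
      noiseSigma = sigma,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Simulate per-assay scalar read-outs
#'
#' Generates every assay channel from one ground-truth composition. Each
#' scalar channel is the exact inverse of the corresponding published
#' evaluation equation (clamped at 0 AU so all signals are non-negative at
#' zero noise; the clamp only engages below each method's valid range), so
#' quantifier-after-forward round trips recover truth exactly:
#' \itemize{
#'   \item \code{direct_A380} = 0.029 c_heme/DF - 0.170;
#'     \code{direct_A405} = 0.158 c_hb/DF - 0.007;
#'   \item \code{harboe_A380/A415/A450}: spectral model at the 100 uL
#'     pathlength (the polychromatic equation is its exact inverse);
#'   \item \code{hak_A400} = (c_heme - 4.85 + 2.59 c_hb/DF) / (25.64 DF),
#'     the inverse of the combined labile-heme estimator;
#'   \item pyridine hemochromogen channels at 1 cm: reduced
#'     \code{A556} = 0.0341 (4 c_hb + c_heme)/DF per the heme extinction
#'     coefficient, \code{A557} alongside, \code{A540} placed so the
#'     557-540 difference obeys its 23.98 mM^-1 cm^-1 coefficient, and an
#'     oxidized-state channel;
#'   \item \code{sls_A395}/\code{sls_A413}: the surfactant-method curves;
#'   \item \code{apohrp_apparent_heme_nM} = c_heme[nM]/DF +
#'     3.629 c_hb[nM]/DF + 21.86, the hemoglobin cross-reactivity relation.
#' }
#' Noise is independent Gaussian per channel in the channel's native units.
#'
#' @param comp a \linkS4class{SampleComposition}.
#' @param sigma per-channel noise SD (>= 0).
#' @param seed integer seed, or NULL.
#' @param dilutionFactor >= 1, the dilution at which channels are read.
#' @param library component library for the spectral (polychromatic)
#'   channels.
#' @param registry the \linkS4class{MethodRegistry}.
#' @return An \linkS4class{AssayReadoutSet}.
#' @export
simulateAssayReadouts <- function(comp, sigma = 0, seed = NULL,
                                  dilutionFactor = 1, library = NULL,
                                  registry = methodRegistry()) {
  stopifnot(is(comp, "SampleComposition"))
  if (sigma < 0) stop("sigma must be >= 0")
  if (dilutionFactor < 1) stop("dilutionFactor must be >= 1")
  if (is.null(library)) library <- buildComponentLibrary()
  df <- dilutionFactor
  k <- registry@constants
  hemeEq <- totalHeme(comp) # 4 per tetramer + labile pool

  harboe <- .mixtureAbsorbance(comp, library, PATHLENGTH_100UL, df)
  idx <- match(c(380, 415, 450), library@wavelengths)
  if (anyNA(idx)) stop("library grid lacks the 380/415/450 nm channels")

  a556 <- k$eps556_heme / 1000 * hemeEq / df
  a557 <- a556
  vals <- c(
    direct_A380 = max(0, 0.029 * comp@labileHeme / df - 0.170),
    direct_A405 = max(0, 0.158 * comp@hb / df - 0.007),
    harboe_A380 = harboe[idx[1]],
    harboe_A415 = harboe[idx[2]],
    harboe_A450 = harboe[idx[3]],
    hak_A400 = max(0, (comp@labileHeme - k$eq1_offset +
                       k$eq1_hb_coeff * comp@hb / df) /
                      (k$eq1_kit_slope * df)),
    pyridine_A556_reduced = a556,
    pyridine_A556_oxidized = 0.6 * a556,
    pyridine_A557_reduced = a557,
    pyridine_A540_reduced = a557 - k$eps557_540 / 1000 * hemeEq / df,
    sls_A395 = 0.020 * comp@labileHeme / df + 0.010,
    sls_A413 = 0.150 * comp@hb / df + 0.005,
    apohrp_apparent_heme_nM = 1000 * comp@labileHeme / df +
      k$apohrp_hb_slope * 1000 * comp@hb / df + k$apohrp_hb_intercept
  )
  if (sigma > 0)
    vals <- vals + .withSeed(seed, stats::rnorm(length(vals), 0, sigma))
  new("AssayReadoutSet", readouts = vals, dilutionFactor = df)
}

# state-specific log-uniform concentration ranges for plasma panels;
# anchored to the plasma-panel observations: non-hemolytic Hb < 5 uM,
# severe Hb > 100 uM (up to ~1080), heme 20-44 uM in low-Hb samples and
# up to ~1056 uM in hemoglobin-rich ones; icteric samples add bilirubin,
# lipemic samples add turbidity and are not quantifiable
.PANEL_STATES <- list(
  `non-hemolytic` = list(hb = c(0.3, 5), heme = c(20, 44),
                         bilirubin = NULL, turbidity = NULL),
  mild = list(hb = c(5, 100), heme = c(20, 250),
              bilirubin = NULL, turbidity = NULL),
  severe = list(hb = c(100, 1080), heme = c(154, 1056),
                bilirubin = NULL, turbidity = NULL),
  icteric = list(hb = c(0.3, 3), heme = c(30, 44),
                 bilirubin = c(50, 300), turbidity = NULL),
  lipemic = list(hb = c(0.3, 5), heme = c(20, 44),
                 bilirubin = NULL, turbidity = c(0.5, 5))
)

.logUniform <- function(n, range)
  exp(stats::runif(n, log(range[1]), log(range[2])))

#' Simulate a plasma sample panel with known ground truth
#'
#' Draws \code{n} samples from the five plasma states
#' (\code{non-hemolytic}, \code{mild}, \code{severe}, \code{icteric},
#' \code{lipemic}) with the given weights; concentrations are log-uniform
#' within state-specific ranges (non-hemolytic Hb < 5 uM; severe
#' Hb > 100 uM; icteric adds bilirubin; lipemic adds turbidity). For each
#' sample an undiluted spectrum and read-out set are generated; the
#' ground-truth composition is retained.
#'
#' @param n number of samples (>= 1).
#' @param stateWeights named non-negative weights over the five states,
#'   summing to 1.
#' @param seed integer panel seed; the panel is bit-reproducible given it.
#' @param sigma noise SD, AU (default 0.005, typical plate-reader
#'   precision).
#' @param library component library.
#' @param pathlength cm for the panel spectra.
#' @return A \linkS4class{PlasmaPanel}.
#' @examples
#' pan <- simulatePlasmaPanel(5, seed = 1)
#' pan
#' @export
simulatePlasmaPanel <- function(n,
    stateWeights = c(`non-hemolytic` = 0.3, mild = 0.3, severe = 0.15,
                     icteric = 0.15, lipemic = 0.1),
    seed = 1L, sigma = 0.005, library = NULL,
    pathlength = PATHLENGTH_100UL) {
  if (n < 1) stop("n must be >= 1")
  states <- names(.PANEL_STATES)
  if (is.null(names(stateWeights)) ||
      !all(names(stateWeights) %in% states) ||
      any(stateWeights < 0) ||
      abs(sum(stateWeights) - 1) > 1e-8)
    stop("stateWeights must be named over the five plasma states, ",
         "non-negative, and sum to 1")
  if (is.null(library)) library <- buildComponentLibrary()
  w <- setNames(numeric(length(states)), states)
  w[names(stateWeights)] <- stateWeights

  samples <- .withSeed(seed, {
    drawn <- sample(states, n, replace = TRUE, prob = w)
    lapply(seq_len(n), function(i) {
      st <- drawn[i]
      rg <- .PANEL_STATES[[st]]
      comp <- SampleComposition(
        labileHeme = .logUniform(1, rg$heme),
        hb = .logUniform(1, rg$hb),
        bilirubin = if (is.null(rg$bilirubin)) 0
                    else .logUniform(1, rg$bilirubin),
        turbidity = if (is.null(rg$turbidity)) 0
                    else .logUniform(1, rg$turbidity))
      sampleSeed <- as.integer((seed + 104729 * i) %% .Machine$integer.max)
      list(id = sprintf("S%03d", i), state = st, composition = comp,
           spectrum = simulateSpectrum(comp, library, pathlength, 1,
                                       sigma, sampleSeed),
           readouts = simulateAssayReadouts(comp, sigma, sampleSeed + 1L,
                                            1, library))
    })
  })
  names(samples) <- vapply(samples, `[[`, character(1), "id")
  new("PlasmaPanel", samples = samples, seed = as.integer(seed),
      noiseSigma = sigma, library = library)
}

#' Ground truth of a simulated panel as a data frame
#'
#' @param panel a \linkS4class{PlasmaPanel}.
#' @return data.frame with one row per sample: id, state, and the
#'   composition fields (including total heme equivalents).
#' @export
panelGroundTruth <- function(panel) {
  stopifnot(is(panel, "PlasmaPanel"))
  rows <- lapply(panel@samples, function(s) {
    cmp <- s$composition
    data.frame(sample_id = s$id, state = s$state,
               c_labile_heme_uM = cmp@labileHeme, c_hb_uM = cmp@hb,
               c_bilirubin_uM = cmp@bilirubin,
               turbidity_index = cmp@turbidity,
               c_total_heme_uM = totalHeme(cmp))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export a panel's spectra as a SummarizedExperiment
#'
#' Wavelength-by-sample absorbance matrix in the \code{absorbance} assay,
#' wavelengths in \code{rowData}, per-sample state, dilution factor,
#' pathlength and ground truth in \code{colData}.
#'
#' @param panel a \linkS4class{PlasmaPanel}.
#' @return A \link[SummarizedExperiment]{SummarizedExperiment}.
#' @export
panelToSummarizedExperiment <- function(panel) {
  stopifnot(is(panel, "PlasmaPanel"))
  mat <- vapply(panel@samples, function(s) absorbance(s$spectrum),
                numeric(length(wavelengths(panel@samples[[1]]$spectrum))))
  gt <- panelGroundTruth(panel)
  cd <- S4Vectors::DataFrame(
    state = gt$state,
    dilution_factor = vapply(panel@samples, function(s)
      dilutionFactor(s$spectrum), numeric(1)),
    pathlength_cm = vapply(panel@samples, function(s)
      pathlength(s$spectrum), numeric(1)),
    c_labile_heme_uM = gt$c_labile_heme_uM,
    c_hb_uM = gt$c_hb_uM,
    c_bilirubin_uM = gt$c_bilirubin_uM,
    turbidity_index = gt$turbidity_index,
    row.names = gt$sample_id)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(absorbance = mat),
    rowData = S4Vectors::DataFrame(
      wavelength_nm = wavelengths(panel@samples[[1]]$spectrum)),
    colData = cd)
}
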