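lib <- buildComponentLibrary()

test_that("component spectra have the documented band structure", {
  wl <- wavelengths(lib)
  heme <- componentSpectrum(lib, "labile_heme")
  hb <- componentSpectrum(lib, "hemoglobin")
  bil <- componentSpectrum(lib, "bilirubin")
  turb <- componentSpectrum(lib, "turbidity")

  expect_true(all(lib@coefficients >= 0))
  expect_equal(wl[which.max(heme)], 380)
  expect_true(wl[which.max(hb)] >= 405 && wl[which.max(hb)] <= 415)
  expect_true(wl[which.max(bil)] >= 450 && wl[which.max(bil)] <= 460)
  # turbidity is the only component alive at 700 nm
  at700 <- lib@coefficients[wl == 700, ]
  expect_gt(at700["turbidity"], 0.1)
  expect_true(all(at700[c("labile_heme", "hemoglobin", "bilirubin")] < 1e-6))

  expect_error(buildComponentLibrary(seq(350, 700)), "must cover")
})

test_that("Harboe is the exact inverse of a pure-hemoglobin spectrum", {
  for (chb in c(2, 5, 13)) {
    sp <- simulateSpectrum(SampleComposition(hb = chb), lib,
                           pathlength = PATHLENGTH_100UL, sigma = 0)
    a <- absorbance(sp)[match(c(380, 415, 450), wavelengths(sp))]
    expect_equal(concentration(harboeHb(a[1], a[2], a[3])), chb,
                 tolerance = 1e-3) # 0.1 % self-consistency
  }
})

test_that("simulated spectra obey the forward-model contracts", {
  # all-zero composition, zero noise -> flat zero spectrum
  z <- simulateSpectrum(SampleComposition(), lib, sigma = 0)
  expect_true(all(absorbance(z) == 0))

  # determinism: same seed, same spectrum (bit-identical)
  s1 <- simulateSpectrum(SampleComposition(labileHeme = 10), lib,
                         sigma = 0.01, seed = 11L)
  s2 <- simulateSpectrum(SampleComposition(labileHeme = 10), lib,
                         sigma = 0.01, seed = 11L)
  expect_identical(absorbance(s1), absorbance(s2))

  # dilution linearity at zero noise: every channel scales as 1/DF
  comp <- SampleComposition(labileHeme = 10, hb = 3, bilirubin = 2,
                            turbidity = 0.4)
  a1 <- absorbance(simulateSpectrum(comp, lib, sigma = 0))
  a2 <- absorbance(simulateSpectrum(comp, lib, dilutionFactor = 2,
                                    sigma = 0))
  expect_lt(max(abs(a2 - a1 / 2)), 1e-12)
  ro1 <- simulateAssayReadouts(comp, library = lib)@readouts
  ro2 <- simulateAssayReadouts(comp, dilutionFactor = 2,
                               library = lib)@readouts
  linear <- c("harboe_A380", "harboe_A415", "harboe_A450",
              "pyridine_A556_reduced", "pyridine_A556_oxidized",
              "pyridine_A557_reduced", "pyridine_A540_reduced")
  # (channels with affine intercepts or clamps are excluded by design)
  expect_lt(max(abs(ro2[linear] - ro1[linear] / 2)), 1e-12)

  expect_error(simulateSpectrum(comp, lib, sigma = -1), "sigma")
  expect_error(simulateSpectrum(comp, lib, dilutionFactor = 0.5),
               "dilutionFactor")
})

test_that("read-out channels encode heme-equivalent conservation", {
  # pyridine channel carries 4*c_hb + c_labile exactly at zero noise
  for (i in 1:10) {
    comp <- SampleComposition(labileHeme = i, hb = 2 * i)
    ro <- simulateAssayReadouts(comp, library = lib)
    enc <- readout(ro, "pyridine_A556_reduced") / (34.1 / 1000)
    expect_equal(enc, totalHeme(comp), tolerance = 1e-12)
    expect_equal(totalHeme(comp), 4 * (2 * i) + i)
  }
  # all channels non-negative at zero noise, across extreme compositions
  for (comp in list(SampleComposition(), SampleComposition(hb = 1000),
                    SampleComposition(labileHeme = 1000),
                    SampleComposition(bilirubin = 300, turbidity = 5))) {
    ro <- simulateAssayReadouts(comp, library = lib)
    expect_true(all(ro@readouts >= 0))
  }
  # apoHRP channel reproduces the cross-reactivity relation at blank
  blank <- simulateAssayReadouts(SampleComposition(), library = lib)
  expect_equal(readout(blank, "apohrp_apparent_heme_nM"), 21.86)
})

test_that("the hyperchromic cross term is off by default and additive", {
  base <- SampleComposition(labileHeme = 10, hb = 5)
  inter <- SampleComposition(labileHeme = 10, hb = 5,
                             interactionCoeff = 1e-3)
  a0 <- absorbance(simulateSpectrum(base, lib, sigma = 0))
  a1 <- absorbance(simulateSpectrum(inter, lib, sigma = 0))
  wl <- wavelengths(lib)
  expect_true(all(a1 >= a0))          # hyperchromic: absorbance increases
  expect_gt(a1[wl == 405] - a0[wl == 405], 0)
  expect_lt(a1[wl == 700] - a0[wl == 700], 1e-12) # localized near 405 nm
})

test_that("plasma panels respect state definitions and seeding", {
  sev <- simulatePlasmaPanel(40, c(severe = 1), seed = 5L, sigma = 0)
  gt <- panelGroundTruth(sev)
  expect_true(all(gt$c_hb_uM > 100))

  lip <- simulatePlasmaPanel(10, c(lipemic = 1), seed = 5L, sigma = 0)
  expect_true(all(panelGroundTruth(lip)$turbidity_index > 0))

  p1 <- simulatePlasmaPanel(25, seed = 9L)
  p2 <- simulatePlasmaPanel(25, seed = 9L)
  expect_identical(panelGroundTruth(p1), panelGroundTruth(p2))
  expect_identical(absorbance(panelSamples(p1)[[3]]$spectrum),
                   absorbance(panelSamples(p2)[[3]]$spectrum))

  expect_error(simulatePlasmaPanel(10, c(severe = 0.5)), "sum to 1")
  expect_error(simulatePlasmaPanel(0), "n must be")
})

test_that("panels export to a SummarizedExperiment", {
  pan <- simulatePlasmaPanel(6, seed = 2L, sigma = 0)
  se <- panelToSummarizedExperiment(pan)
  expect_s4_class(se, "SummarizedExperiment")
  expect_equal(dim(se), c(401L, 6L))
  expect_equal(SummarizedExperiment::assayNames(se), "absorbance")
  expect_true(all(c("state", "c_hb_uM") %in%
                  names(SummarizedExperiment::colData(se))))
})
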