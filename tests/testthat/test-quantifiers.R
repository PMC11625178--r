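test_that("direct UV/Vis inverts the published Soret curves", {
  expect_equal(concentration(uvvisDirect("heme", 0.99)), 40,
               tolerance = 1e-12)
  expect_equal(concentration(uvvisDirect("hemoglobin", 0.158 * 5 - 0.007)),
               5, tolerance = 1e-12)
  blank <- uvvisDirect("heme", 0)
  expect_equal(concentration(blank), 0.170 / 0.029, tolerance = 1e-12)
  expect_true("below_range" %in% flags(blank)) # 5.86 uM < 10 uM bound
  expect_error(uvvisDirect("heme", Inf), "finite")
})

test_that("Harboe equation matches hand arithmetic and flags its range", {
  expect_equal(concentration(harboeHb(0.5, 0.5, 0.5)), 0) # flat spectrum
  expect_equal(concentration(harboeHb(0, 1.0, 0)), 25.916,
               tolerance = 1e-12)
  expect_equal(concentration(harboeHb(0.2, 0.8, 0.1, dilutionFactor = 2)),
               33.6908, tolerance = 1e-12)
  expect_true("above_range" %in% flags(harboeHb(0, 2, 0)))
  expect_true("below_range" %in% flags(harboeHb(0.5, 0.5, 0.5)))
  expect_error(harboeHb(-0.1, 0.5, 0.2), ">= 0")
})

test_that("pyridine hemochromogen supports all five conventions", {
  expect_equal(concentration(pyridineHemochromogen(
    c(pyridine_A556_reduced = 0.341), "reduced_556_heme")), 10,
    tolerance = 1e-12)
  expect_equal(concentration(pyridineHemochromogen(
    c(pyridine_A557_reduced = 0.4398, pyridine_A540_reduced = 0.2),
    "difference_557_540")), 10, tolerance = 1e-12)
  hbres <- pyridineHemochromogen(c(pyridine_A556_reduced = 0.804),
                                 "reduced_556_hb")
  expect_equal(concentration(hbres), 10, tolerance = 1e-12)
  expect_equal(analyte(hbres), "hemoglobin")
  expect_equal(concentration(pyridineHemochromogen(
    c(pyridine_A557_reduced = 0.347), "published_557")), 10,
    tolerance = 1e-12)
  expect_equal(concentration(pyridineHemochromogen(
    c(pyridine_A556_reduced = 0.034 * 20 - 0.161), "linear_fit")), 20,
    tolerance = 1e-12)
  # pathlength scaling of the epsilon modes
  expect_equal(concentration(pyridineHemochromogen(
    c(pyridine_A556_reduced = 0.341), "reduced_556_heme",
    pathlength = 0.5)), 20, tolerance = 1e-12)
  expect_error(pyridineHemochromogen(c(pyridine_A556_reduced = 1),
                                     "difference_557_540"),
               "missing pyridine channel")
})

test_that("the earlier published 557 coefficient under-recovers", {
  # signals generated from the fitted linear heme curve; the published
  # epsilon-557 convention must read them systematically lower
  lv <- seq(7.5, 37.5, length.out = 13)
  for (cc in lv) {
    a <- 0.034 * cc - 0.161
    est_fit <- concentration(pyridineHemochromogen(
      c(pyridine_A556_reduced = a), "linear_fit"))
    est_pub <- concentration(pyridineHemochromogen(
      c(pyridine_A557_reduced = a), "published_557"))
    expect_lt(est_pub, est_fit)
  }
})

test_that("SLS and kit quantifiers invert their curves with range flags", {
  curve <- fitLinearCalibration(c(1, 3, 6), 0.15 * c(1, 3, 6) + 0.005,
                                analyte = "hemoglobin")
  sig <- curveSlope(curve) * 3 + curveIntercept(curve)
  expect_equal(concentration(slsModified("hemoglobin", sig, curve)), 3,
               tolerance = 1e-9)
  expect_error(slsModified("heme", sig, curve), "does not match")
  low <- slsModified("heme", 0.05)
  expect_true("below_range" %in% flags(low)) # below the 10 uM bound
  ok <- slsModified("hemoglobin", 0.15 * 6 + 0.005)
  expect_length(flags(ok), 0) # 6 uM sits on the published bound

  expect_equal(concentration(hemeAssayKitTotal(1.0)), 30.49,
               tolerance = 1e-12)
  expect_equal(concentration(hemeAssayKitTotal(0.5, dilutionFactor = 2)),
               2 * 25.64 * 0.5 + 4.85, tolerance = 1e-12)
  z <- hemeAssayKitTotal(0)
  expect_equal(concentration(z), 4.85, tolerance = 1e-12)
  expect_true("below_range" %in% flags(z))
})

test_that("reagent strips bin semiquantitatively with closed bounds", {
  expect_equal(as.character(hemastixClassify(0, 0)), "negative")
  expect_equal(as.character(hemastixClassify(500, 0)), "positive")
  expect_equal(as.character(hemastixClassify(0, 2500)), "saturated")
  # closed bin edges at the printed endpoints
  expect_equal(as.character(hemastixClassify(10, 0)), "positive")
  expect_equal(as.character(hemastixClassify(1000, 0)), "positive")
  expect_equal(as.character(hemastixClassify(0, 2.5)), "positive")
  expect_equal(as.character(hemastixClassify(0, 250)), "positive")
  expect_equal(as.character(hemastixClassify(1000.1, 0)), "saturated")
  expect_equal(as.character(hemastixClassify(5, 1)), "negative")
  expect_equal(attr(hemastixClassify(0, 0), "flags"), "semiquantitative")
  # invariant under concentration changes within one bin
  expect_equal(as.character(hemastixClassify(11, 0)),
               as.character(hemastixClassify(999, 0)))
})

test_that("apoHRP reports the signal identity with substrate ranges", {
  r <- apoHrpQuantify(40, "TMB")
  expect_equal(concentration(r), 40)
  expect_length(flags(r), 0)
  expect_true("below_range" %in% flags(apoHrpQuantify(25, "TMB")))
  expect_length(flags(apoHrpQuantify(25, "o-dianisidine")), 0)
  expect_error(apoHrpQuantify(10, "luminol"))

  expect_equal(apoHrpApparentHemeFromHb(0), 21.86)
  expect_equal(apoHrpApparentHemeFromHb(10), 58.15)
  expect_equal(apoHrpApparentHemeFromHb(100), 384.76)
})

test_that("every quantifier is strictly increasing in its signal", {
  sigs <- seq(0.05, 1, length.out = 9)
  asc <- function(x) all(diff(x) > 0)
  expect_true(asc(vapply(sigs, function(s)
    concentration(uvvisDirect("heme", s)), numeric(1))))
  expect_true(asc(vapply(sigs, function(s)
    concentration(harboeHb(0.1, 0.2 + s, 0.1)), numeric(1))))
  expect_true(asc(vapply(sigs, function(s)
    concentration(pyridineHemochromogen(
      c(pyridine_A556_reduced = s), "reduced_556_heme")), numeric(1))))
  expect_true(asc(vapply(sigs, function(s)
    concentration(hemeAssayKitTotal(s)), numeric(1))))
  expect_true(asc(vapply(sigs, function(s)
    concentration(slsModified("heme", s)), numeric(1))))
  expect_true(asc(vapply(sigs * 40, function(s)
    concentration(apoHrpQuantify(s)), numeric(1))))
})
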