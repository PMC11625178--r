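test_that("registry holds the published curves and constants", {
  reg <- methodRegistry()

  dh <- registryEntry(reg, "direct_heme_a380")
  expect_equal(curveSlope(dh), 0.029)
  expect_equal(curveIntercept(dh), -0.170)
  expect_equal(validRange(dh), c(10, 40))

  dhb <- registryEntry(reg, "direct_hb_a405")
  expect_equal(curveSlope(dhb), 0.158)
  expect_equal(validRange(dhb), c(1, 7))

  py <- registryEntry(reg, "pyridine_heme_linear")
  expect_equal(c(curveSlope(py), curveIntercept(py)), c(0.034, -0.161))
  expect_equal(validRange(py), c(7.5, 37.5))

  expect_equal(registryConstant(reg, "eps556_heme"), 34.1)
  expect_equal(registryConstant(reg, "eps556_hb"), 80.4)
  expect_equal(registryConstant(reg, "eps557"), 34.7)
  expect_equal(registryConstant(reg, "eps557_540"), 23.98)
  expect_equal(registryConstant(reg, "apohrp_hb_slope"), 3.629)
  expect_equal(registryConstant(reg, "apohrp_hb_intercept"), 21.86)
  expect_equal(registryConstant(reg, "hemastix_heme_range"), c(10, 1000))
  expect_equal(registryConstant(reg, "hemastix_hb_range"), c(2.5, 250))

  expect_equal(curveSlope(registryEntry(reg, "hplc_hb")), 35375434)
  expect_equal(curveIntercept(registryEntry(reg, "hplc_heme")), -15660327)
  expect_equal(validRange(registryEntry(reg, "esi_ms_heme")), c(0.8, 25))
  # the chromatographic unit ambiguity is surfaced in the note field
  expect_match(registryEntry(reg, "hplc_hb")@note, "rangeAlt")

  expect_error(registryEntry(reg, "nope"), "unknown registry entry")
  expect_error(registryConstant(reg, "nope"), "unknown registry constant")
})

test_that("registry JSON export is complete and machine-readable", {
  path <- withr::local_tempfile(fileext = ".json")
  registryToJson(path = path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$version, hemeQuant:::REGISTRY_VERSION)
  expect_true(all(c("direct_heme_a380", "harboe_hb", "hak_heme") %in%
                  names(parsed$entries)))
  expect_equal(parsed$entries$direct_heme_a380$slope, 0.029)
  expect_equal(parsed$constants$eq1_kit_slope, 25.64)
})
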