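test_that("ordinary least squares recovers exact and published lines", {
  cv <- fitLinearCalibration(c(1, 2, 3), c(3, 5, 7), analyte = "heme")
  expect_equal(curveSlope(cv), 2)
  expect_equal(curveIntercept(cv), 1)
  expect_equal(validRange(cv), c(1, 3))

  # regenerate points from the published direct-heme line and refit
  lv <- seq(10, 40, by = 5)
  cv2 <- fitLinearCalibration(lv, 0.029 * lv - 0.170, analyte = "heme")
  expect_equal(curveSlope(cv2), 0.029, tolerance = 1e-12)
  expect_equal(curveIntercept(cv2), -0.170, tolerance = 1e-12)

  expect_error(fitLinearCalibration(c(1, 2), c(1, 2)), "3 distinct")
  expect_error(fitLinearCalibration(c(1, 1, 1), c(1, 2, 3)), "3 distinct")
  expect_error(fitLinearCalibration(c(1, 2, 3), c(5, 5, 5)),
               "slope is zero")
})

test_that("calibration inversion scales with dilution and flags ranges", {
  curve <- registryEntry(methodRegistry(), "direct_heme_a380")
  expect_equal(concentration(applyCalibration(curve, 0.99)), 40,
               tolerance = 1e-12)
  expect_equal(concentration(applyCalibration(curve, 0.120)), 10,
               tolerance = 1e-12)
  r <- applyCalibration(curve, 0.120, dilutionFactor = 2)
  expect_equal(concentration(r), 20, tolerance = 1e-12)
  expect_length(flags(r), 0) # assay side 10 uM is in range

  low <- applyCalibration(curve, 0)
  expect_true("below_range" %in% flags(low))
  neg <- applyCalibration(curve, 0.1, dilutionFactor = 1)
  expect_false("negative_estimate" %in% flags(neg))
  # a signal below a positive intercept back-calculates negative
  neg2 <- applyCalibration(registryEntry(methodRegistry(),
                                         "sls_hb_a413"), 0.001)
  expect_true("negative_estimate" %in% flags(neg2))

  # inversion composed with the affine forward map is the identity
  set.seed(1)
  for (i in 1:20) {
    cc <- runif(1, 10, 40)
    df <- sample(c(1, 2, 4), 1)
    sig <- curveSlope(curve) * cc / df + curveIntercept(curve)
    expect_lt(relErr(concentration(applyCalibration(curve, sig, df)), cc),
              1e-12)
  }
})

test_that("recovery statistics match hand arithmetic", {
  expect_equal(recovery(10, 10), 100)
  expect_equal(recovery(10, 9), 90)
  expect_equal(recovery(4, 5), 125)
  expect_error(recovery(0, 1), "true > 0")

  mr <- meanRecovery(c(10, 20), c(10, 20))
  expect_equal(c(mr$mrr, mr$sd), c(100, 0))
  mr2 <- meanRecovery(c(10, 10), c(9, 11))
  expect_equal(mr2$mrr, 100)
  expect_equal(mr2$sd, sd(c(90, 110))) # 14.142...
  mr3 <- meanRecovery(10, 12)
  expect_equal(mr3$mrr, 120)
  expect_equal(mr3$sd, 0)
  expect_true("sd_undefined" %in% mr3$flags)
  expect_error(meanRecovery(numeric(), numeric()), "empty")
})

test_that("linearity assessment applies the 15 percent rule", {
  curve <- CalibrationCurve("m", "heme", "s", 1, 0, c(1, 8))
  lv <- 1:8

  full <- linearityAssessment(curve, lv, lv)
  expect_equal(full$linearRange, c(1, 8))
  expect_true(full$verdict)

  # interior point at 20 % deviation splits the range; longer side wins
  sig <- as.numeric(lv)
  sig[3] <- 3 * 1.20
  split <- linearityAssessment(curve, lv, sig)
  expect_equal(split$linearRange, c(4, 8))

  # a point at exactly 15 % deviation passes (boundary convention)
  sig2 <- as.numeric(lv)
  sig2[5] <- 5 * 1.15
  expect_equal(linearityAssessment(curve, lv, sig2)$linearRange, c(1, 8))

  # ties broken toward higher concentrations
  sig3 <- as.numeric(lv)
  sig3[4] <- 4 * 1.3
  tie <- linearityAssessment(curve, lv, sig3) # runs 1-3 and 5-8
  expect_equal(tie$linearRange, c(5, 8))

  none <- linearityAssessment(curve, lv, sig * 2)
  expect_length(none$linearRange, 0)
  expect_false(none$verdict)

  # monotone in tolerance: a larger tolerance never shrinks the range
  set.seed(7)
  for (i in 1:10) {
    noisy <- lv * runif(8, 0.7, 1.3)
    prev <- -1
    for (tol in c(5, 10, 15, 25, 40)) {
      la <- linearityAssessment(curve, lv, noisy, tolerance = tol)
      n <- sum(la$pass)
      len <- if (length(la$linearRange)) {
        idx <- which(lv >= la$linearRange[1] & lv <= la$linearRange[2])
        length(idx)
      } else 0
      expect_gte(len, prev)
      prev <- len
    }
  }
})

test_that("detection limits follow the 3.3/10 sigma-over-slope forms", {
  expect_equal(lodLoq(0.01, 0.1), c(lod = 0.33, loq = 1.0))
  expect_equal(lodLoq(0, 5), c(lod = 0, loq = 0))
  ll <- lodLoq(0.005, 0.029)
  expect_equal(unname(ll["lod"]), 3.3 * 0.005 / 0.029) # ~0.569 uM
  expect_lt(ll["lod"], ll["loq"])
  expect_error(lodLoq(0.01, 0), "nonzero")
  expect_error(lodLoq(-1, 1), ">= 0")
})
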