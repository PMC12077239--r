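# CT density calibration and density-modulus mapping.

test_that("phantom curve fit inverts the generating affine map", {
  d <- c(200, 800, 1250, 1750)
  cv <- fitPhantomCurve(d, 1.0123 * d + 93.0710)
  expect_equal(cv@slope, 1.0123, tolerance = 1e-12)
  expect_equal(cv@intercept, 93.0710, tolerance = 1e-9)
  # generic noiseless recovery for arbitrary curves
  set.seed(11)
  for (i in 1:10) {
    sl <- runif(1, 0.5, 2); ic <- runif(1, -200, 200)
    cv2 <- fitPhantomCurve(d, sl * d + ic)
    expect_equal(cv2@slope, sl, tolerance = 1e-9)
    expect_equal(cv2@intercept, ic, tolerance = 1e-6)
  }
})

test_that("noisy plug measurements recover the slope within the OLS band", {
  d <- c(200, 800, 1250, 1750)
  set.seed(7)
  slopes <- replicate(50, {
    hu <- 1.0123 * d + 93.0710 + rnorm(4, 0, 5)
    # independent OLS oracle
    slOracle <- sum((d - mean(d)) * (hu - mean(hu))) / sum((d - mean(d))^2)
    cv <- fitPhantomCurve(d, hu)
    expect_equal(cv@slope, slOracle, tolerance = 1e-12)
    cv@slope
  })
  expect_true(all(abs(slopes - 1.0123) < 0.02))
})

test_that("degenerate calibration inputs are rejected", {
  expect_error(fitPhantomCurve(200, 300), "invalid-input")
  expect_error(fitPhantomCurve(c(800, 200), c(900, 300)), "invalid-input")
  expect_error(fitPhantomCurve(c(200, 800), c(300, NA)), "invalid-input")
})

test_that("CT number maps to radiological density per the default curve", {
  expect_equal(round(huToRhoCt(1500)), 1390)            # threshold density
  expect_equal(huToRhoCt(93.0710), 0, tolerance = 1e-12)
  expect_equal(huToRhoCt(1105.37), (1105.37 - 93.0710) / 1.0123,
               tolerance = 1e-12)
  # exact round trip for arbitrary valid curves
  set.seed(3)
  for (i in 1:10) {
    cv <- fitPhantomCurve(c(100, 900), runif(1, 0.8, 1.5) * c(100, 900) +
                            runif(1, -50, 150))
    hu <- runif(20, -500, 3000)
    expect_equal(rhoCtToHu(huToRhoCt(hu, cv), cv), hu, tolerance = 1e-9)
  }
})

test_that("ash density conversion applies the affine law with a floor", {
  expect_equal(rhoCtToRhoAsh(0), 0.07895, tolerance = 1e-12)
  expect_equal(rhoCtToRhoAsh(1.38996), 0.8772 * 1.38996 + 0.07895,
               tolerance = 1e-12)
  expect_equal(rhoCtToRhoAsh(1.0), 0.95615, tolerance = 1e-9)
  # strongly negative calibrated densities clamp to the floor
  expect_equal(rhoCtToRhoAsh(-2), 0.01)
})

test_that("modulus law and region factors follow the power-law forms", {
  expect_equal(rhoAshToModulus(1), 3378)
  expect_equal(rhoAshToModulus(1, region = "sclerotic",
                               factors = regionFactors(aScl = 0.5)), 1689)
  # frozen oracle value: 3378 * 1.298223^1.52 (ash density at HU 1500)
  expect_equal(rhoAshToModulus(1.298223), 5022.854, tolerance = 1e-6)
  # non-tuned model leaves the lytic modulus unmodified
  expect_equal(rhoAshToModulus(1, region = "lytic",
                               factors = regionFactors(dLys = 0)), 3378)
})

test_that("modulus is monotone in density and ordered across regions", {
  rho <- seq(0.05, 2, length.out = 50)
  for (rg in c("plain", "sclerotic", "lytic")) {
    e <- rhoAshToModulus(rho, region = rg,
                         factors = regionFactors(0.3, 0.6))
    expect_true(all(diff(e) > 0))
    expect_true(all(e > 0))
  }
  ePlain <- rhoAshToModulus(1.2)
  # damage always softens; positive adaptive factor softens, negative
  # stiffens
  expect_lt(rhoAshToModulus(1.2, region = "lytic",
                            factors = regionFactors(dLys = 0.6)), ePlain)
  expect_lt(rhoAshToModulus(1.2, region = "sclerotic",
                            factors = regionFactors(aScl = 0.3)), ePlain)
  expect_gt(rhoAshToModulus(1.2, region = "sclerotic",
                            factors = regionFactors(aScl = -0.5)), ePlain)
})

test_that("factors outside their invariant ranges are rejected", {
  expect_error(regionFactors(aScl = 0.6), "aScl")
  expect_error(regionFactors(aScl = -1.2), "aScl")
  expect_error(regionFactors(dLys = 0.96), "dLys")
  expect_error(regionFactors(dLys = -0.1), "dLys")
})

test_that("adaptive-factor law clamps to its range", {
  expect_equal(asclFromVscl(0), -1)
  expect_equal(asclFromVscl(0.5), 0.5)
  # zero crossing of the raw line at 184.55 / 994.23
  expect_equal(asclFromVscl(184.55 / 994.23), 0, tolerance = 1e-9)
  expect_true(all(asclFromVscl(seq(0, 1, 0.01)) >= -1))
  expect_true(all(asclFromVscl(seq(0, 1, 0.01)) <= 0.5))
  expect_error(asclFromVscl(1.2), "invalid-input")
})

test_that("calibration constants survive a YAML round trip", {
  tf <- withr::local_tempfile(fileext = ".yaml")
  writeCalibrationConfig(tf)
  cfg <- readCalibrationConfig(tf)
  expect_equal(cfg$curve@slope, 1.0123)
  expect_equal(cfg$curve@intercept, 93.0710)
  expect_equal(cfg$law@coefficient, 3378)
  expect_equal(cfg$law@exponent, 1.52)
  expect_equal(cfg$asclLaw@slope, 994.23)
  expect_equal(cfg$asclLaw@intercept, -184.55)
})

test_that("full HU-to-modulus chain handles the unit conversion", {
  out <- huToModulus(1500)
  expect_equal(out$rhoAsh, 0.8772 * huToRhoCt(1500) / 1000 + 0.07895,
               tolerance = 1e-12)
  expect_equal(out$modulus, 3378 * out$rhoAsh^1.52, tolerance = 1e-9)
  # air-like HU lands on the density floor, small positive modulus
  airE <- huToModulus(-1000)
  expect_gt(airE$modulus, 0)
  expect_lt(airE$modulus, 10)
})
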