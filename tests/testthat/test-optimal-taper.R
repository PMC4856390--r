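test_that("alpha fitting solves the volume equation and round-trips", {
  L <- 500; rL <- 0.5
  expect_equal(fitAlphaVolume(L, rL, pi * rL^2 * L), 0)
  expect_error(fitAlphaVolume(L, rL, 0.5 * pi * rL^2 * L), "infeasible")
  q <- makeQuadraticCable(300, 0.4, 0.01, 4001)
  expect_equal(fitAlphaVolume(300, 0.4, cableVolume(q)), 0.01,
               tolerance = 1e-6)
  # independent bracketing oracle for a volume slightly above the floor
  V <- pi * rL^2 * L * 1.01
  volOf <- function(a) pi * (a^2 * L^5 / 5 + 2 * a * rL * L^3 / 3 +
                             rL^2 * L)
  aBis <- uniroot(function(a) volOf(a) - V, c(0, 1), tol = 1e-15)$root
  expect_equal(fitAlphaVolume(L, rL, V), aBis, tolerance = 1e-9)
  expect_equal(volOf(fitAlphaVolume(L, rL, V)), V, tolerance = 1e-9)
})

test_that("proximal-radius fitting is exact and consistent with the
           volume fit", {
  expect_equal(fitAlphaProximal(10, 1, 101), 1)
  expect_equal(fitAlphaProximal(10, 1, 1), 0)
  expect_error(fitAlphaProximal(10, 1, 0.5), "infeasible")
  q <- makeQuadraticCable(200, 0.3, fitAlphaProximal(200, 0.3, 2), 2001)
  expect_equal(profileRadius(q)[1], 2)
  # mutual consistency: volume of the proximal-fitted profile refits to
  # the same alpha
  expect_equal(fitAlphaVolume(200, 0.3, cableVolume(q)),
               fitAlphaProximal(200, 0.3, 2), tolerance = 1e-6)
})

test_that("transfer functional J reduces to the cylinder closed form and
           scales correctly", {
  r <- 1; L <- 1000
  cyl <- makeCylinder(L, r, 2001)
  lam_cm <- sqrt((r / 1e4) / (2 * 60 * 5e-4))
  closed <- lam_cm^(-5 / 2) * (1 - exp(-(L / 1e4) / lam_cm))
  expect_equal(transferFunctionalJ(cyl, flyParams, anchor = "none"),
               closed, tolerance = 1e-6)
  # lambda -> c lambda with x -> c x rescales the bare J by c^(-5/2)
  cc <- 1.7
  stretched <- makeCylinder(cc * L, cc^2 * r, 2001)
  expect_equal(transferFunctionalJ(stretched, flyParams, anchor = "none") /
                 transferFunctionalJ(cyl, flyParams, anchor = "none"),
               cc^(-5 / 2), tolerance = 1e-4)
  # anchored form: cylinder values coincide with the transfer-ratio form
  expect_equal(transferFunctionalJ(cyl, flyParams),
               transferRatioFunctional(cyl, flyParams), tolerance = 1e-9)
})

test_that("quadratic dominates equal-volume cylinder and frustum", {
  L <- 1000; rL <- 0.1; V <- 6 * pi * rL^2 * L
  a <- fitAlphaVolume(L, rL, V)
  quad <- makeQuadraticCable(L, rL, a, 2001)
  cyl <- makeCylinder(L, sqrt(V / (pi * L)), 2001)
  r0f <- (-rL + sqrt(rL^2 - 4 * (rL^2 - 3 * V / (pi * L)))) / 2
  fru <- makeFrustum(L, r0f, rL, 2001)
  expect_equal(cableVolume(cyl), V, tolerance = 1e-9)
  expect_equal(cableVolume(fru), V, tolerance = 1e-6)
  # leading-order functional, proximal anchor
  Jq <- transferFunctionalJ(quad, flyParams)
  expect_gt(Jq, transferFunctionalJ(cyl, flyParams))
  expect_gt(Jq, transferFunctionalJ(fru, flyParams))
  # oracle route: delivered voltage under a common somatic load
  r0q <- profileRadius(quad)[1]
  Jqo <- transferFunctionalNumeric(quad, flyParams, n = 2001,
                                   loadRadius = r0q)
  expect_gt(Jqo, transferFunctionalNumeric(cyl, flyParams, n = 2001,
                                           loadRadius = r0q))
  expect_gt(Jqo, transferFunctionalNumeric(fru, flyParams, n = 2001,
                                           loadRadius = r0q))
})

test_that("Euler-Lagrange residual is 2/7 for cylinders and ~0 for the
           stationary quadratic", {
  resC <- eulerLagrangeResidual(makeCylinder(500, 1, 501), flyParams,
                                n = 501)
  expect_equal(range(resC$residual), c(2 / 7, 2 / 7), tolerance = 1e-12)
  aEL <- alphaStationary(flyParams)
  q <- makeQuadraticCable(1000, 1e-8, aEL, 4001)
  res <- eulerLagrangeResidual(q, flyParams, n = 4001)
  interior <- res$x <= 800
  expect_lt(max(abs(res$residual[interior])), 1e-6)
})

test_that("the stationary quadratic has smaller EL residual than the
           equal-volume frustum", {
  aEL <- alphaStationary(flyParams)
  q <- makeQuadraticCable(1000, 0.05, aEL, 2001)
  V <- cableVolume(q)
  r0f <- (-0.05 + sqrt(0.05^2 - 4 * (0.05^2 - 3 * V / (pi * 1000)))) / 2
  fru <- makeFrustum(1000, r0f, 0.05, 2001)
  rq <- eulerLagrangeResidual(q, flyParams)
  rf <- eulerLagrangeResidual(fru, flyParams)
  expect_lt(sqrt(mean(rq$residual^2)), sqrt(mean(rf$residual^2)))
})

test_that("volume-preserving perturbations keep the contract", {
  q <- makeQuadraticCable(1000, 0.1, 5e-7, 1001)
  expect_equal(profileRadius(perturbVolumePreserving(q, 0, seed = 1)),
               profileRadius(resampleProfile(q, 1001)))
  V0 <- cableVolume(resampleProfile(q, 1001))
  for (s in c(1, 7, 23)) {
    pe <- perturbVolumePreserving(q, 0.02, seed = s)
    expect_equal(cableVolume(pe) / V0, 1, tolerance = 1e-9)
    expect_equal(rev(profileRadius(pe))[1], rev(profileRadius(q))[1])
    expect_equal(profileRadius(pe)[1], profileRadius(q)[1])
    expect_false(identical(profileRadius(pe),
                           profileRadius(resampleProfile(q, 1001))))
  }
  expect_identical(profileRadius(perturbVolumePreserving(q, 0.02, seed = 5)),
                   profileRadius(perturbVolumePreserving(q, 0.02, seed = 5)))
  expect_error(perturbVolumePreserving(makeCylinder(100, 0.01, 101), 5,
                                       seed = 1), "amplitude|volume")
})

test_that("summed transfer is locally maximal at the stationary taper", {
  st <- makeStationaryTaper(2000, flyParams, overhang = 100)
  T0 <- transferRatioFunctional(st, flyParams)
  fails <- 0
  for (s in 1:50) {
    pe <- perturbVolumePreserving(st, 0.02, seed = s)
    if (transferRatioFunctional(pe, flyParams) > T0 * (1 + 1e-7))
      fails <- fails + 1
  }
  expect_lte(fails, 2)    # ~95% of smooth perturbations do not improve it
})
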