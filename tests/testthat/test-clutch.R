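test_that("substrate spring conversion is linear with the documented scale", {
  p <- ClutchParams()
  # 20 kPa x 1 um contact = 0.02 N/m = 20 pN/nm (unit-conversion oracle)
  expect_equal(substrateSpring(scramCondition(20e3), p), 20)
  e1 <- substrateSpring(AdhesionCondition(5e3), p)
  expect_equal(substrateSpring(AdhesionCondition(10e3), p), 2 * e1)
  expect_equal(substrateSpring(AdhesionCondition(1e-3), p), 1e-6)
  p2 <- ClutchParams(adhesionRadius = 500)
  expect_equal(substrateSpring(scramCondition(20e3), p2), 10)
})

test_that("Bell slip bond and force-velocity relations match closed forms", {
  p <- ClutchParams()
  expect_equal(unbindingRate(0, p), p@kOff0)
  expect_equal(unbindingRate(p@bellForce, p), exp(1) * p@kOff0)
  expect_equal(unbindingRate(2 * p@bellForce, p), exp(2) * p@kOff0)
  expect_error(unbindingRate(-1, p), ">= 0")

  stall <- p@nMotors * p@motorStallForce
  expect_equal(retrogradeVelocity(0, p), p@unloadedVelocity)
  expect_equal(retrogradeVelocity(stall, p), 0)
  expect_equal(retrogradeVelocity(stall / 2, p), p@unloadedVelocity / 2)
  expect_warning(v <- retrogradeVelocity(stall * 1.1, p), "stall")
  expect_equal(v, 0)
})

test_that("nothing binds when the binding rate is zero", {
  s <- simulateTraction(scramCondition(20e3), fastClutch(), seed = 1,
                        kOn = 0)
  expect_equal(meanTraction(s), 0)
  expect_equal(meanVelocity(s), ClutchParams()@unloadedVelocity)
  expect_equal(boundFraction(s), 0)
})

test_that("runs are reproducible given the seed and differ across seeds", {
  a <- simulateTraction(scramCondition(15e3), fastClutch(), seed = 42)
  b <- simulateTraction(scramCondition(15e3), fastClutch(), seed = 42)
  c_ <- simulateTraction(scramCondition(15e3), fastClutch(), seed = 43)
  expect_identical(meanTraction(a), meanTraction(b))
  expect_identical(boundFraction(a), boundFraction(b))
  expect_false(meanTraction(a) == meanTraction(c_))
})

test_that("the elastic force balance holds to machine precision", {
  s <- simulateTraction(scramCondition(15e3), fastClutch(), seed = 7,
                        diagnostics = TRUE)
  expect_lt(attr(s, "maxBalanceError"), 1e-9)
})

test_that("traction stays within the ensemble stall bound", {
  p <- fastClutch()
  for (E in c(1e3, 2e4, 1e9)) {
    s <- simulateTraction(AdhesionCondition(E), p, seed = 3, trace = TRUE,
                          traceStride = 10L)
    expect_true(all(s@trace$traction_pN <=
                      p@nMotors * p@motorStallForce + 1e-9))
    expect_true(all(s@trace$traction_pN >= 0))
  }
})

test_that("motors-off occupancy matches the two-state oracle", {
  # with motors off no clutch is ever loaded, so per-clutch occupancy is the
  # bernoulli steady state k_on / (k_on + k_off0)
  p <- fastClutch(unloadedVelocity = 0)
  s <- simulateTraction(scramCondition(20e3), p, seed = 11, kOn = 0.3)
  expect_lt(abs(boundFraction(s) - 0.75), 3 * s@semBoundFraction)
  s2 <- simulateTraction(scramCondition(20e3), p, seed = 12, kOn = 0.1)
  expect_lt(abs(boundFraction(s2) - 0.5), 3 * s2@semBoundFraction)
})

test_that("stiffness sweeps reduce to replicate-averaged single runs", {
  p <- fastClutch()
  sw <- stiffnessSweep(15e3, havdiOccupancy = 0, params = p,
                       nReplicates = 3, seed = 5)
  expect_equal(nrow(sw), 1)
  # reproduce the replicate average from the sweep's own seed derivation
  set.seed(5L)
  seeds <- matrix(sample.int(.Machine$integer.max - 1L, 3), nrow = 1)
  tr <- vapply(seeds[1, ], function(sd)
    meanTraction(simulateTraction(scramCondition(15e3), p, seed = sd)),
    numeric(1))
  expect_equal(sw$mean_traction_pN, mean(tr))
  # determinism of the whole sweep
  expect_identical(sw, stiffnessSweep(15e3, 0, params = p,
                                      nReplicates = 3, seed = 5))
})

test_that("sweep errors name the offending condition", {
  expect_error(stiffnessSweep(numeric(0)), "length")
})
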