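test_that("elastic strain follows the exact exponential relaxation", {
  p <- NucleusParams()
  tauE <- p@nuclearViscosity / p@nuclearStiffness
  st <- NucleusState(elasticStrain = 0.8, plasticStrain = 0.1)
  # unloading: eps_e(t) = eps0 * exp(-t / tau_e), plastic untouched,
  # regardless of how the interval is subdivided
  one <- updateNucleus(st, 0, 3 * tauE, p)
  many <- st
  for (i in 1:30) many <- updateNucleus(many, 0, tauE / 10, p)
  expect_equal(elasticStrain(one), 0.8 * exp(-3), tolerance = 1e-12)
  expect_equal(elasticStrain(many), 0.8 * exp(-3), tolerance = 1e-12)
  expect_equal(plasticStrain(one), 0.1)
  # loading toward equilibrium traction / E_N
  ld <- updateNucleus(NucleusState(), p@yieldForce / 2, 10 * tauE, p)
  expect_equal(elasticStrain(ld), p@yieldForce / 2 / p@nuclearStiffness,
               tolerance = 1e-4)
})

test_that("plastic strain obeys the yield threshold and linear flow", {
  p <- NucleusParams()
  # below yield: exactly zero accrual
  st <- updateNucleus(NucleusState(), p@yieldForce * 0.99, 86400 * 10, p)
  expect_identical(plasticStrain(st), 0)
  # above yield: eps_p = (F - F_y) * T / eta_p with T in days
  f <- p@yieldForce + 0.52
  st2 <- updateNucleus(NucleusState(), f, 86400 * 10, p)
  expect_equal(plasticStrain(st2), 0.52 * 10 / p@plasticViscosity,
               tolerance = 1e-12)
})

test_that("plastic strain never decreases along random load trajectories", {
  p <- NucleusParams()
  set.seed(101)
  for (rep in 1:5) {
    st <- NucleusState()
    prev <- 0
    for (step in 1:50) {
      st <- updateNucleus(st, runif(1, 0, 10), 3600, p)
      expect_gte(plasticStrain(st), prev)
      prev <- plasticStrain(st)
    }
  }
})

test_that("flattening composes strains on the baseline", {
  p <- NucleusParams(baselineFlattening = 2)
  expect_equal(flattening(NucleusState(), params = p), 2)
  a <- flattening(NucleusState(elasticStrain = 0.5), params = p)
  b <- flattening(NucleusState(plasticStrain = 0.5), params = p)
  expect_equal(a, b)   # elastic and plastic strain contribute symmetrically
  expect_equal(flattening(NucleusState(elasticStrain = 0.2,
                                       plasticStrain = 0.3), params = p), 3)
})

test_that("elastic recovery is complete: flattening returns to the plastic floor", {
  p <- NucleusParams()
  st <- NucleusState(elasticStrain = 1.2, plasticStrain = 0.4)
  tauE <- p@nuclearViscosity / p@nuclearStiffness
  st <- updateNucleus(st, 0, 50 * tauE, p)
  expect_equal(flattening(st, params = p),
               p@baselineFlattening * (1 + 0.4), tolerance = 1e-9)
})

test_that("the flattening-to-YAP law is linear with a positive floor", {
  p <- YapParams()
  lam0 <- 2
  base <- yapTarget(lam0, p)
  expect_equal(base, p@slope * lam0 + p@intercept)
  # doubling the flattening excess doubles the target excess
  expect_equal(yapTarget(lam0 + 2, p) - base,
               2 * (yapTarget(lam0 + 1, p) - base))
  # strictly increasing above the floor
  lams <- seq(1.5, 6, by = 0.1)
  expect_true(all(diff(yapTarget(lams, p)) > 0))
  # floor keeps the ratio positive for extreme parameters
  expect_equal(yapTarget(1, YapParams(slope = 0.01, intercept = -1)), 0.1)
})

test_that("YAP relaxation is an exact exponential approach", {
  p <- YapParams()
  st <- YapState(ratio = 3)
  expect_equal(yapRatio(relaxYap(st, 3, 1000, p)), 3)  # fixed point
  out <- relaxYap(st, 1, 5 * p@relaxationTime, p)
  expect_lt(abs(yapRatio(out) - 1), 0.01 * 2)  # < 1% of the initial gap
  # per-step exactness against the closed form
  t <- 4567
  expect_equal(yapRatio(relaxYap(st, 1.3, t, p)),
               1.3 + (3 - 1.3) * exp(-t / p@relaxationTime),
               tolerance = 1e-12)
  # a 2 h time constant reaches steady state within a day
  expect_lt(exp(-86400 / p@relaxationTime), 1e-5)
})

test_that("line and relaxation-time parameters are recoverable from noisy data", {
  p <- YapParams()
  set.seed(202)
  # (slope, intercept) from noisy steady-state pairs, 2% noise
  lam <- runif(200, 2, 5)
  r <- yapTarget(lam, p) * (1 + rnorm(200, sd = 0.02))
  fit <- stats::lm(r ~ lam)
  expect_equal(unname(coef(fit)[2]), p@slope, tolerance = 0.1)
  expect_equal(unname(coef(fit)[1]), p@intercept, tolerance = 0.1 * 2.5)
  # tau_R from a noisy relaxation trajectory, 1% noise
  tt <- seq(0, 6 * p@relaxationTime, length.out = 120)
  traj <- 1.3 + (3 - 1.3) * exp(-tt / p@relaxationTime)
  noisy <- traj * (1 + rnorm(length(tt), sd = 0.01))
  nfit <- stats::nls(noisy ~ a + b * exp(-tt / tau),
                     start = list(a = 1, b = 2, tau = 5000))
  expect_equal(unname(coef(nfit)["tau"]), p@relaxationTime,
               tolerance = 0.1)
})

test_that("invalid nucleus and YAP inputs are rejected", {
  expect_error(updateNucleus(NucleusState(), -1, 10), "non-negative")
  expect_error(updateNucleus(NucleusState(), 5, -10), "positive")
  expect_error(relaxYap(YapState(ratio = 1), 1, 0), "positive")
  expect_error(yapTarget(0.5), ">= 1")
  expect_error(NucleusParams(baselineFlattening = 0.5))
  expect_error(NucleusParams(nuclearViscosity = 7.5 * 2 * 86400),
               "1 day")
  expect_error(YapParams(relaxationTime = 3 * 86400))
})
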