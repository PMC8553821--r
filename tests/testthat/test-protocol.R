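test_that("a pure soft run is its own baseline with zero residual", {
  res <- runProtocol(list(ProtocolStep(scramCondition(20e3), 3)),
                     clutchParams = fastClutch(), nReplicates = 2,
                     seed = 9)
  expect_identical(memoryResidual(res), 0)
  expect_equal(endpointRatio(res), res@baselineRatio)
  # time course is well formed
  expect_equal(length(res@timeGrid), length(yapRatio(res)))
  expect_equal(max(res@timeGrid), 3)
})

test_that("state carries across steps and the residual equals the plastic excess", {
  fc <- fastClutch()
  np <- NucleusParams()
  yp <- YapParams()
  res <- runProtocol(list(ProtocolStep(tcpCondition(), 10),
                          ProtocolStep(scramCondition(20e3), 5)),
                     clutchParams = fc, nucleusParams = np, yapParams = yp,
                     nReplicates = 2, seed = 21)
  # reproduce the cached TCP traction through the same public path
  cache <- new.env(parent = emptyenv())
  fTcp <- steadyTraction(tcpCondition(), fc, KonParams(), 2, 21, cache)
  epsP <- max(0, fTcp - np@yieldForce) * 10 / np@plasticViscosity
  expect_gt(epsP, 0)
  # elastic memory erased, plastic retained: residual = slope*lambda0*eps_p
  expect_equal(memoryResidual(res),
               yp@slope * np@baselineFlattening * epsP, tolerance = 0.01)
  # and the endpoint sits at the target of the plastically offset nucleus
  fSoft <- steadyTraction(scramCondition(20e3), fc, KonParams(), 2, 21,
                          cache)
  lamEnd <- np@baselineFlattening *
    (1 + epsP + fSoft / np@nuclearStiffness)
  expect_equal(endpointRatio(res), yapTarget(lamEnd, yp), tolerance = 0.01)
})

test_that("post-transfer YAP decays monotonically and plateaus within a day", {
  res <- runProtocol(list(ProtocolStep(tcpCondition(), 10),
                          ProtocolStep(havdiCondition(20e3), 10)),
                     clutchParams = fastClutch(), nReplicates = 2,
                     seed = 33)
  post <- res@timeGrid > 10
  r <- yapRatio(res)[post]
  expect_true(all(diff(r) <= 1e-9))
  drop <- r[1] - r[length(r)]
  expect_gt(drop, 0.1)
  atDay1 <- r[which.min(abs(res@timeGrid[post] - 11))]
  expect_lt(abs(atDay1 - r[length(r)]), 0.02 * drop)
})

test_that("the memory panel reproduces single runs and the HAVDI ordering", {
  fc <- fastClutch()
  pan <- memoryPanel(c(0, 1, 10), c(1, 3), clutchParams = fc,
                     nReplicates = 2, seed = 13)
  expect_setequal(unique(pan$condition), c("S/R", "H/R"))
  # zero dosing leaves no memory at all
  expect_true(all(pan$residual[pan$dosing_d == 0] == 0))
  # residual non-decreasing in dosing at fixed condition and post time
  for (cnd in unique(pan$condition)) {
    for (p in unique(pan$post_d)) {
      r <- pan$residual[pan$condition == cnd & pan$post_d == p]
      expect_true(all(diff(r) >= -1e-9))
    }
  }
  # HAVDI never retains more memory than Scram, and its absolute YAP level
  # is strictly lower after identical dosing
  for (d in c(1, 10)) {
    for (p in c(1, 3)) {
      rs <- pan[pan$dosing_d == d & pan$post_d == p, ]
      expect_lte(rs$residual[rs$condition == "H/R"],
                 rs$residual[rs$condition == "S/R"] + 0.005)
      expect_lt(rs$endpoint_R_NC[rs$condition == "H/R"],
                rs$endpoint_R_NC[rs$condition == "S/R"])
    }
  }
  # a one-cell panel agrees with runProtocol
  one <- memoryPanel(10, 3, conditions = list(scramCondition(20e3)),
                     clutchParams = fc, nReplicates = 2, seed = 13)
  direct <- runProtocol(list(ProtocolStep(tcpCondition(), 10),
                             ProtocolStep(scramCondition(20e3), 3)),
                        clutchParams = fc, nReplicates = 2, seed = 13)
  expect_equal(one$endpoint_R_NC, endpointRatio(direct))
  expect_equal(one$residual, memoryResidual(direct))
})

test_that("yield-force calibration tracks the soft-substrate traction", {
  fc <- fastClutch()
  np <- calibrateYieldForce(fc, nReplicates = 3, seed = 2)
  expect_s4_class(np, "NucleusParams")
  soft <- steadyTraction(scramCondition(20e3), fc, nReplicates = 3,
                         seed = 2)
  expect_equal(np@yieldForce, soft)
  stiff <- steadyTraction(tcpCondition(), fc, nReplicates = 3, seed = 2)
  expect_equal(np@plasticViscosity, (stiff - soft) * 10 / 0.5)
})

test_that("malformed protocols are rejected", {
  expect_error(runProtocol(list()), "non-empty")
  expect_error(ProtocolStep(tcpCondition(), 0), "duration")
  expect_error(ProtocolStep(tcpCondition(), -1), "duration")
})
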