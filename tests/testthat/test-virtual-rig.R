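test_that("analogue pre-application alone never generates current", {
  prot <- protocolFromEpochs(data.frame(
    label = "pre", duration_s = 10, gaba_M = 0, analogue_M = 10e-6))
  for (id in paperModelIds()) {
    mod <- makePaperModel(id)
    tr <- runProtocol(mod$scheme, mod$rates, prot, dtOut = 0.1)
    expect_true(all(traceCurrent(tr) == 0), label = id)
  }
  # ... and in scheme b all occupancy stays in R
  modb <- makePaperModel("b_compound5")
  trb <- runProtocol(modb$scheme, modb$rates, prot, dtOut = 0.1)
  occ <- occupancyMatrix(attr(trb, "trajectory"))
  expect_true(all(occ[, "R"] == 1))
})

test_that("agonist-only simulation reproduces the analytic desensitisation", {
  mod <- makePaperModel("a_wt")
  tr <- runProtocol(mod$scheme, mod$rates, concentrationProtocol(),
                    dtOut = 0.01)
  m <- measure(tr)
  # plateau from the equilibrium-ratio oracle; peak from the pre-desensitised
  # fast manifold (R, RA, RA* only)
  eq <- chainEquilibrium(mod$rates, 30e-6)
  w <- eq[c("R", "RA", "RA*")] / sum(eq[c("R", "RA", "RA*")])
  predDesens <- 100 * (1 - eq[["RA*"]] / w[["RA*"]])
  expect_equal(m@percentDesensitisation, predDesens, tolerance = 0.01)
  expect_equal(m@percentDesensitisation, 70, tolerance = 0.02)
  expect_gte(m@peak, m@steady)
})

test_that("protocol timing is respected and scale factors drop out", {
  mod <- makePaperModel("a_wt")
  prot <- concentrationProtocol()
  tr <- runProtocol(mod$scheme, mod$rates, prot, dtOut = 0.05)
  expect_equal(max(timePoints(tr)), sum(epochs(prot)$duration_s))
  # no current before co-application
  expect_true(all(traceCurrent(tr)[timePoints(tr) < 12] == 0))
  # normalization: all ratio measurements invariant under scaling
  trn <- runProtocol(mod$scheme, mod$rates, prot, dtOut = 0.05,
                     normalize = TRUE)
  expect_equal(max(traceCurrent(trn)), 1)
  expect_equal(measure(trn)@percentDesensitisation,
               measure(tr)@percentDesensitisation, tolerance = 1e-12)
})

test_that("measure implements the peak / 20-s steady-state convention", {
  # constant trace: no desensitisation
  const <- new("CurrentTrace", time = seq(0, 20, 0.01),
               current = rep(1, 2001), metadata = list())
  expect_equal(measure(const)@percentDesensitisation, 0)
  # plateau/peak = 0.32 corresponds to 68 % desensitisation
  tr <- syntheticDecayTrace(peak = 1, plateau = 0.32, tau = 3)
  expect_equal(measure(tr)@percentDesensitisation, 68, tolerance = 0.01)
  # monotone decay: peak >= steady
  m <- measure(tr)
  expect_gte(m@peak, m@steady)
  # zero trace: flagged undefined, not silently 0
  zero <- new("CurrentTrace", time = seq(0, 20, 0.1),
              current = rep(0, 201), metadata = list())
  expect_warning(mz <- measure(zero), "undefined")
  expect_true("undefined" %in% mz@flags)
  expect_true(is.na(mz@percentDesensitisation))
})

test_that("inhibition readouts compare matched control/test pairs", {
  mod <- makePaperModel("b_compound5")
  ctrl <- runProtocol(mod$scheme, mod$rates, concentrationProtocol(),
                      dtOut = 0.02)
  expect_equal(unname(inhibitionReadouts(ctrl, ctrl)), c(0, 0))
  tst <- runProtocol(mod$scheme, mod$rates,
                     concentrationProtocol(analogue = 1e-6), dtOut = 0.02)
  inh <- inhibitionReadouts(ctrl, tst)
  expect_gt(inh[["steady"]], inh[["peak"]])
  # mismatched protocols are rejected
  other <- runProtocol(mod$scheme, mod$rates,
                       concentrationProtocol(gaba = 10e-6), dtOut = 0.02)
  expect_error(inhibitionReadouts(ctrl, other), "protocol")
  expect_error(inhibitionReadouts(tst, ctrl), "analogue-free")
})

test_that("steady-state block exceeds peak block across the analogue range", {
  mod <- makePaperModel("b_compound5")
  ctrl <- runProtocol(mod$scheme, mod$rates, concentrationProtocol(),
                      dtOut = 0.02)
  grid <- 10^seq(-7, -4, length.out = 7)  # 0.1 to 100 uM
  prev <- c(peak = -Inf, steady = -Inf)
  for (P in grid) {
    tst <- runProtocol(mod$scheme, mod$rates,
                       concentrationProtocol(analogue = P), dtOut = 0.02)
    inh <- inhibitionReadouts(ctrl, tst)
    expect_gt(inh[["steady"]], inh[["peak"]])
    # inhibition is monotone non-decreasing in concentration
    expect_gte(inh[["peak"]], prev[["peak"]] - 1e-9)
    expect_gte(inh[["steady"]], prev[["steady"]] - 1e-9)
    prev <- inh
  }
  # saturating analogue (100 uM ~ 400x the steady-state midpoint): the
  # steady-state block approaches completeness while the peak, formed before
  # closed-state block develops, is barely touched
  sat <- runProtocol(mod$scheme, mod$rates,
                     concentrationProtocol(analogue = 1e-4), dtOut = 0.02)
  inhSat <- inhibitionReadouts(ctrl, sat)
  expect_gt(inhSat[["steady"]], 99)
  expect_lt(inhSat[["peak"]], 20)
})

test_that("optional exponential solution exchange slows the rising phase", {
  mod <- makePaperModel("a_wt")
  sharp <- runProtocol(mod$scheme, mod$rates, concentrationProtocol(),
                       dtOut = 0.02)
  slow <- runProtocol(mod$scheme, mod$rates,
                      concentrationProtocol(exchangeTau = 0.5), dtOut = 0.02)
  iOn <- which(timePoints(sharp) > 12.05 & timePoints(sharp) < 12.3)
  expect_true(all(traceCurrent(slow)[iOn] < traceCurrent(sharp)[iOn]))
  # but the steady state is unchanged
  expect_equal(measure(slow)@steady, measure(sharp)@steady, tolerance = 1e-3)
})
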