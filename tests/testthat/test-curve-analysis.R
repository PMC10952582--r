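test_that("weighted tau is the area-weighted mean of the two components", {
  expect_equal(weightedTau(1, 5, 1, 5), 5)
  expect_equal(weightedTau(3, 2, 1, 6), 3)
  expect_error(weightedTau(0, 1, 0, 2), "undefined")
  expect_error(weightedTau(-1, 1, 1, 2), "non-negative")
  # property: bounded by the components and invariant to amplitude scale
  set.seed(42)
  for (i in 1:50) {
    A <- runif(2, 0.01, 10)
    tau <- runif(2, 0.01, 10)
    tw <- weightedTau(A[1], tau[1], A[2], tau[2])
    expect_gte(tw, min(tau))
    expect_lte(tw, max(tau))
    expect_equal(weightedTau(7.3 * A[1], tau[1], 7.3 * A[2], tau[2]), tw)
  }
})

test_that("biexponential decay fits recover generating parameters", {
  tt <- seq(0, 20, by = 0.01)
  cur <- 0.5 * exp(-tt / 1) + 0.5 * exp(-tt / 6) + 0.2
  tr <- new("CurrentTrace", time = tt, current = cur, metadata = list())
  fd <- fitDecay(tr, window = c(0, 20))
  expect_false(fd@degenerate)
  expect_equal(fd@A1, 0.5, tolerance = 1e-4)
  expect_equal(fd@tau1, 1, tolerance = 1e-4)
  expect_equal(fd@A2, 0.5, tolerance = 1e-4)
  expect_equal(fd@tau2, 6, tolerance = 1e-4)
  expect_equal(fd@plateau, 0.2, tolerance = 1e-4)
  expect_equal(fd@tauw, 3.5, tolerance = 1e-4)
})

test_that("single-exponential input collapses cleanly to tauw = tau", {
  tr <- syntheticDecayTrace(peak = 1, plateau = 0.3, tau = 4)
  fd <- fitDecay(tr)
  expect_false(fd@degenerate)
  expect_equal(fd@tauw, 4, tolerance = 1e-3)
  expect_equal(fd@tau1, fd@tau2, tolerance = 0.05)
})

test_that("non-decaying traces are flagged degenerate", {
  flat <- new("CurrentTrace", time = seq(0, 10, 0.01),
              current = rep(0.8, 1001), metadata = list())
  fd <- fitDecay(flat, window = c(0, 10))
  expect_true(fd@degenerate)
  expect_true(is.na(fd@tauw))
})

test_that("simulated agonist current decays near the published wild-type rate", {
  mod <- makePaperModel("a_wt")
  tr <- runProtocol(mod$scheme, mod$rates, concentrationProtocol(),
                    dtOut = 0.01)
  fd <- fitDecay(tr)
  expect_equal(fd@tauw, 3.7, tolerance = 0.25)
})

test_that("Hill fits are exact on noise-free generated data", {
  concs <- 10^seq(-8, -4, length.out = 7)
  # half-inhibition forced at IC50
  expect_equal(hillResponse(1e-6, 6, 1), 0.5)
  expect_equal(hillResponse(0, 6.2, 1.7), 1)
  expect_lt(hillResponse(1, 6, 2), 1e-10)
  # round trip across Hill slopes
  for (n in c(0.5, 1, 2)) {
    tab <- genDoseResponse(6.2, n, concs)
    fit <- fitInhibition(tab)
    expect_equal(fit@pic50, 6.2, tolerance = 1e-6)
    expect_equal(fit@hillSlope, n, tolerance = 1e-4)
  }
  # all seven published steady-state potencies round-trip in pIC50
  pot <- potencyTable()
  for (i in seq_len(nrow(pot))) {
    p <- pot$steady_pic50[i]
    grid <- 10^seq(-p - 2.5, -p + 2.5, length.out = 7)
    fit <- fitInhibition(genDoseResponse(p, 1, grid))
    expect_equal(fit@pic50, p, tolerance = 1e-6,
                 label = sprintf("compound %s", pot$compound[i]))
  }
})

test_that("fitInhibition validates input and warns on rising data", {
  concs <- 10^seq(-8, -5, length.out = 6)
  expect_error(fitInhibition(data.frame(concentration_M = concs[1:3],
                                        response = c(1, .5, .1))),
               "at least 4")
  expect_warning(
    fitInhibition(data.frame(concentration_M = concs,
                             response = seq(0.2, 0.9, length.out = 6))),
    "monotone")
})

test_that("pIC50 transforms are exact and consistent with printed pairs", {
  expect_equal(pic50(1e-6), 6)
  expect_equal(pic50(1e-9), 9)
  expect_equal(ic50(7.3), 10^-7.3)
  expect_error(pic50(-1), "positive")
  x <- 10^-runif(20, 3, 9)
  expect_equal(ic50(pic50(x)), x, tolerance = 1e-15)
  # published pIC50/IC50 pairs agree within printed rounding
  pot <- potencyTable()
  expect_equal(ic50(pot$steady_pic50) * 1e6, pot$steady_ic50_uM,
               tolerance = 0.05)
})

test_that("ordinary least squares matches the closed form and a grid oracle", {
  # the wild-type/mutant desensitisation-decay proxy triple
  tab <- desensTauwTable()
  r <- linReg(tab$desens_percent, tab$tauw_s)
  expect_equal(r@slope, -0.104, tolerance = 5e-3)
  expect_equal(r@intercept, 11.23, tolerance = 5e-4)
  expect_equal(r@r2, 0.9738, tolerance = 5e-5)
  # collinear input
  expect_equal(linReg(1:5, 2 * (1:5) + 3)@r2, 1)
  # brute-force grid refinement around the OLS solution cannot beat it
  x <- c(68, 39, 89); y <- c(3.7, 7.4, 2.3)
  sse <- function(a, b) sum((y - a * x - b)^2)
  best <- c(r@slope, r@intercept)
  grid <- expand.grid(a = best[1] + seq(-0.01, 0.01, length.out = 41),
                      b = best[2] + seq(-0.5, 0.5, length.out = 41))
  sseGrid <- mapply(sse, grid$a, grid$b)
  expect_lte(sse(best[1], best[2]), min(sseGrid) + 1e-6)
  i <- which.min(sseGrid)
  expect_equal(grid$a[i], best[1], tolerance = 1e-6)
  expect_equal(grid$b[i], best[2], tolerance = 1e-6)
  # degenerate inputs
  expect_error(linReg(1:2, 1:2), "3 points")
  expect_error(linReg(rep(1, 4), 1:4), "variance")
})

test_that("dose-response pipeline rejects flat curves and orders tau-w", {
  moda <- makePaperModel("a_wt")
  grid <- 10^seq(-8, -5, length.out = 4)
  expect_warning(
    resa <- doseResponsePipeline(moda$scheme, moda$rates,
                                 concentrationProtocol(), grid,
                                 metric = "steady_state", dtOut = 0.05),
    "flat")
  expect_null(resa$fit)

  modc <- makePaperModel("c_compound6")
  grid6 <- 10^seq(-8, -4, length.out = 6)
  resc <- doseResponsePipeline(modc$scheme, modc$rates,
                               concentrationProtocol(), grid6,
                               metric = "tau_w", dtOut = 0.02)
  # decay acceleration: fractional tau-w decreases monotonically
  expect_true(all(diff(resc$table$response) < 0))
  expect_false(is.null(resc$fit))

  modb <- makePaperModel("b_compound5")
  resb <- doseResponsePipeline(modb$scheme, modb$rates,
                               concentrationProtocol(), grid6,
                               metric = "steady_state", dtOut = 0.02)
  expect_true(all(diff(resb$table$response) < 0))
  expect_true(resb$table$response[1] > 0.95)
  expect_true(resb$table$response[6] < 0.1)
})
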