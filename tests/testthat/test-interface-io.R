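test_that("trace files round-trip samples and metadata exactly", {
  mod <- makePaperModel("a_wt")
  prot <- concentrationProtocol(baseline = 0.5, preApplication = 1,
                                coApplication = 5, washout = 1)
  tr <- genTrace(mod$scheme, mod$rates, prot, noiseSd = 0.01, seed = 11,
                 dtOut = 0.01)
  path <- withr::local_tempfile(fileext = ".csv")
  writeTrace(tr, path)
  back <- readTrace(path)
  expect_identical(traceCurrent(back), traceCurrent(tr))
  expect_identical(timePoints(back), timePoints(tr))
  expect_identical(traceMetadata(back)$seed, 11)
  expect_identical(traceMetadata(back)$scheme_id, "a_wt")
  expect_equal(traceMetadata(back)$epochs$duration_s,
               epochs(prot)$duration_s)
})

test_that("malformed trace files fail with informative errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# gabakin trace v1", "t\tcurrent", "0\t1"), path)
  expect_error(readTrace(path), "time_s")
  writeLines(c("time_s\tcurrent", "0\t1", "0.1"), path)
  expect_error(readTrace(path), "ragged row.*line 3")
})

test_that("scheme configs round-trip and validate their schema", {
  mod <- makePaperModel("c_compound6")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeSchemeConfig(mod$scheme, mod$rates, path)
  back <- readSchemeConfig(path)
  expect_identical(schemeStates(back$scheme), schemeStates(mod$scheme))
  expect_identical(transitions(back$scheme), transitions(mod$scheme))
  expect_identical(rateValues(back$rates), rateValues(mod$rates))
  # schema violations are named
  cfg <- yaml::read_yaml(path)
  cfg$rates <- NULL
  yaml::write_yaml(cfg, path)
  expect_error(readSchemeConfig(path), "'rates'")
  expect_error(readSchemeConfig("/nonexistent/x.yaml"), "no such")
})

test_that("invalid user schemes are rejected by validity checks", {
  expect_error(kineticScheme(
    states = c("A", "A"), conducting = "A",
    transitions = data.frame(from = "A", to = "A", rate = "k",
                             ligand = "none"), resting = "A"),
    "unique")
  expect_error(kineticScheme(
    states = c("R", "O"), conducting = "O",
    transitions = data.frame(from = "R", to = "X", rate = "k",
                             ligand = "none")),
    "not declared")
  expect_error(rateSet(c(k = -1)), "positive")
})

test_that("the simulate subcommand writes a desensitising trace", {
  out <- withr::local_tempfile(fileext = ".csv")
  status <- suppressMessages(cliMain(c(
    "simulate", "--scheme", "b", "--gaba", "30e-6", "--analogue", "0",
    "--dt", "0.02", "--out", out)))
  expect_identical(status, 0L)
  expect_true(file.exists(out))
  tr <- readTrace(out)
  m <- measure(tr)
  expect_gt(m@peak, m@steady)
  # CLI output equals the direct library call
  mod <- makePaperModel("b_compound5")
  direct <- runProtocol(mod$scheme, mod$rates, concentrationProtocol(),
                        dtOut = 0.02)
  expect_identical(traceCurrent(tr), traceCurrent(direct))
})

test_that("the regress subcommand matches linReg on the packaged fixture", {
  tab <- system.file("extdata", "desens_tauw_wt_mutants.csv",
                     package = "gabakin")
  msgs <- capture_messages(
    status <- cliMain(c("regress", "--table", tab, "--x", "desens_percent",
                        "--y", "tauw_s")))
  expect_identical(status, 0L)
  r <- linReg(desensTauwTable()$desens_percent, desensTauwTable()$tauw_s)
  expect_match(paste(msgs, collapse = ""),
               sprintf("y = %.6gx", r@slope), fixed = TRUE)
  expect_match(paste(msgs, collapse = ""),
               sprintf("R^2 = %.6f", r@r2), fixed = TRUE)
})

test_that("hill-fit on an empty table exits non-zero without output", {
  tab <- withr::local_tempfile(fileext = ".csv")
  writeLines("concentration_M,response", tab)
  out <- file.path(withr::local_tempdir(), "report.txt")
  status <- suppressMessages(cliMain(c("hill-fit", "--table", tab,
                                       "--out", out)))
  expect_identical(status, 1L)
  expect_false(file.exists(out))
})

test_that("unknown subcommands and malformed flags fail cleanly", {
  expect_identical(suppressMessages(cliMain(character())), 1L)
  expect_identical(suppressMessages(cliMain("frobnicate")), 1L)
  expect_identical(suppressMessages(cliMain(c("simulate", "--scheme"))), 1L)
  expect_identical(suppressMessages(
    cliMain(c("simulate", "--gaba", "x", "--scheme", "a", "--out", "t"))), 1L)
})

test_that("synth subcommands generate reproducible artefacts", {
  out1 <- withr::local_tempfile(fileext = ".csv")
  out2 <- withr::local_tempfile(fileext = ".csv")
  args <- c("synth", "trace", "--scheme", "a", "--noise", "0.02",
            "--seed", "5", "--dt", "0.05", "--co", "5", "--pre", "1",
            "--baseline", "0.5", "--wash", "1")
  expect_identical(suppressMessages(cliMain(c(args, "--out", out1))), 0L)
  expect_identical(suppressMessages(cliMain(c(args, "--out", out2))), 0L)
  expect_identical(readLines(out1), readLines(out2))
  tabOut <- withr::local_tempfile(fileext = ".csv")
  expect_identical(suppressMessages(cliMain(c(
    "synth", "dose-response", "--pic50", "6.555", "--concs",
    "1e-8,1e-7,3e-7,1e-6,3e-6,1e-5,1e-4", "--out", tabOut))), 0L)
  fit <- fitInhibition(readDoseResponse(tabOut))
  expect_equal(fit@pic50, 6.555, tolerance = 1e-6)
})
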