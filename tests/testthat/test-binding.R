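wtParams <- function() kineticParams(1e5, 5e-3, 4e-3, 2e-3, 100)

test_that("the steady-state response has its textbook landmarks", {
  expect_equal(equilibriumResponse(14.6e-9, 14.6e-9, 100), 50)
  expect_equal(equilibriumResponse(0, 1e-8, 100), 0)
  expect_equal(equilibriumResponse(9 * 1e-8, 1e-8, 100), 90)
  expect_error(equilibriumResponse(1e-9, 0, 100), "kd")
  # strictly increasing in concentration and in rmax
  cs <- 10^seq(-10, -5, length.out = 20)
  expect_true(all(diff(equilibriumResponse(cs, 1e-8, 100)) > 0))
  expect_true(all(equilibriumResponse(cs, 1e-8, 120) >
                    equilibriumResponse(cs, 1e-8, 100)))
})

test_that("noiseless equilibrium fits recover the generating Kd", {
  ser <- generateEquilibriumSeries(kd = 14.6e-9, rmax = 100)
  fit <- fitEquilibrium(ser)
  expect_true(fit@converged)
  expect_lt(abs(fit@params[["kd"]] / 14.6e-9 - 1), 1e-3)
  expect_lt(abs(fit@params[["rmax"]] / 100 - 1), 1e-3)
  # half-saturation anchor: response rmax/2 at one concentration
  ser2 <- equilibriumSeries(c(1e-9, 2e-8, 1e-5),
                            c(100 * 1e-9 / (2.1e-8), 50, 99.8))
  fit2 <- fitEquilibrium(ser2)
  expect_lt(abs(fit2@params[["kd"]] / 2e-8 - 1), 0.05)
})

test_that("a non-bracketing series is flagged, not silently fitted", {
  # all concentrations far below Kd
  ser <- generateEquilibriumSeries(kd = 1e-4, rmax = 100,
                                   concentrations = 10^seq(-9, -8,
                                                           length.out = 5))
  fit <- fitEquilibrium(ser)
  expect_false(fit@converged)
  expect_match(paste(fit@diagnostics, collapse = " "), "bracket")
  expect_error(fitEquilibrium(equilibriumSeries(c(1e-9, 2e-9),
                                                c(1, 2))), "3")
  expect_error(fitEquilibrium(equilibriumSeries(c(1e-9, 2e-9, 3e-9),
                                                c(1, 2, 3))),
               "factor of 10")
})

test_that("equilibrium Kd is robust to 2% noise across seeded replicates", {
  errs <- vapply(1:100, function(s) {
    ser <- generateEquilibriumSeries(kd = 14.6e-9, rmax = 100,
                                     noiseSd = 2, seed = s)
    abs(fitEquilibrium(ser)@params[["kd"]] / 14.6e-9 - 1)
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("the two-state forward model reduces to closed-form 1:1", {
  tg <- seq(0, 60, 0.5)
  p <- kineticParams(1e5, 5e-3, 0, 0, 100)
  C <- 1e-7
  sg <- simulateTwoState(p, C, tg, 60)
  req <- 100 * C / (C + 5e-3 / 1e5)
  expect_lt(max(abs(sg@response - req * (1 - exp(-(1e5 * C + 5e-3) * tg)))),
            1e-6)
  # long-time plateau equals the steady-state response
  late <- simulateTwoState(p, C, seq(0, 5000, 100), 5000)
  expect_equal(late@response[length(late@response)],
               equilibriumResponse(C, 5e-3 / 1e5, 100), tolerance = 1e-6)
  # zero concentration gives a flat zero
  z <- simulateTwoState(wtParams(), 0, seq(0, 660, 10), 60)
  expect_true(all(z@response == 0))
})

test_that("the closed-form integrator matches an independent ODE solve", {
  tg <- seq(0, 660, 2)
  for (p in list(wtParams(), kineticParams(2e6, 0.1, 1e-3, 5e-4, 80),
                 kineticParams(1e4, 1e-4, 0.05, 0.02, 150))) {
    for (C in c(1e-8, 3e-7, 1e-5)) {
      sg <- simulateTwoState(p, C, tg, 60)
      expect_lt(max(abs(sg@response - odeTwoStateOracle(p, C, tg, 60))),
                1e-6)
      # basic sanity of the trajectory
      expect_equal(sg@response[1], 0)
      expect_true(all(sg@response >= -1e-9 &
                        sg@response <= p@rmax + 1e-9))
    }
  }
})

test_that("noiseless global two-state fits recover kd_apparent within 1%", {
  p <- wtParams()
  fit <- fitTwoState(simulateSensorgramSet(sprSpec(noiseSd = 0)))
  expect_true(fit@converged)
  expect_lt(abs(fit@kdApparent / kdApparent(p) - 1), 0.01)
  expect_gte(fit@nStarts, 8L)
})

test_that("two-state nests the 1:1 model when the second step vanishes", {
  p11 <- kineticParams(1e5, 2e-3, 0, 0, 100)
  sgs <- simulateSensorgramSet(sprSpec(params = p11, noiseSd = 0))
  fit <- fitTwoState(sgs)
  expect_lt(abs(fit@kdApparent / (2e-3 / 1e5) - 1), 0.02)
})

test_that("parameter recovery holds across the exercised Kd range", {
  # apparent Kd from ~15 nM to ~30 uM, as in the mutant panel
  cases <- list(
    kineticParams(1e5, 5e-3, 4e-3, 2e-3, 100),       # ~17 nM
    kineticParams(1e5, 0.15, 2e-3, 2e-3, 100),       # ~750 nM
    kineticParams(5e4, 1.5, 0, 0, 100))              # 30 uM, fast
  for (p in cases) {
    concs <- kdApparent(p) * c(0.3, 1, 3, 10, 30)
    sgs <- lapply(concs, function(C)
      simulateTwoState(p, C, seq(0, 660, 2), 60))
    fit <- fitTwoState(sgs)
    expect_lt(abs(fit@kdApparent / kdApparent(p) - 1), 0.01)
  }
})

test_that("fold decreases reproduce the published mutant panel", {
  expect_equal(foldChange(2.7e-6, 14.6e-9)$fold, 185L)
  expect_equal(foldChange(6.5e-6, 14.6e-9)$fold, 445L)
  expect_equal(foldChange(14.6e-9, 14.6e-9)$fold, 1L)
  expect_error(foldChange(-1e-9, 14.6e-9), "> 0")
  # scale invariance
  set.seed(9)
  for (rep_ in 1:10) {
    a <- runif(1, 1e-9, 1e-5); b <- runif(1, 1e-9, 1e-5)
    s <- runif(1, 0.1, 1e4)
    expect_equal(foldChange(a * s, b * s)$fold, foldChange(a, b)$fold)
  }
})

test_that("the fold-change table handles deficient and discrepant rows", {
  entries <- data.frame(
    name = c("K290A", "V294A", "K297A", "M298A", "I300A", "M304A",
             "K305A", "R312A", "K297E"),
    kd = c(37.3, 113.3, 54.1, 323.7, 26.3, 24.2, 31.1, 27.8, NA) * 1e-9,
    stringsAsFactors = FALSE)
  tab <- foldChangeTable(entries, 14.6e-9)
  expect_equal(tab$foldDecrease[1:8], c(3L, 8L, 4L, 22L, 2L, 2L, 2L, 2L))
  expect_equal(tab$qualitative[9], "binding_deficient")
  expect_true(is.na(tab$foldDecrease[9]))
  # a printed fold computed from unrounded estimates is flagged
  entries2 <- data.frame(name = c("wt-like", "odd"),
                         kd = c(14.6e-9, 1.1e-6),
                         printedFold = c(1L, 77L))
  tab2 <- foldChangeTable(entries2, 14.6e-9)
  expect_false(tab2$discrepant[1])
  expect_true(tab2$discrepant[2])       # 1100/14.6 rounds to 75, not 77
  expect_match(tab2$note[2], "unrounded")
  expect_error(foldChangeTable(data.frame(name = c("a", "a"),
                                          kd = c(1e-9, 2e-9)), 1e-9),
               "duplicate")
  empty <- foldChangeTable(data.frame(name = character(0),
                                      kd = numeric(0)), 14.6e-9)
  expect_equal(nrow(empty), 0L)
})

test_that("sensorgram and equilibrium CSV round trips are faithful", {
  sg <- simulateTwoState(wtParams(), 2e-7, seq(0, 660, 2), 60)
  f <- tempfile(fileext = ".csv")
  writeSensorgramCsv(sg, f)
  back <- readSensorgramCsv(f)
  expect_equal(back@times, sg@times)
  expect_equal(back@response, sg@response, tolerance = 1e-9)
  expect_equal(back@analyteConc, 2e-7)
  expect_equal(back@tInjEnd, 60)
  ser <- generateEquilibriumSeries()
  f2 <- tempfile(fileext = ".csv")
  writeEquilibriumCsv(ser, f2)
  back2 <- readEquilibriumCsv(f2)
  expect_equal(back2@concs, ser@concs, tolerance = 1e-12)
  expect_equal(back2@req, ser@req, tolerance = 1e-9)
})
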