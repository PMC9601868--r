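test_that("the ideal helix has textbook geometry", {
  h <- buildIdealHelix(36)
  at <- atomTable(h)
  # ~1.5 A rise per residue: full atomic extent of 36 residues is ~54 A
  expect_equal(diff(range(at$x)), 36 * 1.5, tolerance = 1)
  ca <- at[at$elety == "CA", ]
  d <- sqrt(diff(ca$x)^2 + diff(ca$y)^2 + diff(ca$z)^2)
  expect_true(all(abs(d - 3.8) <= 0.05))
  expect_error(buildIdealHelix(3), "at least 4")
})

test_that("helix internal geometry repeats translationally", {
  h <- buildIdealHelix(12, sequence = "LEU")
  at <- atomTable(h)
  geomOf <- function(resno) {
    res <- at[at$resno %in% c(resno, resno + 1), ]
    as.numeric(dist(res[, c("x", "y", "z")]))
  }
  ref <- geomOf(2)
  for (r in 3:10) expect_equal(geomOf(r), ref, tolerance = 1e-9)
})

test_that("helix direction, phase and confidence are honoured", {
  h <- buildIdealHelix(10, direction = c(-1, 0, 0), plddt = 77,
                       startResno = 100)
  at <- atomTable(h)
  ca <- at[at$elety == "CA", ]
  expect_true(all(diff(ca$x) < 0))
  expect_equal(unique(at$b), 77)
  expect_equal(range(at$resno), c(100, 109))
  expect_error(buildIdealHelix(10, up = c(1, 0, 0)), "parallel")
})

test_that("the complex generator is deterministic and self-auditing", {
  a <- buildComplex(complexSpec(), sasaTruth = FALSE)
  b <- buildComplex(complexSpec(), sasaTruth = FALSE)
  expect_identical(atomTable(a$model), atomTable(b$model))
  expect_identical(a$pae@values, b$pae@values)
  expect_identical(a$truth$contacts, b$truth$contacts)
  # spec validation
  expect_error(complexSpec(saltBridgeDist = 4.5), "cutoff")
  expect_error(complexSpec(linkerPlddt = 60), "linkerPlddt")
})

test_that("the generator records a coherent ground truth", {
  built <- sharedComplex()
  tr <- built$truth
  # every designed contact sits at (or within) its class target distance
  cut <- defaultContactCutoffs()
  lim <- c(salt_bridge = cut$saltBridge, hydrogen_bond = cut$hBond,
           hydrophobic = cut$hydrophobic)
  expect_true(all(tr$contacts$distance <= lim[tr$contacts$kind]))
  sb <- tr$contacts[tr$contacts$kind == "salt_bridge", ]
  expect_equal(sb$distance, rep(tr$spec$saltBridgeDist, nrow(sb)),
               tolerance = 0.01)
  hb <- tr$contacts[tr$contacts$kind == "hydrogen_bond", ]
  expect_equal(hb$distance, rep(tr$spec$hBondDist, nrow(hb)),
               tolerance = 0.01)
  # two pockets of 7 and 5 leucines, distinct pins, one per dimer chain
  expect_length(tr$clusters, 2L)
  expect_setequal(vapply(tr$clusters, function(cl) length(cl$members),
                         integer(1)), c(7L, 5L))
  expect_equal(sort(tr$pins$chain), c("A", "B"))
  expect_false(tr$pins$resno[1] == tr$pins$resno[2])
  # 40-residue linkers on each dimer chain, flagged low-confidence
  expect_equal(nrow(tr$linkers), 80L)
  rt <- residueTable(built$model)
  lk <- rt[paste(rt$chain, rt$resno) %in%
             paste(tr$linkers$chain, tr$linkers$resno), ]
  expect_true(all(lk$plddt == tr$linkerPlddt))
  # coil length: ~30 turns x 10.8 A of core helix per chain (~160 A)
  coreA <- atomTable(built$model)
  coreA <- coreA[coreA$chain == "A" & coreA$resno >= 248, ]
  expect_gt(diff(range(coreA$x)), 150)
  # PAE bookkeeping matches the model
  expect_equal(nrow(built$pae@values), nResidues(built$model))
  expect_true(all(diag(built$pae@values) == 0))
})

test_that("noiseless sensorgram sets equal the forward model exactly", {
  spec <- sprSpec(noiseSd = 0)
  sgs <- simulateSensorgramSet(spec)
  expect_length(sgs, length(spec$concentrations))
  for (k in seq_along(sgs)) {
    clean <- simulateTwoState(spec$params, spec$concentrations[k],
                              sgs[[k]]@times, spec$tInjEnd)
    expect_identical(sgs[[k]]@response, clean@response)
  }
})

test_that("sensorgram noise is seeded and reproducible", {
  a <- simulateSensorgramSet(sprSpec(noiseSd = 1, seed = 5))
  b <- simulateSensorgramSet(sprSpec(noiseSd = 1, seed = 5))
  c_ <- simulateSensorgramSet(sprSpec(noiseSd = 1, seed = 6))
  expect_identical(a[[1]]@response, b[[1]]@response)
  expect_false(identical(a[[1]]@response, c_[[1]]@response))
  # the generator does not disturb the caller's RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(simulateSensorgramSet(sprSpec(noiseSd = 1)))
  expect_identical(rnorm(1), before)
})

test_that("generated data round-trip through the fitters", {
  spec <- sprSpec(noiseSd = 0)
  fit <- fitTwoState(simulateSensorgramSet(spec))
  expect_lt(abs(fit@kdApparent / kdApparent(spec$params) - 1), 0.01)
  ser <- generateEquilibriumSeries(kd = 14.6e-9, rmax = 100,
                                   concentrations = 14.6e-9 *
                                     10^seq(-1.2, 1.8, length.out = 8))
  fitE <- fitEquilibrium(ser)
  expect_lt(abs(fitE@params[["kd"]] / 14.6e-9 - 1), 1e-3)
})

test_that("equilibrium series generation is exact and monotone when clean", {
  ser <- generateEquilibriumSeries(kd = 1e-8, rmax = 50)
  expect_equal(ser@req, equilibriumResponse(ser@concs, 1e-8, 50))
  expect_true(all(diff(ser@req[order(ser@concs)]) > 0))
  noisy1 <- generateEquilibriumSeries(noiseSd = 2, seed = 3)
  noisy2 <- generateEquilibriumSeries(noiseSd = 2, seed = 3)
  expect_identical(noisy1@req, noisy2@req)
})
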