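test_that("observed-flux perturbation has the requested moments", {
  v <- c(10, -5, 0.5)
  # sd = 0: all replicates identical
  expect_true(all(perturbObserved(v, 5, sd = c(0, 0, 0)) ==
                    matrix(v, 5, 3, byrow = TRUE)))
  set.seed(77)
  sd <- c(1, 2, 0.1)
  M <- perturbObserved(v, 1e4, sd = sd)
  expect_equal(unname(apply(M, 2, sd)), sd, tolerance = 0.05)
  expect_equal(unname(colMeans(M)), v, tolerance = 0.1)
  expect_error(perturbObserved(v, 3, cv = -0.1), "non-negative")
  expect_message(perturbObserved(c(1, 0), 3, cv = 0.1), "zero")
})

test_that("zero measurement noise makes every nonzero flux significant", {
  sc <- makeToyNetwork(8, 12, seed = 3)
  part <- partitionModel(sc@model, sc@observed)
  sp <- quietFluxSpace(sc@model, sc@observed, sc@obs)
  obs0 <- observedFluxes(fluxValues(sc@obs),
                         sd = rep(0, length(fluxValues(sc@obs))))
  res <- runValidation(part, sp, obs0,
                       simulationDesign(5, 20, "sd", seed = 3))
  expect_true(all(nonsigPct(res) == 0))
  expect_lt(max(res@errPct, na.rm = TRUE), 1e-6)
  expect_equal(chi2RejectPct(res), 0)
})

test_that("the vectorized simulation fit agrees with fitGLS per replicate", {
  sc <- makeToyNetwork(8, 12, seed = 3)
  part <- partitionModel(sc@model, sc@observed)
  sp <- quietFluxSpace(sc@model, sc@observed, sc@obs)
  des <- simulationDesign(1, 4, "sd", seed = 5)
  res <- runValidation(part, sp, sc@obs, des)
  # replay the simulation's RNG stream to recover the same noisy data
  profiles <- sampleHitAndRun(sp, 1, burnIn = 1000, thin = 10,
                              seed = des@seed)
  voT <- fluxes(profiles)[1, part@obsIdx]
  set.seed(des@seed + 1L)
  Vo <- perturbObserved(voT, 4, sd = fluxSD(sc@obs))
  nm <- estimateErrorCovariance(part, sc@obs)
  for (k in 1:4) {
    obsK <- observedFluxes(structure(Vo[k, ], names = obsNames(part)),
                           sd = fluxSD(sc@obs))
    fit <- fitGLS(part, obsK, nm, dfConvention = des@dfConvention)
    expect_equal(res@sigma2[k], fit@sigma2Hat, tolerance = 1e-10)
    expect_identical(unname(res@sigMatrix[k, ]),
                     tTest(fit, des@alpha)$significant)
  }
})

test_that("non-significance grows with measurement variability", {
  sc <- makeToyNetwork(8, 14, nExchange = 8, seed = 4)
  part <- partitionModel(sc@model, sc@observed)
  sp <- quietFluxSpace(sc@model, sc@observed, sc@obs)
  mean_nonsig <- vapply(c(0.05, 0.10, 0.20), function(cv) {
    res <- runValidation(part, sp, sc@obs,
                         simulationDesign(10, 40, "cv", cv = cv, seed = 5))
    mean(nonsigPct(res))
  }, numeric(1))
  expect_true(all(diff(mean_nonsig) > -2))   # non-decreasing up to MC error
  expect_gt(mean_nonsig[3], mean_nonsig[1])  # strictly higher at 4x noise
})

test_that("chi-square rejection is invariant to flux magnitude scale", {
  sc <- makeToyNetwork(8, 12, seed = 6)
  part <- partitionModel(sc@model, sc@observed)
  sp <- quietFluxSpace(sc@model, sc@observed, sc@obs)
  des <- simulationDesign(10, 40, "sd", seed = 8)
  res1 <- runValidation(part, sp, sc@obs, des)
  # scale the whole problem (true space bounds and noise) by 100
  obsS <- observedFluxes(100 * fluxValues(sc@obs), sd = 100 * fluxSD(sc@obs))
  spS <- quietFluxSpace(sc@model, sc@observed, obsS)
  resS <- runValidation(part, spS, obsS, des)
  expect_identical(chi2RejectPct(res1), chi2RejectPct(resS))
  expect_identical(res1@sigMatrix, resS@sigMatrix)
})

test_that("identical seed and design replay bit-identically", {
  sc <- makeToyNetwork(8, 12, seed = 3)
  part <- partitionModel(sc@model, sc@observed)
  sp <- quietFluxSpace(sc@model, sc@observed, sc@obs)
  des <- simulationDesign(4, 10, "cv", cv = 0.1, seed = 21)
  r1 <- runValidation(part, sp, sc@obs, des)
  r2 <- runValidation(part, sp, sc@obs, des)
  expect_identical(r1@errPct, r2@errPct)
  expect_identical(r1@sigMatrix, r2@sigMatrix)
  expect_identical(r1@sigma2, r2@sigma2)
  expect_identical(r1@trueCalc, r2@trueCalc)
})

test_that("rank summaries order fluxes by magnitude and pool correctly", {
  sc <- makeToyNetwork(8, 14, nExchange = 8, seed = 4)
  part <- partitionModel(sc@model, sc@observed)
  sp <- quietFluxSpace(sc@model, sc@observed, sc@obs)
  res <- runValidation(part, sp, sc@obs,
                       simulationDesign(6, 20, "cv", cv = 0.1, seed = 9))
  rs <- rankSummaries(res)
  expect_identical(rs$rank, seq_along(res@calcNames))
  # independent re-aggregation of the stored replicate matrices
  ranks <- t(apply(abs(res@trueCalc), 1, rank, ties.method = "first"))
  k <- 2L
  sel <- ranks[res@profileIndex, ] == k
  expect_equal(rs$median_err_pct[k],
               median(res@errPct[sel], na.rm = TRUE))
  expect_equal(rs$nonsig_pct[k], 100 * mean(!res@sigMatrix[sel]))
  # significance split returns both error curves
  rs2 <- rankSummaries(res, bySignificance = TRUE)
  expect_true(all(c("median_err_sig", "median_err_nonsig") %in% names(rs2)))
})

test_that("a self-consistent fit is not flagged while model error is", {
  sc <- makeToyNetwork(10, 15, nExchange = 9, seed = 4)
  part <- partitionModel(sc@model, sc@observed)
  sp <- quietFluxSpace(sc@model, sc@observed, sc@obs)
  # "observed" data drawn from the no-model-error world itself
  set.seed(33)
  vals <- fluxValues(sc@obs) + rnorm(length(sc@observed), 0,
                                     fluxSD(sc@obs))
  fitSelf <- fitGLS(part, observedFluxes(vals, sd = fluxSD(sc@obs)))
  res <- runValidation(part, sp, sc@obs,
                       simulationDesign(15, 40, "sd", seed = 10))
  cmpSelf <- compareToObserved(fitSelf, res)
  expect_gte(cmpSelf$containment, 0.05)
  expect_identical(nrow(cmpSelf$table), length(res@calcNames))
  # deliberately mis-specified fitting model: delete an active reaction
  mis <- makeMisfitScenario(sc, "R6")
  partM <- partitionModel(mis@model, mis@observed)
  fitM <- fitGLS(partM, mis@obs)
  # gross-error test already collapses ...
  expect_lt(chi2GrossErrorTest(fitM)$p.value, 1e-6)
  # ... and against a (wide-bound) feasible simulation of the reduced model
  # the observed non-significance pattern is essentially impossible
  spM <- quietFluxSpace(mis@model, mis@observed, mis@obs, a = 10)
  resM <- runValidation(partM, spM, mis@obs,
                        simulationDesign(15, 40, "sd", seed = 11))
  cmpM <- compareToObserved(fitM, resM)
  expect_lt(cmpM$containment, 0.05)
  # CI ratio reported per flux
  expect_true(all(is.finite(cmpM$table$ci_ratio)))
})

test_that("deleting a zero-flux reaction leaves the fit unimpaired", {
  base <- deadBranchScenario()
  mis <- makeMisfitScenario(base, "R2")       # R2 carries exactly zero flux
  part <- partitionModel(mis@model, mis@observed)
  fit <- fitGLS(part, mis@obs)
  expect_gt(chi2GrossErrorTest(fit)$p.value, 0.99)  # data still balanced
  expect_equal(unname(estimates(fit)), 10, tolerance = 1e-6)
  sp <- quietFluxSpace(mis@model, mis@observed, mis@obs)
  expect_identical(findInteriorPoint(sp)$status, "interior")
})

test_that("infeasible spaces raise the data-does-not-fit verdict", {
  sc <- makeToyNetwork(10, 15, nExchange = 9, seed = 4)
  mis <- makeMisfitScenario(sc, "R6")
  spM <- quietFluxSpace(mis@model, mis@observed, mis@obs)  # default bands
  expect_identical(findInteriorPoint(spM)$status, "empty")
  partM <- partitionModel(mis@model, mis@observed)
  expect_error(runValidation(partM, spM, mis@obs,
                             simulationDesign(2, 2, "sd", seed = 1)),
               "not fit the specified model")
})

test_that("validation report files are written and consistent", {
  sc <- makeToyNetwork(8, 12, seed = 3)
  part <- partitionModel(sc@model, sc@observed)
  sp <- quietFluxSpace(sc@model, sc@observed, sc@obs)
  res <- runValidation(part, sp, sc@obs,
                       simulationDesign(3, 10, "cv", cv = 0.1, seed = 2))
  dir <- file.path(tempdir(), "valrep")
  writeValidationReport(res, dir)
  ns <- read.delim(file.path(dir, "nonsignificance.tsv"))
  expect_identical(ns$flux, res@calcNames)
  js <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_equal(js$chi2_reject_pct, chi2RejectPct(res))
})
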