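test_that("error covariance propagates observed variance with jitter", {
  part <- methods::new("FluxPartition",
                       Sc = matrix(c(1, 1), 2, 1), So = matrix(c(1, 0), 2, 1),
                       calcNames = "c1", obsNames = "o1",
                       calcIdx = 1L, obsIdx = 2L)
  obs <- observedFluxes(c(o1 = 5), sd = 2)
  nm <- estimateErrorCovariance(part, obs, jitter = 0.5)
  expect_equal(nm@covEps, matrix(c(4.5, 0, 0, 0.5), 2), ignore_attr = TRUE)
  # whitening identity is part of the class validity, checked on build
  expect_true(methods::validObject(nm))
  # orthogonal S_o columns with diagonal Cov(v_o): direct product oracle
  # (S_o spans all balances, so no jitter is needed for invertibility)
  So <- cbind(c(1, 0), c(0, -1))
  part2 <- methods::new("FluxPartition",
                        Sc = matrix(1, 2, 1), So = So, calcNames = "c1",
                        obsNames = c("o1", "o2"), calcIdx = 1L, obsIdx = 2:3)
  obs2 <- observedFluxes(c(o1 = 1, o2 = 1), sd = c(2, 3))
  nm2 <- estimateErrorCovariance(part2, obs2, jitter = 0)
  expect_error(methods::validObject(nm2), NA)
  expect_equal(nm2@covEps, So %*% diag(c(4, 9)) %*% t(So),
               ignore_attr = TRUE)
  # zero row with no jitter: the motivating degenerate case
  expect_error(estimateErrorCovariance(part, obs, jitter = 0), "singular")
})

test_that("the 3-balance fit matches its closed form", {
  fit <- toy3Fit()
  expect_equal(unname(estimates(fit)), 3)
  expect_equal(fit@residW, c(-1, 0, 1))
  expect_equal(fit@sigma2Hat, 2)          # df = 3 - 1 - 1 = 1
  expect_equal(fit@se, sqrt(2 / 3), tolerance = 1e-12)
  tt <- tTest(fit)
  expect_equal(tt$t, 3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(tt$p, 2 * pt(-3 / sqrt(2 / 3), 1), tolerance = 1e-12)
  expect_false(tt$significant)            # p ~ 0.169 at alpha = 0.05
  ci <- confidenceIntervals(fit)
  expect_equal(ci$upper - ci$estimate, qt(0.975, 1) * sqrt(2 / 3),
               tolerance = 1e-10)
  # a zero estimate is never significant
  fit0 <- toy3Fit(values = c(-1, 0, 1))
  expect_equal(unname(estimates(fit0)), 0)
  expect_equal(tTest(fit0)$t, 0)
  expect_false(tTest(fit0)$significant)
})

test_that("GLS equals OLS when V = I and is invariant to covariance scale", {
  set.seed(7)
  for (rep in 1:5) {
    X <- matrix(rnorm(18), 6, 3)
    vo <- rnorm(6)
    part <- methods::new("FluxPartition",
                         Sc = X, So = -diag(6),
                         calcNames = paste0("c", 1:3),
                         obsNames = paste0("o", 1:6),
                         calcIdx = 1:3, obsIdx = 4:9)
    obs <- observedFluxes(structure(vo, names = paste0("o", 1:6)),
                          sd = rep(1, 6))
    fit <- fitGLS(part, obs, noiseModel(diag(6)))
    ols <- lm.fit(X, vo)$coefficients     # independent base-R oracle
    expect_lt(max(abs(estimates(fit) - ols)), 1e-10)
    # any positive scalar on Cov(eps) leaves vHat, t and p unchanged
    fitScaled <- fitGLS(part, obs, noiseModel(7.3 * diag(6)))
    expect_equal(estimates(fitScaled), estimates(fit), tolerance = 1e-10)
    expect_equal(fitScaled@tStat, fit@tStat, tolerance = 1e-10)
    expect_equal(fitScaled@p, fit@p, tolerance = 1e-10)
    # equal-entry diagonal V gives the same estimates as V = I
    fitDiag <- fitGLS(part, obs, noiseModel(diag(rep(2.5, 6))))
    expect_equal(estimates(fitDiag), estimates(fit), tolerance = 1e-10)
    # QR and normal-equation solvers agree
    fitNorm <- fitGLS(part, obs, noiseModel(diag(6)), method = "normal")
    expect_equal(estimates(fitNorm), estimates(fit), tolerance = 1e-9)
  }
})

test_that("the fit minimizes the whitened sum of squares (numerical oracle)", {
  set.seed(11)
  X <- matrix(rnorm(18), 6, 3)
  vo <- rnorm(6)
  A <- crossprod(matrix(rnorm(36), 6)) + 6 * diag(6)  # SPD covariance
  part <- methods::new("FluxPartition",
                       Sc = X, So = -diag(6),
                       calcNames = paste0("c", 1:3),
                       obsNames = paste0("o", 1:6),
                       calcIdx = 1:3, obsIdx = 4:9)
  obs <- observedFluxes(structure(vo, names = paste0("o", 1:6)),
                        sd = rep(1, 6))
  nm <- noiseModel(A)
  fit <- fitGLS(part, obs, nm)
  Ainv <- solve(A)
  ss <- function(b) {
    r <- vo - drop(X %*% b)               # unwhitened residual, V-norm
    drop(t(r) %*% Ainv %*% r)
  }
  opt <- optim(rep(0, 3), ss, method = "BFGS",
               control = list(reltol = 1e-14))
  expect_equal(unname(estimates(fit)), opt$par, tolerance = 1e-5)
  expect_lte(ss(estimates(fit)), opt$value + 1e-8)
})

test_that("noise-free balanced data are recovered exactly", {
  sc <- makeToyNetwork(8, 12, seed = 3)
  part <- partitionModel(sc@model, sc@observed)
  fit <- fitGLS(part, sc@obs)
  expect_equal(estimates(fit), sc@trueFluxes[calcNames(part)],
               tolerance = 1e-8)
  expect_lt(max(abs(fit@residW)), 1e-6)
  ct <- chi2GrossErrorTest(fit)
  expect_equal(ct$p.value, 1, tolerance = 1e-6)
  expect_equal(ct$df, nBalances(part) - nCalculated(part))
})

test_that("chi-square test rejects only the df-starved configuration", {
  fit <- toy3Fit()
  ct <- chi2GrossErrorTest(fit)
  expect_equal(ct$statistic, 2)
  expect_equal(ct$df, 2)
  # textbook df option is exposed
  expect_equal(chi2GrossErrorTest(fit, dfConvention = "textbook")$df, 1)
  # nb == nc leaves no redundancy
  part <- methods::new("FluxPartition",
                       Sc = diag(2), So = -diag(2),
                       calcNames = c("c1", "c2"), obsNames = c("o1", "o2"),
                       calcIdx = 1:2, obsIdx = 3:4)
  obs <- observedFluxes(c(o1 = 1, o2 = 2), sd = c(1, 1))
  fit2 <- suppressWarnings(fitGLS(part, obs, noiseModel(diag(2))))
  expect_error(chi2GrossErrorTest(fit2), "redundancy")
})

test_that("t-test type-I error is calibrated for a true-zero flux", {
  # dead side branch: R2 carries exactly zero flux; under correct noise and
  # the exact residual df, rejection at alpha = 0.05 must be 5 %
  sc <- deadBranchScenario()
  part <- partitionModel(sc@model, sc@observed)
  voTrue <- sc@trueFluxes[obsNames(part)]
  sd <- fluxSD(sc@obs)[obsNames(part)]
  nm <- estimateErrorCovariance(part, observedFluxes(voTrue, sd = sd))
  set.seed(101)
  m <- 1500
  rej <- logical(m)
  for (k in seq_len(m)) {
    vo <- observedFluxes(voTrue + rnorm(3, 0, sd), sd = sd)
    fit <- fitGLS(part, vo, nm, dfConvention = "residual")
    rej[k] <- tTest(fit, alpha = 0.05)$significant[
      match("R2", calcNames(part))]
  }
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / m))
})

test_that("confidence intervals cover the true flux at the nominal rate", {
  sc <- deadBranchScenario()
  part <- partitionModel(sc@model, sc@observed)
  voTrue <- sc@trueFluxes[obsNames(part)]
  sd <- fluxSD(sc@obs)[obsNames(part)]
  nm <- estimateErrorCovariance(part, observedFluxes(voTrue, sd = sd))
  vTrueCalc <- sc@trueFluxes[calcNames(part)]
  set.seed(202)
  m <- 600
  cover <- logical(m)
  for (k in seq_len(m)) {
    vo <- observedFluxes(voTrue + rnorm(3, 0, sd), sd = sd)
    fit <- fitGLS(part, vo, nm, dfConvention = "residual")
    ci <- confidenceIntervals(fit, alpha = 0.05)
    i <- match("R1", ci$flux)
    cover[k] <- ci$lower[i] <= vTrueCalc[["R1"]] &&
      vTrueCalc[["R1"]] <= ci$upper[i]
  }
  expect_lt(abs(mean(cover) - 0.95), 3 * sqrt(0.95 * 0.05 / m))
})

test_that("prediction intervals widen with leverage and vanish at exact fit", {
  fit <- toy3Fit()
  pi <- predictionInterval(fit)
  ci <- confidenceIntervals(fit)
  # prediction band is wider than the estimate's CI on the same scale
  expect_true(all(pi$upper - pi$lower >
                    1e-12 + 0 * (ci$upper - ci$lower)[1]))
  expect_true(all(pi$upper - pi$predicted >=
                    sqrt(fit@sigma2Hat) * qt(0.975, fit@df)))
  # exact data: sigma2Hat = 0 collapses every interval
  sc <- makeToyNetwork(8, 12, seed = 5)
  part <- partitionModel(sc@model, sc@observed)
  fitEx <- fitGLS(part, sc@obs)
  expect_lt(max(predictionInterval(fitEx)$upper -
                  predictionInterval(fitEx)$lower), 1e-4)
  expect_lt(max(confidenceIntervals(fitEx)$upper -
                  confidenceIntervals(fitEx)$lower), 1e-4)
})

test_that("report writer emits a complete, re-readable table", {
  fit <- toy3Fit()
  tf <- tempfile(fileext = ".tsv")
  writeFitReport(fit, tf)
  df <- read.delim(tf)
  expect_identical(names(df),
                   c("flux_name", "estimate", "se", "t", "df", "p",
                     "ci_lo", "ci_hi", "significant"))
  expect_equal(df$estimate, 3)
  tt <- tTest(fit, adjust = "BH")
  expect_true(all(tt$p_adj >= tt$p - 1e-12))
})
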