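#' @include AllClasses.R
NULL

#' Construct a validation-simulation design
#'
#' Defaults mirror the balanced-flux experiment: 100 balanced profiles, each
#' perturbed with 100 independent sets of measurement noise (10 000
#' replicates in total), decisions at alpha = 0.05.  `noiseSource = "sd"`
#' perturbs the observed fluxes with the measured per-flux standard
#' deviations; `noiseSource = "cv"` applies a uniform coefficient of
#' variation (as a fraction, e.g. 0.05 for 5 %) to each profile's true
#' observed fluxes.
#'
#' @param nProfiles,mNoise replicate structure.
#' @param noiseSource `"sd"` or `"cv"`.
#' @param cv coefficient of variation as a fraction (used for `"cv"`).
#' @param alpha significance level.
#' @param seed integer seed; identical seed and design replay bit-identically.
#' @param dfConvention degrees-of-freedom convention for the GLS fits (see
#'   [fitGLS()]).
#' @return A [SimulationDesign].
#' @export
simulationDesign <- function(nProfiles = 100, mNoise = 100,
                             noiseSource = c("sd", "cv"), cv = 0.05,
                             alpha = 0.05, seed = 1,
                             dfConvention = c("textbook", "residual")) {
  methods::new("SimulationDesign",
               nProfiles = as.integer(nProfiles), mNoise = as.integer(mNoise),
               noiseSource = match.arg(noiseSource), cv = as.numeric(cv),
               alpha = as.numeric(alpha), seed = as.integer(seed),
               dfConvention = match.arg(dfConvention))
}

#' Perturb an observed-flux vector with measurement noise
#'
#' Each replicate row is `v + N(0, diag(sd^2))`.  In CV mode the standard
#' deviation is `cv * |v_i|`; fluxes that are exactly zero then receive no
#' noise, which is flagged with a message.
#'
#' @param v numeric vector of true observed fluxes.
#' @param m number of replicates.
#' @param sd per-flux standard deviations (used when `cv` is `NULL`).
#' @param cv uniform coefficient of variation as a fraction.
#' @return numeric matrix, `m` rows (replicates) x `length(v)` columns.
#' @export
perturbObserved <- function(v, m, sd = NULL, cv = NULL) {
  if (!is.null(cv)) {
    if (cv < 0) stop("cv must be non-negative", call. = FALSE)
    sd <- cv * abs(v)
    if (any(v == 0))
      message(sum(v == 0), " observed flux(es) are exactly zero: ",
              "cv-mode noise leaves them unperturbed")
  }
  stopifnot(length(sd) == length(v))
  noise <- matrix(stats::rnorm(m * length(v), sd = rep(sd, each = m)),
                  nrow = m)
  sweep(noise, 2, v, `+`)
}

## vectorized GLS over noise replicates for one balanced profile
.fit.block <- function(X, qrX, XtXinvDiag, Pinv, So, Vo, voTrue, vcTrue,
                       dfSigma, chi2df, alpha, zeroTol) {
  Y <- -Pinv %*% (So %*% t(Vo))                # nb x m
  coefs <- qr.coef(qrX, Y)                     # nc x m
  if (is.null(dim(coefs))) coefs <- matrix(coefs, nrow = 1)
  resid <- Y - X %*% coefs
  rss <- colSums(resid^2)
  sigma2 <- rss / dfSigma
  est <- t(coefs)                              # m x nc
  se <- sqrt(outer(sigma2, XtXinvDiag))
  tcrit <- stats::qt(1 - alpha / 2, dfSigma)
  tstat <- ifelse(se > 0, est / se, ifelse(est == 0, 0, Inf))
  sig <- abs(tstat) >= tcrit
  pchi <- stats::pchisq(rss, chi2df, lower.tail = FALSE)
  denom <- abs(vcTrue)
  err <- 100 * abs(sweep(est, 2, vcTrue)) /
    rep(denom, each = nrow(est))
  err[, denom < zeroTol] <- NA_real_
  list(sig = sig, err = err, sigma2 = sigma2, chi2rej = pchi < alpha,
       ciHalf = tcrit * se)
}

#' Run the balanced-flux validation simulation
#'
#' The central diagnostic: sample `nProfiles` stoichiometrically exact flux
#' profiles from the constrained flux space, perturb each profile's observed
#' components `mNoise` times with measurement noise, re-fit every replicate
#' by GLS, and aggregate t-test significance, chi-square rejections and
#' percent errors against each profile's known true calculated fluxes.
#' Because the profiles come from the model's nullspace, the replicates
#' carry measurement error but no model error: their significance pattern is
#' the best the model could do, and a real-data fit markedly worse than this
#' baseline indicates lack of fit.
#'
#' @param partition a [FluxPartition].
#' @param space a [FluxSpace] over the same model (an infeasible space
#'   raises an error: the observed data do not fit the specified model).
#' @param obs the [ObservedFluxes]; supplies per-flux sd for
#'   `noiseSource = "sd"` and the whitening covariance.
#' @param design a [SimulationDesign].
#' @param zeroTol true fluxes with `|v| < zeroTol` are excluded from percent
#'   errors (reported as `NA`): a relative error is undefined at zero.
#' @param burnIn,thin passed to the hit-and-run sampler of profiles.
#' @return A [SimulationResult].
#' @export
runValidation <- function(partition, space, obs, design,
                          zeroTol = 1e-9, burnIn = 1000, thin = 10) {
  nP <- design@nProfiles
  m <- design@mNoise
  profiles <- sampleHitAndRun(space, n = nP, burnIn = burnIn, thin = thin,
                              seed = design@seed)
  V <- fluxes(profiles)                        # nP x reactions
  VoTrue <- V[, partition@obsIdx, drop = FALSE]
  VcTrue <- V[, partition@calcIdx, drop = FALSE]
  nc <- ncol(partition@Sc)
  nb <- nrow(partition@Sc)
  dfSigma <- .df.value(nb, nc, design@dfConvention)
  if (dfSigma < 1)
    stop("design has no residual degrees of freedom", call. = FALSE)
  chi2df <- nb - nc

  fixedNoise <- design@noiseSource == "sd"
  if (fixedNoise) {
    sdVec <- obs@sd
    nm <- estimateErrorCovariance(partition, obs)
    X <- nm@Pinv %*% partition@Sc
    qrX <- qr(X)
    XtXinvDiag <- diag(chol2inv(chol(crossprod(X))))
  }

  reps <- nP * m
  sig <- matrix(NA, reps, nc)
  err <- matrix(NA_real_, reps, nc)
  ciHalf <- matrix(NA_real_, reps, nc)
  sigma2 <- numeric(reps)
  chi2rej <- logical(reps)
  profileIndex <- rep(seq_len(nP), each = m)

  set.seed(design@seed + 1L)
  for (j in seq_len(nP)) {
    voT <- VoTrue[j, ]
    if (!fixedNoise) {
      sdVec <- design@cv * abs(voT)
      obsj <- methods::new("ObservedFluxes",
                           values = structure(voT, names = partition@obsNames),
                           sd = sdVec)
      nm <- estimateErrorCovariance(partition, obsj)
      X <- nm@Pinv %*% partition@Sc
      qrX <- qr(X)
      XtXinvDiag <- diag(chol2inv(chol(crossprod(X))))
    }
    Vo <- perturbObserved(voT, m, sd = sdVec)
    blk <- .fit.block(X, qrX, XtXinvDiag, nm@Pinv, partition@So, Vo,
                      voT, VcTrue[j, ], dfSigma, chi2df, design@alpha,
                      zeroTol)
    rows <- ((j - 1L) * m + 1L):(j * m)
    sig[rows, ] <- blk$sig
    err[rows, ] <- blk$err
    ciHalf[rows, ] <- blk$ciHalf
    sigma2[rows] <- blk$sigma2
    chi2rej[rows] <- blk$chi2rej
  }

  nonsig <- 100 * colMeans(!sig)
  names(nonsig) <- partition@calcNames
  ciMed <- apply(ciHalf, 2, stats::median)
  names(ciMed) <- partition@calcNames
  colnames(err) <- partition@calcNames
  methods::new("SimulationResult",
               nonsigPct = nonsig,
               chi2RejectPct = 100 * mean(chi2rej),
               errPct = err, sigMatrix = sig, sigma2 = sigma2,
               trueCalc = VcTrue, ciHalfWidth = ciMed,
               profileIndex = profileIndex,
               calcNames = partition@calcNames, design = design)
}

#' Rank-ordered error and significance summaries
#'
#' Within each sampled profile, calculated fluxes are ranked by ascending
#' absolute true magnitude (rank 1 = smallest flux; magnitude ties broken by
#' model column order).  Median percent error and percent non-significance
#' are then pooled per rank across all profiles and noise replicates.  With
#' `bySignificance = TRUE` the error summary is split into significant and
#' non-significant replicates, exposing how t-test decisions track
#' calculation accuracy.
#'
#' @param result a [SimulationResult].
#' @param bySignificance split error medians by t-test outcome.
#' @return `data.frame` with one row per rank: `rank`, `median_err_pct`,
#'   `nonsig_pct` and, when split, `median_err_sig` / `median_err_nonsig`.
#' @export
rankSummaries <- function(result, bySignificance = FALSE) {
  ranks <- t(apply(abs(result@trueCalc), 1, rank, ties.method = "first"))
  R <- ranks[result@profileIndex, , drop = FALSE]
  nc <- length(result@calcNames)
  out <- data.frame(rank = seq_len(nc),
                    median_err_pct = NA_real_,
                    nonsig_pct = NA_real_)
  if (bySignificance) {
    out$median_err_sig <- NA_real_
    out$median_err_nonsig <- NA_real_
  }
  for (k in seq_len(nc)) {
    mask <- R == k
    ek <- result@errPct[mask]
    sk <- result@sigMatrix[mask]
    out$median_err_pct[k] <- stats::median(ek, na.rm = TRUE)
    out$nonsig_pct[k] <- 100 * mean(!sk)
    if (bySignificance) {
      out$median_err_sig[k] <- stats::median(ek[sk], na.rm = TRUE)
      out$median_err_nonsig[k] <- stats::median(ek[!sk], na.rm = TRUE)
    }
  }
  out
}

#' Compare a real-data fit to the no-model-error baseline
#'
#' Per calculated flux, the observed t-test decision is set against the
#' simulated non-significance percentage, and the observed confidence-interval
#' width against the median simulated width.  A joint tail probability is
#' estimated empirically as the fraction of simulated replicates whose
#' non-significant set contains the entire observed non-significant set: if
#' fluxes judged non-significant on real data are routinely significant in
#' the measurement-error-only simulation, that containment fraction is small
#' and model error is indicated.  The containment fraction is descriptive,
#' not a calibrated test.
#'
#' @param fitReal a [GLSFit] of the observed data (same partition).
#' @param result a [SimulationResult] from [runValidation()].
#' @param alpha significance level for the observed decisions.
#' @return list with `table` (per-flux data.frame: `flux`,
#'   `observed_significant`, `sim_nonsig_pct`, `ci_ratio`),
#'   `containment` (empirical joint probability) and `alpha`.
#' @export
compareToObserved <- function(fitReal, result, alpha = 0.05) {
  if (!identical(names(fitReal@vHat), result@calcNames))
    stop("fit and simulation use different calculated-flux sets",
         call. = FALSE)
  tt <- tTest(fitReal, alpha = alpha)
  obsHalf <- stats::qt(1 - alpha / 2, fitReal@df) * fitReal@se
  tab <- data.frame(flux = result@calcNames,
                    observed_significant = tt$significant,
                    sim_nonsig_pct = unname(result@nonsigPct),
                    ci_ratio = obsHalf / unname(result@ciHalfWidth),
                    stringsAsFactors = FALSE)
  nonsigSet <- which(!tt$significant)
  containment <- if (length(nonsigSet) == 0L) 1 else
    mean(apply(!result@sigMatrix[, nonsigSet, drop = FALSE], 1, all))
  list(table = tab, containment = containment, alpha = alpha)
}

#' Write validation outputs
#'
#' Writes the per-flux non-significance table, the rank summary table and a
#' JSON summary (chi-square rejection rate, mean residual variance, design)
#' into a directory.
#'
#' @param result a [SimulationResult].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeValidationReport <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(
    data.frame(flux = result@calcNames,
               nonsig_pct = unname(result@nonsigPct),
               median_ci_half_width = unname(result@ciHalfWidth)),
    file.path(dir, "nonsignificance.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(rankSummaries(result, bySignificance = TRUE),
                     file.path(dir, "rank_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  d <- result@design
  jsonlite::write_json(
    list(chi2_reject_pct = result@chi2RejectPct,
         mean_sigma2 = mean(result@sigma2),
         n_profiles = d@nProfiles, m_noise = d@mNoise,
         noise_source = d@noiseSource, cv = d@cv, alpha = d@alpha,
         seed = d@seed),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
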