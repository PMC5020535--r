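#' @include AllClasses.R
NULL

#' Construct an observed-flux set
#'
#' @param values named numeric vector of specific fluxes
#'   (nmol/1e6 cells/h; consumption positive, production negative).
#' @param sd per-flux standard deviations (same units/order); alternatively
#'   give `cv` and sd is computed as `cv/100 * abs(values)`.
#' @param cv optional per-flux coefficients of variation in percent.
#' @return An [ObservedFluxes].
#' @export
observedFluxes <- function(values, sd = NULL, cv = NULL) {
  if (is.null(names(values)))
    stop("values must be named by reaction", call. = FALSE)
  if (is.null(sd)) {
    if (is.null(cv))
      stop("supply either sd or cv", call. = FALSE)
    sd <- abs(values) * cv / 100
  }
  v <- as.numeric(values)
  names(v) <- names(values)
  methods::new("ObservedFluxes", values = v, sd = as.numeric(sd))
}

.df.value <- function(nb, nc, convention = c("textbook", "residual")) {
  convention <- match.arg(convention)
  as.numeric(if (convention == "textbook") nb - nc - 1 else nb - nc)
}

#' Fit calculated fluxes by generalized least squares
#'
#' Solves the whitened regression
#' `-P^-1 S_o v_o = P^-1 S_c v_c + P^-1 e` for the calculated fluxes:
#' `vHat` minimizes the whitened sum of squares, and the residual variance
#' estimate, standard errors and t-statistics follow the ordinary regression
#' formulas on the whitened scale.  When both the model and the error
#' covariance are correct, `sigma2Hat` is approximately 1.
#'
#' Degrees of freedom: `dfConvention = "textbook"` (default) uses
#' `n_b - n_c - 1`, the intercept-style formula; `"residual"` uses the exact
#' residual degrees of freedom `n_b - n_c` of this no-intercept regression
#' (under which `E[sigma2Hat] = 1` exactly).  Both are exposed because the
#' two differ noticeably at low redundancy; see the package vignette.
#'
#' @param partition a [FluxPartition].
#' @param obs an [ObservedFluxes] aligned to the partition's observed block.
#' @param noise a [NoiseModel]; default propagates `obs` uncertainty via
#'   [estimateErrorCovariance()].
#' @param dfConvention `"textbook"` or `"residual"`.
#' @param method `"qr"` (default, numerically preferred) or `"normal"`
#'   (explicit normal equations, kept for textbook equivalence checks).
#' @return A [GLSFit].
#' @examples
#' part <- methods::new("FluxPartition",
#'   Sc = matrix(1, 3, 1), So = -diag(3),
#'   calcNames = "r", obsNames = c("o1", "o2", "o3"),
#'   calcIdx = 1L, obsIdx = 2:4)
#' obs <- observedFluxes(c(o1 = 2, o2 = 3, o3 = 4), sd = c(1, 1, 1))
#' fit <- fitGLS(part, obs, noiseModel(diag(3)))
#' estimates(fit)        # 3
#' @export
fitGLS <- function(partition, obs, noise = NULL,
                   dfConvention = c("textbook", "residual"),
                   method = c("qr", "normal")) {
  dfConvention <- match.arg(dfConvention)
  method <- match.arg(method)
  if (is.null(noise))
    noise <- estimateErrorCovariance(partition, obs)
  Sc <- partition@Sc
  So <- partition@So
  nb <- nrow(Sc)
  nc <- ncol(Sc)
  if (nc == 0L)
    stop("partition has no calculated fluxes", call. = FALSE)
  X <- noise@Pinv %*% Sc
  y <- drop(-noise@Pinv %*% (So %*% obs@values))
  if (method == "qr") {
    qrX <- qr(X)
    if (qrX$rank < nc)
      stop("whitened S_c is rank deficient: calculated fluxes are not ",
           "identifiable from the observed set", call. = FALSE)
    coef <- qr.coef(qrX, y)
    R <- qr.R(qrX)[, order(qrX$pivot), drop = FALSE]
    XtXinv <- chol2inv(chol(crossprod(R)))
  } else {
    XtX <- crossprod(X)
    XtXinv <- tryCatch(chol2inv(chol(XtX)), error = function(e)
      stop("whitened S_c'S_c is singular: calculated fluxes are not ",
           "identifiable from the observed set", call. = FALSE))
    coef <- drop(XtXinv %*% crossprod(X, y))
  }
  resid <- y - drop(X %*% coef)
  df <- .df.value(nb, nc, dfConvention)
  if (df < 1) {
    warning("no residual degrees of freedom (df = ", df,
            "): sigma2Hat and t-tests are unavailable")
    sigma2 <- NA_real_
  } else {
    sigma2 <- sum(resid^2) / df
  }
  se <- sqrt(pmax(sigma2, 0) * diag(XtXinv))
  tval <- ifelse(se > 0, coef / se, ifelse(coef == 0, 0, Inf * sign(coef)))
  pval <- if (df >= 1) 2 * stats::pt(-abs(tval), df) else rep(NA_real_, nc)
  names(coef) <- partition@calcNames
  methods::new("GLSFit",
               vHat = coef, se = as.numeric(se), tStat = as.numeric(tval),
               p = as.numeric(pval), residW = as.numeric(resid),
               sigma2Hat = sigma2, df = as.numeric(df),
               covVhat = sigma2 * XtXinv,
               nb = as.integer(nb), nc = as.integer(nc),
               Xw = X, yw = y, dfConvention = dfConvention)
}

#' Per-flux t-tests for calculated fluxes
#'
#' A calculated flux is judged statistically distinct from zero when
#' `|t| >= t(alpha/2, df)`.  No multiplicity adjustment is applied by
#' default (decisions at raw alpha); Benjamini-Hochberg adjusted p-values
#' can be reported alongside.
#'
#' @param fit a [GLSFit].
#' @param alpha significance level (default 0.05).
#' @param adjust `"none"` (default) or `"BH"` for an extra adjusted-p column.
#' @return `data.frame` with columns `flux`, `estimate`, `se`, `t`, `df`,
#'   `p`, (`p_adj`,) `significant`.
#' @export
tTest <- function(fit, alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (fit@df < 1)
    stop("t-tests require at least 1 residual degree of freedom",
         call. = FALSE)
  crit <- stats::qt(1 - alpha / 2, fit@df)
  out <- data.frame(
    flux = names(fit@vHat),
    estimate = unname(fit@vHat),
    se = fit@se,
    t = fit@tStat,
    df = fit@df,
    p = fit@p,
    significant = abs(fit@tStat) >= crit,
    stringsAsFactors = FALSE
  )
  if (adjust == "BH")
    out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Confidence intervals for calculated fluxes
#'
#' `vHat_i +/- t(alpha/2, df) * se_i`; zero-width when the fit is exact
#' (`sigma2Hat = 0`).
#'
#' @param fit a [GLSFit].
#' @param alpha significance level.
#' @return `data.frame` with `flux`, `estimate`, `lower`, `upper`.
#' @export
confidenceIntervals <- function(fit, alpha = 0.05) {
  crit <- stats::qt(1 - alpha / 2, fit@df)
  half <- crit * fit@se
  data.frame(flux = names(fit@vHat), estimate = unname(fit@vHat),
             lower = unname(fit@vHat) - half, upper = unname(fit@vHat) + half,
             stringsAsFactors = FALSE)
}

#' Prediction interval around predicted balances
#'
#' For each requested balance (row of the whitened system), the predicted
#' balance load and a prediction interval
#' `pred +/- t(alpha/2, df) * sigmaHat * sqrt(1 + leverage)` on the whitened
#' scale.  A balance whose observed load falls far outside its interval is
#' evidence against that balance closing.
#'
#' @param fit a [GLSFit].
#' @param rows balance indices (default all).
#' @param alpha significance level.
#' @return `data.frame` with `balance`, `observed`, `predicted`, `lower`,
#'   `upper` (whitened scale).
#' @export
predictionInterval <- function(fit, rows = seq_len(fit@nb), alpha = 0.05) {
  X <- fit@Xw[rows, , drop = FALSE]
  pred <- drop(X %*% fit@vHat)
  lev <- rowSums((X %*% (fit@covVhat / fit@sigma2Hat)) * X)
  half <- stats::qt(1 - alpha / 2, fit@df) *
    sqrt(fit@sigma2Hat * (1 + lev))
  data.frame(balance = rows, observed = fit@yw[rows], predicted = pred,
             lower = pred - half, upper = pred + half)
}

#' Chi-square gross measurement error test
#'
#' The classical consistency check: the sum of squared whitened residuals
#' `h = sum(residW^2)` is referred to a chi-square distribution with
#' `n_b - n_c` degrees of freedom (the system redundancy).  Large `h` (small
#' upper-tail p) flags gross measurement error, i.e. deviations between
#' observed and fitted balances too large to be explained by the assumed
#' noise.  The test does not assess overall quality of fit: errors can be
#' large yet still normally distributed.
#'
#' @param fit a [GLSFit].
#' @param dfConvention `"residual"` (`n_b - n_c`, default, the standard
#'   redundancy) or `"textbook"` (`n_b - n_c - 1`).
#' @return list with `statistic`, `df` and `p.value` (upper tail).
#' @export
chi2GrossErrorTest <- function(fit, dfConvention = c("residual", "textbook")) {
  dfConvention <- match.arg(dfConvention)
  df <- .df.value(fit@nb, fit@nc, dfConvention)
  if (df <= 0)
    stop("chi-square test requires positive redundancy (n_b > n_c)",
         call. = FALSE)
  h <- sum(fit@residW^2)
  list(statistic = h, df = df,
       p.value = stats::pchisq(h, df, lower.tail = FALSE))
}

#' Write a fit report as TSV
#'
#' @param fit a [GLSFit].
#' @param path output file path.
#' @param alpha significance level for the decision column and intervals.
#' @return `path`, invisibly.
#' @export
writeFitReport <- function(fit, path, alpha = 0.05) {
  tt <- tTest(fit, alpha = alpha)
  ci <- confidenceIntervals(fit, alpha = alpha)
  out <- data.frame(flux_name = tt$flux, estimate = tt$estimate, se = tt$se,
                    t = tt$t, df = tt$df, p = tt$p,
                    ci_lo = ci$lower, ci_hi = ci$upper,
                    significant = tt$significant)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
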