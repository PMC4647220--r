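#' Spearman rank correlation with t-approximation p-value
#'
#' Rank correlation (average ranks for ties) with a two-sided p-value from
#' the t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on
#' `n - 2` degrees of freedom.
#'
#' @param x,y Paired numeric vectors.
#' @return List with `rho`, `p` and `n`.
#' @export
cor_spearman <- function(x, y) {
  check_paired(x, y)
  n <- length(x)
  rho <- stats::cor(rank(x), rank(y))
  list(rho = rho, p = p_from_r(rho, n), n = n)
}

#' Pearson correlation with two-sided t-test p-value
#'
#' @param x,y Paired numeric vectors.
#' @return List with `r`, `p` and `n`.
#' @export
cor_pearson <- function(x, y) {
  check_paired(x, y)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y; correlation undefined")
  n <- length(x)
  r <- stats::cor(x, y)
  list(r = r, p = p_from_r(r, n), n = n)
}

#' Two-sided p-value for a correlation coefficient
#'
#' Uses the exact-null t distribution of `r * sqrt(n - 2) / sqrt(1 - r^2)`
#' with `n - 2` degrees of freedom.
#'
#' @param r Correlation coefficient.
#' @param n Sample size.
#' @return Two-sided p-value.
#' @export
p_from_r <- function(r, n) {
  stop_if_not_scalar(r, "r")
  if (n < 3) stop("need n >= 3")
  if (abs(r) >= 1) return(0)
  tval <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tval), df = n - 2)
}

#' JZS default Bayes factor for a correlation
#'
#' Default Bayes factor contrasting the model of a linear association
#' (Jeffreys-Zellner-Siow prior: Cauchy on the standardised effect,
#' induced by a scale mixture over the g parameter) against the null of
#' zero correlation. Evaluated by adaptive quadrature of
#' \deqn{BF_{10} = \sqrt{n/2}\,\Gamma(1/2)^{-1} \int_0^\infty
#'   (1+g)^{(n-2)/2}\,[1+(1-r^2)g]^{-(n-1)/2}\, g^{-3/2} e^{-n/(2g)}\,dg.}
#' BF10 > 1 favours the presence of a correlation and the result is
#' symmetric in the sign of `r`.
#'
#' @param r Observed Pearson correlation, `abs(r) < 1`.
#' @param n Number of paired observations, `n >= 3`.
#' @param rel_tol Relative tolerance passed to the quadrature.
#' @return The Bayes factor BF10 (positive scalar).
#' @export
jzs_cor_bf <- function(r, n, rel_tol = 1e-8) {
  stop_if_not_scalar(r, "r")
  stop_if_not_scalar(n, "n")
  if (n < 3) stop("need n >= 3 for the JZS correlation Bayes factor")
  if (abs(r) >= 1)
    stop("|r| = 1: likelihood degenerate, Bayes factor undefined")
  log_integrand <- function(g) {
    ((n - 2) / 2) * log1p(g) - ((n - 1) / 2) * log1p((1 - r^2) * g) -
      1.5 * log(g) - n / (2 * g)
  }
  q <- stats::integrate(function(g) exp(log_integrand(g)), 0, Inf,
                        rel.tol = rel_tol, abs.tol = 0,
                        stop.on.error = FALSE)
  if (q$message != "OK" || !is.finite(q$value) ||
      q$abs.error > max(1e-6, 0.001 * q$value))
    stop(sprintf("Bayes factor quadrature did not converge (message '%s', abs error %.3g)",
                 q$message, q$abs.error))
  sqrt(n / 2) / gamma(0.5) * q$value
}

#' Leave-2-out bootstrap confidence limits for a correlation
#'
#' Repeatedly drops `leave_out` randomly chosen subject pairs (without
#' replacement within a resample), recomputes the correlation, and returns
#' the 2.5/97.5 percentiles of the resampled distribution (percentile
#' method with linear interpolation). Deterministic given `seed`.
#'
#' @param x,y Paired numeric vectors.
#' @param n_resamples Number of resamples (default 200).
#' @param leave_out Number of subjects removed per resample (default 2).
#' @param seed Integer seed.
#' @param method "spearman" (default) or "pearson".
#' @return List with `ci_low`, `ci_high` and the resampled coefficients in
#'   `values`.
#' @export
bootstrap_ci <- function(x, y, n_resamples = 200, leave_out = 2, seed = NULL,
                         method = c("spearman", "pearson")) {
  check_paired(x, y)
  method <- match.arg(method)
  n <- length(x)
  if (n - leave_out < 3)
    stop("need n - leave_out >= 3 for a defined correlation")
  vals <- with_seed(seed, {
    vapply(seq_len(n_resamples), function(i) {
      keep <- setdiff(seq_len(n), sample.int(n, leave_out))
      if (method == "spearman") stats::cor(rank(x[keep]), rank(y[keep]))
      else stats::cor(x[keep], y[keep])
    }, numeric(1))
  })
  ci <- stats::quantile(vals, c(0.025, 0.975), names = FALSE, type = 7)
  list(ci_low = ci[1], ci_high = ci[2], values = vals)
}

#' Remove confound effects by linear regression
#'
#' Ordinary least squares of `values` on the confounds (with intercept);
#' returns the residuals, which have mean zero.
#'
#' @param values Numeric vector (one value per subject).
#' @param confounds Numeric vector or matrix of per-subject confounds.
#' @return Residual vector.
#' @export
regress_out <- function(values, confounds) {
  confounds <- as.matrix(confounds)
  if (nrow(confounds) != length(values))
    stop("confounds must have one row per subject")
  fit <- stats::lm.fit(cbind(1, confounds), values)
  as.numeric(fit$residuals)
}

#' Full correlation summary for one paired sample
#'
#' Convenience wrapper producing Spearman rho and p, Pearson r and p, the
#' JZS Bayes factor (from Pearson's r) and leave-2-out bootstrap limits.
#'
#' @inheritParams bootstrap_ci
#' @return List of class `correlation_result`.
#' @export
correlate_pair <- function(x, y, n_resamples = 200, seed = NULL) {
  sp <- cor_spearman(x, y)
  pe <- cor_pearson(x, y)
  bf <- jzs_cor_bf(pe$r, pe$n)
  ci <- bootstrap_ci(x, y, n_resamples = n_resamples, seed = seed)
  structure(list(rho = sp$rho, rho_p = sp$p, r = pe$r, r_p = pe$p,
                 bf10 = bf, ci_low = ci$ci_low, ci_high = ci$ci_high,
                 n = sp$n),
            class = "correlation_result")
}

check_paired <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y)) stop("x and y must be numeric")
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) stop("missing values in paired sample")
  invisible(TRUE)
}
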