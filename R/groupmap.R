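#' Group-level stimulation-effect map
#'
#' For every grid point, a paired two-sided t-test across subjects
#' compares the average activity in the band's test range between the
#' post-stimulus (0-600 ms) and pre-stimulus (-200-0 ms) windows. Points
#' are flagged at `p < alpha_level`, uncorrected. Points with zero
#' across-subject variance of the difference are undefined and excluded.
#'
#' @param responses List (one per subject) of `source_power` or
#'   `response_array` objects on a common grid.
#' @param band A `band_definition` (uses `test_range`).
#' @param alpha_level Significance threshold (default 0.005).
#' @param t_post Post-stimulus window in seconds (default `c(0, 0.6)`).
#' @return Object of class `significance_map`: list with `t` and `p`
#'   vectors (length = grid points; `NA` where undefined), logical
#'   `flagged`, `n_excluded`, `band`, `alpha_level`.
#' @export
group_stimulation_map <- function(responses, band, alpha_level = 0.005,
                                  t_post = c(0, 0.6)) {
  stopifnot(inherits(band, "band_definition"))
  if (length(responses) < 3) stop("need at least 3 subjects")
  freqs <- as.numeric(attr(responses[[1]], "fgrid"))
  times <- as.numeric(attr(responses[[1]], "tgrid"))
  fi <- which(freqs >= band$test_range[1] - 1e-9 &
                freqs <= band$test_range[2] + 1e-9)
  if (length(fi) == 0) stop("test range does not intersect the frequency grid")
  pre <- baseline_bins(attr(responses[[1]], "tgrid"))
  post <- which(times >= t_post[1] - 1e-9 & times <= t_post[2] + 1e-9)
  diffs <- vapply(responses, function(r) {
    apply(r[, fi, post, drop = FALSE], 1, mean) -
      apply(r[, fi, pre, drop = FALSE], 1, mean)
  }, numeric(dim(responses[[1]])[1]))           # points x subjects
  n <- ncol(diffs)
  mbar <- rowMeans(diffs)
  sdv <- apply(diffs, 1, stats::sd)
  tstat <- ifelse(sdv > 0, mbar / (sdv / sqrt(n)), NA_real_)
  pval <- 2 * stats::pt(-abs(tstat), df = n - 1)
  flagged <- !is.na(pval) & pval < alpha_level
  structure(list(t = tstat, p = pval, flagged = flagged,
                 n_excluded = sum(is.na(tstat)), band = band$name,
                 alpha_level = alpha_level),
            class = "significance_map")
}
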