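#' Temporal smoothing of source power
#'
#' Replaces the value at each time bin by the average of the bin itself
#' and the six preceding and six following bins (13-bin moving average).
#' At the epoch edges the window shrinks to the available bins rather
#' than padding with invented data.
#'
#' @param power A `source_power` (points x freq x time).
#' @param half_width Number of bins on each side (default 6).
#' @return The smoothed `source_power`.
#' @export
temporal_smooth <- function(power, half_width = 6) {
  d <- dim(power)
  n_t <- d[3]
  x <- matrix(power, ncol = n_t)
  lo <- pmax(seq_len(n_t) - half_width, 1L)
  hi <- pmin(seq_len(n_t) + half_width, n_t)
  s_op <- matrix(0, n_t, n_t)
  for (t in seq_len(n_t)) s_op[lo[t]:hi[t], t] <- 1 / (hi[t] - lo[t] + 1)
  out <- array(x %*% s_op, dim = d)
  attributes(out) <- attributes(power)
  dim(out) <- d
  out
}

#' 8-Hz spectral averaging in the high-frequency band
#'
#' For frequency bins at or above 40 Hz, the value is replaced by the
#' mean over the available bins within +/- 4 Hz of the bin centre (so the
#' 40 Hz estimate is the average over 36-44 Hz). Bins below 40 Hz are
#' untouched. Reduces noise in the gamma range where per-bin estimates
#' are unstable.
#'
#' @param power A `source_power`.
#' @return The band-averaged `source_power`.
#' @export
band_average_high <- function(power) {
  freqs <- as.numeric(attr(power, "fgrid"))
  d <- dim(power)
  amat <- diag(length(freqs))
  for (i in which(freqs >= 40)) {
    win <- which(abs(freqs - freqs[i]) <= 4 + 1e-9 & freqs >= 36 - 1e-9)
    amat[i, ] <- 0
    amat[i, win] <- 1 / length(win)
  }
  x <- aperm(power, c(2, 1, 3))
  dim(x) <- c(d[2], d[1] * d[3])
  y <- amat %*% x
  dim(y) <- c(d[2], d[1], d[3])
  out <- aperm(y, c(2, 1, 3))
  attributes(out)[c("fgrid", "tgrid", "lambda", "class")] <-
    attributes(power)[c("fgrid", "tgrid", "lambda", "class")]
  dim(out) <- d
  out
}

#' Baseline-referenced, normalised response
#'
#' Computes the stimulus-induced modulation of source power. The baseline
#' per (point, frequency) is the average power over the pre-stimulus bins
#' (t < 0). In `absolute` mode the modulation is
#' `(power - baseline) / SD_band`, where `SD_band` is the standard
#' deviation of baseline-window power over all V1 grid points and all
#' frequency bins of the band, computed separately for the low (4-30 Hz)
#' and high (>= 36 Hz) bands; this removes head- and brain-geometry
#' effects from the amplitude scale. In `percent` mode the modulation is
#' `100 * (power - baseline) / baseline`.
#'
#' @param power A `source_power` (after smoothing / band averaging).
#' @param grid The `source_grid` (supplies the V1 point set).
#' @param mode `"absolute"` (default) or `"percent"`.
#' @return Object of class `response_array` (points x freq x time) with
#'   attributes `fgrid`, `tgrid`, `mode`, `v1_indices`.
#' @export
normalize_and_modulate <- function(power, grid, mode = c("absolute", "percent")) {
  mode <- match.arg(mode)
  freqs <- as.numeric(attr(power, "fgrid"))
  tgrid <- attr(power, "tgrid")
  bl_bins <- baseline_bins(tgrid)
  if (length(bl_bins) == 0) stop("no baseline bins in time grid")
  d <- dim(power)
  baseline <- matrix(rowMeans(matrix(power[, , bl_bins, drop = FALSE],
                                     nrow = d[1] * d[2])), d[1], d[2])
  centred <- power - array(baseline, dim = d)
  if (mode == "absolute") {
    out <- centred
    for (band in list(freqs <= 30, freqs >= 36)) {
      if (!any(band)) next
      sd_band <- stats::sd(power[grid$v1_indices, band, bl_bins])
      if (!is.finite(sd_band) || sd_band == 0)
        stop("degenerate baseline: zero variance in V1 baseline power")
      out[, band, ] <- centred[, band, ] / sd_band
    }
  } else {
    if (any(baseline <= 0))
      stop("zero or negative baseline power: percent mode undefined")
    out <- 100 * centred / array(baseline, dim = d)
  }
  structure(out, class = "response_array", fgrid = attr(power, "fgrid"),
            tgrid = tgrid, mode = mode, v1_indices = grid$v1_indices,
            baseline = baseline)
}

#' V1-averaged response
#'
#' @param response A `response_array`.
#' @return Matrix (freq x time): the response averaged over V1 grid
#'   points, with `fgrid`, `tgrid`, `mode` attributes retained.
#' @export
v1_response <- function(response) {
  v1 <- attr(response, "v1_indices")
  d <- dim(response)
  out <- apply(response[v1, , , drop = FALSE], c(2, 3), mean)
  structure(out, fgrid = attr(response, "fgrid"),
            tgrid = attr(response, "tgrid"), mode = attr(response, "mode"))
}
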