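#' DICS spatial filters for one frequency
#'
#' Linearly constrained minimum-variance filters in the frequency domain:
#' `W = (L' Cr^-1 L)^-1 L' Cr^-1` per grid point, where
#' `Cr = Re(C) + lambda * mean(diag(Re(C))) * I` is the regularised real
#' part of the sensor CSD. The unit-gain constraint `W L = I` holds by
#' construction.
#'
#' @param cov Real sensor covariance / real-part CSD (N x N).
#' @param lf A `leadfield_set`.
#' @param lambda Diagonal-loading fraction of the mean sensor power
#'   (default 0.05).
#' @return Matrix of stacked filters (2M x N); rows `2i-1`, `2i` are the
#'   two tangential orientations of point `i`.
#' @export
dics_filters <- function(cov, lf, lambda = 0.05) {
  n <- nrow(cov)
  m <- attr(lf, "n_points")
  cr <- cov + lambda * mean(diag(cov)) * diag(n)
  ch <- tryCatch(chol(cr), error = function(e)
    stop("regularised CSD is singular; increase lambda", call. = FALSE))
  lmat <- matrix(lf, nrow = n)                  # N x 2M
  a <- chol2inv(ch) %*% lmat                    # Cr^-1 L
  odd <- seq(1, 2 * m, by = 2)
  l1 <- lmat[, odd, drop = FALSE]; l2 <- lmat[, odd + 1, drop = FALSE]
  a1 <- a[, odd, drop = FALSE];    a2 <- a[, odd + 1, drop = FALSE]
  # 2x2 Gram blocks G_i = L_i' Cr^-1 L_i, inverted in closed form.
  g11 <- colSums(l1 * a1); g12 <- colSums(l1 * a2)
  g21 <- colSums(l2 * a1); g22 <- colSums(l2 * a2)
  det <- g11 * g22 - g12 * g21
  if (any(!is.finite(det)) || any(abs(det) < 1e-300))
    stop("regularised CSD is singular; increase lambda", call. = FALSE)
  wall <- matrix(0, 2 * m, n)
  wall[odd, ] <- (g22 / det) * t(a1) - (g12 / det) * t(a2)
  wall[odd + 1, ] <- (g11 / det) * t(a2) - (g21 / det) * t(a1)
  wall
}

#' Event-related DICS source power
#'
#' Beamforms a time-resolved CSD series onto the source grid. By default
#' one spatial filter per frequency is computed from the time-averaged
#' (baseline + active) real-part CSD and applied at every time bin;
#' `filter_mode = "per_bin"` recomputes the filter at each bin instead.
#' Source power at a grid point is the largest eigenvalue of the 2 x 2
#' filtered real CSD over the two tangential orientations, hence
#' non-negative.
#'
#' @param csd A `csd_series` from [morlet_csd()].
#' @param lf A `leadfield_set` on the analysis grid.
#' @param lambda Diagonal-loading fraction (default 0.05).
#' @param filter_mode `"common"` (default) or `"per_bin"`.
#' @return Object of class `source_power`: array (points, freq, time)
#'   with attributes `fgrid`, `tgrid`, `lambda`.
#' @export
dics_power <- function(csd, lf, lambda = 0.05,
                       filter_mode = c("common", "per_bin")) {
  filter_mode <- match.arg(filter_mode)
  stopifnot(inherits(csd, "csd_series"))
  d <- dim(csd)
  n_f <- d[1]; n_t <- d[2]; n_sen <- d[3]
  m <- attr(lf, "n_points")
  pow <- array(0, dim = c(m, n_f, n_t))
  odd <- seq(1, 2 * m, by = 2)
  for (fi in seq_len(n_f)) {
    re_c <- array(Re(csd[fi, , , , drop = FALSE]), dim = c(n_t, n_sen, n_sen))
    if (filter_mode == "common") {
      cbar <- apply(re_c, c(2, 3), mean)
      wall <- dics_filters(cbar, lf, lambda)
    }
    for (ti in seq_len(n_t)) {
      cft <- matrix(re_c[ti, , ], n_sen, n_sen)
      if (filter_mode == "per_bin") wall <- dics_filters(cft, lf, lambda)
      t1 <- wall %*% cft                        # 2M x N
      p11 <- rowSums(t1[odd, , drop = FALSE] * wall[odd, , drop = FALSE])
      p22 <- rowSums(t1[odd + 1, , drop = FALSE] * wall[odd + 1, , drop = FALSE])
      p12 <- rowSums(t1[odd, , drop = FALSE] * wall[odd + 1, , drop = FALSE])
      pow[, fi, ti] <- eig_max_2x2(p11, p22, p12)
    }
  }
  structure(pow, class = "source_power", fgrid = attr(csd, "fgrid"),
            tgrid = attr(csd, "tgrid"), lambda = lambda)
}

#' DICS source power directly from wavelet coefficients
#'
#' Equivalent to [dics_power()] with common per-frequency filters, but
#' projects the per-trial sensor wavelet coefficients through the filters
#' before trial averaging, avoiding the full per-bin sensor CSD. This is
#' the fast path used by the cohort pipeline.
#'
#' @param coefs Complex coefficient array from [morlet_coefs()].
#' @param lf A `leadfield_set`.
#' @param lambda Diagonal-loading fraction.
#' @return A `source_power` (points, freq, time).
#' @export
dics_power_coefs <- function(coefs, lf, lambda = 0.05) {
  d <- dim(coefs)  # trial, sensor, freq, time
  raw <- list(n_tr = d[1], n_sen = d[2], n_f = d[3], n_t = d[4],
              fgrid = attr(coefs, "fgrid"), tgrid = attr(coefs, "tgrid"))
  # repack into the (time*freq) x (sensor*trial) internal layout
  x <- aperm(coefs, c(4, 3, 2, 1))
  dim(x) <- c(d[3] * d[4], d[1] * d[2])
  raw$re <- Re(x); raw$im <- Im(x)
  dics_power_raw(raw, lf, lambda)
}

# Fast path operating on the internal coefficient representation from
# morlet_coefs_raw(); avoids complex intermediates entirely.
dics_power_raw <- function(raw, lf, lambda = 0.05) {
  n_tr <- raw$n_tr; n_sen <- raw$n_sen; n_f <- raw$n_f; n_t <- raw$n_t
  m <- attr(lf, "n_points")
  odd <- seq(1, 2 * m, by = 2)
  tavg <- kronecker(diag(n_t), matrix(1 / n_tr, n_tr, 1))
  pow <- array(0, dim = c(m, n_f, n_t))
  for (fi in seq_len(n_f)) {
    rows <- ((fi - 1) * n_t + 1):(fi * n_t)
    # rows are (time x sensor*trial); transpose to sensor x (trial*time)
    ar <- t(raw$re[rows, , drop = FALSE])
    ai <- t(raw$im[rows, , drop = FALSE])
    dim(ar) <- c(n_sen, n_tr * n_t)
    dim(ai) <- c(n_sen, n_tr * n_t)
    cbar <- (tcrossprod(ar) + tcrossprod(ai)) / (n_tr * n_t)
    wall <- dics_filters(cbar, lf, lambda)
    sr <- wall %*% ar
    si <- wall %*% ai
    pd <- (sr^2 + si^2) %*% tavg                # 2M x n_t
    p12 <- (sr[odd, , drop = FALSE] * sr[odd + 1, , drop = FALSE] +
              si[odd, , drop = FALSE] * si[odd + 1, , drop = FALSE]) %*% tavg
    pow[, fi, ] <- eig_max_2x2(pd[odd, , drop = FALSE],
                               pd[odd + 1, , drop = FALSE], p12)
  }
  structure(pow, class = "source_power", fgrid = raw$fgrid,
            tgrid = raw$tgrid, lambda = lambda)
}

# Largest eigenvalue of symmetric 2x2 matrices, elementwise.
eig_max_2x2 <- function(p11, p22, p12) {
  0.5 * ((p11 + p22) + sqrt((p11 - p22)^2 + 4 * p12^2))
}
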