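#' Morlet-wavelet coefficients of epoched data
#'
#' Complex wavelet coefficients at every (frequency, time) node of the
#' analysis grids, for every trial and sensor. The wavelet is a Gaussian-
#' windowed complex exponential with width parameter `m` (cycles):
#' `sigma_t = m / (2 * pi * f)`, L2-normalised. The width parameter sets
#' both the spectral bandwidth (`sigma_f = f / m`) and the duration.
#'
#' Nodes whose full +/-3 sigma wavelet support does not fit inside the
#' epoch are computed with the truncated support but flagged invalid in
#' the attribute `valid` (freq x time logical), never silently dropped.
#'
#' @param trials A `trial_set`.
#' @param fgrid A `freq_grid`.
#' @param tgrid A `time_grid`.
#' @param m Wavelet width in cycles (default 7).
#' @return Complex array with dimensions (trial, sensor, freq, time),
#'   attributes `fgrid`, `tgrid`, `m`, `valid`.
#' @export
morlet_coefs <- function(trials, fgrid, tgrid, m = 7) {
  raw <- morlet_coefs_raw(trials, fgrid, tgrid, m)
  co <- complex(real = raw$re, imaginary = raw$im)
  dim(co) <- c(raw$n_t, raw$n_f, raw$n_sen, raw$n_tr)
  co <- aperm(co, c(4, 3, 2, 1))
  structure(co, fgrid = fgrid, tgrid = tgrid, m = m, valid = raw$valid)
}

# Internal fast representation: real and imaginary coefficient matrices
# of dimension (time*freq) x (sensor*trial): time fastest in rows (so
# one frequency is a contiguous row block), sensor fastest in columns.
morlet_coefs_raw <- function(trials, fgrid, tgrid, m = 7) {
  stopifnot(inherits(trials, "trial_set"))
  freqs <- as.numeric(fgrid)
  taus <- as.numeric(tgrid)
  st <- sample_times(trials)
  n_s <- length(st)
  if (min(taus) < st[1] - 1e-9 || max(taus) > st[n_s] + 1e-9)
    stop("time grid extends beyond the epoch")
  kern <- morlet_kernel(freqs, taus, st, m, 1 / trials$srate)
  d <- dim(trials$data)
  x <- matrix(aperm(trials$data, c(3, 2, 1)), nrow = n_s)
  list(re = kern$re %*% x, im = kern$im %*% x,
       n_f = length(freqs), n_t = length(taus), n_tr = d[1], n_sen = d[2],
       valid = kern$valid, fgrid = fgrid, tgrid = tgrid)
}

.kernel_cache <- new.env(parent = emptyenv())

# Stacked real/imaginary kernel matrices ((freq*time) x samples) for the
# conjugate wavelet inner product, plus the support-validity flags.
# Cached: the grids are identical across subjects of a cohort.
morlet_kernel <- function(freqs, taus, st, m, dt) {
  key <- paste(signif(c(freqs, taus, st[1], length(st), m, dt), 12),
               collapse = ",")
  hit <- .kernel_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- morlet_kernel_build(freqs, taus, st, m, dt)
  if (length(ls(.kernel_cache)) > 8) rm(list = ls(.kernel_cache), envir = .kernel_cache)
  .kernel_cache[[key]] <- out
  out
}

morlet_kernel_build <- function(freqs, taus, st, m, dt) {
  sigma <- m / (2 * pi * freqs)
  n_f <- length(freqs)
  n_t <- length(taus)
  n_s <- length(st)
  re <- matrix(0, n_f * n_t, n_s)
  im <- matrix(0, n_f * n_t, n_s)
  valid <- matrix(FALSE, n_f, n_t)
  for (fi in seq_len(n_f)) {
    s <- sigma[fi]
    norm <- (s * sqrt(pi))^-0.5 * dt
    for (ti in seq_len(n_t)) {
      lag <- st - taus[ti]
      env <- norm * exp(-lag^2 / (2 * s^2))
      # flush far-tail values to exact zero: they are numerically
      # irrelevant and subnormal operands stall the matrix product
      env[env < norm * 1e-12] <- 0
      ph <- 2 * pi * freqs[fi] * lag
      row <- (fi - 1) * n_t + ti
      re[row, ] <- env * cos(ph)
      im[row, ] <- -env * sin(ph)
      valid[fi, ti] <- (taus[ti] - 3 * s >= st[1] - 1e-9) &&
        (taus[ti] + 3 * s <= st[n_s] + 1e-9)
    }
  }
  list(re = re, im = im, valid = valid)
}

#' Time-resolved sensor cross-spectral density via Morlet wavelets
#'
#' For each (frequency, time) node, the CSD is the trial average of the
#' outer product of the sensor wavelet-coefficient vector with its
#' conjugate transpose; Hermitian by construction with real non-negative
#' diagonal.
#'
#' @inheritParams morlet_coefs
#' @return Object of class `csd_series`: complex array
#'   (freq, time, sensor, sensor) with attributes `fgrid`, `tgrid`, `m`,
#'   `n_trials_used`, `valid`.
#' @export
morlet_csd <- function(trials, fgrid, tgrid, m = 7) {
  co <- morlet_coefs(trials, fgrid, tgrid, m)
  d <- dim(co)  # trial, sensor, freq, time
  n_f <- d[3]; n_t <- d[4]; n_sen <- d[2]; n_tr <- d[1]
  csd <- array(complex(real = 0), dim = c(n_f, n_t, n_sen, n_sen))
  for (fi in seq_len(n_f)) {
    for (ti in seq_len(n_t)) {
      a <- matrix(co[, , fi, ti], n_tr, n_sen)
      csd[fi, ti, , ] <- crossprod(Conj(a), a) / n_tr
    }
  }
  structure(csd, class = "csd_series", fgrid = attr(co, "fgrid"),
            tgrid = attr(co, "tgrid"), m = m, n_trials_used = n_tr,
            valid = attr(co, "valid"))
}
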