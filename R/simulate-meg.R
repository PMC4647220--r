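#' Simulate a multi-trial MEG recording for one subject
#'
#' Forward-projects V1 source activity through the spherical-conductor
#' model and adds spatially correlated pink sensor noise and an EOG
#' channel with optional blink artifacts. The V1 patch carries three
#' coherent components with random per-trial phases:
#' \itemize{
#'   \item an induced gamma burst at the subject's peak frequency with a
#'     Gaussian envelope centred at the subject's latency (the canonical
#'     morphology: a response around 100-500 ms peaking near 300 ms),
#'   \item ongoing alpha (10 Hz) and beta (20 Hz) rhythms whose
#'     amplitudes are attenuated after stimulus onset by the subject's
#'     suppression depths, yielding post-stimulus alpha/beta suppression.
#' }
#' Blink trials (fraction `blink_rate`) carry a stereotyped biphasic EOG
#' deflection exceeding 150 uV plus a frontal sensor-field artifact.
#'
#' The RNG draws are made in a fixed order independent of the component
#' toggles, so e.g. a signal-only and a noise-only call with the same
#' seed decompose the full recording exactly.
#'
#' @param subject A `subject_truth`.
#' @param head A `head_model`.
#' @param grid A `source_grid` (supplies V1 points).
#' @param n_trials Number of trials (default 180; the reference analyses
#'   accepted 151-254 trials per subject).
#' @param seed Integer seed.
#' @param blink_rate Fraction of trials with a blink artifact.
#' @param noise_sd Sensor pink-noise SD in tesla (default 50 fT).
#' @param source_scale Multiplier on all source amplitudes (used for SNR
#'   sweeps).
#' @param components Character subset of `c("signal", "noise", "blink")`
#'   to include.
#' @param lf Optional precomputed `leadfield_set` for `grid` (saves
#'   recomputation across subjects).
#' @return A `trial_set`; attribute `blink_trials` records the simulated
#'   blink trial indices.
#' @export
simulate_meg_recording <- function(subject, head, grid, n_trials = 180,
                                   seed = NULL, blink_rate = 0.15,
                                   noise_sd = 50e-15, source_scale = 1,
                                   components = c("signal", "noise", "blink"),
                                   lf = NULL) {
  stopifnot(inherits(subject, "subject_truth"), inherits(head, "head_model"),
            inherits(grid, "source_grid"))
  if (n_trials < 1) stop("n_trials must be positive")
  if (length(grid$v1_indices) == 0) stop("empty V1 index set in source grid")
  srate <- 600
  st <- -0.2 + (seq_len(600) - 1) / srate
  n_sen <- head$n_sensors
  if (is.null(lf)) lf <- leadfield(head, grid)
  # Summed topography of the coherent V1 patch (first tangential
  # orientation), one per component; A m units.
  topo1 <- apply(lf[, 1, grid$v1_indices, drop = FALSE], 1, sum)
  amp_q <- source_scale * c(gamma = 8e-9 * subject$gamma_amp,
                            alpha = 12e-9, beta = 8e-9)
  topo <- outer(topo1, amp_q)                       # N x 3

  draws <- with_seed(seed, list(
    phases = matrix(stats::runif(3 * n_trials, 0, 2 * pi), n_trials, 3),
    blink_flag = stats::runif(n_trials) < blink_rate,
    blink_time = stats::runif(n_trials, 0.0, 0.5),
    eog_white = matrix(stats::rnorm(n_trials * 600), 600, n_trials),
    sens_white = matrix(stats::rnorm(n_trials * n_sen * 600), 600,
                        n_trials * n_sen)))

  lat <- subject$gamma_latency / 1000
  g_env <- exp(-(st - lat)^2 / (2 * 0.08^2))
  supp_ramp <- stats::plogis((st - 0.25) / 0.07)
  a_env <- 1 - subject$alpha_supp * supp_ramp
  b_env <- 1 - subject$beta_supp * supp_ramp

  data <- array(0, dim = c(n_trials, n_sen, 600))
  if ("signal" %in% components) {
    u <- array(0, dim = c(n_trials, 600, 3))
    for (r in seq_len(n_trials)) {
      u[r, , 1] <- g_env * cos(2 * pi * subject$gamma_peak_freq * st +
                                 draws$phases[r, 1])
      u[r, , 2] <- a_env * cos(2 * pi * 10 * st + draws$phases[r, 2])
      u[r, , 3] <- b_env * cos(2 * pi * 20 * st + draws$phases[r, 3])
    }
    dim(u) <- c(n_trials * 600, 3)
    sig <- u %*% t(topo)                            # (trial*sample) x N
    dim(sig) <- c(n_trials, 600, n_sen)
    data <- data + aperm(sig, c(1, 3, 2))
  }
  if ("noise" %in% components && noise_sd > 0) {
    pk <- pink_filter(draws$sens_white, srate)      # 600 x (trials*sensors)
    dim(pk) <- c(600, n_trials, n_sen)
    pk <- aperm(pk, c(2, 1, 3))
    dim(pk) <- c(n_trials * 600, n_sen)
    mix <- sensor_mixing(head)
    nz <- noise_sd * (pk %*% mix)
    dim(nz) <- c(n_trials, 600, n_sen)
    data <- data + aperm(nz, c(1, 3, 2))
  }
  eog <- 15e-6 * t(pink_filter(draws$eog_white, srate))
  blink_idx <- integer(0)
  if ("blink" %in% components && any(draws$blink_flag)) {
    blink_idx <- which(draws$blink_flag)
    btopo <- blink_topography(head)
    for (r in blink_idx) {
      w <- blink_waveform(st, draws$blink_time[r])
      eog[r, ] <- eog[r, ] + 350e-6 * w
      data[r, , ] <- data[r, , ] + 1.5e-12 * outer(btopo, w)
    }
  }
  out <- trial_set(data, eog, srate = srate, t0 = -0.2)
  attr(out, "blink_trials") <- blink_idx
  out
}

# 1/sqrt(f) spectral shaping of white columns; output standardised to
# unit column SD (approximately; exact overall scale set by caller).
pink_filter <- function(white, srate) {
  n <- nrow(white)
  fr <- c(0, seq_len(n - 1)) * srate / n
  fr <- pmin(fr, srate - fr)
  amp <- 1 / sqrt(pmax(fr, 2))
  amp[1] <- 0                                       # remove DC
  sp <- stats::mvfft(white) * amp
  x <- Re(stats::mvfft(sp, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Smooth spatial correlation across sensors (30 mm Gaussian) with a
# small independent component per sensor.
sensor_mixing <- function(head) {
  p <- head$sensor_positions
  d2 <- as.matrix(stats::dist(p))^2
  cv <- 0.9 * exp(-d2 / (2 * 0.03^2)) + 0.1 * diag(nrow(p))
  chol(cv)
}

blink_waveform <- function(st, tc) {
  exp(-(st - tc)^2 / (2 * 0.04^2)) - 0.5 * exp(-(st - tc - 0.1)^2 / (2 * 0.05^2))
}

# Fixed frontal field pattern of the ocular artifact.
blink_topography <- function(head) {
  src <- head$sphere_center + c(0.095, 0, 0)
  d2 <- rowSums(sweep(head$sensor_positions, 2, src)^2)
  exp(-d2 / (2 * 0.05^2))
}
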