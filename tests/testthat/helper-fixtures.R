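# Shared fixtures and independent oracles, built in code at test time.

# Small standard cohort configuration (defaults untouched).
test_config <- function(seed = 7, ...) cohort_config(seed = seed, ...)

test_subject <- function(seed = 7) make_cohort(test_config(seed))[[1]]

small_head <- function(n = 32) head_model(n)

small_grid <- function() posterior_grid()

# Trial set holding a pure sinusoid on every sensor (tesla scale).
tone_trialset <- function(freq, n_trials = 3, n_sensors = 2,
                          amp = 1e-12, phase = 0) {
  st <- -0.2 + (0:599) / 600
  wave <- amp * cos(2 * pi * freq * st + phase)
  data <- array(rep(wave, each = n_trials * n_sensors),
                dim = c(n_trials, n_sensors, 600))
  trial_set(data, matrix(0, n_trials, 600))
}

# --- Independent Biot-Savart oracle for the spherical forward model ---
# The radial field outside a spherical conductor depends only on the
# primary current dipole (volume currents are radially silent). The full
# field is reconstructed from B_r alone: the magnetic scalar potential is
# obtained by radial quadrature of B_r and differentiated numerically.
# Shares no code with the closed-form Sarvas implementation under test.

oracle_br_primary <- function(q_pos, q_mom, r_vec) {
  a <- r_vec - q_pos
  qxa <- c(q_mom[2] * a[3] - q_mom[3] * a[2],
           q_mom[3] * a[1] - q_mom[1] * a[3],
           q_mom[1] * a[2] - q_mom[2] * a[1])
  1e-7 * sum(qxa * r_vec / sqrt(sum(r_vec^2))) / sum(a^2)^1.5
}

oracle_potential <- function(q_pos, q_mom, r_vec) {
  rr <- sqrt(sum(r_vec^2))
  rhat <- r_vec / rr
  f <- function(s) vapply(s, function(si)
    oracle_br_primary(q_pos, q_mom, si * rhat), numeric(1))
  stats::integrate(f, rr, Inf, rel.tol = 1e-12)$value / (4 * pi * 1e-7)
}

oracle_field <- function(q_pos, q_mom, r_vec, h = 1e-5) {
  -4 * pi * 1e-7 * vapply(1:3, function(i) {
    e <- numeric(3); e[i] <- h
    (oracle_potential(q_pos, q_mom, r_vec + e) -
       oracle_potential(q_pos, q_mom, r_vec - e)) / (2 * h)
  }, numeric(1))
}

# --- Monte-Carlo oracle for the JZS correlation Bayes factor ---
# BF10 = E_g[(1+g)^((n-2)/2) * (1+(1-r^2)g)^(-(n-1)/2)] with
# g ~ InvGamma(1/2, n/2); estimated by direct sampling, independently of
# the quadrature used by the implementation.
oracle_bf_mc <- function(r, n, nsamp = 1e6, seed = 1) {
  set.seed(seed)
  g <- (n / 2) / stats::rgamma(nsamp, shape = 0.5)
  w <- exp(((n - 2) / 2) * log1p(g) - ((n - 1) / 2) * log1p((1 - r^2) * g))
  mean(w)
}

# Permutation p-value for a rank correlation (two-sided).
perm_spearman_p <- function(x, y, nperm = 1e5, seed = 1) {
  set.seed(seed)
  rx <- rank(x); ry <- rank(y)
  obs <- abs(stats::cor(rx, ry))
  hits <- vapply(seq_len(nperm), function(i)
    abs(stats::cor(rx, sample(ry))) >= obs - 1e-12, logical(1))
  mean(hits)
}

# Minimal hand-built dynamic PET object for estimator unit tests.
manual_pet_dynamic <- function(frames, geometry, rois) {
  structure(list(frames = frames,
                 frame_times = cbind(start = 0:11 * 5, end = 1:12 * 5),
                 voxel_size = geometry$voxel_size,
                 geometry = geometry, rois = rois),
            class = "pet_dynamic")
}
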