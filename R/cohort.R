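#' Configuration of a synthetic MEG-PET cohort
#'
#' Fixes the generative conditions of a cohort of synthetic subjects whose
#' V1 GABA-A receptor density is coupled to the frequency (positively) and
#' amplitude (negatively) of their visual gamma response. Coupling is
#' imposed on the *total* V1 B'max (sum over V1 voxels), matching the
#' aggregation used by the analysis.
#'
#' By default the coupling slopes and residual SDs are derived so that the
#' population correlation between total V1 density and each gamma feature
#' is `target_rho` in magnitude (positive for peak frequency, negative for
#' amplitude), with a population gamma-frequency SD of `freq_sd` around
#' the centre of `gamma_freq_range`.
#'
#' @param n_subjects Number of subjects (default 10).
#' @param coupling_freq Slope of gamma peak frequency on total V1 B'max
#'   (Hz per density unit); derived from `target_rho` when `NULL`.
#' @param coupling_amp Slope of gamma amplitude on total V1 B'max
#'   (negative); derived when `NULL`.
#' @param noise_sd_freq,noise_sd_amp Residual SDs; derived when `NULL`.
#' @param gamma_freq_range Population range of gamma peak frequencies,
#'   must lie within 40-100 Hz (default `c(45, 85)`).
#' @param blink_rate Fraction of MEG trials carrying a blink artifact.
#' @param target_rho Magnitude of the intended population correlation
#'   (default 0.75).
#' @param freq_sd Total population SD of the gamma peak frequency in Hz.
#' @param amp_mean,amp_sd Population mean and SD of gamma amplitude
#'   (normalised units).
#' @param free_conc Static-scale free-ligand concentration.
#' @param kd_app Static-scale apparent dissociation constant (defaults to
#'   `free_conc / 4`, i.e. ~80% receptor occupancy, a well-conditioned
#'   partial-saturation protocol).
#' @param pet_noise_frac PET noise SD as a fraction of `free_conc` on the
#'   static image (default 0.05).
#' @param geometry A `pet_geometry`.
#' @param seed Integer seed making the cohort reproducible.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 10,
                          coupling_freq = NULL, coupling_amp = NULL,
                          noise_sd_freq = NULL, noise_sd_amp = NULL,
                          gamma_freq_range = c(45, 85),
                          blink_rate = 0.15,
                          target_rho = 0.75,
                          freq_sd = 8, amp_mean = 1, amp_sd = 0.25,
                          free_conc = 10, kd_app = free_conc / 4,
                          pet_noise_frac = 0.05,
                          geometry = pet_geometry(),
                          seed = 1) {
  if (n_subjects < 3) stop("n_subjects must be >= 3")
  if (gamma_freq_range[1] < 40 || gamma_freq_range[2] > 100 ||
      diff(gamma_freq_range) <= 0)
    stop("gamma_freq_range must be an interval within [40, 100] Hz")
  if (blink_rate < 0 || blink_rate > 1) stop("blink_rate must be in [0, 1]")
  if (target_rho <= 0 || target_rho >= 1) stop("target_rho must be in (0, 1)")
  rois <- pet_rois(geometry)
  w <- density_profile(geometry, rois)
  # Total V1 density is linear in the subject factor u ~ U(-1, 1):
  # D(u) = d0 + d1 * u, so sd(D) = d1 / sqrt(3).
  d0 <- sum(w$base[rois$v1])
  d1 <- w$spread_frac * d0
  sd_d <- d1 / sqrt(3)
  sig_f <- freq_sd * target_rho
  sig_a <- amp_sd * target_rho
  if (is.null(coupling_freq)) coupling_freq <- sig_f / sd_d
  if (is.null(coupling_amp)) coupling_amp <- -sig_a / sd_d
  if (is.null(noise_sd_freq)) noise_sd_freq <- freq_sd * sqrt(1 - target_rho^2)
  if (is.null(noise_sd_amp)) noise_sd_amp <- amp_sd * sqrt(1 - target_rho^2)
  structure(list(n_subjects = as.integer(n_subjects),
                 coupling_freq = coupling_freq, coupling_amp = coupling_amp,
                 noise_sd_freq = noise_sd_freq, noise_sd_amp = noise_sd_amp,
                 gamma_freq_range = gamma_freq_range,
                 blink_rate = blink_rate,
                 amp_mean = amp_mean,
                 free_conc = free_conc, kd_app = kd_app,
                 pet_noise_frac = pet_noise_frac,
                 geometry = geometry, rois = rois,
                 mean_total_v1_bmax = d0,
                 seed = seed),
            class = "cohort_config")
}

# Deterministic spatial density profile shared by all subjects: a
# receptor-rich occipital/V1 region (with a mild fixed within-region
# gradient), moderate density elsewhere in the brain, zero in the pons.
# `base` is the per-voxel density at subject factor u = 0 for the local
# (occipital) compartment; `background` for the rest of the brain.
density_profile <- function(geometry, rois) {
  nvox <- prod(geometry$dim)
  xyz <- voxel_coords(geometry)
  base <- numeric(nvox)
  background <- numeric(nvox)
  background[rois$brain] <- 4
  # The receptor-rich medial occipital compartment extends a margin
  # beyond V1 and the Scatchard ROI so that after 15-21 mm smoothing the
  # V1 neighbourhood is still dominated by the same subject factor.
  occ_comp <- union(union(rois$v1, rois$occipital),
                    voxel_ball(geometry, rois$v1_center + c(0, 0, 9), 24))
  occ_comp <- intersect(occ_comp, rois$brain)
  occ_comp <- setdiff(occ_comp, rois$pons)
  gradient <- 1 + 0.15 * sin(xyz[occ_comp, 3] / 9) +
    0.10 * cos(xyz[occ_comp, 2] / 11)
  base[occ_comp] <- 10 * gradient
  background[occ_comp] <- 0
  background[rois$pons] <- 0
  list(base = base, background = background, spread_frac = 0.3)
}

#' Generate the ground truth of a synthetic cohort
#'
#' Draws, per subject, the latent quantities behind both modalities: the
#' voxelwise true B'max field, the gamma peak frequency/amplitude/latency
#' (coupled to total V1 density through the configured slopes), alpha and
#' beta suppression depths, and the anatomical confounds (V1 surface
#' area, gray-matter density). Deterministic given `config$seed`.
#'
#' @param config A `cohort_config`.
#' @return List of `subject_truth` objects. Each has fields
#'   `subject_id`, `gamma_peak_freq` (Hz), `gamma_amp`, `gamma_latency`
#'   (ms), `alpha_supp`, `beta_supp`, `bmax_field` (3-D array),
#'   `total_v1_bmax`, `kd_app`, `free_conc`, `v1_surface_area`,
#'   `gm_density`, `gm_map`, `v1_mr_voxels` (MR voxel centres, world mm),
#'   `geometry`, `rois`.
#' @export
make_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_subjects
  geom <- config$geometry
  rois <- config$rois
  prof <- density_profile(geom, rois)
  fr <- config$gamma_freq_range
  mid_freq <- mean(fr)
  # MR-space V1 sampling at 2 mm; maps many-to-one onto PET voxels.
  v1_mr <- mr_v1_coords(rois$v1_center, radius = 12, spacing = 2)
  subjects <- with_seed(config$seed, {
    lapply(seq_len(n), function(i) {
      u_local <- stats::runif(1, -1, 1)       # occipital density factor
      u_rest <- stats::runif(1, -1, 1)        # independent brain-wide factor
      field <- prof$base * (1 + prof$spread_frac * u_local) +
        prof$background * (1 + 0.25 * u_rest)
      texture <- stats::rnorm(length(field), 0, 0.2)
      texture[field == 0] <- 0
      field <- pmax(field + texture, 0)
      d_i <- sum(field[rois$v1])
      freq <- mid_freq + config$coupling_freq * (d_i - config$mean_total_v1_bmax) +
        stats::rnorm(1, 0, config$noise_sd_freq)
      freq <- min(max(freq, fr[1]), fr[2])
      amp <- config$amp_mean +
        config$coupling_amp * (d_i - config$mean_total_v1_bmax) +
        stats::rnorm(1, 0, config$noise_sd_amp)
      amp <- max(amp, 0.05)
      structure(list(subject_id = sprintf("s%02d", i),
                     gamma_peak_freq = freq,
                     gamma_amp = amp,
                     gamma_latency = min(max(stats::rnorm(1, 300, 40), 200), 420),
                     alpha_supp = stats::runif(1, 0.4, 0.7),
                     beta_supp = stats::runif(1, 0.3, 0.6),
                     bmax_field = array(field, dim = geom$dim),
                     total_v1_bmax = d_i,
                     kd_app = config$kd_app,
                     free_conc = config$free_conc,
                     v1_surface_area = stats::rnorm(1, 2000, 150),
                     gm_density = stats::runif(1, 0.55, 0.8),
                     v1_mr_voxels = v1_mr,
                     geometry = geom, rois = rois),
                class = "subject_truth")
    })
  })
  # gm map: flat per-subject gray-matter fraction over the brain.
  for (i in seq_along(subjects)) {
    gm <- array(0, dim = geom$dim)
    gm[rois$brain] <- subjects[[i]]$gm_density
    subjects[[i]]$gm_map <- gm
  }
  subjects
}

mr_v1_coords <- function(center, radius, spacing) {
  ax <- seq(-radius, radius, by = spacing)
  g <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  g <- g[sqrt(rowSums(g^2)) <= radius, , drop = FALSE]
  sweep(g, 2, center, `+`)
}

#' Cohort ground-truth table
#'
#' @param cohort List of `subject_truth` objects from [make_cohort()].
#' @return data.frame with columns `subject_id`, `gamma_peak_freq_hz`,
#'   `gamma_amp`, `gamma_latency_ms`, `total_v1_bmax`,
#'   `v1_surface_area_mm2`, `gm_density`.
#' @export
cohort_truth_table <- function(cohort) {
  data.frame(
    subject_id = vapply(cohort, `[[`, "", "subject_id"),
    gamma_peak_freq_hz = vapply(cohort, `[[`, 0, "gamma_peak_freq"),
    gamma_amp = vapply(cohort, `[[`, 0, "gamma_amp"),
    gamma_latency_ms = vapply(cohort, `[[`, 0, "gamma_latency"),
    total_v1_bmax = vapply(cohort, `[[`, 0, "total_v1_bmax"),
    v1_surface_area_mm2 = vapply(cohort, `[[`, 0, "v1_surface_area"),
    gm_density = vapply(cohort, `[[`, 0, "gm_density"))
}
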