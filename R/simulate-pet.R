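#' Simulate a dynamic flumazenil-PET acquisition
#'
#' Forward model for a single partial-saturation injection, designed to be
#' the exact inverse of the parametric estimator: the five late frames
#' (labels 8-12, nominally 20-55 min post-injection) are at pseudo-
#' equilibrium with declining free-ligand concentration
#' `F_t = free_conc * phi_t` (`sum(phi_t) = 1`, so the summed static pons
#' intensity equals `free_conc`), and per-voxel bound concentration
#' `B_t(v) = bmax(v) * F_t / (F_t + Kd_frame)`. The frame-level Kd is
#' solved so that the summed bound concentration follows the static-scale
#' saturation law `sum(B_t) = bmax * F / (F + kd_app)`; with zero noise
#' the full estimator chain recovers `bmax_field` exactly. Earlier frames
#' carry a rising uptake ramp and are ignored by the estimator. Pons
#' voxels have zero receptor density, so their late-frame intensity is
#' pure free ligand.
#'
#' Noise is additive Gaussian per voxel and frame, with per-frame SD
#' proportional to the square root of the frame activity (as for
#' count-limited PET) and normalised so the static (summed) image has
#' noise SD `noise_frac * free_conc`.
#'
#' @param subject A `subject_truth` (needs `bmax_field`, `kd_app`,
#'   `free_conc`, `geometry`, `rois`).
#' @param geometry PET geometry (defaults to the subject's).
#' @param seed Integer seed; `NULL` for the current RNG stream.
#' @param noise_frac Noise SD as a fraction of `free_conc` on the static
#'   image (default 0.05; 0 gives the noise-free forward model).
#' @return Object of class `pet_dynamic`: `frames` (X x Y x Z x 12),
#'   `frame_times` (12 x 2, minutes), `voxel_size`, `geometry`, `rois`.
#' @export
simulate_pet_dynamic <- function(subject, geometry = subject$geometry,
                                 seed = NULL, noise_frac = 0.05) {
  stopifnot(inherits(subject, "subject_truth"))
  bmax <- as.numeric(subject$bmax_field)
  if (length(bmax) != prod(geometry$dim))
    stop("bmax_field does not match the PET geometry")
  if (any(bmax < 0)) stop("bmax_field must be non-negative")
  f_static <- subject$free_conc
  kd_app <- subject$kd_app
  if (f_static <= 0 || kd_app <= 0) stop("free_conc and kd_app must be positive")
  phi <- late_frame_phi()
  s_target <- f_static / (f_static + kd_app)
  kd_frame <- solve_frame_kd(phi * f_static, s_target)
  ends <- c(2, 4, 6, 9, 12, 16, 20, 27, 34, 41, 48, 55)
  starts <- c(0, ends[-12])
  nvox <- length(bmax)
  frames <- array(0, dim = c(geometry$dim, 12L))
  bound_static <- bmax * s_target
  ramp <- seq(0.15, 1, length.out = 7)
  for (t in 1:7) {
    frames[, , , t] <- ramp[t] * 0.2 * (f_static + bound_static)
  }
  for (k in 1:5) {
    f_t <- phi[k] * f_static
    frames[, , , 7 + k] <- f_t + bmax * f_t / (f_t + kd_frame)
  }
  if (noise_frac > 0) {
    # per-frame SD proportional to sqrt(frame activity), normalised so the
    # static (summed) image carries exactly noise_frac * free_conc
    sd_t <- noise_frac * f_static / sqrt(5) * sqrt(phi / mean(phi))
    noise <- with_seed(seed,
      matrix(stats::rnorm(nvox * 5), nvox, 5) %*% diag(sd_t))
    frames[, , , 8:12] <- frames[, , , 8:12] + array(noise, c(geometry$dim, 5))
  }
  structure(list(frames = frames,
                 frame_times = cbind(start = starts, end = ends),
                 voxel_size = geometry$voxel_size,
                 geometry = geometry, rois = subject$rois),
            class = "pet_dynamic")
}

# Fractions of the static free concentration carried by the five late
# frames; a pronounced washout (10x from first to last late frame) keeps
# the frame-wise Scatchard well conditioned. Sums to 1.
late_frame_phi <- function() c(0.50, 0.24, 0.13, 0.08, 0.05)

# Frame-level Kd such that sum_t F_t / (F_t + kd) equals the target
# summed occupancy. Monotone in kd, so the root is unique.
solve_frame_kd <- function(f_t, s_target) {
  stopifnot(s_target > 0, s_target < 1)
  f <- function(kd) sum(f_t / (f_t + kd)) - s_target
  stats::uniroot(f, lower = 1e-9 * max(f_t), upper = 1e6 * max(f_t),
                 tol = 1e-12 * max(f_t))$root
}

#' Run the complete PET parametric pipeline for one subject
#'
#' Dynamic frames -> static image -> pons free-ligand estimate ->
#' Scatchard fit -> B'max map -> Gaussian smoothing -> V1 aggregation,
#' in the same order as the reference analysis (smoothing before V1
#' aggregation).
#'
#' @param dyn A `pet_dynamic`.
#' @param v1_mr_voxels MR V1 voxel coordinates (world mm) or PET voxel
#'   indices; defaults to the dynamic's own V1 ROI indices.
#' @param fwhm Smoothing kernel FWHM in mm.
#' @param smooth Logical; smooth before aggregation (default TRUE).
#' @param fit Optional precomputed `scatchard_fit` (e.g. from
#'   [fit_scatchard_pooled()]); defaults to the subject's own fit.
#' @return List with `fit` (`scatchard_fit`), `map` (smoothed
#'   `bmax_map`), `total_v1_bmax` (scalar), `whole_brain_bmax` (same
#'   aggregation over the brain mask).
#' @export
analyze_pet_subject <- function(dyn, v1_mr_voxels = dyn$rois$v1,
                                fwhm = c(15, 15, 21), smooth = TRUE,
                                fit = NULL) {
  img <- static_image(dyn)
  if (is.null(fit))
    fit <- fit_scatchard(dyn, dyn$rois$pons, dyn$rois$occipital,
                         weights = "free2")
  map <- bmax_map(img, fit)
  if (smooth) map <- smooth_map(map, fwhm)
  total <- v1_total_density(map, v1_mr_voxels)
  whole <- v1_total_density(map, dyn$rois$brain)
  list(fit = fit, map = map,
       total_v1_bmax = as.numeric(total),
       whole_brain_bmax = as.numeric(whole),
       v1_voxels = attr(total, "voxels"))
}
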