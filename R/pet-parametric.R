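#' Static PET image from late dynamic frames
#'
#' Voxelwise sum of frames 8-12 of the dynamic acquisition (1-based frame
#' labels; these correspond to 20-55 min post-injection in the synthetic
#' frame timing). The summed image is treated as the pseudo-equilibrium
#' concentration map.
#'
#' @param dyn A `pet_dynamic` object (see [simulate_pet_dynamic()]).
#' @param frames Integer vector of 1-based frame labels to sum.
#' @return Object of class `static_image`: list with `values` (3-D array),
#'   `frames_summed` and `geometry`.
#' @export
static_image <- function(dyn, frames = 8:12) {
  stopifnot(inherits(dyn, "pet_dynamic"))
  if (any(frames < 1 | frames > dim(dyn$frames)[4]))
    stop("frame labels out of range")
  d3 <- dim(dyn$frames)[1:3]
  vals <- array(rowSums(matrix(dyn$frames[, , , frames, drop = FALSE],
                               nrow = prod(d3))), dim = d3)
  if (!all(is.finite(vals))) stop("non-finite intensities in static image")
  structure(list(values = vals, frames_summed = frames,
                 geometry = dyn$geometry),
            class = "static_image")
}

#' Free-ligand concentration from the pons reference region
#'
#' The pons is essentially free of benzodiazepine receptors, so its mean
#' static intensity estimates the free (non-specifically bound) ligand
#' concentration.
#'
#' @param img A `static_image`.
#' @param pons_roi Integer vector of 1-based linear voxel indices.
#' @return Scalar free-ligand concentration estimate.
#' @export
estimate_free_ligand <- function(img, pons_roi) {
  stopifnot(inherits(img, "static_image"))
  if (length(pons_roi) == 0) stop("empty pons ROI")
  mean(img$values[pons_roi])
}

#' Partial-saturation Scatchard fit of the apparent dissociation constant
#'
#' Under partial saturation the bound/free ratio falls linearly in the
#' bound concentration (Scatchard line, slope -1/Kd). Occupancy variation
#' from a single injection is only available across time, so the fit is
#' performed across the late dynamic frames: for each frame the free
#' concentration is the pons mean and the bound concentration is the
#' occipital-ROI mean minus free. The frame-level Kd is then converted to
#' the apparent Kd on the scale of the summed static image, so that the
#' closed-form inversion in [bmax_map()] is exact.
#'
#' @param dyn A `pet_dynamic`.
#' @param pons_roi,occ_roi Integer voxel index vectors (reference and
#'   occipital ROI).
#' @param frames Late frames used (1-based labels, default 8:12).
#' @param weights `"none"` for ordinary least squares (default) or
#'   `"free2"` for weights proportional to the squared frame free
#'   concentration, which counteracts the strong heteroscedasticity of
#'   `B/F` in low-activity washout frames.
#' @return Object of class `scatchard_fit`: `free_conc` (static-scale F),
#'   `kd_app` (static-scale apparent Kd), `kd_frame` (frame-level Kd),
#'   `frame_free` (per-frame pons means), `fit_r2`.
#' @export
fit_scatchard <- function(dyn, pons_roi, occ_roi, frames = 8:12,
                          weights = c("none", "free2")) {
  weights <- match.arg(weights)
  stopifnot(inherits(dyn, "pet_dynamic"))
  if (length(pons_roi) == 0 || length(occ_roi) == 0) stop("empty ROI")
  fl <- flat_frames(dyn)
  f_t <- colMeans(fl[pons_roi, frames, drop = FALSE])
  c_t <- colMeans(fl[occ_roi, frames, drop = FALSE])
  scatchard_from_means(f_t, c_t, weights)
}

scatchard_from_means <- function(f_t, c_t, weights = "none") {
  b_t <- c_t - f_t
  if (any(f_t <= 0)) stop("non-positive frame free concentration")
  if (stats::sd(b_t) < 1e-12 * max(abs(b_t), 1))
    stop("Scatchard fit degenerate: no variation in bound concentration across frames")
  y <- b_t / f_t
  w <- if (weights == "free2") f_t^2 else rep(1, length(f_t))
  fit <- stats::lm.wfit(cbind(1, b_t), y, w)
  slope <- fit$coefficients[2]
  r2 <- 1 - sum(w * fit$residuals^2) /
    sum(w * (y - stats::weighted.mean(y, w))^2)
  scatchard_result(slope, f_t, r2)
}

scatchard_result <- function(slope, f_t, r2) {
  if (!is.finite(slope) || slope >= 0)
    stop("Scatchard fit degenerate: non-negative slope (no saturation signal)")
  kd_frame <- -1 / slope
  f_static <- sum(f_t)
  s_total <- sum(f_t / (f_t + kd_frame))
  if (s_total >= 1)
    stop("Scatchard fit degenerate: summed occupancy >= 1; apparent Kd undefined on the static scale")
  kd_app <- f_static * (1 - s_total) / s_total
  structure(list(free_conc = f_static, kd_app = kd_app,
                 kd_frame = kd_frame, frame_free = f_t, fit_r2 = r2),
            class = "scatchard_fit")
}

#' Cohort-pooled Scatchard fit
#'
#' The apparent dissociation constant of the tracer is a property of the
#' ligand-receptor system and is expected to be stable across subjects,
#' while the occipital B'max (the Scatchard intercept) is not. This
#' fitter therefore pools the frame-wise Scatchard points of all
#' subjects and estimates a common slope (-1/Kd_frame) with per-subject
#' intercepts, by weighted least squares (weights `F_t^2`). Each subject
#' then receives their own static-scale `kd_app` and `free_conc` via
#' their own pons frame means.
#'
#' @param dyns List of `pet_dynamic` objects (one per subject).
#' @param frames Late frames used (1-based labels).
#' @return List of `scatchard_fit` objects, one per subject, sharing
#'   `kd_frame`.
#' @export
fit_scatchard_pooled <- function(dyns, frames = 8:12) {
  stopifnot(length(dyns) >= 1)
  pts <- lapply(dyns, function(dyn) {
    fl <- flat_frames(dyn)
    f_t <- colMeans(fl[dyn$rois$pons, frames, drop = FALSE])
    c_t <- colMeans(fl[dyn$rois$occipital, frames, drop = FALSE])
    if (any(f_t <= 0)) stop("non-positive frame free concentration")
    list(f_t = f_t, b_t = c_t - f_t)
  })
  if (length(pts) == 1)
    return(list(scatchard_from_means(pts[[1]]$f_t,
                                     pts[[1]]$f_t + pts[[1]]$b_t, "free2")))
  b <- unlist(lapply(pts, `[[`, "b_t"))
  f <- unlist(lapply(pts, `[[`, "f_t"))
  y <- b / f
  subj <- factor(rep(seq_along(pts), each = length(frames)))
  dummies <- stats::model.matrix(~ subj - 1)
  fit <- stats::lm.wfit(cbind(dummies, b), y, f^2)
  slope <- fit$coefficients[length(fit$coefficients)]
  r2 <- 1 - sum(f^2 * fit$residuals^2) /
    sum(f^2 * (y - stats::weighted.mean(y, f^2))^2)
  lapply(pts, function(p) scatchard_result(slope, p$f_t, r2))
}

#' Voxelwise B'max parametric image
#'
#' Receptor-density image from the partial-saturation model:
#' `B'max(v) = (C(v) - F) * (1 + Kd_app / F)`, with bound concentrations
#' below zero (possible under noise in receptor-free tissue) clipped to 0.
#'
#' @param img A `static_image`.
#' @param fit A `scatchard_fit` (supplies `free_conc` and `kd_app`).
#' @return Object of class `bmax_map`: `values` (3-D, non-negative),
#'   `geometry`, `smoothed`, `fwhm`, `n_clipped`.
#' @export
bmax_map <- function(img, fit) {
  stopifnot(inherits(img, "static_image"), inherits(fit, "scatchard_fit"))
  bound <- img$values - fit$free_conc
  n_clip <- sum(bound < 0)
  bound[bound < 0] <- 0
  vals <- bound * (1 + fit$kd_app / fit$free_conc)
  structure(list(values = vals, geometry = img$geometry, smoothed = FALSE,
                 fwhm = c(0, 0, 0), n_clipped = n_clip),
            class = "bmax_map")
}

#' Gaussian smoothing of a parametric image
#'
#' Separable Gaussian kernel specified by its full width at half maximum
#' per axis (mm), converted to voxels via the image geometry. Reflective
#' boundaries conserve the total image sum.
#'
#' @param map A `bmax_map` (or any list with `values` + `geometry`).
#' @param fwhm FWHM per axis in mm; default `c(15, 15, 21)` to bring the
#'   PET maps to a resolution comparable with the beamformer estimates.
#' @return The smoothed `bmax_map`.
#' @export
smooth_map <- function(map, fwhm = c(15, 15, 21)) {
  stopifnot(length(fwhm) == 3, all(fwhm >= 0))
  sigma_vox <- fwhm / (2 * sqrt(2 * log(2))) / map$geometry$voxel_size
  vals <- map$values
  for (ax in 1:3) {
    if (sigma_vox[ax] > 0) vals <- convolve_axis(vals, sigma_vox[ax], ax)
  }
  out <- map
  out$values <- vals
  out$smoothed <- TRUE
  out$fwhm <- fwhm
  out
}

# 1-D Gaussian convolution along axis `ax` with reflective padding,
# implemented as a dense band-matrix product along that axis.
convolve_axis <- function(arr, sigma, ax) {
  d <- dim(arr)
  n <- d[ax]
  rad <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-rad, rad), sd = sigma)
  k <- k / sum(k)
  # Half-sample reflection (edge value repeated): conserves the total sum.
  idx <- c(rev(seq_len(rad)), seq_len(n), n + 1L - seq_len(rad))
  idx[idx < 1] <- 1L
  idx[idx > n] <- n
  # Smoothing matrix S (n x n): row i averages reflected window around i.
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    cols <- idx[i:(i + 2L * rad)]
    for (j in seq_along(cols)) S[i, cols[j]] <- S[i, cols[j]] + k[j]
  }
  perm <- c(ax, setdiff(1:3, ax))
  x <- aperm(arr, perm)
  dim(x) <- c(n, prod(d[-ax]))
  y <- S %*% x
  dim(y) <- d[perm]
  aperm(y, order(perm))
}

#' Total V1 receptor density
#'
#' Maps each V1 MR voxel to its nearest PET voxel, de-duplicates the
#' resulting PET voxel set, and returns the sum of B'max over that unique
#' set. Using the sum (not the mean) makes the measure sensitive to V1
#' size, which is why surface area and gray-matter density are later
#' available as confound regressors.
#'
#' @param map A `bmax_map`.
#' @param v1_mr_voxels Either an N x 3 matrix of MR voxel centre
#'   coordinates in world mm, or an integer vector of PET voxel linear
#'   indices (already mapped).
#' @param geometry PET geometry (defaults to the map's).
#' @return Scalar total density over the unique V1-PET voxel set, with the
#'   voxel set in attribute `voxels`.
#' @export
v1_total_density <- function(map, v1_mr_voxels, geometry = map$geometry) {
  idx <- map_to_pet_voxels(v1_mr_voxels, geometry)
  if (length(idx) == 0) stop("empty V1-PET voxel set")
  structure(sum(map$values[idx]), voxels = idx)
}

#' Mean gray-matter fraction over the V1-PET voxel set
#'
#' @param gm_fraction_map 3-D array of per-voxel gray matter proportions
#'   in [0, 1] (same geometry as the PET data).
#' @param v1_mr_voxels As in [v1_total_density()].
#' @param geometry PET geometry.
#' @return Scalar mean gray-matter fraction.
#' @export
gm_density_confound <- function(gm_fraction_map, v1_mr_voxels, geometry) {
  idx <- map_to_pet_voxels(v1_mr_voxels, geometry)
  if (length(idx) == 0) stop("empty V1-PET voxel set")
  mean(gm_fraction_map[idx])
}

# Nearest-PET-voxel mapping with de-duplication. Accepts world-mm
# coordinates (matrix) or already-mapped linear indices (integer vector).
map_to_pet_voxels <- function(v1_mr_voxels, geometry) {
  if (is.matrix(v1_mr_voxels)) {
    ijk <- round(sweep(v1_mr_voxels, 2, geometry$origin) %*%
                   diag(1 / geometry$voxel_size)) + 1
    for (a in 1:3) ijk[, a] <- pmin(pmax(ijk[, a], 1), geometry$dim[a])
    idx <- ijk[, 1] + geometry$dim[1] * (ijk[, 2] - 1) +
      geometry$dim[1] * geometry$dim[2] * (ijk[, 3] - 1)
  } else {
    idx <- v1_mr_voxels
  }
  sort(unique(as.integer(idx)))
}

flat_frames <- function(dyn) {
  fr <- dyn$frames
  d <- dim(fr)
  matrix(fr, nrow = prod(d[1:3]), ncol = d[4])
}
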