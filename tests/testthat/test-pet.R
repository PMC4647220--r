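test_that("static images sum exactly the late frames", {
  geom <- pet_geometry(dim = c(6, 6, 6), voxel_size = c(4, 4, 4))
  rois <- list(pons = 1:4, occipital = 5:10, v1 = 11:16, brain = 1:216)
  fr <- array(1, c(6, 6, 6, 12))
  dyn <- manual_pet_dynamic(fr, geom, rois)
  expect_equal(static_image(dyn)$values, array(5, c(6, 6, 6)))

  set.seed(1)
  fr2 <- array(stats::rnorm(6^3 * 12), c(6, 6, 6, 12))
  dyn2 <- manual_pet_dynamic(fr2, geom, rois)
  s2 <- static_image(dyn2)
  # brute-force voxel loop on a few voxels
  for (v in list(c(1, 1, 1), c(3, 4, 2), c(6, 6, 6)))
    expect_equal(s2$values[v[1], v[2], v[3]],
                 sum(fr2[v[1], v[2], v[3], 8:12]))
  # permuting frames that are not summed leaves the output unchanged
  fr3 <- fr2[, , , c(7, 2, 3, 4, 5, 6, 1, 8:12)]
  expect_equal(static_image(manual_pet_dynamic(fr3, geom, rois))$values,
               s2$values)
})

test_that("free ligand is the pons mean and matches the generator contract", {
  geom <- pet_geometry(dim = c(6, 6, 6), voxel_size = c(4, 4, 4))
  rois <- list(pons = 1:10, occipital = 20:30, v1 = 40:50, brain = 1:216)
  fr <- array(0, c(6, 6, 6, 12))
  fr[, , , 8:12] <- 0.6
  dyn <- manual_pet_dynamic(fr, geom, rois)
  expect_equal(estimate_free_ligand(static_image(dyn), rois$pons), 3.0)
  expect_error(estimate_free_ligand(static_image(dyn), integer(0)), "empty")

  sub <- test_subject()
  d0 <- simulate_pet_dynamic(sub, noise_frac = 0)
  expect_equal(estimate_free_ligand(static_image(d0), d0$rois$pons),
               sub$free_conc)
})

test_that("the pons estimate concentrates at the standard-error rate", {
  sub <- test_subject()
  dyn <- simulate_pet_dynamic(sub, seed = 2, noise_frac = 0.05)
  f_hat <- estimate_free_ligand(static_image(dyn), dyn$rois$pons)
  n_vox <- length(dyn$rois$pons)
  expect_lt(abs(f_hat - sub$free_conc),
            3 * 0.05 * sub$free_conc / sqrt(n_vox))
})

test_that("the Scatchard fit recovers kd exactly from noise-free dynamics", {
  sub <- test_subject()
  d0 <- simulate_pet_dynamic(sub, noise_frac = 0)
  fit <- fit_scatchard(d0, d0$rois$pons, d0$rois$occipital)
  expect_equal(fit$kd_app, sub$kd_app, tolerance = 1e-6)
  expect_equal(fit$fit_r2, 1, tolerance = 1e-9)
  # scale equivariance: concentrations in different units scale kd
  d3 <- d0
  d3$frames <- d0$frames * 3
  fit3 <- fit_scatchard(d3, d3$rois$pons, d3$rois$occipital)
  expect_equal(fit3$kd_app, 3 * fit$kd_app, tolerance = 1e-6)
  expect_equal(fit3$free_conc, 3 * fit$free_conc, tolerance = 1e-9)
})

test_that("degenerate occipital dynamics are rejected", {
  geom <- pet_geometry(dim = c(6, 6, 6), voxel_size = c(4, 4, 4))
  rois <- list(pons = 1:10, occipital = 20:30, v1 = 40:50, brain = 1:216)
  fr <- array(0, c(6, 6, 6, 12))
  fr[, , , 8:12] <- 2                      # constant: zero bound everywhere
  dyn <- manual_pet_dynamic(fr, geom, rois)
  expect_error(fit_scatchard(dyn, rois$pons, rois$occipital), "degenerate")
})

test_that("B'max maps invert the forward model exactly without noise", {
  sub <- test_subject()
  d0 <- simulate_pet_dynamic(sub, noise_frac = 0)
  img <- static_image(d0)
  fit <- fit_scatchard(d0, d0$rois$pons, d0$rois$occipital)
  bm <- bmax_map(img, fit)
  rel <- abs(bm$values - sub$bmax_field) / pmax(sub$bmax_field, 1e-9)
  expect_lt(max(rel[sub$bmax_field > 0]), 1e-6)
  expect_lt(max(abs(bm$values[sub$bmax_field == 0])), 1e-6)
})

test_that("B'max closed-form arithmetic and clipping behave as specified", {
  geom <- pet_geometry(dim = c(4, 4, 4), voxel_size = c(4, 4, 4))
  img <- structure(list(values = array(2, c(4, 4, 4)), frames_summed = 8:12,
                        geometry = geom), class = "static_image")
  fit <- structure(list(free_conc = 2, kd_app = 2, kd_frame = 1,
                        frame_free = rep(0.4, 5), fit_r2 = 1),
                   class = "scatchard_fit")
  # C = F -> zero density
  expect_true(all(bmax_map(img, fit)$values == 0))
  # C = F + kd and F = kd -> B'max = 2 kd
  img$values[] <- 4
  expect_true(all(bmax_map(img, fit)$values == 4))
  # negative bound is clipped and counted
  img$values[1, 1, 1] <- 1.5
  bm <- bmax_map(img, fit)
  expect_equal(bm$values[1, 1, 1], 0)
  expect_equal(bm$n_clipped, 1)
})

test_that("Gaussian smoothing conserves mass and leaves uniform volumes alone", {
  geom <- pet_geometry(dim = c(16, 16, 24), voxel_size = c(4, 4, 2.42))
  u <- structure(list(values = array(3, c(16, 16, 24)), geometry = geom,
                      smoothed = FALSE, fwhm = c(0, 0, 0), n_clipped = 0),
                 class = "bmax_map")
  su <- smooth_map(u)
  expect_equal(su$values, u$values, tolerance = 1e-12)

  imp <- u
  imp$values <- array(0, c(16, 16, 24))
  imp$values[8, 8, 12] <- 1
  si <- smooth_map(imp)
  expect_equal(sum(si$values), 1, tolerance = 1e-6)
})

test_that("the smoothing impulse response has the requested FWHM", {
  geom <- pet_geometry(dim = c(24, 24, 40), voxel_size = c(4, 4, 2.42))
  imp <- structure(list(values = array(0, c(24, 24, 40)), geometry = geom,
                        smoothed = FALSE, fwhm = c(0, 0, 0), n_clipped = 0),
                   class = "bmax_map")
  imp$values[12, 12, 20] <- 1
  sm <- smooth_map(imp, fwhm = c(15, 15, 21))
  measure_fwhm <- function(profile, step) {
    half <- max(profile) / 2
    above <- which(profile >= half)
    (max(above) - min(above) + 1) * step
  }
  fx <- measure_fwhm(sm$values[, 12, 20], 4)
  fy <- measure_fwhm(sm$values[12, , 20], 4)
  fz <- measure_fwhm(sm$values[12, 12, ], 2.42)
  expect_lte(abs(fx - 15), 4)
  expect_lte(abs(fy - 15), 4)
  expect_lte(abs(fz - 21), 2.42)
})

test_that("V1 totals use the unique nearest-PET-voxel set", {
  geom <- pet_geometry(dim = c(4, 4, 4), voxel_size = c(10, 10, 10))
  vals <- array(0, c(4, 4, 4))
  vals[2, 2, 2] <- 7
  map <- structure(list(values = vals, geometry = geom, smoothed = FALSE,
                        fwhm = c(0, 0, 0), n_clipped = 0),
                   class = "bmax_map")
  centre <- geom$origin + c(1, 1, 1) * 10   # voxel (2,2,2) centre
  two_mr <- rbind(centre + c(1, 1, 0), centre - c(1, 0, 1))
  expect_equal(as.numeric(v1_total_density(map, two_mr)), 7)

  map$values[] <- 3
  idx <- c(1, 5, 9, 20)
  expect_equal(as.numeric(v1_total_density(map, idx)), 4 * 3)
  # doubling the mask doubles the total on a uniform map
  expect_equal(as.numeric(v1_total_density(map, c(idx, 25:28))), 8 * 3)
  expect_error(v1_total_density(map, integer(0)), "empty")
})

test_that("gray-matter confound is the mean over the V1-PET set", {
  geom <- pet_geometry(dim = c(4, 4, 4), voxel_size = c(10, 10, 10))
  gm <- array(0.6, c(4, 4, 4))
  expect_equal(gm_density_confound(gm, c(1, 7, 12), geom), 0.6)
  set.seed(4)
  gm2 <- array(stats::runif(64), c(4, 4, 4))
  idx <- c(3, 9, 33)
  expect_equal(gm_density_confound(gm2, idx, geom), mean(gm2[idx]))
  expect_gte(gm_density_confound(gm2, idx, geom), 0)
  expect_lte(gm_density_confound(gm2, idx, geom), 1)
})

test_that("B'max estimation is nearly unbiased with a 1000-voxel ROI at 5% noise", {
  sub <- test_subject()
  region <- which(sub$bmax_field > 3)      # receptor-bearing brain tissue
  expect_gt(length(region), 1000)
  truth <- sum(sub$bmax_field[region])
  errs <- vapply(1:40, function(k) {
    dyn <- simulate_pet_dynamic(sub, seed = 100 + k, noise_frac = 0.05)
    # Scatchard over the full 1000+-voxel receptor-rich ROI
    fit <- fit_scatchard(dyn, dyn$rois$pons, region, weights = "free2")
    bm <- bmax_map(static_image(dyn), fit)
    sum(bm$values[region]) / truth - 1
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.02)
})

test_that("end-to-end PET recovery across a cohort is nearly perfect", {
  cfg <- test_config(seed = 31)
  study <- simulate_cohort_study(cfg, run_meg = FALSE)
  expect_gte(cor(study$density$total_v1_bmax, study$truth$total_v1_bmax),
             0.99)
})

test_that("volumes and dynamics survive the NIfTI round trip", {
  sub <- test_subject()
  dyn <- simulate_pet_dynamic(sub, seed = 5, noise_frac = 0.05)
  base <- file.path(withr::local_tempdir(), "pet")
  write_pet_dynamic(dyn, base)
  back <- read_pet_dynamic(base)
  expect_equal(back$frames, dyn$frames, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$geometry$voxel_size, dyn$geometry$voxel_size,
               tolerance = 1e-6)
  expect_setequal(back$rois$pons, dyn$rois$pons)
  expect_setequal(back$rois$v1, dyn$rois$v1)

  fit <- fit_scatchard(dyn, dyn$rois$pons, dyn$rois$occipital)
  bm <- bmax_map(static_image(dyn), fit)
  p <- file.path(withr::local_tempdir(), "bmax.nii.gz")
  write_volume_nifti(bm, p)
  rv <- read_volume_nifti(p)
  expect_equal(rv$values, bm$values, tolerance = 1e-6, ignore_attr = TRUE)
})
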