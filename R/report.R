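#' Full MEG-PET correlation battery
#'
#' For every band (alpha, beta, gamma), MEG feature (frequency,
#' amplitude, timing) and density variant (raw total V1 density, and the
#' density after regressing out V1 surface area and gray-matter density),
#' computes Spearman's rho with its t-approximation p-value, Pearson's r
#' with its p-value, the JZS correlation Bayes factor and leave-2-out
#' bootstrap 95% limits. Control correlations (whole-brain density and
#' V1 surface area against the gamma features) are reported separately.
#' All p-values are uncorrected.
#'
#' @param features data.frame (or CSV path) with columns `subject_id`,
#'   `band`, `peak_freq_hz`, `peak_time_ms`, `peak_amp`.
#' @param density data.frame (or CSV path) with columns `subject_id`,
#'   `total_v1_bmax` and optionally `whole_brain_bmax`.
#' @param confounds data.frame (or CSV path) with columns `subject_id`,
#'   `v1_surface_area_mm2`, `gm_density`; `NULL` skips the regressed
#'   variant and surface-area controls.
#' @param n_resamples Bootstrap resamples per correlation (default 200).
#' @param seed Integer seed for the bootstrap.
#' @return Object of class `correlation_report`: list with `report` (one
#'   row per band x feature x variant) and `controls` data.frames.
#' @export
run_full_analysis <- function(features, density, confounds = NULL,
                              n_resamples = 200, seed = NULL) {
  features <- read_table_arg(features)
  density <- read_table_arg(density)
  confounds <- if (!is.null(confounds)) read_table_arg(confounds)
  ids <- sort(unique(features$subject_id))
  check_ids(ids, density$subject_id, "density")
  if (!is.null(confounds)) check_ids(ids, confounds$subject_id, "confounds")
  density <- density[match(ids, density$subject_id), ]
  x_raw <- density$total_v1_bmax
  variants <- list(raw = x_raw)
  if (!is.null(confounds)) {
    confounds <- confounds[match(ids, confounds$subject_id), ]
    cf <- cbind(confounds$v1_surface_area_mm2, confounds$gm_density)
    variants$regressed <- regress_out(x_raw, cf)
  }
  feature_cols <- c(frequency = "peak_freq_hz", amplitude = "peak_amp",
                    timing = "peak_time_ms")
  rows <- list()
  k <- 0
  bands <- intersect(c("alpha", "beta", "gamma"), unique(features$band))
  if (length(bands) == 0) stop("no recognised bands in the feature table")
  for (band in bands) {
    fb <- features[features$band == band, ]
    fb <- fb[match(ids, fb$subject_id), ]
    if (anyNA(fb$subject_id))
      stop(sprintf("missing %s-band features for some subjects", band))
    for (feat in names(feature_cols)) {
      y <- fb[[feature_cols[[feat]]]]
      for (vn in names(variants)) {
        k <- k + 1
        cr <- correlate_pair(variants[[vn]], y, n_resamples = n_resamples,
                             seed = derive_seed(seed, k))
        rows[[k]] <- data.frame(
          correlation_name = sprintf("gamma_ref_%s", k),
          band = band, feature = feat, density = vn,
          spearman_rho = cr$rho, spearman_p = cr$rho_p,
          pearson_r = cr$r, pearson_p = cr$r_p, bf10 = cr$bf10,
          ci_low = cr$ci_low, ci_high = cr$ci_high, n = cr$n)
      }
    }
  }
  report <- do.call(rbind, rows)
  report$correlation_name <- paste(report$band, report$feature,
                                   report$density, sep = "_")
  gamma_f <- features[features$band == "gamma", ]
  gamma_f <- gamma_f[match(ids, gamma_f$subject_id), ]
  controls <- list()
  ctrl_x <- list()
  if (!is.null(density$whole_brain_bmax))
    ctrl_x$whole_brain_density <- density$whole_brain_bmax
  if (!is.null(confounds)) {
    ctrl_x$v1_surface_area <- confounds$v1_surface_area_mm2
    ctrl_x$gm_density <- confounds$gm_density
  }
  j <- 0
  for (cn in names(ctrl_x)) {
    for (feat in c("frequency", "amplitude")) {
      j <- j + 1
      y <- gamma_f[[feature_cols[[feat]]]]
      cr <- correlate_pair(ctrl_x[[cn]], y, n_resamples = n_resamples,
                           seed = derive_seed(seed, 1000 + j))
      controls[[j]] <- data.frame(
        correlation_name = paste(cn, "gamma", feat, sep = "_"),
        spearman_rho = cr$rho, spearman_p = cr$rho_p,
        pearson_r = cr$r, pearson_p = cr$r_p, bf10 = cr$bf10,
        ci_low = cr$ci_low, ci_high = cr$ci_high, n = cr$n)
    }
  }
  structure(list(report = report,
                 controls = if (j > 0) do.call(rbind, controls)),
            class = "correlation_report")
}

#' Write a correlation report as CSV and JSON
#'
#' @param x A `correlation_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_correlation_report <- function(x, dir) {
  stopifnot(inherits(x, "correlation_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(x$report, file.path(dir, "correlations.csv"),
                   row.names = FALSE)
  if (!is.null(x$controls))
    utils::write.csv(x$controls, file.path(dir, "controls.csv"),
                     row.names = FALSE)
  jsonlite::write_json(list(report = x$report, controls = x$controls),
                       file.path(dir, "correlations.json"),
                       digits = NA, dataframe = "rows")
  invisible(dir)
}

read_table_arg <- function(x) {
  if (is.character(x) && length(x) == 1) utils::read.csv(x) else
    as.data.frame(x)
}

check_ids <- function(ids, other, what) {
  missing_ids <- setdiff(ids, other)
  extra <- setdiff(other, ids)
  if (length(missing_ids) > 0 || length(extra) > 0)
    stop(sprintf("subject ids mismatch in %s: missing [%s], unexpected [%s]",
                 what, paste(missing_ids, collapse = ", "),
                 paste(extra, collapse = ", ")))
  invisible(TRUE)
}
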