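#' Write a parametric map or mask as NIfTI-1
#'
#' @param x A `bmax_map`, or a 3-D array with a `pet_geometry` supplied
#'   via `geometry`.
#' @param path Output file path (`.nii` or `.nii.gz`).
#' @param geometry Geometry used when `x` is a bare array.
#' @return The path, invisibly.
#' @export
write_volume_nifti <- function(x, path, geometry = NULL) {
  if (inherits(x, "bmax_map")) {
    vals <- x$values
    geometry <- x$geometry
  } else {
    vals <- x
    if (is.null(geometry)) stop("geometry required for bare arrays")
  }
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- geometry$voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a voxel index set as a 0/1 NIfTI mask
#'
#' @param idx Integer vector of 1-based linear voxel indices.
#' @param geometry A `pet_geometry`.
#' @param path Output file path.
#' @export
write_mask_nifti <- function(idx, geometry, path) {
  m <- array(0L, dim = geometry$dim)
  m[idx] <- 1L
  write_volume_nifti(m, path, geometry)
}

#' Read a NIfTI volume together with its voxel sizes
#'
#' @param path NIfTI file path.
#' @return List with `values` (array) and `geometry` (`pet_geometry`).
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  vox <- RNifti::pixdim(img)[seq_len(3)]
  vals <- as.array(img)
  list(values = vals, geometry = pet_geometry(dim(vals)[1:3], vox))
}

#' Write a dynamic PET acquisition (frames + ROI masks + timing sidecar)
#'
#' Produces `<base>.nii.gz` (4-D frames), `<base>_pons.nii.gz`,
#' `<base>_occ.nii.gz`, `<base>_v1.nii.gz` masks and `<base>.json` with
#' the frame timing (minutes).
#'
#' @param dyn A `pet_dynamic`.
#' @param base Output path prefix.
#' @return `base`, invisibly.
#' @export
write_pet_dynamic <- function(dyn, base) {
  img <- RNifti::asNifti(dyn$frames)
  RNifti::pixdim(img) <- c(dyn$geometry$voxel_size, 1)
  RNifti::writeNifti(img, paste0(base, ".nii.gz"))
  write_mask_nifti(dyn$rois$pons, dyn$geometry, paste0(base, "_pons.nii.gz"))
  write_mask_nifti(dyn$rois$occipital, dyn$geometry, paste0(base, "_occ.nii.gz"))
  write_mask_nifti(dyn$rois$v1, dyn$geometry, paste0(base, "_v1.nii.gz"))
  jsonlite::write_json(list(frame_start_min = dyn$frame_times[, 1],
                            frame_end_min = dyn$frame_times[, 2]),
                       paste0(base, ".json"), digits = NA)
  invisible(base)
}

#' Read a dynamic PET acquisition written by [write_pet_dynamic()]
#' @param base Path prefix used at write time.
#' @return A `pet_dynamic`.
#' @export
read_pet_dynamic <- function(base) {
  img <- RNifti::readNifti(paste0(base, ".nii.gz"))
  vals <- as.array(img)
  vox <- RNifti::pixdim(img)[1:3]
  geom <- pet_geometry(dim(vals)[1:3], vox)
  tim <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  rois <- list(pons = which(as.array(RNifti::readNifti(paste0(base, "_pons.nii.gz"))) > 0),
               occipital = which(as.array(RNifti::readNifti(paste0(base, "_occ.nii.gz"))) > 0),
               v1 = which(as.array(RNifti::readNifti(paste0(base, "_v1.nii.gz"))) > 0))
  structure(list(frames = vals,
                 frame_times = cbind(start = tim$frame_start_min,
                                     end = tim$frame_end_min),
                 voxel_size = geom$voxel_size, geometry = geom, rois = rois),
            class = "pet_dynamic")
}
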