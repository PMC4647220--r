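#' Random-voxel-set specificity nulls
#'
#' Tests whether a MEG-PET correlation is specific to V1 by recomputing
#' it with receptor densities aggregated over voxel sets far from V1:
#' 100 sets of fully random voxels and 100 sets of random contiguous
#' clusters (region-grown in the 6-neighbourhood), each with exactly as
#' many voxels as the V1 set and every voxel more than `min_distance_cm`
#' from V1.
#'
#' @param maps List (one per subject) of `bmax_map` objects on a shared
#'   geometry.
#' @param v1_voxels Integer vector of V1 PET voxel indices (shared grid).
#' @param meg_features Numeric vector, one MEG feature value per subject.
#' @param n_each Number of sets of each type (default 100).
#' @param min_distance_cm Exclusion distance from V1 in cm (default 4).
#' @param seed Integer seed.
#' @param pool Optional index vector of candidate voxels (defaults to the
#'   brain mask of the shared geometry's standard ROI layout).
#' @return Object of class `null_ensemble`: `correlations` (length
#'   `2 * n_each` Spearman rhos), `type` (random/contiguous), `set_size`,
#'   and the voxel `sets`.
#' @export
random_voxel_nulls <- function(maps, v1_voxels, meg_features, n_each = 100,
                               min_distance_cm = 4, seed = NULL,
                               pool = NULL) {
  geom <- maps[[1]]$geometry
  if (length(meg_features) != length(maps))
    stop("one MEG feature value per subject map is required")
  k <- length(v1_voxels)
  xyz <- voxel_coords(geom)
  if (is.null(pool)) pool <- pet_rois(geom)$brain
  # minimum distance (mm) of each pool voxel to any V1 voxel
  v1_xyz <- xyz[v1_voxels, , drop = FALSE]
  dmin <- apply(xyz[pool, , drop = FALSE], 1, function(p)
    sqrt(min(colSums((t(v1_xyz) - p)^2))))
  eligible <- pool[dmin > 10 * min_distance_cm]
  if (length(eligible) <= k)
    stop("eligible voxel pool (>= 4 cm from V1) smaller than the V1 set")
  dens <- vapply(maps, function(m) as.numeric(m$values)[eligible],
                 numeric(length(eligible)))      # eligible x subjects
  sets <- with_seed(seed, {
    rnd <- lapply(seq_len(n_each), function(i) sample(length(eligible), k))
    ctg <- lapply(seq_len(n_each), function(i)
      grow_cluster(eligible, geom, k))
    c(rnd, ctg)
  })
  rho <- vapply(sets, function(s)
    stats::cor(rank(colSums(dens[s, , drop = FALSE])), rank(meg_features)),
    numeric(1))
  structure(list(correlations = rho,
                 type = rep(c("random", "contiguous"), each = n_each),
                 set_size = k,
                 sets = lapply(sets, function(s) eligible[s]),
                 min_distance_cm = min_distance_cm),
            class = "null_ensemble")
}

# Region-grow a contiguous set of `k` voxels inside `eligible` (linear
# indices into `geom`), returning positions within `eligible`. Uses
# 6-connectivity with proper lattice bounds (no index wrap-around).
grow_cluster <- function(eligible, geom, k) {
  d <- geom$dim
  elig_pos <- integer(prod(d))
  elig_pos[eligible] <- seq_along(eligible)
  steps <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
                 c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  to_lin <- function(ijk) ijk[, 1] + d[1] * (ijk[, 2] - 1) +
    d[1] * d[2] * (ijk[, 3] - 1)
  for (attempt in 1:50) {
    seed_vox <- eligible[sample(length(eligible), 1)]
    members <- seed_vox
    frontier <- seed_vox
    while (length(members) < k && length(frontier) > 0) {
      f_ijk <- arrayInd(frontier, d)
      nb_ijk <- do.call(rbind, lapply(seq_len(nrow(steps)), function(s)
        sweep(f_ijk, 2, steps[s, ], `+`)))
      ok <- nb_ijk[, 1] >= 1 & nb_ijk[, 1] <= d[1] &
        nb_ijk[, 2] >= 1 & nb_ijk[, 2] <= d[2] &
        nb_ijk[, 3] >= 1 & nb_ijk[, 3] <= d[3]
      nb <- unique(to_lin(nb_ijk[ok, , drop = FALSE]))
      nb <- nb[elig_pos[nb] > 0 & !(nb %in% members)]
      if (length(nb) == 0) break
      take <- nb[seq_len(min(length(nb), k - length(members)))]
      members <- c(members, take)
      frontier <- take
    }
    if (length(members) == k) return(elig_pos[members])
  }
  stop("could not grow a contiguous cluster of the requested size")
}
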