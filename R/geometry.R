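#' Spherical-cap magnetometer array
#'
#' Ideal point magnetometers placed on a spherical cap around the head
#' sphere centre, with radial orientations. This is the forward-model
#' geometry used by the synthetic recordings; a realistic gradiometer
#' layout is deliberately not reproduced.
#'
#' Head coordinates: x towards the face, y towards the left ear, z up,
#' origin at the sphere centre; SI units (metres).
#'
#' @param n_sensors Number of sensors (default 102).
#' @param radius Sensor shell radius in metres (default 0.10).
#' @param cap_cos Cosine of the maximal polar angle of the cap; the default
#'   -0.45 extends the cap well below the equator so occipital sources are
#'   covered.
#' @param center Sphere centre (3-vector, metres).
#' @return Object of class `head_model` with fields `sphere_center`,
#'   `sensor_positions` (n x 3), `sensor_orientations` (n x 3, unit norm)
#'   and `n_sensors`.
#' @export
head_model <- function(n_sensors = 102, radius = 0.10, cap_cos = -0.45,
                       center = c(0, 0, 0)) {
  stopifnot(n_sensors >= 8, radius > 0, cap_cos > -1, cap_cos < 1)
  # Fibonacci lattice on the cap [cap_cos, 1] in cos(theta).
  k <- seq_len(n_sensors) - 0.5
  z <- cap_cos + (1 - cap_cos) * k / n_sensors
  golden <- pi * (3 - sqrt(5))
  phi <- golden * seq_len(n_sensors)
  dirs <- cbind(sqrt(1 - z^2) * cos(phi), sqrt(1 - z^2) * sin(phi), z)
  pos <- sweep(radius * dirs, 2, center, `+`)
  structure(list(sphere_center = as.numeric(center),
                 sensor_positions = pos,
                 sensor_orientations = dirs,
                 n_sensors = n_sensors),
            class = "head_model")
}

#' Volumetric source grid
#'
#' Regular lattice of candidate source points inside the head sphere, with
#' a contiguous patch of points labelled as primary visual cortex (V1).
#' One shared grid is used for all subjects.
#'
#' @param spacing Lattice spacing in millimetres (default 6).
#' @param shell Radial limits `c(inner, outer)` in metres; points outside
#'   are discarded. Ignored when `box` is given.
#' @param box Optional list with elements `x`, `y`, `z`, each `c(lo, hi)`
#'   in metres, restricting the lattice to a box (used for reduced grids).
#' @param v1_center Centre of the V1 patch (metres); the default sits in
#'   medial occipital cortex (negative x = posterior).
#' @param v1_radius Radius of the V1 patch in metres.
#' @param center Head sphere centre.
#' @return Object of class `source_grid` with fields `points` (M x 3,
#'   metres), `v1_indices` (1-based), `spacing` (mm).
#' @export
source_grid <- function(spacing = 6, shell = c(0.030, 0.075), box = NULL,
                        v1_center = c(-0.055, 0, 0.015), v1_radius = 0.011,
                        center = c(0, 0, 0)) {
  stopifnot(spacing > 0)
  s <- spacing / 1000
  if (is.null(box)) {
    r <- shell[2]
    ax <- seq(-r, r, by = s)
    pts <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
    pts <- sweep(pts, 2, center, `+`)
    d <- sqrt(rowSums(sweep(pts, 2, center)^2))
    pts <- pts[d >= shell[1] & d <= shell[2], , drop = FALSE]
  } else {
    pts <- as.matrix(expand.grid(x = seq(box$x[1], box$x[2], by = s),
                                 y = seq(box$y[1], box$y[2], by = s),
                                 z = seq(box$z[1], box$z[2], by = s)))
  }
  dimnames(pts) <- NULL
  dv1 <- sqrt(rowSums(sweep(pts, 2, v1_center)^2))
  v1 <- which(dv1 <= v1_radius)
  if (length(v1) == 0)
    stop("source grid contains no V1 points; enlarge v1_radius or the grid")
  structure(list(points = pts, v1_indices = v1, spacing = spacing,
                 center = as.numeric(center)),
            class = "source_grid")
}

#' Reduced posterior source grid
#'
#' A 10-mm lattice over occipital cortex containing the V1 patch; the
#' problem size used by the fast simulation-study pipeline.
#'
#' @param spacing Lattice spacing in mm.
#' @return A `source_grid`.
#' @export
posterior_grid <- function(spacing = 10) {
  source_grid(spacing = spacing,
              box = list(x = c(-0.075, -0.035), y = c(-0.02, 0.02),
                         z = c(-0.005, 0.035)),
              v1_radius = 0.012)
}

#' PET volume geometry
#'
#' Voxel lattice for the synthetic dynamic PET volumes. World coordinates
#' are in millimetres with the origin at the volume centre.
#'
#' @param dim Integer 3-vector of voxel counts.
#' @param voxel_size Voxel edge lengths in mm; the default slice thickness
#'   is 2.42 mm.
#' @return Object of class `pet_geometry` with `dim`, `voxel_size`,
#'   `origin` (world mm of voxel (1,1,1) centre).
#' @export
pet_geometry <- function(dim = c(24L, 24L, 32L), voxel_size = c(4, 4, 2.42)) {
  stopifnot(length(dim) == 3, all(dim >= 4), all(voxel_size > 0))
  extent <- dim * voxel_size
  origin <- -extent / 2 + voxel_size / 2
  structure(list(dim = as.integer(dim), voxel_size = as.numeric(voxel_size),
                 origin = origin),
            class = "pet_geometry")
}

# World-mm coordinates of all voxel centres (nvox x 3), voxel order = R
# linear array order.
voxel_coords <- function(geom) {
  ijk <- as.matrix(expand.grid(i = seq_len(geom$dim[1]),
                               j = seq_len(geom$dim[2]),
                               k = seq_len(geom$dim[3])))
  sweep((ijk - 1) %*% diag(geom$voxel_size), 2, geom$origin, `+`)
}

# Linear voxel indices within a ball of `radius` mm around `center` (mm).
voxel_ball <- function(geom, center, radius) {
  xyz <- voxel_coords(geom)
  which(sqrt(rowSums(sweep(xyz, 2, center)^2)) <= radius)
}

#' Standard synthetic ROI layout for the PET volume
#'
#' Pons reference region (receptor-free), occipital Scatchard ROI and the
#' V1 voxel set. The occipital ROI and V1 set are kept disjoint.
#'
#' @param geom A `pet_geometry`.
#' @return List with integer index vectors `pons`, `occipital`, `v1`, a
#'   `brain` mask index vector, and the mm-coordinates `v1_center`.
#' @export
pet_rois <- function(geom) {
  v1_center <- c(0, -34, 4)
  occ_center <- c(0, -34, 22)
  pons_center <- c(0, 14, -22)
  v1 <- voxel_ball(geom, v1_center, 12)
  occ <- setdiff(voxel_ball(geom, occ_center, 12), v1)
  pons <- voxel_ball(geom, pons_center, 12)
  stopifnot(length(v1) > 0, length(occ) > 2, length(pons) > 0,
            length(intersect(pons, c(v1, occ))) == 0)
  brain_r <- min(geom$dim * geom$voxel_size) / 2 - max(geom$voxel_size)
  brain <- voxel_ball(geom, c(0, 0, 0), max(brain_r, 40))
  list(pons = pons, occipital = occ, v1 = v1, brain = brain,
       v1_center = v1_center)
}
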