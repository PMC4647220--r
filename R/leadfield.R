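#' Magnetic field of a current dipole in a spherical conductor
#'
#' Closed-form (Sarvas) solution for the field outside a homogeneous
#' conducting sphere, including the contribution of volume currents.
#' Radial dipoles are magnetically silent; the field outside does not
#' depend on the conductivity profile or sphere radius, only on the
#' centre.
#'
#' @param q_pos Dipole position (3-vector, metres).
#' @param q_moment Dipole moment (3-vector, A m).
#' @param sensor_pos N x 3 sensor positions (metres).
#' @param center Sphere centre (default origin).
#' @return N x 3 matrix of the magnetic field vector (tesla) at each
#'   sensor.
#' @export
sarvas_field <- function(q_pos, q_moment, sensor_pos, center = c(0, 0, 0)) {
  mu0_4pi <- 1e-7
  r0 <- as.numeric(q_pos) - as.numeric(center)
  if (vnorm(r0) < 1e-9)
    stop("source at the sphere centre: tangential directions undefined")
  rp <- sweep(as.matrix(sensor_pos), 2, as.numeric(center))
  q <- as.numeric(q_moment)
  qxr0 <- c(q[2] * r0[3] - q[3] * r0[2],
            q[3] * r0[1] - q[1] * r0[3],
            q[1] * r0[2] - q[2] * r0[1])
  a_vec <- sweep(rp, 2, r0)             # r - r0 per sensor
  a <- sqrt(rowSums(a_vec^2))
  r <- sqrt(rowSums(rp^2))
  if (any(a < 1e-9)) stop("sensor coincides with the source")
  r0_dot_r <- drop(rp %*% r0)
  a_dot_r <- rowSums(a_vec * rp)
  f <- a * (r * a + r^2 - r0_dot_r)
  # grad F = (a^2/r + a.r/a + 2a + 2r) r - (a + 2r + a.r/a) r0
  c1 <- a^2 / r + a_dot_r / a + 2 * a + 2 * r
  c2 <- a + 2 * r + a_dot_r / a
  grad_f <- rp * c1 - outer(c2, r0)
  qxr0_dot_r <- drop(rp %*% qxr0)
  b <- (outer(f, qxr0) - grad_f * qxr0_dot_r) * (mu0_4pi / f^2)
  b
}

#' Leadfield set for tangential dipoles on a source grid
#'
#' For every grid point, the sensor fields of two orthogonal tangential
#' unit dipoles (1 A m), projected onto the sensor orientations. Radial
#' source components are excluded by construction (they are silent in the
#' spherical model).
#'
#' @param head A `head_model`.
#' @param grid A `source_grid`.
#' @return Object of class `leadfield_set`: numeric array
#'   (n_sensors, 2, n_points), tesla per A m, with attribute
#'   `orientations` (list of 2 x 3 tangential bases per point).
#' @export
leadfield <- function(head, grid) {
  pts <- grid$points
  m <- nrow(pts)
  n <- head$n_sensors
  rad <- sqrt(rowSums(sweep(pts, 2, head$sphere_center)^2))
  sens_r <- min(sqrt(rowSums(sweep(head$sensor_positions, 2,
                                   head$sphere_center)^2)))
  if (any(rad >= sens_r))
    stop("all source points must lie strictly inside the sensor shell")
  lf <- array(0, dim = c(n, 2L, m))
  bases <- vector("list", m)
  for (i in seq_len(m)) {
    tb <- tangential_basis(pts[i, ] - head$sphere_center)
    bases[[i]] <- tb
    for (k in 1:2) {
      b <- sarvas_field(pts[i, ], tb[k, ], head$sensor_positions,
                        head$sphere_center)
      lf[, k, i] <- rowSums(b * head$sensor_orientations)
    }
  }
  if (!all(is.finite(lf))) stop("non-finite leadfield values")
  structure(lf, class = "leadfield_set", orientations = bases,
            n_points = m)
}

# Restrict a leadfield set to a subset of grid points (beamformer
# estimates are per-point independent, so slicing is exact).
lf_subset <- function(lf, idx) {
  structure(lf[, , idx, drop = FALSE], class = "leadfield_set",
            orientations = attr(lf, "orientations")[idx],
            n_points = length(idx))
}

# Two orthonormal unit vectors tangential to the radial direction `p`.
tangential_basis <- function(p) {
  r <- vnorm(p)
  if (r < 1e-9) stop("source at the sphere centre: tangential directions undefined")
  ref <- if (abs(p[3]) / r < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- c(ref[2] * p[3] - ref[3] * p[2],
          ref[3] * p[1] - ref[1] * p[3],
          ref[1] * p[2] - ref[2] * p[1])
  e1 <- e1 / vnorm(e1)
  e2 <- c(p[2] * e1[3] - p[3] * e1[2],
          p[3] * e1[1] - p[1] * e1[3],
          p[1] * e1[2] - p[2] * e1[1])
  rbind(e1, e2 / vnorm(e2))
}
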