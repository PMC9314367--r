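# Rotation and Euler-angle machinery.
#
# Orientations map particle-frame vectors into the tomogram frame and are stored
# as proper 3x3 rotation matrices.  Euler angles follow the intrinsic ZYZ
# convention dominant in subtomogram-averaging metadata:
#   R = Rz(rot) %*% Ry(tilt) %*% Rz(psi)       (angles in degrees)
# The particle symmetry (fourfold) axis is particle-frame +z, so the axis in the
# tomogram frame is the third column of R.

rot_z <- function(deg) {
  a <- deg * .deg2rad
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
}

rot_y <- function(deg) {
  a <- deg * .deg2rad
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3, 3)
}

rot_x <- function(deg) {
  a <- deg * .deg2rad
  ca <- cos(a); sa <- sin(a)
  matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3, 3)
}

#' Convert ZYZ Euler angles to a rotation matrix
#'
#' Builds the orientation `R = Rz(rot) Ry(tilt) Rz(psi)` (intrinsic ZYZ,
#' degrees) mapping particle-frame vectors to tomogram-frame vectors.
#'
#' @param rot,tilt,psi Euler angles in degrees (finite scalars).
#' @return A proper 3x3 rotation matrix.
#' @seealso [matrix_to_euler()], [fourfold_axis()]
#' @examples
#' euler_to_matrix(0, 0, 0)          # identity
#' euler_to_matrix(90, 0, 0)         # == euler_to_matrix(0, 0, 90)
#' @export
euler_to_matrix <- function(rot, tilt, psi) {
  stopifnot(is.finite(rot), is.finite(tilt), is.finite(psi))
  rot_z(rot) %*% rot_y(tilt) %*% rot_z(psi)
}

#' Recover ZYZ Euler angles from a rotation matrix
#'
#' Inverse of [euler_to_matrix()]; at the gimbal degeneracy (tilt near 0 or
#' 180 degrees) psi is fixed to 0 and the full in-plane angle is carried by
#' rot.  The recovered triplet always reproduces the input matrix.
#'
#' @param R A proper 3x3 rotation matrix.
#' @return Named numeric vector `c(rot, tilt, psi)` in degrees.
#' @export
matrix_to_euler <- function(R) {
  check_rotation(R)
  ct <- clamp(R[3, 3], -1, 1)
  tilt <- acos(ct) * .rad2deg
  st <- sqrt(max(0, 1 - ct^2))
  if (st > 1e-9) {
    rot <- atan2(R[2, 3], R[1, 3]) * .rad2deg
    psi <- atan2(R[3, 2], -R[3, 1]) * .rad2deg
  } else if (ct > 0) {      # tilt ~ 0: R ~ Rz(rot + psi)
    rot <- atan2(R[2, 1], R[1, 1]) * .rad2deg
    psi <- 0
  } else {                  # tilt ~ 180: R ~ Rz(rot) diag(-1, 1, -1) Rz(psi)
    rot <- atan2(-R[2, 1], -R[1, 1]) * .rad2deg
    psi <- 0
  }
  c(rot = rot, tilt = tilt, psi = psi)
}

#' @keywords internal
check_rotation <- function(R, tol = 1e-6) {
  if (!is.matrix(R) || !all(dim(R) == c(3, 3)) || !all(is.finite(R)))
    stopf("orientation must be a finite 3x3 matrix")
  if (max(abs(crossprod(R) - diag(3))) > tol)
    stopf("orientation matrix is not orthonormal (tol %g)", tol)
  if (abs(det(R) - 1) > tol)
    stopf("orientation matrix is not proper (det != +1)")
  invisible(R)
}

# Vectorized Euler -> rotation: returns a 3 x 3 x n array
euler_to_matrices <- function(rot, tilt, psi) {
  n <- length(rot)
  a <- rot * .deg2rad; b <- tilt * .deg2rad; c_ <- psi * .deg2rad
  ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b); cc <- cos(c_); sc <- sin(c_)
  R <- array(0, c(3, 3, n))
  R[1, 1, ] <- ca * cb * cc - sa * sc
  R[2, 1, ] <- sa * cb * cc + ca * sc
  R[3, 1, ] <- -sb * cc
  R[1, 2, ] <- -ca * cb * sc - sa * cc
  R[2, 2, ] <- -sa * cb * sc + ca * cc
  R[3, 2, ] <- sb * sc
  R[1, 3, ] <- ca * sb
  R[2, 3, ] <- sa * sb
  R[3, 3, ] <- cb
  R
}

#' Fourfold symmetry axis of an oriented particle
#'
#' The Rubisco fourfold axis is particle-frame +z; in the tomogram frame it is
#' the third column of the orientation matrix.
#'
#' @param o Orientation matrix (3x3 proper rotation).
#' @return Unit 3-vector in the tomogram frame.
#' @examples
#' fourfold_axis(diag(3))                 # (0, 0, 1)
#' @export
fourfold_axis <- function(o) {
  check_rotation(o)
  o[, 3]
}

# Vectorized axis from Euler angles: axis = (cos rot sin tilt, sin rot sin tilt, cos tilt)
fourfold_axes <- function(rot, tilt) {
  b <- tilt * .deg2rad; a <- rot * .deg2rad
  cbind(cos(a) * sin(b), sin(a) * sin(b), cos(b))
}

# Rotation by angle_deg about an arbitrary (unnormalized) axis
rotation_about_axis <- function(axis, angle_deg) {
  u <- unit3(axis)
  a <- angle_deg * .deg2rad
  ca <- cos(a); sa <- sin(a)
  ux <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  ca * diag(3) + sa * ux + (1 - ca) * tcrossprod(u)
}

# Exponential map: rotation vector (radians) -> rotation matrix
rotvec_to_matrix <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3))
  rotation_about_axis(w, th * .rad2deg)
}

# Rotation matrix -> unit quaternion (w, x, y, z), Shepperd's method
rot_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q / sqrt(sum(q^2))
}

# Uniform random rotation matrices (n of them) from uniform quaternions
random_rotations <- function(n) {
  q <- matrix(stats::rnorm(4 * n), n, 4)
  q <- q / sqrt(rowSums(q^2))
  out <- array(0, c(3, 3, n))
  for (i in seq_len(n)) {
    w <- q[i, 1]; x <- q[i, 2]; y <- q[i, 3]; z <- q[i, 4]
    out[, , i] <- matrix(c(
      1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
      2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
      2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)), 3, 3)
  }
  out
}

# Small random perturbation rotations: rotation vector with iid N(0, sd_deg^2)
# components (applied on the left, i.e. in the tomogram frame)
jitter_rotations <- function(n, sd_deg) {
  out <- array(0, c(3, 3, n))
  w <- matrix(stats::rnorm(3 * n, sd = sd_deg * .deg2rad), n, 3)
  for (i in seq_len(n)) out[, , i] <- rotvec_to_matrix(w[i, ])
  out
}

# Any rotation carrying +z onto the given unit axis (minimal geodesic swing)
frame_from_axis <- function(axis) {
  u <- unit3(axis)
  z <- c(0, 0, 1)
  c_ <- sum(z * u)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) return(rot_x(180))
  v <- c(z[2] * u[3] - z[3] * u[2], z[3] * u[1] - z[1] * u[3], z[1] * u[2] - z[2] * u[1])
  rotation_about_axis(v, acos(clamp(c_, -1, 1)) * .rad2deg)
}
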