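# Quaternion and rotation-matrix utilities.
#
# Quaternions are length-4 numeric vectors c(w, x, y, z), unit norm, scalar
# part first. Rotation matrices follow the frame convention R_B^A: columns are
# the axes of frame B expressed in frame A, so v_A = R %*% v_B.

#' Normalize a quaternion to unit norm
#' @param q numeric length-4 `(w, x, y, z)`.
#' @return Unit quaternion.
#' @export
quat_normalize <- function(q) {
  n <- sqrt(sum(q * q))
  if (n == 0) stop_gfsfan("cannot normalize a zero quaternion")
  q / n
}

#' Hamilton product of two quaternions
#' @param p,q numeric length-4 quaternions `(w, x, y, z)`.
#' @return The product `p * q`.
#' @export
quat_multiply <- function(p, q) {
  c(p[1] * q[1] - p[2] * q[2] - p[3] * q[3] - p[4] * q[4],
    p[1] * q[2] + p[2] * q[1] + p[3] * q[4] - p[4] * q[3],
    p[1] * q[3] - p[2] * q[4] + p[3] * q[1] + p[4] * q[2],
    p[1] * q[4] + p[2] * q[3] - p[3] * q[2] + p[4] * q[1])
}

#' @rdname quat_multiply
#' @export
quat_conjugate <- function(q) c(q[1], -q[2], -q[3], -q[4])

#' Convert a unit quaternion to a rotation matrix
#'
#' The returned matrix is the attitude matrix of the rotated frame with
#' respect to the base frame (`v_base = R %*% v_body`).
#'
#' @param q unit quaternion `(w, x, y, z)`.
#' @return 3x3 rotation matrix.
#' @export
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y * y + z * z), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x * x + z * z), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x * x + y * y)),
         nrow = 3, byrow = TRUE)
}

#' Quaternion from an axis-angle rotation
#' @param axis numeric length-3 rotation axis (need not be unit).
#' @param angle rotation angle in radians.
#' @return Unit quaternion.
#' @export
quat_from_axis_angle <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n == 0) return(c(1, 0, 0, 0))
  a <- axis / n
  c(cos(angle / 2), sin(angle / 2) * a)
}

#' Rotation matrix about a fixed axis
#' @param axis numeric length-3 axis.
#' @param angle angle in radians.
#' @return 3x3 rotation matrix (Rodrigues formula).
#' @export
rotation_about_axis <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0),
              nrow = 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Geodesic distance between two rotations, in degrees
#' @param R1,R2 3x3 rotation matrices.
#' @return Rotation angle of `t(R1) %*% R2` in degrees.
#' @export
rotation_distance_deg <- function(R1, R2) {
  tr <- sum(diag(crossprod(R1, R2)))
  acos(pmin(1, pmax(-1, (tr - 1) / 2))) * 180 / pi
}

is_rotation_matrix <- function(R, tol = 1e-8) {
  is.matrix(R) && all(dim(R) == c(3, 3)) &&
    max(abs(crossprod(R) - diag(3))) < tol && abs(det(R) - 1) < tol
}

#' Angle between two 3-vectors, in degrees
#' @param a,b numeric length-3 vectors.
#' @return Angle in `[0, 180]` degrees.
#' @export
vector_angle_deg <- function(a, b) {
  ca <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(pmin(1, pmax(-1, ca))) * 180 / pi
}
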