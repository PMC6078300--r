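# Rotation-matrix machinery for validating skin-landmark-derived joint angles
# against rigidly mounted marker triads.
#
# A triad is a rigid plate with an origin marker and two arm markers nominally
# 19 mm along its +X and +Y directions; it defines a bone-fixed frame. Angles
# from the bony-landmark frames are related to triad-frame angles by
# R_transform = R3 R2 R1, where R2 is the per-frame joint rotation from the
# bony-landmark frames and R1, R3 are constant alignment rotations computed
# once at a neutral-pose frame. On a rigid body this recovers the triad-frame
# joint rotation exactly.

check_rotation <- function(R, tol = 1e-9) {
  stopifnot(is.matrix(R), all(dim(R) == c(3L, 3L)))
  if (max(abs(crossprod(R) - diag(3))) > tol || abs(det(R) - 1) > tol) {
    stop_degenerate("matrix is not a proper rotation (orthogonal, det +1)")
  }
  R
}

#' Rotation matrix from three angles
#'
#' Assembles the direction-cosine matrix used to parameterize the rotation
#' that transforms one coordinate system into another, entry by entry:
#' \deqn{R = \begin{bmatrix}
#'  c_2 c_3 & c_1 s_3 + s_1 s_2 c_3 & s_1 s_3 - c_1 s_2 c_3 \\
#'  -c_2 s_3 & c_1 c_3 - s_1 s_2 s_3 & s_1 c_3 + c_1 s_2 s_3 \\
#'  s_2 & -s_1 c_2 & c_1 c_2 \end{bmatrix}}
#' with \eqn{c_i = \cos\theta_i}, \eqn{s_i = \sin\theta_i}.
#'
#' @param theta1,theta2,theta3 Rotation angles, degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_from_angles <- function(theta1, theta2, theta3) {
  a <- deg2rad(theta1); b <- deg2rad(theta2); g <- deg2rad(theta3)
  c1 <- cos(a); s1 <- sin(a)
  c2 <- cos(b); s2 <- sin(b)
  c3 <- cos(g); s3 <- sin(g)
  matrix(c(
    c2 * c3,            c1 * s3 + s1 * s2 * c3,  s1 * s3 - c1 * s2 * c3,
    -c2 * s3,           c1 * c3 - s1 * s2 * s3,  s1 * c3 + c1 * s2 * s3,
    s2,                 -s1 * c2,                c1 * c2
  ), nrow = 3L, byrow = TRUE)
}

#' Extract the three angles from a rotation matrix
#'
#' Inverse of [rotation_from_angles()], using atan2 throughout for quadrant
#' correctness: `theta2 = asin(R[3,1])`, `theta1 = atan2(-R[3,2], R[3,3])`,
#' `theta3 = atan2(-R[2,1], R[1,1])`.
#'
#' @param R 3x3 rotation matrix.
#' @return Numeric vector `c(theta1, theta2, theta3)`, degrees.
#' @export
angles_from_rotation <- function(R) {
  check_rotation(R, tol = 1e-6)
  if (abs(R[3L, 1L]) > 1 - 1e-9) {
    stop_gimbal("gimbal lock: |R[3,1]| = 1, theta1/theta3 are not separable")
  }
  c(theta1 = rad2deg(atan2(-R[3L, 2L], R[3L, 3L])),
    theta2 = rad2deg(asin(clamp1(R[3L, 1L]))),
    theta3 = rad2deg(atan2(-R[2L, 1L], R[1L, 1L])))
}

#' Coordinate frame of a marker triad
#'
#' x̂ points from the origin marker to the X-arm marker; ẑ is the cross
#' product of x̂ with the (unit) Y-arm direction; ŷ = ẑ x x̂. The frame is
#' re-orthogonalized with x̂ primary, so slightly non-square physical arms
#' still yield an exactly orthonormal frame.
#'
#' @param origin,x_marker,y_marker Triad marker positions (mm).
#' @return A [segment_frame()] at the origin marker.
#' @export
triad_cs <- function(origin, x_marker, y_marker) {
  x <- unit3(x_marker - origin, scale = max(norm3(origin), norm3(x_marker), 1),
             what = "triad X arm")
  yr <- unit3(y_marker - origin, scale = max(norm3(origin), norm3(y_marker), 1),
              what = "triad Y arm")
  z <- guarded_cross(x, yr, "triad Z axis (X arm x Y arm)")
  y <- cross3(z, x)
  segment_frame(origin, x, y, z)
}

#' Rotation between two segment frames
#'
#' Returns the matrix of the rotation taking coordinates expressed in `from`
#' to coordinates expressed in `to`: `R = B_to' B_from` with bases as
#' column-vector matrices in lab coordinates.
#'
#' @param from,to [segment_frame()]s.
#' @return 3x3 rotation matrix.
#' @export
frame_rotation <- function(from, to) {
  t(frame_basis(to)) %*% frame_basis(from)
}

#' Alignment rotations between bony-landmark and triad frames
#'
#' Computed at a single neutral-pose frame and then applied to all frames:
#' `R3` maps the proximal bony-landmark frame to the proximal triad frame;
#' `R1` maps the distal triad frame to the distal bony-landmark frame.
#'
#' @param bony_prox,bony_dist Bony-landmark [segment_frame()]s at the neutral
#'   frame.
#' @param triad_prox,triad_dist Triad [segment_frame()]s at the neutral frame.
#' @return List with rotation matrices `R1` and `R3`.
#' @export
alignment_rotations <- function(bony_prox, bony_dist, triad_prox, triad_dist) {
  for (f in list(bony_prox, bony_dist, triad_prox, triad_dist)) {
    if (!inherits(f, "segment_frame")) {
      stop("alignment_rotations requires four segment_frame objects (invalid neutral frame?)")
    }
  }
  list(R1 = frame_rotation(triad_dist, bony_dist),
       R3 = frame_rotation(bony_prox, triad_prox))
}

#' Apply the alignment transform to a joint rotation series
#'
#' Per frame, `R_transform = R3 %*% R2 %*% R1` where `R2` is the joint
#' rotation determined from the bony-landmark frames at that frame.
#'
#' @param R1,R3 Alignment rotations from [alignment_rotations()].
#' @param bony_joint_rotations List of 3x3 joint rotation matrices (one per
#'   frame).
#' @return List of transformed rotation matrices, same length.
#' @export
transform_series <- function(R1, R3, bony_joint_rotations) {
  if (!length(bony_joint_rotations)) stop("empty rotation series")
  lapply(bony_joint_rotations, function(R2) R3 %*% R2 %*% R1)
}

#' Compare two joint-angle series
#'
#' @param a,b Numeric matrices `n x k` (angle series in degrees, columns =
#'   planes) or vectors.
#' @return Data frame with one row per plane: mean and max absolute
#'   difference.
#' @export
compare_series <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("angle series have mismatched dimensions")
  d <- abs(a - b)
  planes <- colnames(a)
  if (is.null(planes)) planes <- paste0("plane", seq_len(ncol(a)))
  data.frame(plane = planes,
             mean_abs_diff = colMeans(d, na.rm = TRUE),
             max_abs_diff = apply(d, 2L, max, na.rm = TRUE),
             row.names = NULL)
}
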