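# Lateral stifle virtual marker prediction.
#
# Skin motion across the quadruped stifle makes a physical knee marker
# unreliable, so the stifle is predicted from rigid landmarks: a fibula-length
# vector from the lateral malleolus through the fibular "vector" marker gives
# a tibial endpoint; a femur-length vector from the greater trochanter toward
# that endpoint gives a femoral endpoint; the virtual marker is their
# midpoint. The two analysis techniques share this prediction and differ only
# in which tibia frame variant downstream angle computation uses.

#' Predict the lateral stifle virtual marker at one frame
#'
#' @param gt Greater trochanter position (mm).
#' @param lm Lateral malleolus position (mm).
#' @param v Fibular vector marker position (mm).
#' @param l_fem Femur length (greater trochanter to distal femoral condyle), mm.
#' @param l_fib Fibula length (lateral malleolus to fibular head), mm.
#' @return A list of class `stifle_prediction` with `position` (the virtual
#'   marker), `tibia_endpoint`, and `femur_endpoint`, all mm.
#' @export
predict_stifle <- function(gt, lm, v, l_fem, l_fib) {
  if (!is.numeric(l_fem) || l_fem <= 0 || !is.numeric(l_fib) || l_fib <= 0) {
    stop("l_fem and l_fib must be positive lengths (mm)")
  }
  u_tib <- unit3(v - lm, scale = max(norm3(v), norm3(lm), 1),
                 what = "malleolus-to-vector-marker direction")
  tibia_end <- lm + l_fib * u_tib
  u_fem <- unit3(tibia_end - gt, scale = max(norm3(tibia_end), norm3(gt), 1),
                 what = "trochanter-to-tibia-endpoint direction")
  femur_end <- gt + l_fem * u_fem
  structure(list(position = (tibia_end + femur_end) / 2,
                 tibia_endpoint = tibia_end,
                 femur_endpoint = femur_end),
            class = "stifle_prediction")
}

#' Predict the stifle virtual marker over a whole trial
#'
#' Appends the virtual marker (named `RS` or `LS` per side) to the trajectory
#' set. Frames where the greater trochanter, lateral malleolus, or vector
#' marker is invalid yield an invalid virtual-marker sample. The prediction
#' itself is identical for both techniques; `technique` is recorded so that
#' downstream angle computation selects the matching tibia frame variant
#' (1 = vector-marker tibia axis, 2 = stifle-adjusted tibia axis).
#'
#' @param traj A [trajectory_set()].
#' @param limb A [limb_definition()].
#' @param technique 1 or 2.
#' @return The augmented [trajectory_set()] with attribute `technique`.
#' @export
stifle_trajectory <- function(traj, limb, technique = 1L) {
  technique <- as.integer(technique)
  stopifnot(technique %in% c(1L, 2L))
  mm_ <- limb$marker_map
  gt <- marker_xyz(traj, mm_[["gt"]])
  lm <- marker_xyz(traj, mm_[["lm"]])
  v <- marker_xyz(traj, mm_[["v"]])
  ok <- marker_valid(traj, mm_[["gt"]]) &
    marker_valid(traj, mm_[["lm"]]) &
    marker_valid(traj, mm_[["v"]])
  nf <- n_frames(traj)
  out <- matrix(NA_real_, nf, 3L)
  for (i in which(ok)) {
    out[i, ] <- predict_stifle(gt[i, ], lm[i, ], v[i, ],
                               limb$femur_length, limb$fibula_length)$position
  }
  res <- add_marker(traj, mm_[["stifle"]], out, valid = ok)
  attr(res, "technique") <- technique
  res
}
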