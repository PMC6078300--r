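# Shared fixtures: small synthetic trials, built in code at test time.

synth_trial <- function(style = "multiplane", sides = c("right", "left"),
                        n_cycles = 2, rate = 100, triads = FALSE,
                        stance_fraction = 0.6, ...) {
  spec <- synthetic_limb_spec(
    sides = sides, rate = rate, n_cycles = n_cycles,
    stance_fraction = stance_fraction,
    waveforms = default_gait_waveforms(style, stance_fraction),
    triads = triads, ...)
  forward_kinematics(spec)
}

default_limb <- function(side = "right") {
  g <- default_geometry()
  limb_definition(side, g$femur_length, g$fibula_length)
}

# Independent projection oracle for JCS angles: measures each rotation by
# direct geometric projection, sharing no code with jcs_angles().
jcs_oracle <- function(P, D, side) {
  e1 <- P[, 3]; e3 <- D[, 2]
  # flexion: angle between long axes after removing the e1 component
  u <- P[, 2] - sum(P[, 2] * e1) * e1
  v <- e3 - sum(e3 * e1) * e1
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  fe <- acos(max(-1, min(1, sum(u * v)))) * 180 / pi
  # abduction: complement of the angle between the two fixed axes
  ab <- 90 - acos(max(-1, min(1, sum(e1 * e3)))) * 180 / pi
  # rotation: signed angle about e3 from the floating axis to distal x
  e2 <- crossprod_vec(e3, e1); e2 <- e2 / sqrt(sum(e2^2))
  w <- D[, 1]
  ie <- atan2(sum(crossprod_vec(e2, w) * e3), sum(e2 * w)) * 180 / pi
  s <- if (side == "right") -1 else 1
  c(fe = fe, ie = s * ie, ab = s * ab)
}

crossprod_vec <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

expect_frame_valid <- function(fr, tol = 1e-9) {
  B <- frame_basis(fr)
  expect_lt(max(abs(crossprod(B) - diag(3))), tol)
  expect_lt(abs(det(B) - 1), tol)
}

# Random rotation matrix (uniform-ish, via QR of a Gaussian matrix).
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
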