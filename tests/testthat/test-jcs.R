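# Joint coordinate system decomposition and the sagittal comparison model.

id_frame <- function(origin = c(0, 0, 0)) {
  segment_frame(origin, c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
}

rotated_frame <- function(R, origin = c(0, 0, 0)) {
  segment_frame(origin, R[, 1], R[, 2], R[, 3])
}

test_that("identical frames give (0, 0, 0) and pure flexion isolates one plane", {
  a <- jcs_angles(id_frame(), id_frame(), "right")
  expect_equal(unname(a[1:3]), c(0, 0, 0), tolerance = 1e-12)

  for (side in c("right", "left")) {
    b <- jcs_angles(id_frame(), rotated_frame(hindkin:::rot_z(30)), side)
    expect_equal(unname(b["flexion_extension"]), 30, tolerance = 1e-9)
    expect_equal(unname(b["internal_external"]), 0, tolerance = 1e-9)
    expect_equal(unname(b["abduction_adduction"]), 0, tolerance = 1e-9)
  }
})

test_that("multiplane rotations match the independent projection oracle", {
  set.seed(33)
  cases <- rbind(c(5, 10, 40), c(60, -20, 15), c(120, 25, -30),
                 matrix(runif(45, -70, 70), 15, 3))
  cases[, 1] <- abs(cases[, 1])  # flexion folded to [0, 180]
  for (side in c("right", "left")) {
    s <- if (side == "right") -1 else 1
    for (i in seq_len(nrow(cases))) {
      a <- cases[i, 1]; b <- s * cases[i, 3]; cc <- s * cases[i, 2]
      R <- hindkin:::rot_z(a) %*% hindkin:::rot_x(b) %*% hindkin:::rot_y(cc)
      P <- diag(3)
      got <- jcs_angles(rotated_frame(P), rotated_frame(R), side)
      want <- jcs_oracle(P, R, side)
      expect_equal(unname(got["flexion_extension"]), unname(want["fe"]),
                   tolerance = 1e-6)
      expect_equal(unname(got["internal_external"]), unname(want["ie"]),
                   tolerance = 1e-6)
      expect_equal(unname(got["abduction_adduction"]), unname(want["ab"]),
                   tolerance = 1e-6)
      # and the oracle itself recovers the generating parameters
      expect_equal(unname(want["fe"]), a, tolerance = 1e-6)
      expect_equal(unname(want["ab"]), cases[i, 3], tolerance = 1e-6)
      expect_equal(unname(want["ie"]), cases[i, 2], tolerance = 1e-6)
    }
  }
})

test_that("proximal-frame orientation does not change the decomposition", {
  set.seed(44)
  for (k in 1:25) {
    P <- random_rotation()
    Rrel <- hindkin:::rot_z(70) %*% hindkin:::rot_x(-15) %*% hindkin:::rot_y(20)
    got <- jcs_angles(rotated_frame(P), rotated_frame(P %*% Rrel), "left")
    expect_equal(unname(got[1:3]), c(70, 20, -15), tolerance = 1e-8)
  }
})

test_that("gimbal configuration errors without a previous floating axis", {
  # distal long axis parallel to the proximal z axis
  R <- hindkin:::rot_x(90)
  expect_error(jcs_angles(id_frame(), rotated_frame(R), "right"),
               class = "hindkin_gimbal_error")
  prev <- c(1, 0, 0)
  expect_warning(
    a <- jcs_angles(id_frame(), rotated_frame(R), "right", prev_e2 = prev),
    "gimbal")
  expect_equal(abs(unname(a["abduction_adduction"])), 90, tolerance = 1e-9)
})

test_that("flexion convention switch reports the complementary angle", {
  R <- hindkin:::rot_z(30)
  a <- jcs_angles(id_frame(), rotated_frame(R), "right",
                  convention = "complement")
  expect_equal(unname(a["flexion_extension"]), 150, tolerance = 1e-9)
})

test_that("sagittal angle matches direct arccos arithmetic", {
  expect_equal(sagittal_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)), 90,
               tolerance = 1e-12)
  expect_equal(sagittal_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), 180,
               tolerance = 1e-12)
  # oracle: angle at (1,0,0) between (-1,0,0) and (0,1,1)/sqrt(2)
  want <- acos(sum(c(-1, 0, 0) * c(0, 1, 1) / sqrt(2))) * 180 / pi
  expect_equal(sagittal_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 1)), want,
               tolerance = 1e-9)
  expect_error(sagittal_angle(c(0, 0, 0), c(0, 0, 0), c(1, 1, 1)),
               class = "hindkin_degenerate_error")
})

test_that("constant prescribed angles are recovered as constants; planar motion stays planar", {
  wf <- list(hip = list(fe = wf_constant(70), ie = wf_constant(4),
                        ab = wf_constant(-6)),
             stifle = list(fe = wf_constant(50), ab = wf_constant(-5)),
             tarsus = list(fe = wf_constant(62), ie = wf_constant(8),
                           ab = wf_constant(4)))
  fk <- forward_kinematics(synthetic_limb_spec(sides = "right", n_cycles = 1,
                                               rate = 25, waveforms = wf))
  ser <- limb_angle_series(fk$traj, default_limb("right"), 1)
  for (j in names(ser)) {
    expect_lt(max(abs(sweep(ser[[j]]$angles, 2,
                            ser[[j]]$angles[1, ]))), 1e-6)
    expect_lt(max(abs(ser[[j]]$angles -
                        fk$truth$sides$right$angles[[j]])), 1e-6)
  }

  # hinge motion: transverse and frontal series identically zero
  fkh <- synth_trial("hinge", sides = "right", n_cycles = 1, rate = 50)
  serh <- limb_angle_series(fkh$traj, default_limb("right"), 1)
  for (j in names(serh)) {
    expect_lt(max(abs(serh[[j]]$angles[, c("internal_external",
                                           "abduction_adduction")])), 1e-6)
  }
})

test_that("mirror-symmetric gait yields identical signed series on both sides", {
  fk <- synth_trial(n_cycles = 1, rate = 50, phase_lag = 0)
  serR <- limb_angle_series(fk$traj, default_limb("right"), 1)
  serL <- limb_angle_series(fk$traj, default_limb("left"), 1)
  for (j in names(serR)) {
    expect_lt(max(abs(serR[[j]]$angles - serL[[j]]$angles)), 1e-9)
  }
})

test_that("invalid markers propagate to per-frame invalid angles", {
  fk <- synth_trial(sides = "right", n_cycles = 1, rate = 25)
  tg <- add_noise_and_gaps(fk$traj, 0,
                           data.frame(marker = "RMM", start = 4, end = 5))
  ser <- limb_angle_series(tg, default_limb("right"), 1)
  expect_false(any(ser$hip$valid[4:5]))     # femur frame needs the malleoli
  expect_false(any(ser$stifle$valid[4:5]))
  expect_true(all(ser$hip$valid[-(4:5)]))
  expect_true(all(is.na(ser$hip$angles[4:5, ])))
})
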