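# Forward-kinematics generator of synthetic marker trajectories for an
# articulated pelvis-femur-tibia-tarsus chain.
#
# Segment poses are composed proximal to distal using the same frame
# conventions as the anatomy module, and markers are placed at fixed local
# coordinates chosen so that rebuilding each frame from the generated markers
# reproduces it exactly. Because the model's femur frame borrows the tibial
# mediolateral axis, the stifle internal-external rotation is not a free
# degree of freedom: given the raw stifle flexion angle a and abduction angle
# b, marker-frame consistency forces the raw stifle IE to
# c = atan2(-sin(a) sin(b), cos(a)). The generator therefore accepts free
# waveforms for hip FE/IE/AbAd, stifle FE/AbAd, and tarsus FE/IE/AbAd, and
# emits the induced stifle IE as part of the ground truth (see the methods
# vignette for why the model couples these segments).

#' Waveform constructors for prescribed joint angles
#'
#' Waveforms are functions of gait-cycle phase in `[0, 1)` returning degrees.
#' `wf_constant` is a flat angle; `wf_sine` is `offset + amplitude *
#' sin(2*pi*(phase + phase0))`; `wf_swing_bump` holds `offset` during stance
#' (`phase < stance_fraction`) and adds a smooth raised-cosine excursion of
#' height `amplitude` during swing, returning to `offset` at the next contact
#' — the shape that keeps the limb stationary while the paw bears weight.
#'
#' @param value,offset Baseline angle, degrees.
#' @param amplitude Excursion, degrees.
#' @param phase0 Phase offset in cycles.
#' @param stance_fraction Fraction of the cycle spent in stance.
#' @return A function of phase.
#' @export
wf_constant <- function(value) {
  force(value)
  function(phi) rep(value, length(phi))
}

#' @rdname wf_constant
#' @export
wf_sine <- function(offset, amplitude, phase0 = 0) {
  force(offset); force(amplitude); force(phase0)
  function(phi) offset + amplitude * sin(2 * pi * (phi + phase0))
}

#' @rdname wf_constant
#' @export
wf_swing_bump <- function(offset, amplitude, stance_fraction = 0.6) {
  force(offset); force(amplitude); force(stance_fraction)
  function(phi) {
    out <- rep(offset, length(phi))
    sw <- phi >= stance_fraction
    u <- (phi[sw] - stance_fraction) / (1 - stance_fraction)
    out[sw] <- offset + amplitude * 0.5 * (1 - cos(2 * pi * u))
    out
  }
}

#' Default prescribed joint waveforms
#'
#' Three styles. `"multiplane"`: sinusoids in every free plane with offsets
#' and amplitudes loosely matching published feline gait ranges (hip FE
#' oscillating so the included segment angle spans roughly 82-130 degrees),
#' used for round-trip recovery tests. `"stance_flat"`: raised-cosine swing
#' bumps that hold the limb still during stance, so the paw is stationary and
#' near the ground while bearing weight — the shape gait-event detection
#' needs. `"hinge"`: pure sagittal flexion-extension with all transverse and
#' frontal waveforms identically zero.
#'
#' Flexion-extension waveforms are expressed in the `absolute` convention
#' (aligned long axes = 0 degrees); stifle IE is induced by the model's
#' femur-tibia coupling and cannot be prescribed.
#'
#' @param style `"multiplane"`, `"stance_flat"`, or `"hinge"`.
#' @param stance_fraction Stance fraction used by `"stance_flat"`.
#' @return Nested list `list(hip = list(fe, ie, ab), stifle = list(fe, ab),
#'   tarsus = list(fe, ie, ab))` of waveform functions.
#' @export
default_gait_waveforms <- function(style = c("multiplane", "stance_flat",
                                             "hinge"),
                                   stance_fraction = 0.6) {
  style <- match.arg(style)
  switch(style,
    multiplane = list(
      hip = list(fe = wf_sine(75, 20), ie = wf_sine(5, 7, 0.25),
                 ab = wf_sine(-7, 6, 0.5)),
      stifle = list(fe = wf_sine(52, 18, 0.1), ab = wf_sine(-6, 5, 0.35)),
      tarsus = list(fe = wf_sine(63, 12, 0.2), ie = wf_sine(9, 8, 0.6),
                    ab = wf_sine(5, 3, 0.8))
    ),
    stance_flat = list(
      hip = list(fe = wf_swing_bump(75, 25, stance_fraction),
                 ie = wf_constant(5), ab = wf_constant(-7)),
      stifle = list(fe = wf_swing_bump(45, 30, stance_fraction),
                    ab = wf_constant(-6)),
      tarsus = list(fe = wf_swing_bump(60, 20, stance_fraction),
                    ie = wf_constant(9), ab = wf_constant(5))
    ),
    hinge = list(
      hip = list(fe = wf_sine(75, 20), ie = wf_constant(0),
                 ab = wf_constant(0)),
      stifle = list(fe = wf_sine(52, 18, 0.1), ab = wf_constant(0)),
      tarsus = list(fe = wf_sine(63, 12, 0.2), ie = wf_constant(0),
                    ab = wf_constant(0))
    ))
}

#' Default limb geometry for the synthetic cat
#'
#' Segment dimensions in mm, scaled to an adult cat: pelvis width (distance
#' between iliac crests), drop from iliac crest to hip center, femur and
#' fibula lengths, malleolus marker separation, fibular vector-marker offset
#' proximal to the lateral malleolus (~2.5 cm), tarsus-to-5th-metatarsal
#' length, metatarsal half-width, calcaneus offset, standing pelvis height,
#' and the cranial/lateral offsets of the foot markers from the tarsus long
#' axis (0 by default, i.e. idealized on-axis placement; set them to emulate
#' a realistic laterodistal 5th-metatarsal marker).
#'
#' @return Named list of dimensions.
#' @export
default_geometry <- function() {
  list(pelvis_width = 60, pelvis_it_drop = 40, hip_drop = 25,
       femur_length = 105, fibula_length = 100, malleolus_width = 18,
       v_offset = 25, foot_length = 55, metatarsal_halfwidth = 8,
       calcaneus_drop = 20, pelvis_height = 240, foot_cranial_offset = 0,
       foot_lateral_offset = 0)
}

#' Specification for a synthetic gait trial
#'
#' @param sides Character vector, subset of `c("right", "left")`.
#' @param rate Sampling frequency, Hz.
#' @param n_cycles Number of complete step cycles.
#' @param cycle_duration Cycle duration, seconds.
#' @param stance_fraction Fraction of each cycle in stance (0-1).
#' @param speed Pelvis advance speed along lab x, mm/s (0 = treadmill-style).
#' @param waveforms Per-side waveform lists as produced by
#'   [default_gait_waveforms()]; a single list is applied to both sides
#'   (mirror-symmetric gait).
#' @param geometry Limb dimensions, see [default_geometry()].
#' @param phase_lag Phase offset of the left limb relative to the right, in
#'   cycles (default 0.5, alternating gait).
#' @param triads If `TRUE`, rigid marker triads (origin + 19 mm X and Y arms)
#'   are mounted on the pelvis and on each generated limb's femur, tibia, and
#'   tarsus segments.
#' @param triad_mounts Named list (`pelvis`, `femur`, `tibia`, `tarsus`) of
#'   3x3 mounting rotations of each triad relative to its segment frame;
#'   defaults to distinct known rotations.
#' @return An object of class `synthetic_limb_spec`.
#' @export
synthetic_limb_spec <- function(sides = c("right", "left"), rate = 100,
                                n_cycles = 3, cycle_duration = 0.7,
                                stance_fraction = 0.6, speed = 0,
                                waveforms = default_gait_waveforms(),
                                geometry = default_geometry(),
                                phase_lag = 0.5,
                                triads = FALSE, triad_mounts = NULL) {
  sides <- match.arg(sides, c("right", "left"), several.ok = TRUE)
  stopifnot(rate > 0, n_cycles >= 1, cycle_duration > 0,
            stance_fraction > 0, stance_fraction < 1)
  g <- default_geometry()
  g[names(geometry)] <- geometry
  if (any(unlist(g[c("pelvis_width", "femur_length", "fibula_length",
                     "foot_length")]) <= 0)) {
    stop("segment dimensions must be positive")
  }
  if (!is.null(waveforms$hip)) {
    waveforms <- list(right = waveforms, left = waveforms)
  }
  if (is.null(triad_mounts)) {
    triad_mounts <- list(
      pelvis = rot_z(8) %*% rot_x(-5),
      femur = rot_y(12) %*% rot_z(-6),
      tibia = rot_x(7) %*% rot_y(-9),
      tarsus = rot_z(-10) %*% rot_x(4))
  }
  structure(list(sides = sides, rate = rate, n_cycles = n_cycles,
                 cycle_duration = cycle_duration,
                 stance_fraction = stance_fraction, speed = speed,
                 waveforms = waveforms, geometry = g, phase_lag = phase_lag,
                 triads = isTRUE(triads), triad_mounts = triad_mounts),
            class = "synthetic_limb_spec")
}

# Raw (model-frame) z-x-y rotation parameters from clinical angles for a side.
clinical_to_raw <- function(fe, ie, ab, side) {
  s <- if (side == "right") -1 else 1
  list(a = fe, b = s * ab, c = s * ie)
}

# Induced raw stifle IE from raw stifle FE (a) and AbAd (b), degrees.
induced_stifle_ie <- function(a, b) {
  ar <- deg2rad(a); br <- deg2rad(b)
  rad2deg(atan2(-sin(ar) * sin(br), cos(ar)))
}

#' Generate marker trajectories by forward kinematics
#'
#' Composes the pelvis-femur-tibia-tarsus chain from the prescribed joint
#' waveforms and emits all standard markers (iliac crests, ischial
#' tuberosities, greater trochanter, malleoli, fibular vector marker,
#' calcaneus, 5th and 2nd metatarsals per generated side), plus marker triads
#' when requested. The true stifle joint center lies exactly at fibula length
#' from the lateral malleolus along the malleolus-to-vector-marker line and
#' at femur length from the greater trochanter, so the stifle prediction is
#' exact on noise-free output.
#'
#' If a stifle `ie` waveform is supplied it is ignored with a warning: the
#' model's femur-tibia coupling determines stifle IE from stifle FE and AbAd
#' (the induced series is returned as ground truth).
#'
#' @param spec A [synthetic_limb_spec()].
#' @return List with `traj` (a [trajectory_set()], up axis `y`) and `truth`:
#'   per-side clinical angle matrices (`n x 3` per joint, `absolute` FE
#'   convention), true stifle positions, contact/liftoff frames,
#'   stance fraction, triad mounting rotations, and the phase vector.
#' @export
forward_kinematics <- function(spec) {
  stopifnot(inherits(spec, "synthetic_limb_spec"))
  g <- spec$geometry
  cf <- spec$cycle_duration * spec$rate           # frames per cycle
  nf <- as.integer(round(spec$n_cycles * cf)) + 1L
  t_s <- (seq_len(nf) - 1L) / spec$rate
  markers <- list()
  truth <- list(sides = list(), stance_fraction = spec$stance_fraction,
                rate = spec$rate)

  o_p <- cbind(spec$speed * t_s, g$pelvis_height, 0)  # pelvis origin path
  P <- diag(3)  # pelvis basis: x cranial, y up, z animal-right
  w <- g$pelvis_width
  markers$RIC <- o_p
  markers$LIC <- o_p + matrix(P %*% c(0, 0, -w), nf, 3, byrow = TRUE)
  markers$RIT <- o_p + matrix(P %*% c(0, -g$pelvis_it_drop, 0), nf, 3, byrow = TRUE)
  markers$LIT <- o_p + matrix(P %*% c(0, -g$pelvis_it_drop, -w), nf, 3, byrow = TRUE)

  if (spec$triads) {
    tri <- triad_markers(o_p, P, spec$triad_mounts$pelvis,
                         offset = c(0, 30, -w / 2))
    markers[paste0("PV_T", c("O", "X", "Y"))] <- tri
  }

  for (side in spec$sides) {
    pre <- if (side == "right") "R" else "L"
    wf <- spec$waveforms[[side]]
    if (!is.null(wf$stifle$ie)) {
      warning("stifle internal-external rotation is induced by the femur-tibia coupling; supplied stifle ie waveform ignored",
              call. = FALSE)
    }
    lag <- if (side == "left") spec$phase_lag else 0
    phi <- (t_s / spec$cycle_duration + lag) %% 1

    hip <- cbind(fe = wf$hip$fe(phi), ie = wf$hip$ie(phi), ab = wf$hip$ab(phi))
    sti <- cbind(fe = wf$stifle$fe(phi), ab = wf$stifle$ab(phi))
    tar <- cbind(fe = wf$tarsus$fe(phi), ie = wf$tarsus$ie(phi),
                 ab = wf$tarsus$ab(phi))

    s <- if (side == "right") -1 else 1
    hz <- if (side == "right") 0 else -w
    m_hw <- g$malleolus_width
    d_mt <- g$metatarsal_halfwidth
    mal_sign <- if (side == "right") -1 else 1   # medial malleolus local z
    ankle_local <- c(0, -g$calcaneus_drop, -mal_sign * d_mt)

    pos <- list()
    for (nm in c("GT", "LM", "MM", "V", "C", "5MT", "2MT")) {
      pos[[nm]] <- matrix(NA_real_, nf, 3)
    }
    s_true <- matrix(NA_real_, nf, 3)
    sti_ie <- numeric(nf)
    tri_f <- tri_t <- tri_a <- NULL
    if (spec$triads) {
      tri_f <- lapply(1:3, function(i) matrix(NA_real_, nf, 3))
      tri_t <- lapply(1:3, function(i) matrix(NA_real_, nf, 3))
      tri_a <- lapply(1:3, function(i) matrix(NA_real_, nf, 3))
    }

    for (i in seq_len(nf)) {
      hip_raw <- clinical_to_raw(hip[i, "fe"], hip[i, "ie"], hip[i, "ab"], side)
      Fb <- P %*% rot_z(hip_raw$a) %*% rot_x(hip_raw$b) %*% rot_y(hip_raw$c)
      H <- o_p[i, ] + P %*% c(0, -g$hip_drop, hz)
      gt <- drop(H)
      stifle <- gt - g$femur_length * Fb[, 2]

      a_st <- sti[i, "fe"]
      b_st <- s * sti[i, "ab"]
      c_st <- induced_stifle_ie(a_st, b_st)
      sti_ie[i] <- s * c_st
      Tb <- Fb %*% rot_z(a_st) %*% rot_x(b_st) %*% rot_y(c_st)
      lm <- stifle - g$fibula_length * Tb[, 2]
      mm <- lm + mal_sign * m_hw * Tb[, 3]
      v <- lm + g$v_offset * Tb[, 2]

      tar_raw <- clinical_to_raw(tar[i, "fe"], tar[i, "ie"], tar[i, "ab"], side)
      Ab <- Tb %*% rot_z(tar_raw$a) %*% rot_x(tar_raw$b) %*% rot_y(tar_raw$c)
      # the calcaneus and metatarsal markers share a cranial/lateral offset
      # from the tarsus long axis; shifting them together leaves the rebuilt
      # frame unchanged (only marker differences enter it) but places the
      # 5MT marker off-axis, as a laterodistal skin marker really sits
      off <- c(g$foot_cranial_offset, 0, -mal_sign * g$foot_lateral_offset)
      c_pos <- lm + drop(Ab %*% (off - ankle_local))
      mt5 <- lm + drop(Ab %*% (off + c(0, -g$foot_length, 0)))
      mt2 <- lm + drop(Ab %*% (off + c(0, -g$foot_length, mal_sign * 2 * d_mt)))

      pos$GT[i, ] <- gt
      pos$LM[i, ] <- lm
      pos$MM[i, ] <- drop(mm)
      pos$V[i, ] <- drop(v)
      pos$C[i, ] <- drop(c_pos)
      pos$`5MT`[i, ] <- drop(mt5)
      pos$`2MT`[i, ] <- drop(mt2)
      s_true[i, ] <- drop(stifle)

      if (spec$triads) {
        mount_off <- c(15, -20, -mal_sign * 12)  # lateral mid-segment plate
        Tri <- Fb %*% spec$triad_mounts$femur
        o <- gt + drop(Fb %*% mount_off)
        tri_f[[1]][i, ] <- o
        tri_f[[2]][i, ] <- o + 19 * Tri[, 1]
        tri_f[[3]][i, ] <- o + 19 * Tri[, 2]
        Tri <- Tb %*% spec$triad_mounts$tibia
        o <- lm + drop(Tb %*% mount_off)
        tri_t[[1]][i, ] <- o
        tri_t[[2]][i, ] <- o + 19 * Tri[, 1]
        tri_t[[3]][i, ] <- o + 19 * Tri[, 2]
        Tri <- Ab %*% spec$triad_mounts$tarsus
        o <- c_pos + drop(Ab %*% mount_off)
        tri_a[[1]][i, ] <- o
        tri_a[[2]][i, ] <- o + 19 * Tri[, 1]
        tri_a[[3]][i, ] <- o + 19 * Tri[, 2]
      }
    }

    for (nm in names(pos)) markers[[paste0(pre, nm)]] <- pos[[nm]]
    if (spec$triads) {
      for (seg in list(list("FM", tri_f), list("TB", tri_t),
                       list("TA", tri_a))) {
        sfx <- c("O", "X", "Y")
        for (k in 1:3) {
          markers[[paste0(pre, seg[[1]], "_T", sfx[k])]] <- seg[[2]][[k]]
        }
      }
    }

    ang <- list(
      hip = cbind(flexion_extension = hip[, "fe"],
                  internal_external = hip[, "ie"],
                  abduction_adduction = hip[, "ab"]),
      stifle = cbind(flexion_extension = sti[, "fe"],
                     internal_external = sti_ie,
                     abduction_adduction = sti[, "ab"]),
      tarsus = cbind(flexion_extension = tar[, "fe"],
                     internal_external = tar[, "ie"],
                     abduction_adduction = tar[, "ab"]))
    # contacts at phase-0 crossings, liftoffs at phase = stance_fraction
    k <- 0:(spec$n_cycles + 1L)
    contact_f <- as.integer(round((k - lag) * cf)) + 1L
    liftoff_f <- as.integer(round((k - lag + spec$stance_fraction) * cf)) + 1L
    contact_f <- contact_f[contact_f >= 1L & contact_f <= nf]
    liftoff_f <- liftoff_f[liftoff_f > min(contact_f) &
                             liftoff_f < max(contact_f)]
    truth$sides[[side]] <- list(angles = ang, stifle = s_true,
                                contacts = contact_f,
                                liftoffs = liftoff_f,
                                phase = phi)
  }

  traj <- trajectory_set(markers, spec$rate, up_axis = "y")
  list(traj = traj,
       truth = c(truth, list(triad_mounts = if (spec$triads) spec$triad_mounts)))
}

# Markers of a triad mounted on a moving segment (pelvis path version).
triad_markers <- function(origin_path, basis, mount, offset) {
  Tri <- basis %*% mount
  nf <- nrow(origin_path)
  o <- origin_path + matrix(drop(basis %*% offset), nf, 3, byrow = TRUE)
  list(o,
       o + matrix(19 * Tri[, 1], nf, 3, byrow = TRUE),
       o + matrix(19 * Tri[, 2], nf, 3, byrow = TRUE))
}

#' Add measurement noise and occlusion gaps to a trajectory set
#'
#' Adds isotropic Gaussian noise (stationary, per coordinate) to every valid
#' sample and invalidates scheduled frame ranges, reproducibly under `seed`.
#'
#' @param traj A [trajectory_set()].
#' @param noise_sd Noise standard deviation, mm (>= 0).
#' @param gap_schedule Optional data frame with columns `marker`, `start`,
#'   `end` (inclusive frame ranges to invalidate).
#' @param seed Optional integer seed.
#' @return A [trajectory_set()].
#' @export
add_noise_and_gaps <- function(traj, noise_sd = 0, gap_schedule = NULL,
                               seed = NULL) {
  stopifnot(noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  pos <- traj$positions
  val <- traj$valid
  if (noise_sd > 0) {
    for (m in marker_names(traj)) {
      ok <- val[, m]
      pos[ok, , m] <- pos[ok, , m] +
        matrix(stats::rnorm(sum(ok) * 3L, sd = noise_sd), sum(ok), 3L)
    }
  }
  if (!is.null(gap_schedule) && nrow(gap_schedule)) {
    for (r in seq_len(nrow(gap_schedule))) {
      m <- as.character(gap_schedule$marker[r])
      rng <- gap_schedule$start[r]:gap_schedule$end[r]
      rng <- rng[rng >= 1L & rng <= n_frames(traj)]
      val[rng, m] <- FALSE
      pos[rng, , m] <- NA_real_
    }
  }
  trajectory_set(pos, traj$rate, val, traj$up_axis)
}
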