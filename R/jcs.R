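# Joint coordinate system angle decomposition and the 3-marker sagittal
# comparison model.
#
# The JCS uses a body-fixed flexion axis e1 = proximal ẑ, a body-fixed
# long/rotation axis e3 = distal ŷ, and the floating axis e2 = unit(e3 x e1).
# Flexion-extension is the angle between the proximal and distal long axes
# measured in the plane normal to e1 (folded to [0, 180]);
# abduction-adduction is 90° minus the angle between e1 and e3;
# internal-external rotation is the signed angle about e3 between the
# floating axis and the distal frame, referenced so that coincident frames
# read zero. Signed angles are mapped per side so that positive means
# external rotation / abduction for both limbs.

#' Joint coordinate system angles between two segment frames
#'
#' @param proximal,distal [segment_frame()]s in lab coordinates.
#' @param side `"right"` or `"left"` — selects the sign map that makes
#'   positive mean external rotation / abduction on either limb.
#' @param convention Flexion-extension reporting convention: `"absolute"`
#'   (default; aligned long axes read 0°) or `"complement"` (the included
#'   angle between the segments: aligned long axes read 180°).
#' @param prev_e2 Optional floating axis from the previous sample, used when
#'   the configuration is within 1e-9 of gimbal lock (|e1 . e3| ~ 1). With no
#'   previous axis available, gimbal lock raises an error.
#' @return Named numeric vector `c(flexion_extension, internal_external,
#'   abduction_adduction)` in degrees, with the floating axis attached as
#'   attribute `e2`.
#' @export
jcs_angles <- function(proximal, distal, side,
                       convention = c("absolute", "complement"),
                       prev_e2 = NULL) {
  convention <- match.arg(convention)
  side <- match_side(side)
  e1 <- proximal$z_axis
  e3 <- distal$y_axis
  c13 <- sum(e1 * e3)
  gimbal <- abs(c13) > 1 - 1e-9
  if (gimbal) {
    if (is.null(prev_e2)) {
      stop_gimbal("gimbal configuration: distal long axis parallel to flexion axis and no previous floating axis available")
    }
    warning("gimbal configuration: abduction saturated, reusing previous floating axis",
            call. = FALSE)
    e2 <- prev_e2
  } else {
    e2 <- unit3(cross3(e3, e1), what = "floating axis")
  }

  # flexion-extension: proximal vs distal long axes in the plane normal to e1
  u <- proximal$y_axis - sum(proximal$y_axis * e1) * e1
  v <- e3 - c13 * e1
  u <- unit3(u, what = "proximal long axis projection")
  if (gimbal) {
    fe <- 0  # distal long axis has no component in the flexion plane
  } else {
    v <- unit3(v, what = "distal long axis projection")
    fe <- rad2deg(atan2(norm3(cross3(u, v)), sum(u * v)))
  }

  ab_raw <- 90 - rad2deg(acos(clamp1(c13)))

  # internal-external rotation about e3: signed angle from the floating axis
  # to the distal ẑ, minus the 90° the two subtend at the neutral pose
  w <- distal$z_axis
  ie_raw <- rad2deg(atan2(sum(cross3(e2, w) * e3), sum(e2 * w))) + 90
  ie_raw <- wrap180(ie_raw)

  s <- if (side == "right") -1 else 1
  fe_out <- if (convention == "absolute") fe else 180 - fe
  out <- c(flexion_extension = fe_out,
           internal_external = s * ie_raw,
           abduction_adduction = s * ab_raw)
  attr(out, "e2") <- e2
  out
}

#' Joint angle time series container
#'
#' @param joint `"hip"`, `"stifle"`, or `"tarsus"`.
#' @param side `"right"` or `"left"`.
#' @param angles Numeric matrix `n x 3`, columns flexion_extension,
#'   internal_external, abduction_adduction (degrees).
#' @param rate Sampling frequency, Hz.
#' @param valid Logical vector, length `n`.
#' @param convention Flexion-extension convention used, see [jcs_angles()].
#' @return An object of class `joint_angle_series`.
#' @export
joint_angle_series <- function(joint, side, angles, rate, valid = NULL,
                               convention = "absolute") {
  joint <- match.arg(joint, c("hip", "stifle", "tarsus"))
  side <- match_side(side)
  angles <- as.matrix(angles)
  stopifnot(ncol(angles) == 3L)
  colnames(angles) <- c("flexion_extension", "internal_external",
                        "abduction_adduction")
  if (is.null(valid)) valid <- apply(is.finite(angles), 1L, all)
  stopifnot(length(valid) == nrow(angles))
  structure(list(joint = joint, side = side, angles = angles,
                 rate = as.numeric(rate), valid = valid,
                 convention = convention),
            class = "joint_angle_series")
}

#' @export
print.joint_angle_series <- function(x, ...) {
  cat(sprintf("<joint_angle_series> %s %s, %d frames @ %g Hz (%s FE)\n",
              x$side, x$joint, nrow(x$angles), x$rate, x$convention))
  ok <- x$valid
  if (any(ok)) {
    rng <- apply(x$angles[ok, , drop = FALSE], 2L, range)
    for (j in colnames(x$angles)) {
      cat(sprintf("  %-20s %8.2f .. %8.2f deg\n", j, rng[1L, j], rng[2L, j]))
    }
  }
  invisible(x)
}

# Build the four segment frames of one limb at one frame index.
# Returns list(pelvis, femur, tibia, tarsus) or NULL if any marker invalid /
# geometry degenerate.
limb_frames_at <- function(traj, limb, technique, i) {
  mm_ <- limb$marker_map
  need <- c("ric", "lic", "rit", "gt", "lm", "mm", "v", "c", "mt5", "mt2",
            "stifle")
  pts <- list()
  for (k in need) {
    name <- mm_[[k]]
    if (!traj$valid[i, name]) return(NULL)
    pts[[k]] <- traj$positions[i, , name]
  }
  tryCatch({
    pelvis <- build_pelvis_cs(pts$ric, pts$lic, pts$rit)
    femur <- build_femur_cs(limb$side, pts$gt, pts$stifle, pts$mm, pts$lm)
    ref <- if (technique == 1L) pts$v else pts$stifle
    tibia <- build_tibia_cs(limb$side, technique, pts$lm, pts$mm, ref)
    tarsus <- build_tarsus_cs(limb$side, pts$c, pts$mt5, pts$mt2)
    list(pelvis = pelvis, femur = femur, tibia = tibia, tarsus = tarsus)
  }, hindkin_degenerate_error = function(e) NULL)
}

#' Multiplane joint angle series for one hind limb
#'
#' Runs the full frame-by-frame pipeline: predicts the stifle virtual marker
#' (unless already present), builds the pelvis, femur, tibia (variant per
#' `technique`), and tarsus frames, and decomposes hip (pelvis to femur),
#' stifle (femur to tibia), and tarsal (tibia to tarsus) rotations with
#' [jcs_angles()]. Frames with invalid markers or degenerate geometry
#' propagate as invalid samples.
#'
#' @param traj A [trajectory_set()] containing all limb and pelvis markers.
#' @param limb A [limb_definition()].
#' @param technique Stifle technique, 1 (vector-marker tibia axis) or 2
#'   (stifle-adjusted tibia axis).
#' @param convention Flexion-extension convention, see [jcs_angles()].
#' @return Named list of three [joint_angle_series()]: `hip`, `stifle`,
#'   `tarsus`.
#' @export
limb_angle_series <- function(traj, limb, technique = 1L,
                              convention = "absolute") {
  technique <- as.integer(technique)
  if (!limb$marker_map[["stifle"]] %in% marker_names(traj)) {
    traj <- stifle_trajectory(traj, limb, technique)
  }
  nf <- n_frames(traj)
  res <- list(hip = matrix(NA_real_, nf, 3L),
              stifle = matrix(NA_real_, nf, 3L),
              tarsus = matrix(NA_real_, nf, 3L))
  prev_e2 <- list(hip = NULL, stifle = NULL, tarsus = NULL)
  pairs <- list(hip = c("pelvis", "femur"),
                stifle = c("femur", "tibia"),
                tarsus = c("tibia", "tarsus"))
  for (i in seq_len(nf)) {
    fr <- limb_frames_at(traj, limb, technique, i)
    if (is.null(fr)) next
    for (j in names(pairs)) {
      a <- tryCatch(
        jcs_angles(fr[[pairs[[j]][1L]]], fr[[pairs[[j]][2L]]], limb$side,
                   convention, prev_e2 = prev_e2[[j]]),
        hindkin_gimbal_error = function(e) NULL)
      if (!is.null(a)) {
        res[[j]][i, ] <- a
        prev_e2[[j]] <- attr(a, "e2")
      }
    }
  }
  lapply(stats::setNames(names(pairs), names(pairs)), function(j) {
    joint_angle_series(j, limb$side, res[[j]], traj$rate,
                       convention = convention)
  })
}

#' Included angle at a joint marker (sagittal-plane model)
#'
#' The angle at `p_joint` between the rays toward `p_prox` and `p_dist`,
#' i.e. the angle within the dynamically defined plane containing the three
#' markers, in degrees in `[0, 180]`.
#'
#' @param p_prox,p_joint,p_dist Positions (mm).
#' @return Angle in degrees.
#' @export
sagittal_angle <- function(p_prox, p_joint, p_dist) {
  a <- unit3(p_prox - p_joint, scale = max(norm3(p_prox), norm3(p_joint), 1),
             what = "proximal ray")
  b <- unit3(p_dist - p_joint, scale = max(norm3(p_dist), norm3(p_joint), 1),
             what = "distal ray")
  rad2deg(atan2(norm3(cross3(a, b)), sum(a * b)))
}

#' Sagittal-plane flexion-extension series for one hind limb
#'
#' The 3-marker comparison model: hip = angle at the greater trochanter
#' between the iliac crest and the stifle virtual marker; stifle = angle at
#' the stifle virtual marker between the greater trochanter and the lateral
#' malleolus; tarsus = angle at the lateral malleolus between the stifle
#' virtual marker and the 5th metatarsal.
#'
#' @inheritParams limb_angle_series
#' @return Named list of numeric vectors (`hip`, `stifle`, `tarsus`), degrees,
#'   `NA` where any required marker is invalid.
#' @export
sagittal_limb_series <- function(traj, limb, technique = 1L) {
  technique <- as.integer(technique)
  mm_ <- limb$marker_map
  if (!mm_[["stifle"]] %in% marker_names(traj)) {
    traj <- stifle_trajectory(traj, limb, technique)
  }
  ic_name <- if (limb$side == "right") mm_[["ric"]] else mm_[["lic"]]
  chains <- list(
    hip = c(ic_name, mm_[["gt"]], mm_[["stifle"]]),
    stifle = c(mm_[["gt"]], mm_[["stifle"]], mm_[["lm"]]),
    tarsus = c(mm_[["stifle"]], mm_[["lm"]], mm_[["mt5"]])
  )
  nf <- n_frames(traj)
  lapply(chains, function(ch) {
    ok <- traj$valid[, ch[1L]] & traj$valid[, ch[2L]] & traj$valid[, ch[3L]]
    out <- rep(NA_real_, nf)
    for (i in which(ok)) {
      out[i] <- tryCatch(
        sagittal_angle(traj$positions[i, , ch[1L]],
                       traj$positions[i, , ch[2L]],
                       traj$positions[i, , ch[3L]]),
        hindkin_degenerate_error = function(e) NA_real_)
    }
    out
  })
}
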