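# End-to-end pipelines: skin-marker gait analysis, triad validation, and
# synthetic-trial generation. These back the command-line interface
# (inst/cli/hindkin) and are usable directly from R.

#' Validate bony-landmark joint angles against marker triads
#'
#' Builds per-frame bony-landmark segment frames (pelvis, femur, tibia,
#' tarsus) and triad frames, computes the constant alignment rotations at the
#' neutral frame, applies the `R3 R2 R1` transform to the bony-landmark joint
#' rotation at each frame, extracts angles with [angles_from_rotation()] from
#' both the transformed and the triad rotations, and summarizes per-plane
#' differences with [compare_series()].
#'
#' @param traj A [trajectory_set()] containing landmark markers and triad
#'   markers.
#' @param limb A [limb_definition()].
#' @param technique Stifle technique (tibia frame variant), 1 or 2.
#' @param neutral_frame Frame index at which the limb is in the neutral
#'   (unloaded) pose; alignment rotations are computed there and applied to
#'   all frames.
#' @param triad_map Named list (`pelvis`, `femur`, `tibia`, `tarsus`) of
#'   3-element character vectors naming each triad's origin, X-arm, and Y-arm
#'   markers. Defaults to the names the synthetic generator emits
#'   (`PV_TO/..`, `<R|L>FM_T*`, `<R|L>TB_T*`, `<R|L>TA_T*`).
#' @return List with `angles` (per joint: transformed vs triad angle
#'   matrices) and `summary` (per joint, per plane mean/max absolute
#'   difference data frame).
#' @export
triad_validation <- function(traj, limb, technique = 1L, neutral_frame = 1L,
                             triad_map = NULL) {
  if (is.null(triad_map)) {
    pre <- if (limb$side == "right") "R" else "L"
    sfx <- c("O", "X", "Y")
    triad_map <- list(pelvis = paste0("PV_T", sfx),
                      femur = paste0(pre, "FM_T", sfx),
                      tibia = paste0(pre, "TB_T", sfx),
                      tarsus = paste0(pre, "TA_T", sfx))
  }
  if (!limb$marker_map[["stifle"]] %in% marker_names(traj)) {
    traj <- stifle_trajectory(traj, limb, technique)
  }
  nf <- n_frames(traj)
  if (neutral_frame < 1L || neutral_frame > nf) {
    stop("neutral_frame outside trial")
  }

  triad_at <- function(seg, i) {
    nm <- triad_map[[seg]]
    if (!all(traj$valid[i, nm])) return(NULL)
    triad_cs(traj$positions[i, , nm[1L]], traj$positions[i, , nm[2L]],
             traj$positions[i, , nm[3L]])
  }

  joints <- list(hip = c("pelvis", "femur"), stifle = c("femur", "tibia"),
                 tarsus = c("tibia", "tarsus"))
  bony0 <- limb_frames_at(traj, limb, technique, neutral_frame)
  if (is.null(bony0)) stop("invalid neutral frame: occluded marker or degenerate geometry")
  triad0 <- lapply(stats::setNames(nm = names(bony0)), triad_at,
                   i = neutral_frame)
  if (any(vapply(triad0, is.null, logical(1)))) {
    stop("invalid neutral frame: occluded triad marker")
  }

  out_angles <- list()
  out_summary <- list()
  for (j in names(joints)) {
    pseg <- joints[[j]][1L]; dseg <- joints[[j]][2L]
    align <- alignment_rotations(bony0[[pseg]], bony0[[dseg]],
                                 triad0[[pseg]], triad0[[dseg]])
    R2 <- vector("list", nf)
    Rtri <- vector("list", nf)
    for (i in seq_len(nf)) {
      fr <- limb_frames_at(traj, limb, technique, i)
      tp <- triad_at(pseg, i); td <- triad_at(dseg, i)
      if (is.null(fr) || is.null(tp) || is.null(td)) next
      R2[[i]] <- frame_rotation(fr[[dseg]], fr[[pseg]])
      Rtri[[i]] <- frame_rotation(td, tp)
    }
    ok <- !vapply(R2, is.null, logical(1))
    Rt <- transform_series(align$R1, align$R3, R2[ok])
    ang_t <- t(vapply(Rt, angles_from_rotation, numeric(3)))
    ang_tri <- t(vapply(Rtri[ok], angles_from_rotation, numeric(3)))
    colnames(ang_t) <- colnames(ang_tri) <- c("theta1", "theta2", "theta3")
    out_angles[[j]] <- list(transformed = ang_t, triad = ang_tri,
                            frames = which(ok), R1 = align$R1, R3 = align$R3)
    cs <- compare_series(ang_t, ang_tri)
    cs$joint <- j
    out_summary[[j]] <- cs
  }
  list(angles = out_angles,
       summary = do.call(rbind, out_summary)[, c("joint", "plane",
                                                 "mean_abs_diff",
                                                 "max_abs_diff")])
}

#' Read a run configuration file
#'
#' YAML with keys: `input` (trajectory file, .c3d or .csv), `side`(s),
#' `femur_length`, `fibula_length`, `technique` (1|2), `angle_convention`
#' (`absolute`|`complement`), `rate` (CSV input only), `up_axis`,
#' `events` (optional events CSV path), `marker_map` (optional logical-name
#' to marker-name map), `out` (output directory), `seed`.
#'
#' @param path YAML file path.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read config files")
  }
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

load_trajectories <- function(cfg) {
  input <- cfg$input
  if (is.null(input) || !file.exists(input)) {
    stop("config error: 'input' file missing or not found")
  }
  up <- if (is.null(cfg$up_axis)) "z" else cfg$up_axis
  if (grepl("\\.c3d$", input, ignore.case = TRUE)) {
    read_c3d(input, up_axis = up)
  } else {
    read_trajectory_csv(input, rate = if (is.null(cfg$rate)) 100 else cfg$rate,
                        up_axis = up)
  }
}

limb_from_config <- function(cfg, side) {
  for (k in c("femur_length", "fibula_length")) {
    if (is.null(cfg[[k]])) stop("config error: missing required field '", k, "'")
  }
  mm_ <- if (!is.null(cfg$marker_map)) unlist(cfg$marker_map) else NULL
  limb_definition(side, cfg$femur_length, cfg$fibula_length, marker_map = mm_)
}

#' Run the full gait-analysis pipeline from a configuration
#'
#' read -> fill gaps -> predict stifle -> segment frames -> multiplane and
#' sagittal angles -> gait events -> percent-cycle waveforms -> summary
#' table. Writes per-frame angle CSVs, cycle waveform CSVs, and a summary CSV
#' into `cfg$out`.
#'
#' @param cfg Configuration list, see [read_run_config()].
#' @return Invisibly, a list with per-side results (`angles`, `sagittal`,
#'   `events`, `waveforms`, `summary`) and the paths written.
#' @export
run_analyze <- function(cfg) {
  traj <- load_trajectories(cfg)
  traj <- fill_gaps(traj, max_gap = if (is.null(cfg$max_gap)) 4L else cfg$max_gap)
  fill_log <- attr(traj, "fill_log")
  technique <- if (is.null(cfg$technique)) 1L else as.integer(cfg$technique)
  convention <- if (is.null(cfg$angle_convention)) "absolute" else cfg$angle_convention
  sides <- if (is.null(cfg$side)) c("right", "left") else cfg$side
  out_dir <- if (is.null(cfg$out)) "." else cfg$out
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  results <- list()
  summaries <- list()
  for (side in sides) {
    limb <- limb_from_config(cfg, side)
    traj_s <- stifle_trajectory(traj, limb, technique)
    series <- limb_angle_series(traj_s, limb, technique, convention)
    sagittal <- sagittal_limb_series(traj_s, limb, technique)
    events <- if (!is.null(cfg$events)) {
      read_events_csv(cfg$events, side)
    } else {
      detect_events(traj_s, side, limb)
    }
    waves <- lapply(series, normalize_cycles, events = events)
    summ <- gait_summary(series, events)
    summaries[[side]] <- summ

    ang_path <- file.path(out_dir, sprintf("angles_%s_technique%d.csv",
                                           side, technique))
    write_angles_csv(series, sagittal, ang_path)
    wave_path <- file.path(out_dir, sprintf("waveforms_%s_technique%d.csv",
                                            side, technique))
    write_waveforms_csv(waves, wave_path)
    results[[side]] <- list(angles = series, sagittal = sagittal,
                            events = events, waveforms = waves,
                            summary = summ)
  }
  summary_all <- do.call(rbind, summaries)
  sum_path <- file.path(out_dir, sprintf("summary_technique%d.csv", technique))
  utils::write.csv(summary_all, sum_path, row.names = FALSE)
  if (!is.null(fill_log) && nrow(fill_log)) {
    utils::write.csv(fill_log, file.path(out_dir, "fill_log.csv"),
                     row.names = FALSE)
  }
  invisible(list(sides = results, summary = summary_all,
                 paths = c(summary = sum_path)))
}

write_angles_csv <- function(series, sagittal, path) {
  nf <- nrow(series[[1L]]$angles)
  d <- data.frame(frame = seq_len(nf))
  for (j in names(series)) {
    for (p in colnames(series[[j]]$angles)) {
      d[[paste(j, p, sep = "_")]] <- series[[j]]$angles[, p]
    }
    d[[paste0(j, "_sagittal")]] <- sagittal[[j]]
  }
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

write_waveforms_csv <- function(waves, path) {
  rows <- list()
  for (j in names(waves)) {
    w <- waves[[j]]
    for (p in colnames(w$mean)) {
      rows[[length(rows) + 1L]] <- data.frame(
        joint = j, plane = p, percent = w$percent,
        mean = w$mean[, p], sd = w$sd[, p])
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Run the triad validation pipeline from a configuration
#'
#' Requires `input`, `side`, `femur_length`, `fibula_length`, and
#' `neutral_frame` in the configuration; writes a per-frame comparison CSV
#' and a per-plane summary CSV into `cfg$out`.
#'
#' @param cfg Configuration list.
#' @return Invisibly, the [triad_validation()] result.
#' @export
run_validate <- function(cfg) {
  if (is.null(cfg$neutral_frame)) {
    stop("config error: missing required field 'neutral_frame'")
  }
  traj <- load_trajectories(cfg)
  side <- if (is.null(cfg$side)) "right" else cfg$side[1L]
  limb <- limb_from_config(cfg, side)
  technique <- if (is.null(cfg$technique)) 1L else as.integer(cfg$technique)
  res <- triad_validation(traj, limb, technique,
                          neutral_frame = as.integer(cfg$neutral_frame))
  out_dir <- if (is.null(cfg$out)) "." else cfg$out
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (j in names(res$angles)) {
    a <- res$angles[[j]]
    for (p in colnames(a$transformed)) {
      rows[[length(rows) + 1L]] <- data.frame(
        joint = j, frame = a$frames, plane = p,
        transformed = a$transformed[, p], triad = a$triad[, p])
    }
  }
  utils::write.csv(do.call(rbind, rows),
                   file.path(out_dir, "validation_angles.csv"),
                   row.names = FALSE)
  utils::write.csv(res$summary,
                   file.path(out_dir, "validation_summary.csv"),
                   row.names = FALSE)
  invisible(res)
}

#' Generate a synthetic trial from a configuration
#'
#' Writes the generated trajectories as C3D and CSV, the ground-truth events
#' CSV, and a ground-truth JSON (angle waveforms, true stifle positions,
#' events, stance fraction) into `cfg$out`. Deterministic given `cfg$seed`.
#'
#' @param cfg Configuration list; recognized keys: `sides`, `rate`,
#'   `n_cycles`, `cycle_duration`, `stance_fraction`, `speed`, `style`
#'   (waveform style for [default_gait_waveforms()]), `noise_sd`, `triads`,
#'   `seed`, `out`.
#' @return Invisibly, the [forward_kinematics()] result.
#' @export
run_synth <- function(cfg) {
  style <- if (is.null(cfg$style)) "multiplane" else cfg$style
  sf <- if (is.null(cfg$stance_fraction)) 0.6 else cfg$stance_fraction
  spec <- synthetic_limb_spec(
    sides = if (is.null(cfg$sides)) c("right", "left") else cfg$sides,
    rate = if (is.null(cfg$rate)) 100 else cfg$rate,
    n_cycles = if (is.null(cfg$n_cycles)) 3 else cfg$n_cycles,
    cycle_duration = if (is.null(cfg$cycle_duration)) 0.7 else cfg$cycle_duration,
    stance_fraction = sf,
    speed = if (is.null(cfg$speed)) 0 else cfg$speed,
    waveforms = default_gait_waveforms(style, sf),
    triads = isTRUE(cfg$triads))
  fk <- forward_kinematics(spec)
  traj <- fk$traj
  if (!is.null(cfg$noise_sd) && cfg$noise_sd > 0) {
    traj <- add_noise_and_gaps(traj, cfg$noise_sd, seed = cfg$seed)
  }
  out_dir <- if (is.null(cfg$out)) "." else cfg$out
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_c3d(traj, file.path(out_dir, "synthetic_trial.c3d"))
  write_trajectory_csv(traj, file.path(out_dir, "synthetic_trial.csv"))
  for (side in spec$sides) {
    tr <- fk$truth$sides[[side]]
    write_events_csv(gait_events(tr$contacts, tr$liftoffs, side),
                     file.path(out_dir, sprintf("events_%s.csv", side)))
  }
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    truth <- fk$truth
    truth$sides <- lapply(truth$sides, function(s) {
      s$angles <- lapply(s$angles, function(m) as.data.frame(m))
      s$stifle <- as.data.frame(s$stifle)
      s
    })
    truth$triad_mounts <- NULL
    jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(fk)
}
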