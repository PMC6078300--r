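# Gait-cycle segmentation, percent-cycle normalization, and summary
# statistics of joint-angle waveforms.

#' Gait events container
#'
#' Paw contact and liftoff frame indices for one limb. Events must be
#' strictly increasing and alternate so that every stride (contact to next
#' contact) contains exactly one liftoff. Liftoffs before the first or after
#' the last contact are dropped.
#'
#' @param contacts Integer frame indices of paw contact.
#' @param liftoffs Integer frame indices of paw liftoff.
#' @param side `"right"` or `"left"`.
#' @return An object of class `gait_events`.
#' @export
gait_events <- function(contacts, liftoffs, side) {
  side <- match_side(side)
  contacts <- as.integer(sort(contacts))
  liftoffs <- as.integer(sort(liftoffs))
  if (length(contacts) < 2L) {
    stop("at least two contacts (one complete cycle) are required")
  }
  liftoffs <- liftoffs[liftoffs > contacts[1L] &
                         liftoffs < contacts[length(contacts)]]
  for (i in seq_len(length(contacts) - 1L)) {
    k <- sum(liftoffs > contacts[i] & liftoffs < contacts[i + 1L])
    if (k != 1L) {
      stop(sprintf("cycle %d (frames %d-%d) contains %d liftoffs, expected 1",
                   i, contacts[i], contacts[i + 1L], k))
    }
  }
  structure(list(contacts = contacts, liftoffs = liftoffs, side = side),
            class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events> %s limb: %d cycles\n", x$side,
              length(x$contacts) - 1L))
  cat("  contacts:", x$contacts, "\n  liftoffs:", x$liftoffs, "\n")
  invisible(x)
}

#' Number of complete cycles
#' @param events A [gait_events()].
#' @export
n_cycles <- function(events) length(events$contacts) - 1L

#' Detect paw contact and liftoff events from a foot marker
#'
#' Threshold-based detection on the distal foot marker (5th metatarsal by
#' default, 2nd metatarsal as fallback): a frame is classified as stance when
#' the marker's speed along the up axis is below `vel_threshold` and its
#' height is within `height_margin` of the low (ground) band. Contacts are
#' the falling crossings into stance, liftoffs the rising crossings out of
#' it. Events supplied from a file (see [read_events_csv()]) always take
#' precedence over detection.
#'
#' @param traj A [trajectory_set()] (its `up_axis` defines height).
#' @param side `"right"` or `"left"`.
#' @param limb Optional [limb_definition()] for marker-name mapping; defaults
#'   to the conventional side-prefixed names.
#' @param vel_threshold Stance vertical-speed band, mm/s (default 50).
#' @param height_margin Height band above the 10th percentile of marker
#'   height, mm (default 10).
#' @return A [gait_events()].
#' @export
detect_events <- function(traj, side, limb = NULL, vel_threshold = 50,
                          height_margin = 10) {
  side <- match_side(side)
  if (is.null(limb)) limb <- limb_definition(side, 100, 100)
  cand <- c(limb$marker_map[["mt5"]], limb$marker_map[["mt2"]])
  name <- cand[cand %in% marker_names(traj)][1L]
  if (is.na(name)) stop_marker("no metatarsal marker available for event detection")
  up <- match(traj$up_axis, c("x", "y", "z"))
  h <- marker_xyz(traj, name)[, up]
  ok <- marker_valid(traj, name)
  if (!all(ok)) {
    stop("event detection requires the foot marker to be valid over the trial (fill gaps first)")
  }
  nf <- length(h)
  v <- c(0, (h[3:nf] - h[1:(nf - 2L)]) * traj$rate / 2, 0)
  v[1L] <- v[2L]; v[nf] <- v[nf - 1L]
  band <- stats::quantile(h, 0.10, names = FALSE) + height_margin
  stance <- abs(v) < vel_threshold & h <= band
  if (!any(stance) || all(stance)) {
    stop("no complete gait cycle found (marker stationary or never in stance)")
  }
  r <- rle(stance)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  contacts <- starts[r$values & starts > 1L]
  liftoffs <- ends[r$values & ends < nf] + 1L
  if (length(contacts) < 2L) {
    stop("no complete gait cycle found (fewer than two contacts)")
  }
  gait_events(contacts, liftoffs, side)
}

#' Read gait events from CSV
#'
#' Format: `side,event_type,frame` with `event_type` in
#' `{contact, liftoff}`. Events are validated against the [gait_events()]
#' invariants.
#'
#' @param path CSV file path.
#' @param side Which side to extract.
#' @return A [gait_events()].
#' @export
read_events_csv <- function(path, side) {
  side <- match_side(side)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("side", "event_type", "frame")
  if (!all(need %in% names(d))) {
    stop_format("events CSV must have columns side,event_type,frame")
  }
  d <- d[tolower(d$side) == side, ]
  gait_events(d$frame[d$event_type == "contact"],
              d$frame[d$event_type == "liftoff"], side)
}

#' Write gait events to CSV
#' @param events A [gait_events()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  d <- rbind(
    data.frame(side = events$side, event_type = "contact",
               frame = events$contacts),
    data.frame(side = events$side, event_type = "liftoff",
               frame = events$liftoffs))
  d <- d[order(d$frame), ]
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Normalize a joint-angle series into percent-cycle waveforms
#'
#' Each stride (contact to next contact) is linearly resampled onto a
#' 101-point 0-100% grid; the pointwise mean and SD waveforms are computed
#' over cycles. Cycles containing invalid samples are dropped and logged.
#'
#' @param series A [joint_angle_series()].
#' @param events A [gait_events()].
#' @return An object of class `cycle_waveforms`: `percent` (grid),
#'   `cycles` (array `101 x 3 x n_cycles`), `mean`, `sd` (matrices `101 x 3`),
#'   `stance_fraction` (per cycle), `dropped` (indices of dropped cycles).
#' @export
normalize_cycles <- function(series, events) {
  stopifnot(inherits(series, "joint_angle_series"),
            inherits(events, "gait_events"))
  grid <- seq(0, 100, length.out = 101L)
  nc <- n_cycles(events)
  keep <- logical(nc)
  waves <- array(NA_real_, c(101L, 3L, nc),
                 dimnames = list(NULL, colnames(series$angles), NULL))
  sf <- rep(NA_real_, nc)
  for (i in seq_len(nc)) {
    a <- events$contacts[i]
    b <- events$contacts[i + 1L]
    idx <- a:b
    if (b > nrow(series$angles) || !all(series$valid[idx])) next
    keep[i] <- TRUE
    x <- (idx - a) / (b - a) * 100
    for (j in 1:3) {
      waves[, j, i] <- stats::approx(x, series$angles[idx, j], xout = grid)$y
    }
    lo <- events$liftoffs[events$liftoffs > a & events$liftoffs < b]
    sf[i] <- (lo - a) / (b - a)
  }
  if (!any(keep)) stop("no complete valid cycle available")
  w <- waves[, , keep, drop = FALSE]
  mean_w <- apply(w, c(1L, 2L), mean)
  sd_w <- if (dim(w)[3L] > 1L) apply(w, c(1L, 2L), stats::sd) else
    matrix(0, 101L, 3L, dimnames = dimnames(mean_w))
  structure(list(percent = grid, cycles = w, mean = mean_w, sd = sd_w,
                 stance_fraction = sf[keep], joint = series$joint,
                 side = series$side, dropped = which(!keep)),
            class = "cycle_waveforms")
}

#' @export
print.cycle_waveforms <- function(x, ...) {
  cat(sprintf("<cycle_waveforms> %s %s: %d cycles, stance fraction %.2f\n",
              x$side, x$joint, dim(x$cycles)[3L], mean(x$stance_fraction)))
  if (length(x$dropped)) cat("  dropped cycles:", x$dropped, "\n")
  invisible(x)
}

#' Summary statistics of a joint-plane waveform over the average step cycle
#'
#' By default statistics describe the mean (cycle-averaged) waveform: its
#' mean and SD over the percent grid, its extrema, and the range of motion
#' `rom = max - min`. `sd_mode = "pooled"` instead reports the SD pooled
#' across all cycle samples.
#'
#' @param wave A `cycle_waveforms` object from [normalize_cycles()].
#' @param plane `"flexion_extension"`, `"internal_external"`, or
#'   `"abduction_adduction"`.
#' @param sd_mode `"mean_waveform"` (default) or `"pooled"`.
#' @return List of class `summary_stats`: `mean`, `sd`, `max`, `min`, `rom`
#'   (degrees).
#' @export
summarize_cycles <- function(wave, plane = c("flexion_extension",
                                             "internal_external",
                                             "abduction_adduction"),
                             sd_mode = c("mean_waveform", "pooled")) {
  plane <- match.arg(plane)
  sd_mode <- match.arg(sd_mode)
  m <- wave$mean[, plane]
  s <- if (sd_mode == "mean_waveform") stats::sd(m) else
    stats::sd(as.vector(wave$cycles[, plane, ]))
  structure(list(mean = mean(m), sd = s, max = max(m), min = min(m),
                 rom = max(m) - min(m)),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("mean %.1f (SD %.1f)  max %.1f  min %.1f  ROM %.1f deg\n",
              x$mean, x$sd, x$max, x$min, x$rom))
  invisible(x)
}

#' Tabulate summary statistics for all joints and planes of one limb
#'
#' Produces the conventional joint-by-plane summary table (mean, SD, max,
#' min, ROM over the average step cycle).
#'
#' @param series_list Named list of [joint_angle_series()] (`hip`, `stifle`,
#'   `tarsus`), as returned by [limb_angle_series()].
#' @param events A [gait_events()].
#' @param sd_mode See [summarize_cycles()].
#' @return Data frame with columns joint, plane, mean, sd, max, min, rom.
#' @export
gait_summary <- function(series_list, events, sd_mode = "mean_waveform") {
  planes <- c("flexion_extension", "internal_external",
              "abduction_adduction")
  rows <- list()
  for (j in names(series_list)) {
    wave <- normalize_cycles(series_list[[j]], events)
    for (p in planes) {
      s <- summarize_cycles(wave, p, sd_mode)
      rows[[length(rows) + 1L]] <- data.frame(
        joint = j, side = series_list[[j]]$side, plane = p,
        mean = s$mean, sd = s$sd, max = s$max, min = s$min, rom = s$rom)
    }
  }
  do.call(rbind, rows)
}
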