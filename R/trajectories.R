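# Marker-trajectory container and CSV I/O.
#
# Positions are stored as an array [n_frames, 3, n_markers] in mm, lab frame,
# with a parallel logical validity matrix [n_frames, n_markers]. Occluded or
# missing samples are valid = FALSE; their coordinates are NA.

#' Construct a marker trajectory set
#'
#' @param positions Numeric array `[n_frames, 3, n_markers]` (mm, lab frame)
#'   with marker names as the third dimnames, or a named list of
#'   `n_frames x 3` matrices.
#' @param rate Sampling frequency, Hz (> 0).
#' @param valid Logical matrix `[n_frames, n_markers]`; `FALSE` marks
#'   occluded/missing samples. Defaults to finiteness of all three
#'   coordinates.
#' @param up_axis Which lab axis points up: `"z"` (default, common motion
#'   capture practice), `"y"`, or `"x"`. Used by gait event detection.
#' @return An object of class `trajectory_set`.
#' @export
trajectory_set <- function(positions, rate, valid = NULL, up_axis = "z") {
  if (is.list(positions)) {
    nm <- names(positions)
    if (is.null(nm) || any(nm == "")) stop("marker list must be named")
    nf <- nrow(positions[[1L]])
    arr <- array(NA_real_, c(nf, 3L, length(positions)),
                 dimnames = list(NULL, c("x", "y", "z"), nm))
    for (i in seq_along(positions)) {
      m <- as.matrix(positions[[i]])
      if (!all(dim(m) == c(nf, 3L))) {
        stop("all markers must share the same frame count (n x 3 matrices)")
      }
      arr[, , i] <- m
    }
    positions <- arr
  }
  stopifnot(is.array(positions), length(dim(positions)) == 3L,
            dim(positions)[2L] == 3L)
  if (is.null(dimnames(positions)[[3L]])) {
    stop("positions must carry marker names in dimnames[[3]]")
  }
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0) {
    stop("rate must be a single positive number (Hz)")
  }
  up_axis <- match.arg(tolower(up_axis), c("z", "y", "x"))
  nf <- dim(positions)[1L]
  nm <- dim(positions)[3L]
  if (is.null(valid)) {
    valid <- apply(is.finite(positions), c(1L, 3L), all)
    dim(valid) <- c(nf, nm)
  }
  stopifnot(is.logical(valid), all(dim(valid) == c(nf, nm)))
  colnames(valid) <- dimnames(positions)[[3L]]
  # invariant: positions finite wherever valid
  ok <- apply(is.finite(positions), c(1L, 3L), all)
  if (any(valid & !ok)) stop("valid samples must have finite coordinates")
  structure(list(positions = positions, rate = as.numeric(rate),
                 valid = valid, up_axis = up_axis),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("<trajectory_set> %d markers x %d frames @ %g Hz (up: %s)\n",
              n_markers(x), n_frames(x), x$rate, x$up_axis))
  cat("  markers:", paste(marker_names(x), collapse = ", "), "\n")
  miss <- sum(!x$valid)
  if (miss > 0) cat(sprintf("  %d invalid marker-frames\n", miss))
  invisible(x)
}

#' @rdname trajectory_set
#' @param x A `trajectory_set`.
#' @export
n_frames <- function(x) dim(x$positions)[1L]

#' @rdname trajectory_set
#' @export
n_markers <- function(x) dim(x$positions)[3L]

#' @rdname trajectory_set
#' @export
marker_names <- function(x) dimnames(x$positions)[[3L]]

#' Extract one marker's `n x 3` position matrix
#' @param x A `trajectory_set`.
#' @param name Marker name.
#' @return Numeric matrix `n_frames x 3` (mm).
#' @export
marker_xyz <- function(x, name) {
  if (!name %in% marker_names(x)) {
    stop_marker(sprintf("marker '%s' not present in trajectory set", name))
  }
  x$positions[, , name, drop = TRUE]
}

#' Marker validity flags
#' @inheritParams marker_xyz
#' @return Logical vector of length `n_frames`.
#' @export
marker_valid <- function(x, name) {
  if (!name %in% marker_names(x)) {
    stop_marker(sprintf("marker '%s' not present in trajectory set", name))
  }
  x$valid[, name]
}

#' Append or replace a marker in a trajectory set
#' @param x A `trajectory_set`.
#' @param name Marker name to add.
#' @param xyz `n_frames x 3` matrix (mm).
#' @param valid Logical validity vector; defaults to finite rows.
#' @return The augmented `trajectory_set`.
#' @export
add_marker <- function(x, name, xyz, valid = NULL) {
  xyz <- as.matrix(xyz)
  stopifnot(all(dim(xyz) == c(n_frames(x), 3L)))
  if (is.null(valid)) valid <- apply(is.finite(xyz), 1L, all)
  keep <- setdiff(marker_names(x), name)
  nm <- c(keep, name)
  arr <- array(NA_real_, c(n_frames(x), 3L, length(nm)),
               dimnames = list(NULL, c("x", "y", "z"), nm))
  arr[, , keep] <- x$positions[, , keep]
  arr[, , name] <- xyz
  vl <- cbind(x$valid[, keep, drop = FALSE], valid)
  colnames(vl) <- nm
  trajectory_set(arr, x$rate, vl, x$up_axis)
}

#' Read marker trajectories from CSV
#'
#' Dialect: a header row `frame,<M>_x,<M>_y,<M>_z,...`, one row per frame,
#' comma separator, `.` decimal, units mm. A blank cell marks an occluded
#' sample: the frame is flagged invalid for that marker only.
#'
#' @param path CSV file path.
#' @param rate Sampling frequency in Hz (the dialect does not store it);
#'   default 100.
#' @param up_axis Up axis label, see [trajectory_set()].
#' @return A [trajectory_set()].
#' @export
read_trajectory_csv <- function(path, rate = 100, up_axis = "z") {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  lines <- readLines(path)
  if (length(lines) < 1L) stop_format("empty CSV file")
  header <- strsplit(lines[[1L]], ",", fixed = TRUE)[[1L]]
  if (header[1L] != "frame") stop_format("first CSV column must be 'frame'")
  coord_cols <- header[-1L]
  if (length(coord_cols) %% 3L != 0L) {
    stop_format("coordinate columns must come in <marker>_x,_y,_z triples")
  }
  mk <- sub("_[xyz]$", "", coord_cols)
  sfx <- sub("^.*_([xyz])$", "\\1", coord_cols)
  markers <- unique(mk)
  for (m in markers) {
    if (!identical(sfx[mk == m], c("x", "y", "z"))) {
      stop_format(sprintf("marker '%s' must have consecutive _x,_y,_z columns", m))
    }
  }
  body <- lines[-1L]
  body <- body[nzchar(body)]
  nf <- length(body)
  arr <- array(NA_real_, c(nf, 3L, length(markers)),
               dimnames = list(NULL, c("x", "y", "z"), markers))
  ncols <- length(header)
  for (i in seq_len(nf)) {
    nfields <- nchar(gsub("[^,]", "", body[[i]])) + 1L
    if (nfields != ncols) {
      stop_format(sprintf("ragged CSV row %d: %d cells, expected %d",
                          i, nfields, ncols))
    }
    cells <- strsplit(body[[i]], ",", fixed = TRUE)[[1L]]
    # trailing blank cells are dropped by strsplit; pad them back
    if (length(cells) < ncols) cells <- c(cells, rep("", ncols - length(cells)))
    vals <- cells[-1L]
    blank <- !nzchar(trimws(vals))
    num <- suppressWarnings(as.numeric(vals))
    if (any(!blank & is.na(num))) {
      stop_format(sprintf("non-numeric cell in CSV row %d", i))
    }
    arr[i, , ] <- num  # column-major fill: 3 coords vary fastest, as in header
  }
  valid <- apply(is.finite(arr), c(1L, 3L), all)
  dim(valid) <- c(nf, length(markers))
  trajectory_set(arr, rate, valid, up_axis)
}

#' Write marker trajectories to CSV
#'
#' Inverse of [read_trajectory_csv()]: values are written with full double
#' precision (`%.17g`) so a read/write/read round trip is exact; invalid
#' samples become blank cells.
#'
#' @param traj A [trajectory_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  nm <- marker_names(traj)
  header <- c("frame", as.vector(t(outer(nm, c("_x", "_y", "_z"), paste0))))
  nf <- n_frames(traj)
  rows <- character(nf)
  for (i in seq_len(nf)) {
    cells <- character(length(nm) * 3L)
    k <- 1L
    for (m in nm) {
      if (traj$valid[i, m]) {
        cells[k:(k + 2L)] <- sprintf("%.17g", traj$positions[i, , m])
      } else {
        cells[k:(k + 2L)] <- ""
      }
      k <- k + 3L
    }
    rows[i] <- paste(c(i, cells), collapse = ",")
  }
  writeLines(c(paste(header, collapse = ","), rows), path)
  invisible(path)
}

#' Fill short occlusion gaps with quintic spline interpolation
#'
#' Gaps of at most `max_gap` consecutive invalid frames are bridged, per
#' coordinate, by an exact quintic (degree <= 5) polynomial interpolant
#' through up to three valid frames on each side of the gap, in the spirit of
#' Woltring's quintic splines as used for short motion-capture dropouts.
#' Longer gaps, and gaps at a sequence boundary (no valid flank on one side),
#' are left invalid. Valid input samples are never modified.
#'
#' @param traj A [trajectory_set()].
#' @param max_gap Longest gap (frames) that will be filled; default 4, i.e.
#'   gaps strictly shorter than 5 frames.
#' @return A [trajectory_set()] with filled samples marked valid and a
#'   `fill_log` attribute (data frame: marker, start, end, filled).
#' @export
fill_gaps <- function(traj, max_gap = 4L) {
  stopifnot(max_gap >= 0L)
  nf <- n_frames(traj)
  log <- list()
  pos <- traj$positions
  val <- traj$valid
  for (m in marker_names(traj)) {
    v <- val[, m]
    if (all(v) || !any(v)) next
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in seq_along(r$values)) {
      if (r$values[j]) next
      gs <- starts[j]; ge <- ends[j]
      glen <- ge - gs + 1L
      if (glen > max_gap) {
        log[[length(log) + 1L]] <- data.frame(
          marker = m, start = gs, end = ge, filled = FALSE,
          reason = "gap longer than max_gap")
        next
      }
      left <- which(v[seq_len(gs - 1L)])
      right <- which(v) ; right <- right[right > ge]
      if (length(left) == 0L || length(right) == 0L) {
        log[[length(log) + 1L]] <- data.frame(
          marker = m, start = gs, end = ge, filled = FALSE,
          reason = "gap at sequence boundary")
        next
      }
      sup <- c(utils::tail(left, 3L), utils::head(right, 3L))
      for (d in 1:3) {
        pos[gs:ge, d, m] <- quintic_interp(sup, pos[sup, d, m], gs:ge)
      }
      val[gs:ge, m] <- TRUE
      log[[length(log) + 1L]] <- data.frame(
        marker = m, start = gs, end = ge, filled = TRUE, reason = "")
    }
  }
  out <- trajectory_set(pos, traj$rate, val, traj$up_axis)
  attr(out, "fill_log") <- if (length(log)) do.call(rbind, log) else
    data.frame(marker = character(), start = integer(), end = integer(),
               filled = logical(), reason = character())
  out
}

# Exact polynomial interpolation of degree length(xs) - 1 (<= 5) through
# support points (xs, ys), evaluated at xout. Centered/scaled for conditioning.
quintic_interp <- function(xs, ys, xout) {
  n <- length(xs)
  x0 <- mean(xs)
  sc <- max(xs) - min(xs)
  if (sc == 0) return(rep(ys[1L], length(xout)))
  t <- (xs - x0) / sc
  V <- outer(t, 0:(n - 1L), `^`)
  coef <- solve(V, ys)
  to <- (xout - x0) / sc
  drop(outer(to, 0:(n - 1L), `^`) %*% coef)
}
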