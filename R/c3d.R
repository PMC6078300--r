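# Minimal C3D (binary motion-capture interchange) reader and writer.
#
# Supported subset: Intel (processor type 84) files, 3D point data in
# floating-point or scaled-integer representation, POINT group parameters
# USED, FRAMES, RATE, SCALE, LABELS, UNITS, DATA_START. This covers the
# point-trajectory payload this package consumes; analog channels are skipped
# on read and never written. Files written here are read back by any
# conforming C3D implementation.

C3D_PROC_INTEL <- 84L

#' Read marker trajectories from a C3D file
#'
#' Point coordinates are converted to mm using the file's POINT:UNITS
#' metadata ("m" or "mm"). Samples whose residual word is negative (the C3D
#' convention for invalid/ungenerated points) are flagged as gaps.
#'
#' @param path C3D file path.
#' @param name_map Optional named character vector renaming file marker
#'   labels to the names wanted downstream (`c(new = "FILE_LABEL")`). Every
#'   mapped label must be present in the file.
#' @param up_axis Up axis label, see [trajectory_set()].
#' @return A [trajectory_set()] in mm at the file's native rate.
#' @export
read_c3d <- function(path, name_map = NULL, up_axis = "z") {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  raw_head <- readBin(con, "raw", 512L)
  if (length(raw_head) < 512L) stop_format("truncated C3D header")
  if (as.integer(raw_head[2L]) != 0x50L) {
    stop_format("not a C3D file (magic byte 0x50 missing)")
  }
  param_block <- as.integer(raw_head[1L])

  # parameter section: first 4 bytes, then key-length-value records
  seek(con, (param_block - 1L) * 512L)
  phead <- readBin(con, "raw", 4L)
  proc <- as.integer(phead[4L])
  if (proc != C3D_PROC_INTEL) {
    stop_format(sprintf("unsupported C3D processor type %d (only Intel/84)", proc))
  }
  n_param_blocks <- as.integer(phead[3L])
  praw <- readBin(con, "raw", n_param_blocks * 512L)
  params <- parse_c3d_params(praw)

  getp <- function(name, default = NULL) {
    key <- paste0("POINT:", name)
    if (!is.null(params[[key]])) params[[key]] else default
  }
  n_points <- as.integer(getp("USED"))
  n_frames_p <- as.integer(getp("FRAMES"))
  rate <- as.numeric(getp("RATE"))
  scale <- as.numeric(getp("SCALE"))
  data_start <- as.integer(getp("DATA_START"))
  labels <- getp("LABELS")
  units <- getp("UNITS", "mm")
  if (is.null(n_points) || is.null(rate) || is.null(scale) ||
      is.null(data_start)) {
    stop_format("C3D file lacks required POINT parameters")
  }
  # header words 4/5 carry first/last frame; prefer POINT:FRAMES when present
  first_frame <- readBin(raw_head[7:8], "integer", 1L, 2L, endian = "little")
  last_frame <- readBin(raw_head[9:10], "integer", 1L, 2L, endian = "little")
  n_frames <- if (!is.null(n_frames_p)) n_frames_p else
    last_frame - first_frame + 1L
  labels <- trimws(labels)
  if (length(labels) < n_points) {
    labels <- c(labels, sprintf("M%03d", seq_len(n_points - length(labels))))
  }
  labels <- labels[seq_len(n_points)]

  seek(con, (data_start - 1L) * 512L)
  float_fmt <- scale < 0
  vals_per_frame <- n_points * 4L
  arr <- array(NA_real_, c(n_frames, 3L, n_points),
               dimnames = list(NULL, c("x", "y", "z"), labels))
  resid <- matrix(0, n_frames, n_points)
  if (float_fmt) {
    d <- readBin(con, "numeric", n_frames * vals_per_frame, size = 4L,
                 endian = "little")
  } else {
    d <- readBin(con, "integer", n_frames * vals_per_frame, size = 2L,
                 signed = TRUE, endian = "little") * abs(scale)
  }
  if (length(d) < n_frames * vals_per_frame) {
    stop_format("truncated C3D data section")
  }
  dm <- matrix(d, nrow = 4L)  # rows: x, y, z, residual; frames*points columns
  xyz <- array(dm[1:3, ], c(3L, n_points, n_frames))
  rs <- matrix(dm[4L, ], n_points, n_frames)
  if (!float_fmt) rs <- rs / abs(scale)  # residual word was not scaled
  for (p in seq_len(n_points)) {
    arr[, , p] <- t(xyz[, p, ])
    resid[, p] <- rs[p, ]
  }
  unit_scale <- switch(tolower(units[1L]), m = 1000, mm = 1, cm = 10,
                       stop_format(sprintf("unsupported POINT:UNITS '%s'", units[1L])))
  arr <- arr * unit_scale
  valid <- resid >= 0 & apply(is.finite(arr), c(1L, 3L), all)
  arr[!is.finite(arr)] <- NA_real_
  for (p in seq_len(n_points)) arr[!valid[, p], , p] <- NA_real_

  if (!is.null(name_map)) {
    missing <- setdiff(unname(name_map), labels)
    if (length(missing)) {
      stop_marker(sprintf("marker(s) required by name_map not in C3D file: %s",
                          paste(missing, collapse = ", ")))
    }
    idx <- match(name_map, labels)
    arr <- arr[, , idx, drop = FALSE]
    valid <- valid[, idx, drop = FALSE]
    dimnames(arr)[[3L]] <- names(name_map)
  }
  trajectory_set(arr, rate, valid, up_axis)
}

# Parse the C3D parameter section into a named list "GROUP:PARAM" -> value.
parse_c3d_params <- function(praw) {
  groups <- character()  # id -> name
  out <- list()
  i <- 1L
  n <- length(praw)
  i8 <- function(b) { x <- as.integer(b); if (x > 127L) x - 256L else x }
  while (i + 1L <= n) {
    name_len <- i8(praw[i])
    id <- i8(praw[i + 1L])
    if (id == 0L || name_len == 0L) break
    locked <- name_len < 0L
    name_len <- abs(name_len)
    nm <- rawToChar(praw[(i + 2L):(i + 1L + name_len)])
    j <- i + 2L + name_len
    offset <- readBin(praw[j:(j + 1L)], "integer", 1L, 2L, endian = "little")
    if (id < 0L) {  # group record
      groups[as.character(-id)] <- nm
    } else {        # parameter record
      k <- j + 2L
      type <- i8(praw[k])
      ndim <- as.integer(praw[k + 1L])
      dims <- if (ndim > 0L) as.integer(praw[(k + 2L):(k + 1L + ndim)]) else integer()
      dstart <- k + 2L + ndim
      count <- if (length(dims)) prod(dims) else 1L
      val <- switch(as.character(type),
        `-1` = {  # character
          chars <- rawToChar(praw[dstart:(dstart + count - 1L)])
          if (length(dims) >= 2L) {
            w <- dims[1L]
            substring(chars, seq(1L, count, w), seq(w, count, w))
          } else chars
        },
        `1` = as.integer(praw[dstart:(dstart + count - 1L)]),
        `2` = readBin(praw[dstart:(dstart + 2L * count - 1L)], "integer",
                      count, 2L, endian = "little"),
        `4` = readBin(praw[dstart:(dstart + 4L * count - 1L)], "numeric",
                      count, 4L, endian = "little"),
        NULL)
      gname <- groups[as.character(id)]
      key <- paste0(if (is.na(gname)) paste0("G", id) else gname, ":", nm)
      out[[key]] <- val
    }
    if (offset == 0L) break
    i <- j + offset
  }
  # group records may appear after their parameters; re-key unresolved ones
  if (any(grepl("^G[0-9]+:", names(out)))) {
    for (key in grep("^G[0-9]+:", names(out), value = TRUE)) {
      id <- sub("^G([0-9]+):.*$", "\\1", key)
      if (!is.na(groups[id])) {
        newkey <- sub("^G[0-9]+:", paste0(groups[id], ":"), key)
        out[[newkey]] <- out[[key]]
        out[[key]] <- NULL
      }
    }
  }
  out
}

#' Write marker trajectories to a C3D file
#'
#' Writes an Intel-format C3D file with floating-point 3D point data, units
#' metadata, and marker labels. Invalid samples are written with a negative
#' residual word (the C3D gap convention) and zero coordinates.
#'
#' @param traj A [trajectory_set()].
#' @param path Output file path.
#' @param units `"mm"` (default) or `"m"`; positions are converted on write.
#' @return `path`, invisibly.
#' @export
write_c3d <- function(traj, path, units = "mm") {
  units <- match.arg(units, c("mm", "m"))
  scale <- if (units == "m") 1 / 1000 else 1
  nm <- marker_names(traj)
  np <- length(nm)
  nf <- n_frames(traj)

  lab_w <- max(4L, max(nchar(nm)))
  labels_padded <- formatC(nm, width = lab_w, flag = "-")

  # ---- parameter section ----
  p <- raw_buffer()
  put <- function(b) p$add(b)
  wi8 <- function(x) put(as.raw(bitwAnd(as.integer(x), 0xFFL)))
  wi16 <- function(x) put(writeBin(as.integer(x), raw(), 2L, endian = "little"))
  wf32 <- function(x) put(writeBin(as.numeric(x), raw(), 4L, endian = "little"))
  wchr <- function(s) put(charToRaw(s))

  group_rec <- function(name, desc = "") {
    wi8(nchar(name)); wi8(256L - 1L)  # id -1 as signed byte
    wchr(name)
    wi16(2L + nchar(desc) + 1L)       # offset to next record
    wi8(nchar(desc)); if (nchar(desc)) wchr(desc)
  }
  param_rec <- function(name, type, dims, payload_writer, payload_bytes) {
    wi8(nchar(name)); wi8(1L)  # group id +1 (POINT)
    wchr(name)
    wi16(2L + 1L + 1L + length(dims) + payload_bytes + 1L)
    wi8(if (type < 0) 256L + type else type)
    wi8(length(dims))
    for (d in dims) wi8(d)
    payload_writer()
    wi8(0L)  # description length 0
  }

  group_rec("POINT")
  param_rec("USED", 2L, integer(), function() wi16(np), 2L)
  param_rec("FRAMES", 2L, integer(), function() wi16(nf), 2L)
  param_rec("DATA_START", 2L, integer(), function() wi16(0L), 2L)  # patched below
  ds_patch_at <- p$length() - 2L  # position of the 2-byte DATA_START payload
  param_rec("SCALE", 4L, integer(), function() wf32(-1), 4L)
  param_rec("RATE", 4L, integer(), function() wf32(traj$rate), 4L)
  param_rec("UNITS", -1L, c(nchar(units)), function() wchr(units), nchar(units))
  param_rec("LABELS", -1L, c(lab_w, np),
            function() wchr(paste(labels_padded, collapse = "")), lab_w * np)
  # terminator record: zero name length, zero id
  wi8(0L); wi8(0L)

  pbytes <- p$get()
  n_param_blocks <- as.integer(ceiling((4L + length(pbytes)) / 512L))
  data_start_block <- 2L + n_param_blocks  # header block + param blocks, 1-based
  # patch DATA_START payload
  pbytes[(ds_patch_at):(ds_patch_at + 1L)] <-
    writeBin(data_start_block, raw(), 2L, endian = "little")

  # ---- header block ----
  h <- raw_buffer()
  h$add(as.raw(c(2L, 0x50L)))                                   # param block, magic
  h$add(writeBin(np, raw(), 2L, endian = "little"))             # points used
  h$add(writeBin(0L, raw(), 2L, endian = "little"))             # analog/frame
  h$add(writeBin(1L, raw(), 2L, endian = "little"))             # first frame
  h$add(writeBin(nf, raw(), 2L, endian = "little"))             # last frame
  h$add(writeBin(as.integer(4L), raw(), 2L, endian = "little")) # max gap
  h$add(writeBin(-1, raw(), 4L, endian = "little"))             # 3D scale (float)
  h$add(writeBin(data_start_block, raw(), 2L, endian = "little"))
  h$add(writeBin(0L, raw(), 2L, endian = "little"))             # analog samples
  h$add(writeBin(as.numeric(traj$rate), raw(), 4L, endian = "little"))
  hb <- h$get()
  hb <- c(hb, raw(512L - length(hb)))

  pb <- c(as.raw(c(1L, 0x50L)), as.raw(n_param_blocks), as.raw(C3D_PROC_INTEL),
          pbytes)
  pb <- c(pb, raw(n_param_blocks * 512L - length(pb)))  # pad to block size

  # ---- data section ----
  dat <- numeric(nf * np * 4L)
  k <- 1L
  for (i in seq_len(nf)) {
    for (m in nm) {
      if (traj$valid[i, m]) {
        dat[k:(k + 2L)] <- traj$positions[i, , m] * scale
        dat[k + 3L] <- 0
      } else {
        dat[k:(k + 2L)] <- 0
        dat[k + 3L] <- -1
      }
      k <- k + 4L
    }
  }
  db <- writeBin(dat, raw(), 4L, endian = "little")

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(hb, con)
  writeBin(pb, con)
  writeBin(db, con)
  invisible(path)
}

# Growable raw buffer (chunked append to avoid quadratic copying).
raw_buffer <- function() {
  chunks <- list()
  list(
    add = function(b) chunks[[length(chunks) + 1L]] <<- b,
    get = function() do.call(c, chunks),
    length = function() sum(vapply(chunks, length, integer(1)))
  )
}
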