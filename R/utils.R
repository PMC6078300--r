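# Small 3-vector and rotation helpers shared across modules.

DEG <- 180 / pi

deg2rad <- function(x) x / DEG
rad2deg <- function(x) x * DEG

#' @noRd
cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

norm3 <- function(a) sqrt(sum(a * a))

#' Normalize a 3-vector, failing loudly on (near-)zero input.
#' `scale` carries the magnitude of the operands so the degeneracy test is
#' relative, not absolute.
#' @noRd
unit3 <- function(a, scale = 1, what = "vector") {
  n <- norm3(a)
  if (!is.finite(n) || n < 1e-9 * max(scale, .Machine$double.xmin)) {
    stop_degenerate(sprintf("degenerate geometry: %s has (near-)zero length", what))
  }
  a / n
}

clamp1 <- function(x) pmin(1, pmax(-1, x))

#' Wrap an angle in degrees to (-180, 180].
#' @noRd
wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

stop_degenerate <- function(msg) {
  stop(errorCondition(msg, class = c("hindkin_degenerate_error", "hindkin_error")))
}

stop_format <- function(msg) {
  stop(errorCondition(msg, class = c("hindkin_format_error", "hindkin_error")))
}

stop_marker <- function(msg) {
  stop(errorCondition(msg, class = c("hindkin_marker_error", "hindkin_error")))
}

stop_gimbal <- function(msg) {
  stop(errorCondition(msg, class = c("hindkin_gimbal_error", "hindkin_error")))
}

#' Elementary active rotation matrices (column-vector convention, degrees).
#' @noRd
rot_x <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(1, 0, 0,
           0, cos(a), sin(a),
           0, -sin(a), cos(a)), 3, 3)
}

#' @noRd
rot_y <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(cos(a), 0, -sin(a),
           0, 1, 0,
           sin(a), 0, cos(a)), 3, 3)
}

#' @noRd
rot_z <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(cos(a), sin(a), 0,
           -sin(a), cos(a), 0,
           0, 0, 1), 3, 3)
}

match_side <- function(side) {
  match.arg(tolower(side), c("right", "left"))
}
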