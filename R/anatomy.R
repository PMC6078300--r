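# Anatomical segment coordinate systems for the quadruped hind limb.
#
# Each segment frame is a right-handed orthonormal basis anchored at a bony
# landmark. The mediolateral z axes of all segments share one sense (toward
# the animal's right), which is what makes left/right signed joint angles
# comparable after the per-side sign map applied in the JCS module.

#' Construct a segment coordinate frame
#'
#' A `segment_frame` is an origin plus a right-handed orthonormal basis
#' (`x_axis`, `y_axis`, `z_axis`), all expressed in lab coordinates (mm).
#' Orthonormality and right-handedness are enforced at construction to 1e-9.
#'
#' @param origin Numeric 3-vector, mm.
#' @param x_axis,y_axis,z_axis Numeric unit 3-vectors.
#' @return An object of class `segment_frame`.
#' @export
segment_frame <- function(origin, x_axis, y_axis, z_axis) {
  B <- cbind(x_axis, y_axis, z_axis)
  stopifnot(length(origin) == 3L, all(dim(B) == c(3L, 3L)), all(is.finite(B)))
  if (max(abs(crossprod(B) - diag(3))) > 1e-9) {
    stop_degenerate("segment frame basis is not orthonormal to 1e-9")
  }
  if (abs(det(B) - 1) > 1e-9) {
    stop_degenerate("segment frame basis is not right-handed (det != +1)")
  }
  structure(list(origin = as.numeric(origin),
                 x_axis = as.numeric(x_axis),
                 y_axis = as.numeric(y_axis),
                 z_axis = as.numeric(z_axis)),
            class = "segment_frame")
}

#' @export
print.segment_frame <- function(x, ...) {
  cat("<segment_frame>\n")
  cat("  origin:", sprintf("%.3f", x$origin), "\n")
  for (ax in c("x_axis", "y_axis", "z_axis")) {
    cat(" ", ax, ":", sprintf("%+.6f", x[[ax]]), "\n")
  }
  invisible(x)
}

#' Basis matrix of a segment frame (axes as columns, lab coordinates)
#' @param frame A `segment_frame`.
#' @return 3x3 rotation matrix with columns x̂, ŷ, ẑ.
#' @export
frame_basis <- function(frame) {
  cbind(frame$x_axis, frame$y_axis, frame$z_axis, deparse.level = 0)
}

# Guarded cross product: errors if operands are (near-)parallel.
guarded_cross <- function(a, b, what) {
  v <- cross3(a, b)
  unit3(v, scale = norm3(a) * norm3(b), what = what)
}

#' Pelvis anatomical coordinate system
#'
#' Origin at the right iliac crest. ẑ points from the left to the right iliac
#' crest (mediolateral, toward the animal's right); x̂ is the normalized cross
#' product of the iliac-crest-to-ischial-tuberosity vector with ẑ; ŷ = ẑ x x̂.
#' One pelvis frame serves both hips.
#'
#' @param ric,lic,rit Positions (mm) of the right iliac crest, left iliac
#'   crest, and right ischial tuberosity.
#' @return A [segment_frame()].
#' @export
build_pelvis_cs <- function(ric, lic, rit) {
  z <- unit3(ric - lic, scale = max(norm3(ric), norm3(lic), 1),
             what = "iliac crest axis (RIC - LIC)")
  x <- guarded_cross(ric - rit, z, "pelvis x axis ((RIC - RIT) x z)")
  y <- cross3(z, x)
  segment_frame(ric, x, y, z)
}

#' Femur anatomical coordinate system
#'
#' Origin at the greater trochanter. ŷ points from the predicted lateral
#' stifle virtual marker to the greater trochanter (distal to proximal).
#' Because skin motion precludes reliable femoral condyle markers, the
#' mediolateral direction is borrowed from the tibia: x̂ is the cross product
#' of the malleolus axis (medial minus lateral for the right limb, lateral
#' minus medial for the left) with ŷ, and ẑ = x̂ x ŷ. This couples the femoral
#' and tibial frames; see the methods vignette for consequences.
#'
#' @param side `"right"` or `"left"`.
#' @param gt Greater trochanter position (mm).
#' @param stifle Lateral stifle virtual marker position (mm).
#' @param mm,lm Medial and lateral malleolus positions (mm).
#' @return A [segment_frame()].
#' @export
build_femur_cs <- function(side, gt, stifle, mm, lm) {
  side <- match_side(side)
  y <- unit3(gt - stifle, scale = max(norm3(gt), norm3(stifle), 1),
             what = "femur long axis (GT - stifle)")
  mal <- if (side == "right") mm - lm else lm - mm
  if (norm3(mal) < 1e-9) {
    stop_degenerate("degenerate geometry: malleolus markers coincide")
  }
  x <- guarded_cross(mal, y, "femur x axis (malleolus axis x y)")
  z <- cross3(x, y)
  segment_frame(gt, x, y, z)
}

#' Tibia anatomical coordinate system (two variants)
#'
#' Origin at the lateral malleolus. ẑ is the malleolus axis (lateral minus
#' medial for the right limb, medial minus lateral for the left). x̂ is the
#' cross product of the vector from the lateral malleolus to a proximal
#' reference point with ẑ, and ŷ = ẑ x x̂. Variant 1 ("unadjusted tibia
#' axis") takes the reference from the fibular vector marker; variant 2
#' ("adjusted tibia axis") takes it from the predicted lateral stifle virtual
#' marker. Pass the corresponding point as `ref`.
#'
#' @param side `"right"` or `"left"`.
#' @param variant Integer 1 or 2; recorded on the returned frame.
#' @param lm,mm Lateral and medial malleolus positions (mm).
#' @param ref Proximal reference point: vector marker (variant 1) or
#'   predicted stifle (variant 2).
#' @return A [segment_frame()] with attribute `variant`.
#' @export
build_tibia_cs <- function(side, variant, lm, mm, ref) {
  side <- match_side(side)
  variant <- as.integer(variant)
  stopifnot(variant %in% c(1L, 2L))
  z <- unit3(if (side == "right") lm - mm else mm - lm,
             scale = max(norm3(lm), norm3(mm), 1), what = "malleolus axis")
  x <- guarded_cross(ref - lm, z, "tibia x axis ((ref - LM) x z)")
  y <- cross3(z, x)
  fr <- segment_frame(lm, x, y, z)
  attr(fr, "variant") <- variant
  fr
}

#' Tarsus anatomical coordinate system
#'
#' Origin at the calcaneus. ẑ is the metatarsal axis (5th minus 2nd for the
#' right limb, 2nd minus 5th for the left); x̂ is the cross product of the
#' vector from the 5th metatarsal to the calcaneus with ẑ; ŷ = ẑ x x̂.
#'
#' @param side `"right"` or `"left"`.
#' @param c_pos Calcaneus position (mm).
#' @param mt5,mt2 5th and 2nd metatarsal positions (mm).
#' @return A [segment_frame()].
#' @export
build_tarsus_cs <- function(side, c_pos, mt5, mt2) {
  side <- match_side(side)
  z <- unit3(if (side == "right") mt5 - mt2 else mt2 - mt5,
             scale = max(norm3(mt5), norm3(mt2), 1), what = "metatarsal axis")
  x <- guarded_cross(c_pos - mt5, z, "tarsus x axis ((C - 5MT) x z)")
  y <- cross3(z, x)
  segment_frame(c_pos, x, y, z)
}

#' Hind limb definition
#'
#' Bundles the per-subject inputs the model needs: the limb side, the palpated
#' femur length (greater trochanter to distal femoral condyle) and fibula
#' length (lateral malleolus to fibular head) in mm, and a map from the
#' model's logical marker names to the trajectory's marker names.
#'
#' Logical names follow the standard abbreviations: IC, IT (iliac crest,
#' ischial tuberosity — both sides needed for the pelvis), GT, LM, MM, V
#' (fibular vector marker), C, MT5, MT2, all side-prefixed R/L in the
#' trajectory by default.
#'
#' @param side `"right"` or `"left"`.
#' @param femur_length,fibula_length Segment lengths, mm, > 0.
#' @param marker_map Named character vector mapping logical names
#'   (`ric`, `lic`, `rit`, `gt`, `lm`, `mm`, `v`, `c`, `mt5`, `mt2`) to the
#'   marker names present in the trajectory. Defaults to the conventional
#'   side-prefixed names (e.g. `gt` -> `"RGT"` for the right side).
#' @return An object of class `limb_definition`.
#' @export
limb_definition <- function(side, femur_length, fibula_length,
                            marker_map = NULL) {
  side <- match_side(side)
  if (!is.numeric(femur_length) || femur_length <= 0 ||
      !is.numeric(fibula_length) || fibula_length <= 0) {
    stop("femur_length and fibula_length must be positive (mm)")
  }
  p <- if (side == "right") "R" else "L"
  default_map <- c(
    ric = "RIC", lic = "LIC", rit = "RIT",
    gt = paste0(p, "GT"), lm = paste0(p, "LM"), mm = paste0(p, "MM"),
    v = paste0(p, "V"), c = paste0(p, "C"),
    mt5 = paste0(p, "5MT"), mt2 = paste0(p, "2MT"),
    stifle = paste0(p, "S")
  )
  if (!is.null(marker_map)) {
    bad <- setdiff(names(marker_map), names(default_map))
    if (length(bad)) stop("unknown logical marker name(s): ",
                          paste(bad, collapse = ", "))
    default_map[names(marker_map)] <- marker_map
  }
  structure(list(side = side,
                 femur_length = as.numeric(femur_length),
                 fibula_length = as.numeric(fibula_length),
                 marker_map = default_map),
            class = "limb_definition")
}

#' @export
print.limb_definition <- function(x, ...) {
  cat(sprintf("<limb_definition> %s limb, femur %.1f mm, fibula %.1f mm\n",
              x$side, x$femur_length, x$fibula_length))
  invisible(x)
}
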