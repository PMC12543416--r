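#' Construct bounding boxes
#'
#' A bounding box is parameterized by its midpoint `(x, y)` and its extent
#' `(w, h)`, in image pixels with the origin at the top-left corner and the
#' y axis increasing downward. All arguments are recycled to a common length,
#' so a single call can build one box per frame.
#'
#' @param x,y midpoint coordinates (pixels).
#' @param w,h width and height (pixels), strictly positive.
#' @return a `data.frame` with columns `x`, `y`, `w`, `h`.
#' @examples
#' bbox(5, 5, 4, 4)
#' @export
bbox <- function(x, y, w, h) {
  n <- max(length(x), length(y), length(w), length(h))
  out <- data.frame(x = rep_len(as.numeric(x), n), y = rep_len(as.numeric(y), n),
                    w = rep_len(as.numeric(w), n), h = rep_len(as.numeric(h), n))
  if (!all(is.finite(out$x)) || !all(is.finite(out$y)))
    ct_stop("bounding-box midpoints must be finite")
  if (!all(is.finite(out$w) & out$w > 0) || !all(is.finite(out$h) & out$h > 0))
    ct_stop("bounding-box width and height must be finite and > 0")
  out
}

#' Construct 2D view points
#'
#' A detection midpoint in one camera view. `view` records which camera the
#' coordinates belong to, so that downstream fusion can refuse to mix views.
#'
#' @param x,y pixel coordinates.
#' @param view `"front"` or `"side"`.
#' @return a `data.frame` with columns `x`, `y`, `view`.
#' @export
view_point <- function(x, y, view = c("front", "side")) {
  view <- match.arg(view)
  n <- max(length(x), length(y))
  data.frame(x = rep_len(as.numeric(x), n), y = rep_len(as.numeric(y), n),
             view = view)
}

#' Midpoint-in-box containment predicate
#'
#' Tests whether a detection midpoint lies strictly inside a bounding box:
#' `box$x - w/2 < px < box$x + w/2` and `box$y - h/2 < py < box$y + h/2`.
#' Boundary points are outside (strict inequalities). Vectorized over points
#' and boxes (recycled).
#'
#' @param px,py point coordinates (pixels), or a `view_point()` data frame as
#'   `px` with `py` missing.
#' @param box a [bbox()] data frame.
#' @return logical vector.
#' @examples
#' point_in_box(5, 5, bbox(5, 5, 4, 4))   # TRUE: at box center
#' point_in_box(7, 5, bbox(5, 5, 4, 4))   # FALSE: on the boundary
#' @export
point_in_box <- function(px, py = NULL, box) {
  if (is.data.frame(px) && is.null(py)) {
    py <- px$y; px <- px$x
  }
  px <- as.numeric(px); py <- as.numeric(py)
  if (!all(is.finite(px)) || !all(is.finite(py)))
    ct_stop("point coordinates must be finite")
  stopifnot(is.data.frame(box))
  (px > box$x - 0.5 * box$w) & (px < box$x + 0.5 * box$w) &
    (py > box$y - 0.5 * box$h) & (py < box$y + 0.5 * box$h)
}

# Vectorized containment that propagates NA points (absent detections)
# instead of erroring; internal to frame classification.
pib_na <- function(px, py, bx, by, bw, bh) {
  (px > bx - 0.5 * bw) & (px < bx + 0.5 * bw) &
    (py > by - 0.5 * bh) & (py < by + 0.5 * bh)
}

#' Dual-view region containment
#'
#' The rodent counts as inside a region only when its midpoint lies inside
#' the region's bounding box in the front view *and* in the side view
#' (`q = q_front & q_side`).
#'
#' @param rodent_front,rodent_side [view_point()] rows for the rodent
#'   midpoint in each view.
#' @param region_front,region_side [bbox()] rows for the region in each view.
#' @return logical vector.
#' @export
in_region_both_views <- function(rodent_front, rodent_side,
                                 region_front, region_side) {
  if (!all(rodent_front$view == "front") || !all(rodent_side$view == "side"))
    ct_stop("rodent_front must have view 'front' and rodent_side view 'side'")
  point_in_box(rodent_front$x, rodent_front$y, region_front) &
    point_in_box(rodent_side$x, rodent_side$y, region_side)
}

#' Fuse front and side view points into a 3D position
#'
#' The front camera contributes the cage-width axis, the side camera the
#' cage-depth axis, and both contribute the height axis:
#' `P = (F_x, S_x, (F_y + S_y)/2)`. The fused `z` inherits the image y
#' convention (larger z = lower in the cage).
#'
#' @param front,side [view_point()] data frames of equal length.
#' @param units unit label attached to the result (`"px"` by default).
#' @return a `data.frame` with columns `x`, `y`, `z` and a `"units"`
#'   attribute.
#' @examples
#' fuse_views(view_point(100, 180, "front"), view_point(250, 220, "side"))
#' @export
fuse_views <- function(front, side, units = "px") {
  if (!all(front$view == "front") || !all(side$view == "side"))
    ct_stop("fuse_views() requires a front-view and a side-view point")
  if (nrow(front) != nrow(side))
    ct_stop("front and side point sets must have equal length")
  out <- data.frame(x = front$x, y = side$x, z = 0.5 * (front$y + side$y))
  attr(out, "units") <- units
  out
}

#' Construct fused 3D positions
#'
#' Builds a position data frame directly (rather than via [fuse_views()]),
#' e.g. for trajectories from other sources. Coordinates follow the fused
#' convention: x = cage width, y = cage depth, z = height (image-downward).
#'
#' @param x,y,z coordinates (recycled to a common length).
#' @param units unit label (`"px"` or `"mm"`).
#' @return a `data.frame` with columns `x`, `y`, `z` and a units attribute.
#' @export
position3d <- function(x, y, z, units = "px") {
  out <- data.frame(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z))
  attr(out, "units") <- units
  out
}

units_of <- function(p) attr(p, "units") %||% "px"
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Distance moved between two positions
#'
#' `euclidean` (default) returns `sqrt(dx^2 + dy^2 + dz^2)`; `paper_literal`
#' returns the plain sum of squared per-axis displacements (no square root),
#' reproducing the printed per-frame displacement formula bit-for-bit.
#' Vectorized over rows.
#'
#' @param p_prev,p_curr position data frames (columns `x`, `y`, `z`) with
#'   matching units.
#' @param mode `"euclidean"` or `"paper_literal"`.
#' @return numeric vector of non-negative step distances.
#' @examples
#' step_distance(position3d(0, 0, 0), position3d(3, 4, 0))       # 5
#' step_distance(position3d(0, 0, 0), position3d(1, 2, 2),
#'               mode = "paper_literal")                          # 9
#' @export
step_distance <- function(p_prev, p_curr, mode = c("euclidean", "paper_literal")) {
  mode <- match.arg(mode)
  if (!identical(units_of(p_prev), units_of(p_curr)))
    ct_stop("positions have mismatched units")
  d2 <- (p_curr$x - p_prev$x)^2 + (p_curr$y - p_prev$y)^2 + (p_curr$z - p_prev$z)^2
  if (mode == "euclidean") sqrt(d2) else d2
}

#' Total path length of a trajectory
#'
#' Sums [step_distance()] over consecutive frame pairs. A single-point
#' trajectory has length 0.
#'
#' @param trajectory a position data frame (columns `x`, `y`, `z`), one row
#'   per frame, in order.
#' @inheritParams step_distance
#' @return non-negative scalar.
#' @export
path_distance <- function(trajectory, mode = c("euclidean", "paper_literal")) {
  mode <- match.arg(mode)
  n <- nrow(trajectory)
  if (is.null(n) || n < 1) ct_stop("trajectory must contain at least one position")
  if (n == 1) return(0)
  prev <- trajectory[-n, , drop = FALSE]
  curr <- trajectory[-1, , drop = FALSE]
  attr(prev, "units") <- attr(curr, "units") <- units_of(trajectory)
  sum(step_distance(prev, curr, mode))
}

#' Pixel-to-millimeter calibration
#'
#' A per-axis linear scale mapping fused pixel coordinates to cage
#' millimeters. The fused x axis comes from the front view, y from the side
#' view, z from both views' vertical axes.
#'
#' @param scale_x,scale_y,scale_z millimeters per pixel on each fused axis
#'   (> 0). The default identity calibration leaves coordinates in pixels.
#' @param cage_dims optional cage (width, depth, height) in mm, retained for
#'   reference.
#' @return an object of class `"calibration"`.
#' @seealso [calibration_from_extent()]
#' @export
calibration <- function(scale_x = 1, scale_y = 1, scale_z = 1, cage_dims = NULL) {
  s <- c(scale_x, scale_y, scale_z)
  if (!all(is.finite(s) & s > 0)) ct_config_error("calibration scales must be > 0")
  structure(list(scale_x = scale_x, scale_y = scale_y, scale_z = scale_z,
                 cage_dims = cage_dims), class = "calibration")
}

#' Calibration from known cage dimensions and pixel extents
#'
#' Computes mm/px scales from the physical cage size and the cage's pixel
#' extent in each view: the front view fixes the width and height scales,
#' the side view the depth scale; the height scale averages both views.
#'
#' @param cage_dims_mm numeric (width, depth, height) of the cage in mm.
#' @param front_extent_px (width, height) of the cage in front-view pixels.
#' @param side_extent_px (depth, height) of the cage in side-view pixels.
#' @return a [calibration()] object.
#' @export
calibration_from_extent <- function(cage_dims_mm, front_extent_px, side_extent_px) {
  if (length(cage_dims_mm) != 3 || any(cage_dims_mm <= 0))
    ct_config_error("cage_dims_mm must be 3 positive values (width, depth, height)")
  calibration(scale_x = cage_dims_mm[1] / front_extent_px[1],
              scale_y = cage_dims_mm[2] / side_extent_px[1],
              scale_z = cage_dims_mm[3] / mean(c(front_extent_px[2], side_extent_px[2])),
              cage_dims = cage_dims_mm)
}

#' Apply a calibration to fused positions
#'
#' @param positions a position data frame in pixels.
#' @param cal a [calibration()] object.
#' @return positions in millimeters (units attribute `"mm"`).
#' @export
apply_calibration <- function(positions, cal) {
  stopifnot(inherits(cal, "calibration"))
  out <- data.frame(x = positions$x * cal$scale_x,
                    y = positions$y * cal$scale_y,
                    z = positions$z * cal$scale_z)
  attr(out, "units") <- "mm"
  out
}
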