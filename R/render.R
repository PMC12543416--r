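# Rendered intensity bands (8-bit): background, house marker, wheel marker,
# mouse blob. The static markers sit in distinct dim bands so a reference
# frame suffices to locate them; the mouse is far brighter than either.
RENDER_LEVELS <- c(background = 8, house = 64, wheel = 96, mouse = 224)

draw_rect <- function(mat, box) {
  # box in pixel midpoint/extent; pixel (x, y) 0-based lives at mat[y+1, x+1]
  H <- nrow(mat); W <- ncol(mat)
  x0 <- max(0, ceiling(box$x - box$w / 2)); x1 <- min(W - 1, floor(box$x + box$w / 2))
  y0 <- max(0, ceiling(box$y - box$h / 2)); y1 <- min(H - 1, floor(box$y + box$h / 2))
  if (x1 >= x0 && y1 >= y0) mat[(y0:y1) + 1, (x0:x1) + 1] <- box$value
  mat
}

#' Render a mouse-free reference frame
#'
#' Dark background with the dim static rectangles marking the house and
#' wheel zone projections, used by [detect_static_regions()].
#'
#' @param scenario a [sim_scenario()].
#' @param view `"front"` or `"side"`.
#' @param size frame (width, height) in pixels; defaults to the scenario's
#'   `render_size`.
#' @return a `height x width` numeric matrix of intensities in \[0, 255\].
#' @export
reference_frame <- function(scenario, view = c("front", "side"), size = NULL) {
  view <- match.arg(view)
  sc <- scenario
  if (is.null(size)) size <- sc$render_size
  mat <- matrix(RENDER_LEVELS[["background"]], nrow = size[2], ncol = size[1])
  axis_h <- if (view == "front") "x" else "y"
  for (lb in c("house", "wheel")) {
    b <- project_zone_box(sc$zones[[lb]], axis_h, sc$scale_mm_per_px)
    b$value <- RENDER_LEVELS[[lb]]
    mat <- draw_rect(mat, b)
  }
  mat
}

draw_ellipse <- function(mat, cx, cy, a, b, value) {
  H <- nrow(mat); W <- ncol(mat)
  x0 <- max(0, floor(cx - a)); x1 <- min(W - 1, ceiling(cx + a))
  y0 <- max(0, floor(cy - b)); y1 <- min(H - 1, ceiling(cy + b))
  clipped <- (cx - a < 0) || (cx + a > W - 1) || (cy - b < 0) || (cy + b > H - 1)
  if (x1 >= x0 && y1 >= y0) {
    xs <- x0:x1; ys <- y0:y1
    inside <- outer(((ys - cy) / b)^2, ((xs - cx) / a)^2, `+`) <= 1
    patch <- mat[ys + 1, xs + 1, drop = FALSE]
    patch[inside] <- value
    mat[ys + 1, xs + 1] <- patch
  }
  attr(mat, "clipped") <- clipped
  mat
}

#' Render grayscale frames of a simulated session
#'
#' Each frame is the view's reference frame plus a bright ellipse at the
#' projected mouse midpoint, with axes set by the scenario's mouse size.
#' Deterministic given the scenario seed (optional Gaussian pixel noise
#' draws from the `render` substream). A mouse projected outside the frame
#' bounds is clipped and flagged via the per-frame `"clipped"` attribute.
#'
#' @param truth a [simulate_session()] result.
#' @param scenario defaults to `truth$scenario`.
#' @param view `"front"` or `"side"`.
#' @param frames frame indices (0-based) to render; default all.
#' @param size frame (width, height) in pixels.
#' @param noise_sd optional Gaussian intensity noise SD.
#' @return a list of intensity matrices (one per requested frame).
#' @export
render_frames <- function(truth, scenario = truth$scenario,
                          view = c("front", "side"), frames = NULL,
                          size = NULL, noise_sd = 0) {
  view <- match.arg(view)
  sc <- scenario
  if (is.null(size)) size <- sc$render_size
  if (any(size <= 0)) ct_config_error("frame size must be positive")
  if (is.null(frames)) frames <- truth$frames$frame_index
  ref <- reference_frame(sc, view, size)
  s <- sc$scale_mm_per_px
  a <- sc$mouse_size_mm[1] / s / 2
  b <- sc$mouse_size_mm[2] / s / 2
  axis_h <- if (view == "front") "x" else "y"
  idx <- match(frames, truth$frames$frame_index)
  if (any(is.na(idx))) ct_stop("requested frame index not in ground truth")
  cx <- truth$frames[[axis_h]][idx] / s
  cy <- truth$frames$z[idx] / s
  out <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    m <- draw_ellipse(ref, cx[k], cy[k], a, b, RENDER_LEVELS[["mouse"]])
    if (noise_sd > 0)
      m <- with_substream(sc$seed, paste0("render_", view, "_", frames[k]), {
        cl <- attr(m, "clipped")
        m2 <- pmin(255, pmax(0, m + rnorm(length(m), 0, noise_sd)))
        attr(m2, "clipped") <- cl
        m2
      })
    out[[k]] <- m
  }
  names(out) <- frames
  out
}

#' Write rendered frames as PNG files
#'
#' @param frames list of intensity matrices from [render_frames()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return the written paths, invisibly.
#' @export
write_frames <- function(frames, dir, prefix = "frame") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, sprintf("%s_%06d.png", prefix,
                                  as.integer(names(frames))))
  for (k in seq_along(frames)) png::writePNG(frames[[k]] / 255, paths[k])
  invisible(paths)
}

#' Read grayscale frames from PNG/TIFF files
#'
#' @param paths image paths.
#' @return list of intensity matrices in \[0, 255\].
#' @export
read_frames <- function(paths) {
  lapply(paths, function(p) {
    img <- if (grepl("\\.tiff?$", p, ignore.case = TRUE)) {
      EBImage::imageData(EBImage::readImage(p))
    } else png::readPNG(p)
    if (length(dim(img)) == 3) img <- img[, , 1]
    if (grepl("\\.tiff?$", p, ignore.case = TRUE)) img <- t(img)
    img * 255
  })
}
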