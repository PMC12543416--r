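#' Blob-detector configuration
#'
#' Settings for the threshold-plus-connected-components detector that
#' stands in for a neural-network object detector on synthetic frames.
#'
#' @param threshold intensity threshold in \[0, 255\], or `"otsu"` to pick it
#'   per frame by Otsu's method.
#' @param min_area smallest connected component (pixels) accepted as the
#'   mouse.
#' @param max_components upper bound on components considered (guards
#'   against pathological frames).
#' @return a list of class `"detector_config"`.
#' @export
detector_config <- function(threshold = "otsu", min_area = 20,
                            max_components = 64) {
  if (!identical(threshold, "otsu") &&
      (!is.numeric(threshold) || threshold < 0 || threshold > 255))
    ct_config_error("threshold must be 'otsu' or an intensity in [0, 255]")
  if (min_area < 1) ct_config_error("min_area must be >= 1")
  structure(list(threshold = threshold, min_area = min_area,
                 max_components = max_components), class = "detector_config")
}

resolve_threshold <- function(frame, config) {
  if (identical(config$threshold, "otsu"))
    EBImage::otsu(EBImage::Image(t(frame) / 255), range = c(0, 1)) * 255
  else config$threshold
}

component_boxes <- function(mask, frame, min_area, max_components) {
  # mask: logical [y, x]; returns boxes for components >= min_area,
  # largest first, with 0-based midpoint pixel coordinates.
  lab <- EBImage::bwlabel(EBImage::Image(t(mask)))
  labm <- EBImage::imageData(lab)          # [x, y]
  areas <- tabulate(labm[labm > 0])
  keep <- which(areas >= min_area)
  if (!length(keep)) return(NULL)
  keep <- keep[order(areas[keep], decreasing = TRUE)]
  keep <- head(keep, max_components)
  lapply(keep, function(k) {
    px <- which(labm == k, arr.ind = TRUE)   # col1 = x index, col2 = y index
    xs <- px[, 1] - 1; ys <- px[, 2] - 1     # 0-based
    list(x = (min(xs) + max(xs)) / 2, y = (min(ys) + max(ys)) / 2,
         w = max(xs) - min(xs) + 1, h = max(ys) - min(ys) + 1,
         area = areas[k],
         mean_intensity = mean(frame[cbind(px[, 2], px[, 1])]))
  })
}

#' Detect the mouse in a grayscale frame
#'
#' Thresholds the frame, labels connected components, discards components
#' smaller than `min_area`, and returns the bounding box of the largest
#' survivor with confidence = mean component intensity / 255. Returns `NULL`
#' when nothing survives (an all-dark frame).
#'
#' @param frame `height x width` intensity matrix in \[0, 255\].
#' @param config a [detector_config()].
#' @return a list (`x`, `y`, `w`, `h`, `confidence`) or `NULL`.
#' @export
detect_mouse <- function(frame, config = detector_config()) {
  if (is.null(dim(frame)) || length(dim(frame)) != 2 || !length(frame))
    ct_stop("frame must be a non-empty 2D intensity matrix")
  thr <- resolve_threshold(frame, config)
  mask <- frame > thr
  if (!any(mask)) return(NULL)
  comps <- component_boxes(mask, frame, config$min_area, config$max_components)
  if (is.null(comps)) return(NULL)
  best <- comps[[1]]
  list(x = best$x, y = best$y, w = best$w, h = best$h,
       confidence = best$mean_intensity / 255)
}

#' Locate the static house and wheel markers in a reference frame
#'
#' The renderer draws the two static regions in distinct dim intensity
#' bands; this reads them back as bounding boxes from a mouse-free
#' reference frame. Deterministic.
#'
#' @param reference a reference intensity matrix (see [reference_frame()]).
#' @param config a [detector_config()] (unused bands are fixed).
#' @return named list of `house` and `wheel` boxes (`x`, `y`, `w`, `h`).
#' @export
detect_static_regions <- function(reference, config = detector_config()) {
  bands <- list(house = c(48, 80), wheel = c(81, 128))
  out <- lapply(names(bands), function(lb) {
    b <- bands[[lb]]
    px <- which(reference >= b[1] & reference <= b[2], arr.ind = TRUE)
    if (!nrow(px))
      ct_config_error(sprintf("static region '%s' not found in reference frame", lb))
    xs <- px[, 2] - 1; ys <- px[, 1] - 1
    list(x = (min(xs) + max(xs)) / 2, y = (min(ys) + max(ys)) / 2,
         w = max(xs) - min(xs) + 1, h = max(ys) - min(ys) + 1)
  })
  names(out) <- names(bands)
  out
}

#' Render and detect a simulated session in chunks
#'
#' Convenience wrapper around [render_frames()] and [detect_session()] that
#' processes the session `chunk_size` frames at a time, so multi-minute
#' sessions never hold more than one chunk of images in memory.
#'
#' @param truth a [simulate_session()] result.
#' @param view `"front"` or `"side"`.
#' @param scenario defaults to `truth$scenario`.
#' @param config a [detector_config()].
#' @param chunk_size frames rendered per batch.
#' @param noise_sd optional render noise SD (see [render_frames()]).
#' @return a detection `data.frame` for the whole session.
#' @export
detect_rendered_session <- function(truth, view, scenario = truth$scenario,
                                    config = detector_config(),
                                    chunk_size = 500, noise_sd = 0) {
  ref <- reference_frame(scenario, view)
  idx <- truth$frames$frame_index
  t_offset <- if (view == "side") scenario$latency_offset_s else 0
  chunks <- split(idx, ceiling(seq_along(idx) / chunk_size))
  out <- lapply(chunks, function(fr_idx) {
    frames <- render_frames(truth, scenario, view, frames = fr_idx,
                            noise_sd = noise_sd)
    detect_session(frames, ref, view, fps = scenario$fps, config = config,
                   t_offset = t_offset)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Run the blob detector over a rendered session
#'
#' Produces a detection stream in the standard schema: one mouse record per
#' frame where a blob was found, plus the static house and wheel boxes
#' (from the reference frame) emitted every frame.
#'
#' @param frames list of intensity matrices, named by 0-based frame index
#'   (as returned by [render_frames()]).
#' @param reference mouse-free reference frame for the static regions.
#' @param view `"front"` or `"side"`.
#' @param fps frames per second (timestamps = frame / fps).
#' @param config a [detector_config()].
#' @param t_offset constant added to all timestamps (camera latency).
#' @return a detection `data.frame` (see [read_detections()]).
#' @export
detect_session <- function(frames, reference, view, fps = 15,
                           config = detector_config(), t_offset = 0) {
  if (!length(frames)) ct_stop("no frames to detect on")
  statics <- detect_static_regions(reference, config)
  fidx <- as.numeric(names(frames))
  rows <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    det <- detect_mouse(frames[[k]], config)
    if (!is.null(det))
      rows[[k]] <- data.frame(frame_index = fidx[k],
                              timestamp_s = fidx[k] / fps + t_offset,
                              view = view, label = "mouse",
                              x = det$x, y = det$y, w = det$w, h = det$h,
                              confidence = det$confidence)
  }
  mouse <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  static <- do.call(rbind, lapply(names(statics), function(lb) {
    b <- statics[[lb]]
    data.frame(frame_index = fidx, timestamp_s = fidx / fps + t_offset,
               view = view, label = lb,
               x = b$x, y = b$y, w = b$w, h = b$h, confidence = 0.9)
  }))
  out <- rbind(mouse, static)
  out <- out[order(out$frame_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}
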