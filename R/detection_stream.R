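DETECTION_COLUMNS <- c("frame_index", "timestamp_s", "view", "label",
                       "x", "y", "w", "h", "confidence")
DETECTION_LABELS <- c("mouse", "house", "wheel")
VIEWS <- c("front", "side")

#' Read a per-frame detection stream
#'
#' Reads the detection-stream schema
#' `frame_index,timestamp_s,view,label,x,y,w,h,confidence` from CSV (header
#' required) or JSON-lines (one object per line, identical field names).
#' Rows violating the schema (unknown label/view, non-positive box extent,
#' confidence outside \[0, 1\], non-finite coordinates) are dropped with a
#' warning naming their line numbers. Missing timestamps are derived as
#' `frame_index / fps`.
#'
#' @param path file path (`.csv`, or `.json`/`.jsonl` for JSON-lines).
#' @param view if given, require/assign this view for all records.
#' @param fps frames per second used to derive absent timestamps
#'   (recording default: 15).
#' @return a `data.frame` of detection records sorted by `frame_index`
#'   (stable), with the columns listed above.
#' @export
read_detections <- function(path, view = NULL, fps = 15) {
  if (!file.exists(path)) ct_stop(sprintf("detection stream not found: %s", path))
  json <- grepl("\\.jsonl?$", path, ignore.case = TRUE)
  if (json) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    df <- if (length(lines)) jsonlite::stream_in(textConnection(lines), verbose = FALSE)
          else data.frame()
  } else {
    df <- tryCatch(
      as.data.frame(data.table::fread(path, header = TRUE, showProgress = FALSE)),
      error = function(e) ct_stop(sprintf("cannot parse %s: %s", path, conditionMessage(e))))
  }
  if (nrow(df) == 0) {
    warning(sprintf("empty detection stream: %s", path))
    out <- as.data.frame(setNames(rep(list(numeric(0)), length(DETECTION_COLUMNS)),
                                  DETECTION_COLUMNS))
    out$view <- character(0); out$label <- character(0)
    return(out)
  }
  if (!"view" %in% names(df) && !is.null(view)) df$view <- view
  if (!"timestamp_s" %in% names(df)) df$timestamp_s <- NA_real_
  missing_cols <- setdiff(DETECTION_COLUMNS, names(df))
  if (length(missing_cols))
    ct_stop(sprintf("missing required column(s) in %s: %s", path,
                    paste(missing_cols, collapse = ", ")))
  df <- df[DETECTION_COLUMNS]
  for (col in c("frame_index", "timestamp_s", "x", "y", "w", "h", "confidence"))
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  if (any(is.na(df$timestamp_s))) {
    if (fps <= 0) ct_config_error("fps must be > 0 to derive timestamps")
    df$timestamp_s[is.na(df$timestamp_s)] <- df$frame_index[is.na(df$timestamp_s)] / fps
  }
  bad <- !is.finite(df$x) | !is.finite(df$y) |
    !is.finite(df$w) | df$w <= 0 | !is.finite(df$h) | df$h <= 0 |
    !is.finite(df$confidence) | df$confidence < 0 | df$confidence > 1 |
    !is.finite(df$frame_index) | df$frame_index < 0 |
    !(df$label %in% DETECTION_LABELS) | !(df$view %in% VIEWS)
  if (any(bad)) {
    lines_bad <- which(bad) + 1L  # +1 for the header line
    warning(sprintf("dropped %d malformed row(s) in %s (line %s)",
                    sum(bad), path, paste(head(lines_bad, 20), collapse = ", ")))
    df <- df[!bad, , drop = FALSE]
  }
  if (!is.null(view) && nrow(df) && !all(df$view == view))
    ct_stop(sprintf("stream %s contains records for a different view than '%s'", path, view))
  ord <- order(df$frame_index)         # stable
  df <- df[ord, , drop = FALSE]
  if (nrow(df) > 1 && is.unsorted(df$timestamp_s))
    warning(sprintf("non-monotone timestamps in %s; records stably sorted by frame_index", path))
  rownames(df) <- NULL
  df
}

#' Write a detection stream to CSV
#'
#' @param records a detection `data.frame` (see [read_detections()]).
#' @param path output CSV path.
#' @export
write_detections <- function(records, path) {
  missing_cols <- setdiff(DETECTION_COLUMNS, names(records))
  if (length(missing_cols))
    ct_stop(sprintf("cannot write stream, missing column(s): %s",
                    paste(missing_cols, collapse = ", ")))
  data.table::fwrite(records[DETECTION_COLUMNS], path)
  invisible(path)
}

#' Keep the best detection per frame, view and label
#'
#' Object detectors can emit several candidate boxes for the same object in
#' one frame. For each `(view, label, frame_index)` group, keeps the record
#' with maximal confidence; ties broken by largest box area, then lowest x.
#'
#' @param records a detection `data.frame`.
#' @return the filtered `data.frame`, sorted by view, label, frame.
#' @export
select_best <- function(records) {
  if (nrow(records) == 0) return(records)
  dt <- data.table::as.data.table(records)
  dt[, `:=`(.area = w * h)]
  data.table::setorder(dt, view, label, frame_index, -confidence, -.area, x)
  dt <- dt[!duplicated(dt, by = c("view", "label", "frame_index"))]
  dt[, .area := NULL]
  out <- as.data.frame(dt)
  rownames(out) <- NULL
  out
}

# Frame-level table (one row per frame_index) for one view.
frame_table <- function(records) {
  if (nrow(records) == 0)
    return(data.frame(frame_index = numeric(0), timestamp_s = numeric(0)))
  dt <- data.table::as.data.table(records)
  out <- as.data.frame(dt[, list(timestamp_s = min(timestamp_s)), by = "frame_index"])
  out[order(out$timestamp_s, out$frame_index), , drop = FALSE]
}

#' Pair front and side frames under a latency tolerance
#'
#' Two free-running cameras never share exact timestamps; frames are matched
#' greedily to the nearest timestamp in the other stream, each frame used at
#' most once, and matches farther apart than `tolerance` are dropped. The
#' recording setup tolerated a latency offset of 300 ms, the default.
#'
#' @param front,side detection `data.frame`s (after [select_best()]), or
#'   frame tables with columns `frame_index`, `timestamp_s`.
#' @param tolerance maximum |front time - side time| in seconds (> 0).
#' @return a list with `pairs` (a `data.frame`: `front_frame`, `side_frame`,
#'   `front_time`, `side_time`, `pair_time`, `dt`), `n_unmatched_front`,
#'   `n_unmatched_side`.
#' @export
pair_frames <- function(front, side, tolerance = 0.3) {
  if (!is.finite(tolerance) || tolerance <= 0)
    ct_config_error("sync tolerance must be > 0")
  ft <- if (all(c("label", "view") %in% names(front))) frame_table(front) else front
  st <- if (all(c("label", "view") %in% names(side))) frame_table(side) else side
  m <- match_streams_greedy(ft$timestamp_s, st$timestamp_s, tolerance)
  keep <- m > 0L
  pairs <- data.frame(front_frame = ft$frame_index[keep],
                      side_frame = st$frame_index[m[keep]],
                      front_time = ft$timestamp_s[keep],
                      side_time = st$timestamp_s[m[keep]])
  pairs$pair_time <- pairs$front_time
  pairs$dt <- pairs$front_time - pairs$side_time
  list(pairs = pairs,
       n_unmatched_front = nrow(ft) - nrow(pairs),
       n_unmatched_side = nrow(st) - nrow(pairs))
}

#' Fill detection gaps in a mouse track
#'
#' When the detector loses the mouse for one or more frames, the missing
#' midpoints are reconstructed: `hold_last` (default) repeats the last known
#' position into the gap, `linear` interpolates between the flanking known
#' positions. Gaps longer than `max_gap` frames remain absent and are booked
#' as *unknown* rather than fabricated occupancy. Leading gaps are
#' back-filled from the first known position (same cap); trailing gaps hold
#' the last known position under either policy.
#'
#' @param track a `data.frame` with columns `frame_index`, `x`, `y`; absent
#'   detections are `NA` in `x`/`y`.
#' @param policy `"hold_last"` or `"linear"`.
#' @param max_gap maximum gap length (frames) that may be filled.
#' @return the track with a `filled` logical column and `NA`s only in
#'   unknown frames; the gap report is attached as attribute `"gap_report"`
#'   (`n_frames`, `n_missing_mouse`, `n_interpolated`, `n_unknown`).
#' @export
fill_gaps <- function(track, policy = c("hold_last", "linear"), max_gap = 30) {
  policy <- match.arg(policy)
  if (!is.finite(max_gap) || max_gap < 0) ct_config_error("max_gap must be >= 0")
  n <- nrow(track)
  absent <- is.na(track$x) | is.na(track$y)
  if (all(absent)) ct_stop("track has no detected positions to fill from")
  # runs of absence; runs longer than max_gap stay unknown
  r <- rle(absent)
  run_id <- rep(seq_along(r$lengths), r$lengths)
  unknown <- absent & rep(r$values & r$lengths > max_gap, r$lengths)
  fillable <- absent & !unknown

  fill_axis <- function(v) {
    filled <- if (policy == "hold_last") {
      zoo::na.locf(v, na.rm = FALSE)
    } else {
      idx <- which(!is.na(v))
      if (length(idx) >= 2)
        approx(track$frame_index[idx], v[idx], xout = track$frame_index,
               method = "linear", rule = 1)$y
      else v
      # rule = 1: leading/trailing stay NA here, handled below
    }
    filled[is.na(filled)] <- zoo::na.locf(v, na.rm = FALSE)[is.na(filled)]   # trailing
    filled[is.na(filled)] <- zoo::na.locf(v, fromLast = TRUE, na.rm = FALSE)[is.na(filled)] # leading
    out <- v
    out[fillable] <- filled[fillable]
    out
  }
  out <- track
  out$x <- fill_axis(track$x)
  out$y <- fill_axis(track$y)
  out$filled <- fillable
  attr(out, "gap_report") <- list(n_frames = n,
                                  n_missing_mouse = sum(absent),
                                  n_interpolated = sum(fillable),
                                  n_unknown = sum(unknown))
  out
}

#' Forward-fill static object boxes
#'
#' House and wheel are static objects: frames where the detector missed them
#' reuse the most recent detected box, with no cap; frames before the first
#' detection use the first one. Errors if the label was never detected.
#'
#' @param boxes a `data.frame` of per-frame box columns (`x`, `y`, `w`, `h`)
#'   aligned to the frame sequence; `NA` rows are missing detections.
#' @param label object name, used in error messages.
#' @return the gap-free box `data.frame`.
#' @export
fill_static_boxes <- function(boxes, label = "object") {
  if (all(is.na(boxes$x)))
    ct_config_error(sprintf("no '%s' box was ever detected; cannot classify frames", label))
  for (col in c("x", "y", "w", "h")) {
    v <- zoo::na.locf(boxes[[col]], na.rm = FALSE)
    v[is.na(v)] <- zoo::na.locf(boxes[[col]], fromLast = TRUE, na.rm = FALSE)[is.na(v)]
    boxes[[col]] <- v
  }
  boxes
}
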