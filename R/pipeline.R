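#' Evaluation configuration
#'
#' Bundles every tunable of the evaluation pipeline. Defaults follow the
#' recording setup being emulated: 15 FPS, a 300 ms synchronization
#' tolerance, last-known-position gap filling capped at two seconds'
#' worth of frames, and an 11.5 cm wheel.
#'
#' @param fps frames per second of the recording.
#' @param sync_tolerance_s maximum front/side timestamp difference for
#'   pairing (seconds).
#' @param min_confidence detections below this confidence are discarded
#'   before per-frame selection; a frame whose only candidates fall below
#'   the floor counts as a miss and is gap-filled instead of trusting a
#'   spurious box.
#' @param gap_policy `"hold_last"` or `"linear"` (see [fill_gaps()]).
#' @param max_gap_frames longest fillable detection gap; default `2 * fps`.
#' @param distance_mode `"euclidean"` or `"paper_literal"`.
#' @param region_precedence `"wheel"` or `"house"` when both containments
#'   hold.
#' @param phase_preset `"periods"` or `"phases"` (see [phase_schedule()]),
#'   or a custom schedule `data.frame`.
#' @param session_start_clock local clock hour at stream time 0.
#' @param wheel_diameter_m wheel diameter in meters.
#' @param calibration optional [calibration()] for metric distances.
#' @return a list of class `"eval_config"`.
#' @export
eval_config <- function(fps = 15, sync_tolerance_s = 0.3,
                        min_confidence = 0.5,
                        gap_policy = "hold_last", max_gap_frames = NULL,
                        distance_mode = "euclidean",
                        region_precedence = "wheel",
                        phase_preset = "periods",
                        session_start_clock = 15,
                        wheel_diameter_m = 0.115,
                        calibration = NULL) {
  if (!is.finite(fps) || fps <= 0) ct_config_error("fps must be > 0")
  if (is.null(max_gap_frames)) max_gap_frames <- 2 * fps
  if (!is.finite(min_confidence) || min_confidence < 0 || min_confidence > 1)
    ct_config_error("min_confidence must lie in [0, 1]")
  schedule <- if (is.data.frame(phase_preset)) phase_preset
              else phase_schedule(phase_preset)
  validate_schedule(schedule)
  structure(list(fps = fps, sync_tolerance_s = sync_tolerance_s,
                 min_confidence = min_confidence,
                 gap_policy = gap_policy, max_gap_frames = max_gap_frames,
                 distance_mode = distance_mode,
                 region_precedence = region_precedence,
                 schedule = schedule,
                 session_start_clock = session_start_clock,
                 wheel_diameter_m = wheel_diameter_m,
                 calibration = calibration),
            class = "eval_config")
}

#' Read an evaluation configuration from YAML
#'
#' Recognized keys match the arguments of [eval_config()]; `calibration`
#' may be a mapping with `scale_x`, `scale_y`, `scale_z`.
#'
#' @param path YAML file path.
#' @return an `"eval_config"` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) ct_stop(sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$calibration)) cfg$calibration <- do.call(calibration, cfg$calibration)
  known <- names(formals(eval_config))
  bad <- setdiff(names(cfg), known)
  if (length(bad)) ct_config_error(sprintf("unknown config key(s): %s",
                                           paste(bad, collapse = ", ")))
  do.call(eval_config, cfg)
}

# per-pair series of one label's boxes in one view, aligned to pair rows
aligned_boxes <- function(records, lab, frames) {
  sub <- records[records$label == lab, , drop = FALSE]
  i <- match(frames, sub$frame_index)
  data.frame(x = sub$x[i], y = sub$y[i], w = sub$w[i], h = sub$h[i])
}

#' Evaluate a dual-view detection session
#'
#' The full evaluation pipeline: de-duplicates detections per frame
#' ([select_best()]), pairs front and side frames under the sync tolerance
#' ([pair_frames()]), fills mouse detection gaps ([fill_gaps()]),
#' forward-fills the static house and wheel boxes, classifies every paired
#' frame ([classify_frames()]), assigns circadian phases
#' ([segment_phases()]) and aggregates the per-phase report
#' ([aggregate_report()]).
#'
#' @param front,side detection `data.frame`s (see [read_detections()]).
#' @param revolutions optional hourly revolutions `data.frame`
#'   (see [read_revolutions()]).
#' @param config an [eval_config()].
#' @return a list with `report` (the per-phase metrics), `frames` (per-pair
#'   `frame_index`, `time_s`, `phase`, `region`, fused `x`, `y`, `z`),
#'   and `gaps` (gap and pairing report:
#'   `n_frames`, `n_missing_mouse`, `n_interpolated`, `n_unknown`,
#'   `n_unmatched`).
#' @export
evaluate_session <- function(front, side, revolutions = NULL,
                             config = eval_config()) {
  stopifnot(inherits(config, "eval_config"))
  front <- front[front$confidence >= config$min_confidence, , drop = FALSE]
  side <- side[side$confidence >= config$min_confidence, , drop = FALSE]
  front <- select_best(front)
  side <- select_best(side)
  pairing <- pair_frames(front, side, config$sync_tolerance_s)
  pairs <- pairing$pairs
  if (nrow(pairs) == 0) ct_stop("no front/side frame pairs within the sync tolerance")

  track <- function(records, frames) {
    sub <- records[records$label == "mouse", , drop = FALSE]
    i <- match(frames, sub$frame_index)
    data.frame(frame_index = frames, x = sub$x[i], y = sub$y[i])
  }
  tf <- fill_gaps(track(front, pairs$front_frame),
                  config$gap_policy, config$max_gap_frames)
  ts <- fill_gaps(track(side, pairs$side_frame),
                  config$gap_policy, config$max_gap_frames)
  gf <- attr(tf, "gap_report"); gs <- attr(ts, "gap_report")

  boxes <- lapply(c(house_front = "house", wheel_front = "wheel"), function(lb)
    fill_static_boxes(aligned_boxes(front, lb, pairs$front_frame), lb))
  boxes_s <- lapply(c(house_side = "house", wheel_side = "wheel"), function(lb)
    fill_static_boxes(aligned_boxes(side, lb, pairs$side_frame), lb))

  cls <- classify_frames(tf[c("x", "y")], ts[c("x", "y")],
                         boxes$house_front, boxes_s$house_side,
                         boxes$wheel_front, boxes_s$wheel_side,
                         precedence = config$region_precedence)
  time_s <- pairs$pair_time
  phase <- segment_phases(time_s, config$schedule, config$session_start_clock)
  report <- aggregate_report(cls, phase, config$fps,
                             revolutions = revolutions,
                             schedule = config$schedule,
                             calibration = config$calibration,
                             distance_mode = config$distance_mode,
                             wheel_diameter = config$wheel_diameter_m)
  frames <- data.frame(frame_index = pairs$front_frame, time_s = time_s,
                       phase = phase, region = cls$region,
                       x = cls$x, y = cls$y, z = cls$z)
  gaps <- list(n_frames = nrow(pairs),
               n_missing_mouse = gf$n_missing_mouse + gs$n_missing_mouse,
               n_interpolated = gf$n_interpolated + gs$n_interpolated,
               n_unknown = sum(is.na(tf$x) | is.na(ts$x)),
               n_unmatched = pairing$n_unmatched_front + pairing$n_unmatched_side)
  list(report = report, frames = frames, gaps = gaps)
}

#' Per-hour wheel time from evaluated frames
#'
#' Aggregates the classified frame sequence into hourly wheel-occupancy
#' seconds, the series compared against hourly wheel-revolution counts.
#'
#' @param frames the `frames` element of an [evaluate_session()] result.
#' @param fps frames per second.
#' @return a `data.frame` with `hour` and `wheel_s`.
#' @export
hourly_wheel_time <- function(frames, fps) {
  hour <- floor(frames$time_s / 3600)
  n_hours <- max(hour) + 1
  wheel <- tabulate(hour[frames$region == "wheel"] + 1L, nbins = n_hours)
  data.frame(hour = seq_len(n_hours) - 1, wheel_s = wheel / fps)
}
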