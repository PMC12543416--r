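REGION_LEVELS <- c("house", "wheel", "outside", "unknown")

#' Classify frames into house / wheel / outside occupancy
#'
#' Applies the dual-view containment predicate to the house and wheel boxes:
#' the mouse is inside a region only if its midpoint lies inside the
#' region's box in *both* views. When both containments hold (the wheel is
#' mounted above the cage floor, so its 2D projection can overlap the
#' house's) the wheel takes precedence by default. Frames where the mouse
#' midpoint is absent in either view are `unknown`. Classification depends
#' only on midpoints, never on the mouse box extent.
#'
#' @param mouse_front,mouse_side per-frame mouse midpoints: `data.frame`s
#'   with columns `x`, `y` (`NA` = absent), one row per paired frame.
#' @param house_front,house_side,wheel_front,wheel_side per-frame region
#'   boxes ([bbox()] columns), recycled if a single row.
#' @param precedence region that wins when both containments hold
#'   (`"wheel"` or `"house"`).
#' @return a `data.frame` with `region` (factor house/wheel/outside/unknown)
#'   and fused position columns `x`, `y`, `z` (`NA` when unknown).
#' @export
classify_frames <- function(mouse_front, mouse_side,
                            house_front, house_side,
                            wheel_front, wheel_side,
                            precedence = c("wheel", "house")) {
  precedence <- match.arg(precedence)
  n <- nrow(mouse_front)
  if (nrow(mouse_side) != n) ct_stop("front and side mouse tracks differ in length")
  rec <- function(b) lapply(b[c("x", "y", "w", "h")], rep_len, n)
  hf <- rec(house_front); hs <- rec(house_side)
  wf <- rec(wheel_front); ws <- rec(wheel_side)
  in_house <- pib_na(mouse_front$x, mouse_front$y, hf$x, hf$y, hf$w, hf$h) &
              pib_na(mouse_side$x, mouse_side$y, hs$x, hs$y, hs$w, hs$h)
  in_wheel <- pib_na(mouse_front$x, mouse_front$y, wf$x, wf$y, wf$w, wf$h) &
              pib_na(mouse_side$x, mouse_side$y, ws$x, ws$y, ws$w, ws$h)
  region <- rep("outside", n)
  if (precedence == "wheel") {
    region[in_house %in% TRUE] <- "house"
    region[in_wheel %in% TRUE] <- "wheel"
  } else {
    region[in_wheel %in% TRUE] <- "wheel"
    region[in_house %in% TRUE] <- "house"
  }
  absent <- is.na(mouse_front$x) | is.na(mouse_side$x) |
    is.na(mouse_front$y) | is.na(mouse_side$y)
  region[absent] <- "unknown"
  z <- 0.5 * (mouse_front$y + mouse_side$y)
  out <- data.frame(region = factor(region, levels = REGION_LEVELS),
                    x = mouse_front$x, y = mouse_side$x, z = z)
  out$x[absent] <- NA_real_; out$y[absent] <- NA_real_; out$z[absent] <- NA_real_
  out
}

#' Accumulate region occupancy times
#'
#' Each frame contributes `1/FPS` seconds to the region it was classified
#' into: `t_region = n_region / FPS`. Unknown frames are booked separately,
#' so that house + wheel + outside + unknown always accounts for every
#' frame.
#'
#' @param region factor of per-frame regions (levels house, wheel, outside,
#'   unknown).
#' @param fps frames per second (> 0).
#' @return named numeric vector of seconds per region, with the raw frame
#'   counts attached as attribute `"counts"`.
#' @export
accumulate_times <- function(region, fps) {
  if (!is.finite(fps) || fps <= 0) ct_config_error("fps must be > 0")
  region <- factor(region, levels = REGION_LEVELS)
  counts <- table(region)
  out <- as.numeric(counts) / fps
  names(out) <- names(counts)
  attr(out, "counts") <- as.integer(counts)
  out
}

#' Cumulative travel distance outside house and wheel
#'
#' Sums the step distance over consecutive frame pairs whose *both* members
#' are classified outside; runs interrupted by another region (or an unknown
#' frame) contribute nothing across the interruption. With a calibration the
#' result is in meters, otherwise in pixels.
#'
#' @param classification output of [classify_frames()] (or any `data.frame`
#'   with `region`, `x`, `y`, `z`).
#' @param calibration optional [calibration()] (mm/px); result converted to
#'   meters.
#' @param mode distance mode, see [step_distance()].
#' @param group optional per-frame grouping (e.g. phase); steps crossing a
#'   group boundary are not counted. Returns one value per group.
#' @return distance(s) with a `"units"` attribute (`"m"` or `"px"`).
#' @export
outside_activity <- function(classification, calibration = NULL,
                             mode = c("euclidean", "paper_literal"),
                             group = NULL) {
  mode <- match.arg(mode)
  n <- nrow(classification)
  units <- if (is.null(calibration)) "px" else "m"
  if (n < 2) {
    out <- if (is.null(group)) 0 else setNames(numeric(0), character(0))
    attr(out, "units") <- units
    return(out)
  }
  dx <- diff(classification$x); dy <- diff(classification$y); dz <- diff(classification$z)
  if (!is.null(calibration)) {
    dx <- dx * calibration$scale_x
    dy <- dy * calibration$scale_y
    dz <- dz * calibration$scale_z
  }
  d <- dx^2 + dy^2 + dz^2
  if (mode == "euclidean") d <- sqrt(d)
  if (units == "m") d <- d / 1000   # mm -> m (paper_literal: mm^2 -> arbitrary)
  out_pair <- classification$region[-n] == "outside" &
    classification$region[-1] == "outside"
  d[!(out_pair %in% TRUE)] <- 0
  d[is.na(d)] <- 0
  if (is.null(group)) {
    out <- sum(d)
  } else {
    g <- group[-n]
    same <- group[-n] == group[-1]
    d[!(same %in% TRUE)] <- 0
    out <- tapply(d, g, sum, default = 0)
    out <- setNames(as.numeric(out), names(out))
  }
  attr(out, "units") <- units
  out
}

#' Running speed inside the wheel
#'
#' The wheel counter reports revolutions `R`; combined with the time the
#' mouse spent inside the wheel this gives `v_wheel = R / t_wheel` in
#' revolutions per second. With the wheel diameter (11.5 cm for the wheels
#' used here) the rim speed `v * pi * d` in m/s is also reported. The
#' degenerate case `t_wheel = 0, R = 0` is defined as 0; `t_wheel = 0` with
#' `R > 0` is undefined and flagged.
#'
#' @param revolutions revolution count(s), >= 0.
#' @param t_wheel wheel occupancy time(s) in seconds, >= 0.
#' @param wheel_diameter optional wheel diameter in meters.
#' @return a `data.frame` with `rev_per_s`, `m_per_s` (NA without a
#'   diameter) and `undefined` (logical).
#' @examples
#' running_speed(450, 900, wheel_diameter = 0.115)
#' @export
running_speed <- function(revolutions, t_wheel, wheel_diameter = NULL) {
  if (any(revolutions < 0, na.rm = TRUE) || any(t_wheel < 0, na.rm = TRUE))
    ct_stop("revolutions and t_wheel must be non-negative")
  n <- max(length(revolutions), length(t_wheel))
  revolutions <- rep_len(as.numeric(revolutions), n)
  t_wheel <- rep_len(as.numeric(t_wheel), n)
  undefined <- t_wheel == 0 & revolutions > 0
  rev_per_s <- ifelse(t_wheel > 0, revolutions / t_wheel,
                      ifelse(revolutions == 0, 0, NA_real_))
  m_per_s <- if (is.null(wheel_diameter)) rep(NA_real_, n)
             else rev_per_s * pi * wheel_diameter
  data.frame(rev_per_s = rev_per_s, m_per_s = m_per_s, undefined = undefined)
}

#' Circadian phase window schedules
#'
#' Two presets mirror the windows used with a 12/12 light/dark cycle
#' (lights on at 6 A.M., feeding at 1 P.M.):
#' * `"periods"` — FAA (food-anticipatory activity, 9 A.M.-1 P.M.),
#'   PA (postprandial, 2-6 P.M.), NA (night, 6 P.M.-6 A.M.),
#'   PRA (preprandial, 6-9 A.M.); the feeding hour (1-2 P.M.) is excluded
#'   from analysis.
#' * `"phases"` — Light1 (3-6 P.M.), Dark (6 P.M.-6 A.M.),
#'   Light2 (6 A.M.-1 P.M.); 1-3 P.M. is unassigned.
#'
#' Windows are half-open `[start, end)` in local clock hours and may cross
#' midnight (`start > end`).
#'
#' @param preset `"periods"` or `"phases"`.
#' @return a `data.frame` with columns `name`, `start_h`, `end_h`,
#'   `excluded`.
#' @export
phase_schedule <- function(preset = c("periods", "phases")) {
  preset <- match.arg(preset)
  if (preset == "periods") {
    data.frame(name = c("FAA", "PA", "NA", "PRA", "feeding"),
               start_h = c(9, 14, 18, 6, 13),
               end_h = c(13, 18, 6, 9, 14),
               excluded = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  } else {
    data.frame(name = c("Light1", "Dark", "Light2"),
               start_h = c(15, 18, 6),
               end_h = c(18, 6, 13),
               excluded = c(FALSE, FALSE, FALSE))
  }
}

# length of intersection of two clock windows (hours, mod 24)
window_overlap_h <- function(a_start, a_end, b_start, b_end) {
  split24 <- function(s, e) {
    if (s < e) list(c(s, e)) else list(c(s, 24), c(0, e))
  }
  ov <- 0
  for (ia in split24(a_start, a_end)) for (ib in split24(b_start, b_end))
    ov <- ov + max(0, min(ia[2], ib[2]) - max(ia[1], ib[1]))
  ov
}

validate_schedule <- function(schedule) {
  req <- c("name", "start_h", "end_h", "excluded")
  if (!all(req %in% names(schedule))) ct_config_error("schedule lacks required columns")
  act <- schedule[!schedule$excluded, , drop = FALSE]
  if (nrow(act) >= 2) {
    for (i in seq_len(nrow(act) - 1)) for (j in (i + 1):nrow(act)) {
      if (window_overlap_h(act$start_h[i], act$end_h[i],
                           act$start_h[j], act$end_h[j]) > 0)
        ct_config_error(sprintf("phase windows '%s' and '%s' overlap",
                                act$name[i], act$name[j]))
    }
  }
  invisible(schedule)
}

clock_in_window <- function(clock_h, start_h, end_h) {
  if (start_h < end_h) clock_h >= start_h & clock_h < end_h
  else clock_h >= start_h | clock_h < end_h
}

#' Assign frames to circadian phase windows
#'
#' Converts per-frame session times to local clock time and assigns each
#' frame to the unique window containing it. Frames inside an excluded
#' window (the feeding hour) are labeled `"excluded"`; frames covered by no
#' window are `"unassigned"`. Windows crossing midnight are handled.
#'
#' @param time_s seconds since session start, per frame.
#' @param schedule a schedule `data.frame` (see [phase_schedule()]).
#' @param session_start_clock local clock time (hours, 0-24) at `time_s = 0`.
#' @return a factor with levels = window names, `"excluded"`,
#'   `"unassigned"`.
#' @export
segment_phases <- function(time_s, schedule = phase_schedule("periods"),
                           session_start_clock = 15) {
  validate_schedule(schedule)
  if (!is.finite(session_start_clock) || session_start_clock < 0 || session_start_clock >= 24)
    ct_config_error("session_start_clock must be in [0, 24)")
  clock <- (session_start_clock + time_s / 3600) %% 24
  phase <- rep("unassigned", length(clock))
  for (i in seq_len(nrow(schedule))) {
    hit <- clock_in_window(clock, schedule$start_h[i], schedule$end_h[i])
    phase[hit & phase == "unassigned"] <-
      if (schedule$excluded[i]) "excluded" else schedule$name[i]
  }
  # excluded windows override any later-listed overlapping window
  for (i in which(schedule$excluded)) {
    hit <- clock_in_window(clock, schedule$start_h[i], schedule$end_h[i])
    phase[hit] <- "excluded"
  }
  factor(phase, levels = c(schedule$name[!schedule$excluded], "excluded", "unassigned"))
}

#' Phase of a single clock time
#'
#' Point query used to book hourly wheel-revolution records into phases by
#' the clock time of the hour's start.
#' @inheritParams segment_phases
#' @param clock_h clock hour(s) in \[0, 24).
#' @return factor as in [segment_phases()].
#' @export
phase_of_clock <- function(clock_h, schedule = phase_schedule("periods")) {
  segment_phases((clock_h %% 24) * 3600, schedule, session_start_clock = 0)
}

#' Aggregate a full per-phase behavior report
#'
#' Combines frame classifications, phase assignments, optional hourly wheel
#' revolutions and an optional calibration into one report: per phase (and
#' for the whole session) the house/wheel/outside/unknown times, the outside
#' activity, the summed revolutions, and the running speed. Hourly
#' revolution records are booked into the phase containing the hour's start
#' clock time. Phases with zero frames are reported as 0 and flagged
#' `empty`.
#'
#' @param classification output of [classify_frames()].
#' @param phase per-frame phase factor from [segment_phases()].
#' @param fps frames per second.
#' @param revolutions optional `data.frame` with `hour_start_clock`,
#'   `revolutions` (see [read_revolutions()]).
#' @param schedule the schedule used for `phase` (needed to book
#'   revolutions); defaults to the periods preset.
#' @param calibration optional [calibration()]; outside activity in meters.
#' @param distance_mode see [step_distance()].
#' @param wheel_diameter optional wheel diameter (m) for rim speed.
#' @return a `data.frame`, one row per phase plus a `"total"` row: columns
#'   `phase`, `n_frames`, `t_house_s`, `t_wheel_s`, `t_outside_s`,
#'   `t_unknown_s`, `outside_activity`, `revolutions`, `speed_rev_s`,
#'   `speed_m_s`, `empty`. Attribute `"activity_units"` gives the distance
#'   unit.
#' @export
aggregate_report <- function(classification, phase, fps,
                             revolutions = NULL,
                             schedule = phase_schedule("periods"),
                             calibration = NULL,
                             distance_mode = "euclidean",
                             wheel_diameter = NULL) {
  if (nrow(classification) != length(phase))
    ct_stop("classification and phase assignment differ in length")
  act <- outside_activity(classification, calibration, distance_mode, group = phase)
  phases <- levels(phase)
  rev_by_phase <- setNames(rep(NA_real_, length(phases)), phases)
  if (!is.null(revolutions) && nrow(revolutions)) {
    rp <- phase_of_clock(revolutions$hour_start_clock, schedule)
    s <- tapply(revolutions$revolutions, factor(rp, levels = phases), sum)
    rev_by_phase[names(s)] <- ifelse(is.na(s), 0, s)
    rev_by_phase[is.na(rev_by_phase)] <- 0
  }
  rows <- lapply(phases, function(ph) {
    sel <- phase == ph
    tt <- accumulate_times(classification$region[sel], fps)
    data.frame(phase = ph, n_frames = sum(sel),
               t_house_s = tt[["house"]], t_wheel_s = tt[["wheel"]],
               t_outside_s = tt[["outside"]], t_unknown_s = tt[["unknown"]],
               outside_activity = if (ph %in% names(act)) as.numeric(act[[ph]]) else 0,
               revolutions = rev_by_phase[[ph]],
               empty = sum(sel) == 0)
  })
  tt_all <- accumulate_times(classification$region, fps)
  act_all <- outside_activity(classification, calibration, distance_mode)
  rows <- c(rows, list(data.frame(
    phase = "total", n_frames = nrow(classification),
    t_house_s = tt_all[["house"]], t_wheel_s = tt_all[["wheel"]],
    t_outside_s = tt_all[["outside"]], t_unknown_s = tt_all[["unknown"]],
    outside_activity = as.numeric(act_all),
    revolutions = if (is.null(revolutions)) NA_real_ else sum(revolutions$revolutions),
    empty = nrow(classification) == 0)))
  out <- do.call(rbind, rows)
  spd <- running_speed(ifelse(is.na(out$revolutions), 0, out$revolutions),
                       out$t_wheel_s, wheel_diameter)
  out$speed_rev_s <- ifelse(is.na(out$revolutions), NA_real_, spd$rev_per_s)
  out$speed_m_s <- ifelse(is.na(out$revolutions), NA_real_, spd$m_per_s)
  out <- out[c("phase", "n_frames", "t_house_s", "t_wheel_s", "t_outside_s",
               "t_unknown_s", "outside_activity", "revolutions",
               "speed_rev_s", "speed_m_s", "empty")]
  rownames(out) <- NULL
  attr(out, "activity_units") <- attr(act_all, "units")
  out
}

#' Read hourly wheel-revolution counts
#'
#' CSV schema: `hour_start_clock,revolutions` (clock hour in \[0, 24) at
#' which the hour begins, and the summed revolutions for that hour, the
#' convention of hourly-summing wheel counters). An optional `hour` column
#' (index since session start) is preserved.
#'
#' @param path CSV path.
#' @return a `data.frame`.
#' @export
read_revolutions <- function(path) {
  if (!file.exists(path)) ct_stop(sprintf("revolutions file not found: %s", path))
  df <- as.data.frame(data.table::fread(path, header = TRUE, showProgress = FALSE))
  if (!all(c("hour_start_clock", "revolutions") %in% names(df)))
    ct_stop("revolutions CSV needs columns hour_start_clock, revolutions")
  if (any(df$revolutions < 0)) ct_stop("revolution counts must be non-negative")
  df
}

#' Write a metrics report
#'
#' JSON keeps the per-phase rows as an array of objects; CSV is tidy long
#' format (one row per phase x metric).
#'
#' @param report output of [aggregate_report()].
#' @param path output path.
#' @param format `"json"` or `"csv"`.
#' @export
write_report <- function(report, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(list(activity_units = attr(report, "activity_units"),
                              phases = report),
                         path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    metrics <- setdiff(names(report), c("phase", "empty"))
    long <- do.call(rbind, lapply(metrics, function(m)
      data.frame(phase = report$phase, metric = m, value = as.numeric(report[[m]]))))
    data.table::fwrite(long, path)
  }
  invisible(path)
}
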