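#' Default diurnal activity profile
#'
#' Hour-of-day multipliers applied to the rate of leaving the current dwell
#' region: activity is elevated in the dark phase (6 P.M.-6 A.M. under a
#' 12/12 cycle with lights on at 6 A.M.), ramps up over the hours preceding
#' the 1 P.M. feeding (a food-anticipatory pattern), and is low otherwise.
#'
#' @return numeric vector of length 24, named by hour 0-23.
#' @export
circadian_profile <- function() {
  m <- rep(0.6, 24)
  m[c(19:24, 1:6)] <- 1.8       # 18:00-05:59 dark phase (index = hour + 1)
  m[10:13] <- 1.4               # 09:00-12:59 pre-feeding ramp
  names(m) <- 0:23
  m
}

zone3d <- function(x, y, z) list(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z))

default_zones <- function() {
  # Disjoint 3D dwell zones in cage mm; z follows the image convention
  # (0 = top of cage, increasing downward). The wheel hangs from the cage
  # top; its side-view projection overlaps the house's, exercising the
  # wheel-over-house precedence. No zone lies inside another's box in both
  # views.
  list(house = zone3d(c(10, 110), c(10, 110), c(81, 141)),
       wheel = zone3d(c(150, 265), c(60, 175), c(0, 115)),
       outside = zone3d(c(115, 265), c(10, 205), c(120, 141)))
}

#' Define a simulated cage session
#'
#' Bundles every parameter of the synthetic session: cage geometry, the
#' Markov dwell model over house/wheel/outside, the within-region random
#' walk, diurnal modulation, detection corruption, and the wheel-counter
#' model. Defaults mirror the recording conditions of the system being
#' emulated: a 268 x 215 x 141 mm home cage filmed at 15 FPS for 22 h, an
#' 11.5 cm wheel, and detection reliability in the high-90s percent range.
#'
#' @param seed master seed; all randomness flows from it via named
#'   substreams.
#' @param duration_s session length in seconds (default 22 h).
#' @param fps frames per second (default 15).
#' @param cage_dims cage (width, depth, height) in mm.
#' @param zones named list (`house`, `wheel`, `outside`) of 3D boxes, each a
#'   list of `x`, `y`, `z` ranges in mm.
#' @param dwell_mean_s mean sojourn seconds per region.
#' @param transition 3x3 row-stochastic matrix of jump destinations
#'   (rows/cols house, wheel, outside; zero diagonal).
#' @param step_mm per-axis random-walk step standard deviation (mm/frame).
#' @param zone_margin_mm wall margin: the walk is confined to each zone
#'   shrunk by this much, while the emitted region boxes are the full zones
#'   (a shelter's bounding box includes walls the mouse centroid cannot
#'   reach).
#' @param circadian length-24 hour-of-day multiplier on the rate of leaving
#'   the current region (see [circadian_profile()]).
#' @param session_start_clock local clock hour at session start.
#' @param miss_prob per-frame probability that a mouse detection is lost.
#' @param jitter_sd_px localization jitter SD (pixels) on surviving mouse
#'   midpoints.
#' @param latency_offset_s constant timestamp offset added to the side
#'   stream.
#' @param false_box_rate per-frame rate of spurious low-confidence mouse
#'   boxes.
#' @param wheel_rate_rps wheel revolutions per second of wheel occupancy.
#' @param wheel_noise_sd Gaussian noise SD on hourly revolution counts.
#' @param wheel_diameter_m wheel diameter in meters (11.5 cm wheel).
#' @param mouse_size_mm mouse (length, height) in mm, used for box extents
#'   and rendering.
#' @param scale_mm_per_px camera scale: cage mm per image pixel.
#' @param render_size rendered frame (width, height) in pixels.
#' @return an object of class `"sim_scenario"`.
#' @export
sim_scenario <- function(seed = 1, duration_s = 22 * 3600, fps = 15,
                         cage_dims = c(268, 215, 141),
                         zones = default_zones(),
                         dwell_mean_s = c(house = 300, wheel = 120, outside = 60),
                         transition = matrix(c(0, .5, .5,
                                               .5, 0, .5,
                                               .5, .5, 0), 3, 3, byrow = TRUE,
                                             dimnames = list(c("house", "wheel", "outside"),
                                                             c("house", "wheel", "outside"))),
                         step_mm = 6, zone_margin_mm = 8,
                         circadian = circadian_profile(),
                         session_start_clock = 15,
                         miss_prob = 0.02, jitter_sd_px = 1,
                         latency_offset_s = 0, false_box_rate = 0.01,
                         wheel_rate_rps = 1, wheel_noise_sd = 20,
                         wheel_diameter_m = 0.115,
                         mouse_size_mm = c(60, 25),
                         scale_mm_per_px = 0.5,
                         render_size = c(1640, 1232)) {
  if (!is.finite(duration_s) || duration_s <= 0) ct_config_error("duration_s must be > 0")
  if (!is.finite(fps) || fps <= 0) ct_config_error("fps must be > 0")
  if (any(dwell_mean_s <= 0)) ct_config_error("dwell means must be > 0")
  if (!all(dim(transition) == c(3, 3)) ||
      any(abs(rowSums(transition) - 1) > 1e-9) ||
      any(transition < 0 | transition > 1))
    ct_config_error("transition must be a 3x3 row-stochastic matrix")
  if (miss_prob < 0 || miss_prob > 1 || false_box_rate < 0 || false_box_rate > 1)
    ct_config_error("probabilities must lie in [0, 1]")
  if (length(circadian) != 24 || any(circadian <= 0))
    ct_config_error("circadian must be 24 positive hourly multipliers")
  structure(list(seed = seed, duration_s = duration_s, fps = fps,
                 cage_dims = cage_dims, zones = zones,
                 dwell_mean_s = dwell_mean_s, transition = transition,
                 step_mm = step_mm, zone_margin_mm = zone_margin_mm,
                 circadian = circadian, session_start_clock = session_start_clock,
                 miss_prob = miss_prob, jitter_sd_px = jitter_sd_px,
                 latency_offset_s = latency_offset_s, false_box_rate = false_box_rate,
                 wheel_rate_rps = wheel_rate_rps, wheel_noise_sd = wheel_noise_sd,
                 wheel_diameter_m = wheel_diameter_m,
                 mouse_size_mm = mouse_size_mm,
                 scale_mm_per_px = scale_mm_per_px,
                 render_size = render_size),
            class = "sim_scenario")
}

#' Read a scenario from a YAML file
#'
#' Scalar fields override [sim_scenario()] defaults; `transition` may be
#' given as a 9-element row-major vector.
#'
#' @param path YAML file path.
#' @return a `"sim_scenario"` object.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) ct_stop(sprintf("scenario file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$transition))
    cfg$transition <- matrix(unlist(cfg$transition), 3, 3, byrow = TRUE,
                             dimnames = list(c("house", "wheel", "outside"),
                                             c("house", "wheel", "outside")))
  if (!is.null(cfg$dwell_mean_s)) cfg$dwell_mean_s <- unlist(cfg$dwell_mean_s)
  if (!is.null(cfg$circadian)) cfg$circadian <- unlist(cfg$circadian)
  known <- names(formals(sim_scenario))
  bad <- setdiff(names(cfg), known)
  if (length(bad)) ct_config_error(sprintf("unknown scenario field(s): %s",
                                           paste(bad, collapse = ", ")))
  do.call(sim_scenario, cfg)
}

# reflect values into [lo, hi] (triangular fold), vectorized
reflect_into <- function(v, lo, hi) {
  if (hi <= lo) return(rep((lo + hi) / 2, length(v)))
  L <- hi - lo
  p <- (v - lo) %% (2 * L)
  lo + pmin(p, 2 * L - p)
}

shrink_zone <- function(zone, margin) {
  sh <- function(r) {
    m <- min(margin, (r[2] - r[1]) / 2 * 0.99)
    c(r[1] + m, r[2] - m)
  }
  list(x = sh(zone$x), y = sh(zone$y), z = sh(zone$z))
}

#' Simulate a ground-truth cage session
#'
#' Region sojourns follow a continuous-time Markov chain with exponential
#' dwell times whose leave rate is modulated by the hour-of-day activity
#' profile; within each sojourn the mouse performs a reflected Gaussian
#' random walk inside the (margin-shrunk) region zone, entering each new
#' region at the point of the previous position clamped into it. Hourly
#' wheel revolutions are `rate x wheel-occupancy seconds + noise`, floored
#' at 0 and rounded. Fully reproducible from the scenario seed.
#'
#' @param scenario a [sim_scenario()].
#' @return an object of class `"cage_truth"`: list with `frames`
#'   (`frame_index`, `time_s`, `region`, true `x`, `y`, `z` in mm), `hourly`
#'   (`hour`, `hour_start_clock`, `wheel_s`, `revolutions`), `dwell_s`
#'   (named seconds per region), and the `scenario`.
#' @export
simulate_session <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  sc <- scenario
  regions <- c("house", "wheel", "outside")
  n_frames <- round(sc$duration_s * sc$fps)
  frame_t <- (seq_len(n_frames) - 1) / sc$fps

  traj <- with_substream(sc$seed, "trajectory", {
    # --- sojourn schedule ---
    t <- 0; reg <- character(0); dur <- numeric(0)
    cur <- sample(regions, 1)
    while (t < sc$duration_s) {
      hour <- floor(((sc$session_start_clock * 3600 + t) %% 86400) / 3600)
      rate <- sc$circadian[[hour + 1]] / sc$dwell_mean_s[[cur]]
      d <- rexp(1, rate)
      reg <- c(reg, cur); dur <- c(dur, d)
      t <- t + d
      cur <- sample(regions, 1, prob = sc$transition[cur, ])
    }
    ends <- cumsum(dur)
    seg <- findInterval(frame_t, c(0, head(ends, -1)), rightmost.closed = FALSE)
    region <- reg[seg]

    # --- within-zone reflected random walk ---
    x <- numeric(n_frames); y <- numeric(n_frames); z <- numeric(n_frames)
    pos <- NULL
    seg_rle <- rle(seg)
    idx_end <- cumsum(seg_rle$lengths)
    idx_start <- idx_end - seg_rle$lengths + 1
    for (k in seq_along(seg_rle$values)) {
      zn <- shrink_zone(sc$zones[[reg[seg_rle$values[k]]]], sc$zone_margin_mm)
      i0 <- idx_start[k]; i1 <- idx_end[k]; m <- i1 - i0 + 1
      if (is.null(pos)) pos <- c(mean(zn$x), mean(zn$y), mean(zn$z))
      start <- pmin(pmax(pos, c(zn$x[1], zn$y[1], zn$z[1])),
                    c(zn$x[2], zn$y[2], zn$z[2]))
      x[i0:i1] <- reflect_into(start[1] + cumsum(rnorm(m, 0, sc$step_mm)), zn$x[1], zn$x[2])
      y[i0:i1] <- reflect_into(start[2] + cumsum(rnorm(m, 0, sc$step_mm)), zn$y[1], zn$y[2])
      z[i0:i1] <- reflect_into(start[3] + cumsum(rnorm(m, 0, sc$step_mm)), zn$z[1], zn$z[2])
      pos <- c(x[i1], y[i1], z[i1])
    }
    list(region = region, x = x, y = y, z = z)
  })

  hour_idx <- floor(frame_t / 3600)
  n_hours <- max(hour_idx) + 1
  wheel_frames <- tabulate(hour_idx[traj$region == "wheel"] + 1L, nbins = n_hours)
  wheel_s <- wheel_frames / sc$fps
  revolutions <- with_substream(sc$seed, "revolutions", {
    noise <- if (sc$wheel_noise_sd > 0) rnorm(n_hours, 0, sc$wheel_noise_sd) else 0
    round(pmax(0, sc$wheel_rate_rps * wheel_s + noise))
  })
  hourly <- data.frame(hour = seq_len(n_hours) - 1,
                       hour_start_clock = (sc$session_start_clock + seq_len(n_hours) - 1) %% 24,
                       wheel_s = wheel_s, revolutions = revolutions)
  dwell <- table(factor(traj$region, levels = regions)) / sc$fps
  structure(list(frames = data.frame(frame_index = seq_len(n_frames) - 1,
                                     time_s = frame_t,
                                     region = factor(traj$region, levels = regions),
                                     x = traj$x, y = traj$y, z = traj$z),
                 hourly = hourly,
                 dwell_s = setNames(as.numeric(dwell), regions),
                 scenario = sc),
            class = "cage_truth")
}

project_zone_box <- function(zone, axis_h, scale) {
  # project a 3D zone to an image-view box: axis_h in {"x" (front), "y" (side)}
  h <- zone[[axis_h]]; v <- zone$z
  bbox(x = mean(h) / scale, y = mean(v) / scale,
       w = diff(h) / scale, h = diff(v) / scale)
}

#' Project ground truth into dual-view detection streams
#'
#' The inverse of [fuse_views()]: the front view sees (cage width, height),
#' the side view (cage depth, height), both divided by the camera scale
#' (mm/px). Static house and wheel boxes (the full zone projections) are
#' emitted every frame; the side stream's timestamps carry the scenario's
#' latency offset. At zero corruption, `fuse_views()` of these streams
#' recovers the true position exactly (up to the calibration scale).
#'
#' @param truth a [simulate_session()] result.
#' @param scenario defaults to `truth$scenario`.
#' @param static `"every_frame"` emits the house and wheel boxes in every
#'   frame; `"once"` emits them only in the first frame (the evaluation
#'   pipeline forward-fills static objects, so both are equivalent inputs;
#'   `"once"` keeps multi-hour streams small).
#' @return list of two detection `data.frame`s, `front` and `side`.
#' @export
project_views <- function(truth, scenario = truth$scenario,
                          static = c("every_frame", "once")) {
  static <- match.arg(static)
  stopifnot(inherits(truth, "cage_truth"))
  sc <- scenario
  s <- sc$scale_mm_per_px
  fr <- truth$frames
  n <- nrow(fr)
  mouse_w <- sc$mouse_size_mm[1] / s
  mouse_h <- sc$mouse_size_mm[2] / s
  one_view <- function(axis_h, view, t_offset) {
    mouse <- data.frame(frame_index = fr$frame_index,
                        timestamp_s = fr$time_s + t_offset,
                        view = view, label = "mouse",
                        x = fr[[axis_h]] / s, y = fr$z / s,
                        w = mouse_w, h = mouse_h, confidence = 0.99)
    keep <- if (static == "once") 1L else seq_len(n)
    static_rows <- lapply(c("house", "wheel"), function(lb) {
      b <- project_zone_box(sc$zones[[lb]], axis_h, s)
      data.frame(frame_index = fr$frame_index[keep],
                 timestamp_s = fr$time_s[keep] + t_offset,
                 view = view, label = lb,
                 x = b$x, y = b$y, w = b$w, h = b$h, confidence = 0.97)
    })
    out <- rbind(mouse, static_rows[[1]], static_rows[[2]])
    out <- out[order(out$frame_index), , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  list(front = one_view("x", "front", 0),
       side = one_view("y", "side", sc$latency_offset_s))
}

#' Corrupt a detection stream
#'
#' Emulates detector failure modes: each mouse record is dropped
#' independently with `miss_prob`; surviving mouse midpoints receive
#' Gaussian pixel jitter; spurious low-confidence mouse boxes are injected
#' at `false_box_rate` per frame at uniform positions. Static boxes are
#' untouched. Seeded per view from the scenario seed, so front and side
#' corruption are independent and reproducible.
#'
#' @param stream one detection `data.frame` (a single view).
#' @param scenario the [sim_scenario()] providing corruption parameters.
#' @return the corrupted stream.
#' @export
corrupt_stream <- function(stream, scenario) {
  sc <- scenario
  if (nrow(stream) == 0) return(stream)
  view <- stream$view[1]
  with_substream(sc$seed, paste0("corrupt_", view), {
    is_mouse <- stream$label == "mouse"
    midx <- which(is_mouse)
    drop <- runif(length(midx)) < sc$miss_prob
    out <- stream[-midx[drop], , drop = FALSE]
    if (length(midx[drop]) == 0) out <- stream
    m2 <- which(out$label == "mouse")
    if (sc$jitter_sd_px > 0 && length(m2)) {
      out$x[m2] <- out$x[m2] + rnorm(length(m2), 0, sc$jitter_sd_px)
      out$y[m2] <- out$y[m2] + rnorm(length(m2), 0, sc$jitter_sd_px)
    }
    if (sc$false_box_rate > 0) {
      ft <- frame_table(out)
      sel <- runif(nrow(ft)) < sc$false_box_rate
      if (any(sel)) {
        s <- sc$scale_mm_per_px
        ext_h <- (if (view == "front") sc$cage_dims[1] else sc$cage_dims[2]) / s
        ext_v <- sc$cage_dims[3] / s
        fake <- data.frame(frame_index = ft$frame_index[sel],
                           timestamp_s = ft$timestamp_s[sel],
                           view = view, label = "mouse",
                           x = runif(sum(sel), 0, ext_h),
                           y = runif(sum(sel), 0, ext_v),
                           w = sc$mouse_size_mm[1] / s, h = sc$mouse_size_mm[2] / s,
                           confidence = runif(sum(sel), 0.05, 0.3))
        out <- rbind(out, fake)
      }
    }
    out <- out[order(out$frame_index), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}
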