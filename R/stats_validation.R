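#' Pearson correlation between hourly wheel time and revolutions
#'
#' The cross-modality agreement statistic: product-moment correlation of
#' per-hour wheel-occupancy seconds (video pipeline) against per-hour wheel
#' revolutions (magnetic counter), with the two-sided p-value from the t
#' transform on n - 2 degrees of freedom.
#'
#' @param wheel_time_s hourly wheel time (seconds), or a `data.frame` with
#'   columns `wheel_time_s`/`wheel_s` and `revolutions`.
#' @param revolutions hourly revolution counts.
#' @return a list with `r`, `p`, `n`, `df`.
#' @export
pearson_r <- function(wheel_time_s, revolutions = NULL) {
  if (is.data.frame(wheel_time_s)) {
    df <- wheel_time_s
    revolutions <- df$revolutions
    wheel_time_s <- if (!is.null(df$wheel_time_s)) df$wheel_time_s else df$wheel_s
  }
  x <- as.numeric(wheel_time_s); y <- as.numeric(revolutions)
  if (length(x) != length(y)) ct_stop("series must have equal length")
  if (length(x) < 3) ct_stop("need at least 3 paired hours")
  if (sd(x) == 0 || sd(y) == 0)
    ct_stop("correlation undefined: a series has zero variance")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value,
       n = length(x), df = length(x) - 2)
}

#' Parameter-recovery report against simulator ground truth
#'
#' Compares a pipeline result with the ground truth of the session it was
#' computed from: absolute and relative errors of the recovered house,
#' wheel and outside times and of the outside activity, plus the hourly
#' wheel-time series error.
#'
#' @param truth a [simulate_session()] result.
#' @param result an [evaluate_session()] result for streams derived from
#'   the same session.
#' @param px_calibration calibration (mm/px) used to convert a pixel-unit
#'   recovered outside activity to meters; defaults to the scenario's
#'   camera scale, so truth (mm-based) and recovered activity are compared
#'   in meters.
#' @return a `data.frame` (`metric`, `truth`, `recovered`, `abs_err`,
#'   `rel_err`), with the hourly wheel-time comparison attached as
#'   attribute `"hourly"`.
#' @export
recovery_report <- function(truth, result, px_calibration = NULL) {
  stopifnot(inherits(truth, "cage_truth"))
  sc <- truth$scenario
  dur_truth <- nrow(truth$frames) / sc$fps
  dur_rec <- max(result$frames$time_s) - min(result$frames$time_s) + 1 / sc$fps
  if (abs(dur_truth - dur_rec) > 0.02 * dur_truth + 2)
    ct_stop("ground truth and result cover different session durations")

  # truth outside activity (mm walk -> meters), same consecutive-pair rule
  tr_cls <- data.frame(region = truth$frames$region,
                       x = truth$frames$x, y = truth$frames$y, z = truth$frames$z)
  act_truth <- as.numeric(outside_activity(tr_cls, calibration(1, 1, 1)))

  tot <- result$report[result$report$phase == "total", ]
  cal <- px_calibration %||% calibration(sc$scale_mm_per_px, sc$scale_mm_per_px,
                                         sc$scale_mm_per_px)
  # recovered activity was computed with the eval config's calibration; if
  # the result is in pixels, convert here for a like-for-like comparison
  act_rec <- tot$outside_activity
  if (identical(attr(result$report, "activity_units"), "px"))
    act_rec <- act_rec * cal$scale_x / 1000

  truth_vals <- c(t_house = unname(truth$dwell_s["house"]),
                  t_wheel = unname(truth$dwell_s["wheel"]),
                  t_outside = unname(truth$dwell_s["outside"]),
                  outside_activity = act_truth)
  rec_vals <- c(t_house = tot$t_house_s, t_wheel = tot$t_wheel_s,
                t_outside = tot$t_outside_s, outside_activity = act_rec)
  out <- data.frame(metric = names(truth_vals),
                    truth = unname(truth_vals), recovered = unname(rec_vals))
  out$abs_err <- abs(out$recovered - out$truth)
  out$rel_err <- ifelse(out$truth > 0, out$abs_err / out$truth, NA_real_)

  hw <- hourly_wheel_time(result$frames, sc$fps)
  hourly <- merge(truth$hourly[c("hour", "wheel_s", "revolutions")], hw,
                  by = "hour", suffixes = c("_truth", "_recovered"))
  attr(out, "hourly") <- hourly
  out
}
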