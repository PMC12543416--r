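# Small hand-built frame set: house box at (50, 50) 40x40 in both views,
# wheel box at (150, 30) 40x40 front / (50, 30) 40x40 side (overlapping the
# house box in the side view, as a top-mounted wheel projection does).
hb_f <- bbox(50, 50, 40, 40); hb_s <- bbox(50, 50, 40, 40)
wb_f <- bbox(150, 30, 40, 40); wb_s <- bbox(50, 30, 40, 40)

test_that("frame classification follows the dual-view conjunction and precedence", {
  mf <- data.frame(x = c(150, 50, 50, NA, 150),
                   y = c(30, 50, 30, 20, 30))
  ms <- data.frame(x = c(50, 50, 200, 20, 35),
                   y = c(30, 50, 30, 20, 35))
  cls <- classify_frames(mf, ms, hb_f, hb_s, wb_f, wb_s)
  # frame 1: inside wheel in both views -> wheel
  # frame 2: inside house both views -> house
  # frame 3: inside house front only -> outside
  # frame 4: mouse absent in front -> unknown
  # frame 5: wheel in front; side point (35,35) is in BOTH house and wheel
  #          side boxes; wheel conjunction holds -> wheel
  expect_equal(as.character(cls$region),
               c("wheel", "house", "outside", "unknown", "wheel"))
  expect_true(is.na(cls$x[4]) && is.na(cls$z[4]))
  expect_equal(cls$z[1], 30)
})

test_that("a frame inside both house and wheel follows the configured precedence", {
  # point inside house AND wheel in both views: overlap region of the side
  # boxes, plus front boxes placed to overlap
  wf2 <- bbox(50, 30, 40, 40)
  mf <- data.frame(x = 50, y = 35); ms <- data.frame(x = 50, y = 35)
  both_wheel <- classify_frames(mf, ms, hb_f, hb_s, wf2, wb_s, precedence = "wheel")
  both_house <- classify_frames(mf, ms, hb_f, hb_s, wf2, wb_s, precedence = "house")
  expect_equal(as.character(both_wheel$region), "wheel")
  expect_equal(as.character(both_house$region), "house")
})

test_that("classification ignores the mouse box extent (midpoints only)", {
  mf <- data.frame(x = 50, y = 50); ms <- data.frame(x = 50, y = 50)
  a <- classify_frames(mf, ms, hb_f, hb_s, wb_f, wb_s)
  expect_equal(as.character(a$region), "house")
  # moving the midpoint just over the boundary flips it, regardless of size
  mf2 <- data.frame(x = 70.5, y = 50)
  b <- classify_frames(mf2, ms, hb_f, hb_s, wb_f, wb_s)
  expect_equal(as.character(b$region), "outside")
})

test_that("time accumulation is count/FPS and conserves total time", {
  r <- factor(c(rep("house", 15)), levels = c("house", "wheel", "outside", "unknown"))
  tt <- accumulate_times(r, 15)
  expect_equal(tt[["house"]], 1)
  expect_equal(tt[["wheel"]], 0)
  r2 <- factor(rep(c("house", "wheel", "outside"), each = 10),
               levels = levels(r))
  tt2 <- accumulate_times(r2, 15)
  expect_equal(unname(tt2[c("house", "wheel", "outside")]), rep(10 / 15, 3))
  expect_equal(sum(tt2), 30 / 15)
  expect_error(accumulate_times(r, 0), class = "cagetrack_config_error")
})

test_that("outside activity counts only consecutive outside-outside pairs", {
  lv <- c("house", "wheel", "outside", "unknown")
  cls <- data.frame(region = factor(rep("house", 5), levels = lv),
                    x = 1:5, y = 1:5, z = 1:5)
  expect_equal(as.numeric(outside_activity(cls)), 0)
  cls2 <- data.frame(region = factor(c("outside", "outside"), levels = lv),
                     x = c(0, 3), y = c(0, 4), z = c(0, 0))
  expect_equal(as.numeric(outside_activity(cls2)), 5)
  # an interrupting wheel frame breaks the run: no distance across it
  cls3 <- data.frame(region = factor(c("outside", "wheel", "outside"), levels = lv),
                     x = c(0, 3, 6), y = c(0, 4, 8), z = 0)
  expect_equal(as.numeric(outside_activity(cls3)), 0)
  # calibration converts to meters
  cal <- calibration(2, 2, 2)  # 2 mm per px
  expect_equal(as.numeric(outside_activity(cls2, cal)), 10 / 1000)
  expect_identical(attr(outside_activity(cls2, cal), "units"), "m")
})

test_that("outside activity is additive as frames are appended", {
  set.seed(13)
  lv <- c("house", "wheel", "outside", "unknown")
  cls <- data.frame(region = factor(sample(lv[1:3], 300, TRUE), levels = lv),
                    x = cumsum(rnorm(300)), y = cumsum(rnorm(300)), z = cumsum(rnorm(300)))
  acc <- vapply(2:300, function(k)
    as.numeric(outside_activity(cls[1:k, ], mode = "euclidean")), numeric(1))
  expect_true(all(diff(acc) >= -1e-12))   # monotone non-decreasing
})

test_that("running speed implements R / t_wheel with defined degenerate cases", {
  v <- running_speed(450, 900)
  expect_equal(v$rev_per_s, 0.5)
  # 11.5 cm wheel: rim speed = 0.5 * pi * 0.115, verified by hand: 0.180642...
  vd <- running_speed(450, 900, wheel_diameter = 0.115)
  expect_equal(vd$m_per_s, 0.5 * pi * 0.115)
  expect_equal(round(vd$m_per_s, 4), 0.1806)
  z <- running_speed(0, 0)
  expect_equal(z$rev_per_s, 0)
  expect_false(z$undefined)
  u <- running_speed(10, 0)
  expect_true(u$undefined)
  expect_true(is.na(u$rev_per_s))
  expect_error(running_speed(-1, 10), class = "cagetrack_input_error")
  # scale equivariance: doubling revolutions doubles speed
  expect_equal(running_speed(900, 900)$rev_per_s, 2 * running_speed(450, 900)$rev_per_s)
})

test_that("phase segmentation assigns the printed schedules correctly", {
  # 24 hourly probes starting at midnight, probed at half past each hour
  probes_h <- 0:23 + 0.5
  per <- segment_phases(probes_h * 3600, phase_schedule("periods"),
                        session_start_clock = 0)
  expected_per <- rep("NA", 24)
  expected_per[7:9] <- "PRA"        # 06:30-08:30
  expected_per[10:13] <- "FAA"      # 09:30-12:30
  expected_per[14] <- "excluded"    # 13:30 feeding hour
  expected_per[15:18] <- "PA"       # 14:30-17:30
  expect_equal(as.character(per), expected_per)
  ph <- segment_phases(probes_h * 3600, phase_schedule("phases"),
                       session_start_clock = 0)
  expected_ph <- rep("unassigned", 24)
  expected_ph[7:13] <- "Light2"     # 06:30-12:30
  expected_ph[16:18] <- "Light1"    # 15:30-17:30
  expected_ph[c(19:24, 1:6)] <- "Dark"
  expect_equal(as.character(ph), expected_ph)
})

test_that("phase segmentation handles midnight-spanning windows and session offsets", {
  # session starting 3 P.M.: a frame 11 h in is 2 A.M. -> night window
  p <- segment_phases(11 * 3600, phase_schedule("periods"), session_start_clock = 15)
  expect_equal(as.character(p), "NA")
  # boundary conventions: window start is inside, end is not
  expect_equal(as.character(segment_phases(9 * 3600, phase_schedule("periods"), 0)), "FAA")
  expect_equal(as.character(segment_phases(13 * 3600, phase_schedule("periods"), 0)),
               "excluded")
  bad <- data.frame(name = c("A", "B"), start_h = c(1, 2), end_h = c(3, 4),
                    excluded = FALSE)
  expect_error(segment_phases(0, bad, 0), class = "cagetrack_config_error")
})

test_that("aggregated reports satisfy conservation and book revolutions by hour", {
  set.seed(17)
  lv <- c("house", "wheel", "outside", "unknown")
  n <- 3 * 3600 * 5    # 3 h at 5 FPS
  cls <- data.frame(region = factor(sample(lv, n, TRUE, prob = c(.4, .3, .2, .1)),
                                    levels = lv),
                    x = cumsum(rnorm(n)), y = cumsum(rnorm(n)), z = cumsum(rnorm(n)))
  cls$x[cls$region == "unknown"] <- NA
  time_s <- (seq_len(n) - 1) / 5
  phase <- segment_phases(time_s, phase_schedule("periods"), session_start_clock = 8)
  revs <- data.frame(hour_start_clock = c(8, 9, 10), revolutions = c(100, 200, 300))
  rep <- aggregate_report(cls, phase, fps = 5, revolutions = revs)
  sums <- rep$t_house_s + rep$t_wheel_s + rep$t_outside_s + rep$t_unknown_s
  expect_equal(sums, rep$n_frames / 5)
  expect_equal(sum(rep$n_frames[rep$phase != "total"]), n)
  # hours 8 and 9-10 fall in PRA and FAA respectively
  expect_equal(rep$revolutions[rep$phase == "PRA"], 100)
  expect_equal(rep$revolutions[rep$phase == "FAA"], 500)
  expect_equal(rep$revolutions[rep$phase == "total"], 600)
  expect_true(all(rep$empty[rep$n_frames == 0]))
  # speed consistency on the total row
  tot <- rep[rep$phase == "total", ]
  expect_equal(tot$speed_rev_s, tot$revolutions / tot$t_wheel_s)
})

test_that("simulator sessions reproduce ground-truth dwell times in the report", {
  sc <- clean_scenario(seed = 23, duration_s = 900)
  tr <- simulate_session(sc)
  pv <- project_views(tr)
  res <- evaluate_session(pv$front, pv$side,
                          config = eval_config(fps = sc$fps,
                                               session_start_clock = sc$session_start_clock))
  tot <- res$report[res$report$phase == "total", ]
  # transitions can misbook at most one frame each
  n_trans <- sum(diff(as.integer(tr$frames$region)) != 0)
  tol <- (n_trans + 1) / sc$fps
  expect_lt(abs(tot$t_house_s - tr$dwell_s[["house"]]), tol)
  expect_lt(abs(tot$t_wheel_s - tr$dwell_s[["wheel"]]), tol)
  expect_lt(abs(tot$t_outside_s - tr$dwell_s[["outside"]]), tol)
})

test_that("reports serialize to JSON and tidy CSV", {
  lv <- c("house", "wheel", "outside", "unknown")
  cls <- data.frame(region = factor(c("house", "outside"), levels = lv),
                    x = c(1, 2), y = c(1, 2), z = c(1, 2))
  phase <- segment_phases(c(0, 0.5), phase_schedule("phases"), 16)
  rep <- aggregate_report(cls, phase, fps = 2)
  jp <- withr::local_tempfile(fileext = ".json")
  cp <- withr::local_tempfile(fileext = ".csv")
  write_report(rep, jp, "json")
  write_report(rep, cp, "csv")
  back <- jsonlite::read_json(jp)
  expect_equal(length(back$phases), nrow(rep))
  long <- read.csv(cp)
  expect_true(all(c("phase", "metric", "value") %in% names(long)))
  expect_equal(nrow(long), nrow(rep) * 9)
})
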