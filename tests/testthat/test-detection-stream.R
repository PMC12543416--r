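test_that("detection stream CSV round-trips through write and read", {
  df <- rbind(make_stream_df("front", 0:4, "mouse"),
              make_stream_df("front", 0:4, "house", x = 50, y = 60, w = 30, h = 20,
                             confidence = 0.8))
  df <- df[order(df$frame_index), ]
  path <- withr::local_tempfile(fileext = ".csv")
  write_detections(df, path)
  back <- read_detections(path, view = "front")
  expect_equal(back[order(back$frame_index, back$label), ],
               df[order(df$frame_index, df$label), ],
               ignore_attr = TRUE)
})

test_that("malformed rows are rejected with their line numbers", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame_index,timestamp_s,view,label,x,y,w,h,confidence",
               "0,0.0,front,mouse,10,20,4,3,0.9",
               "1,0.066,front,mouse,11,21,-4,3,0.9",   # negative width
               "2,0.133,front,mouse,12,22,4,3,1.7"),   # confidence > 1
             path)
  expect_warning(got <- read_detections(path), "line 3, 4")
  expect_equal(nrow(got), 1)
  expect_equal(got$frame_index, 0)
})

test_that("an empty stream file yields an empty stream with a warning", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("frame_index,timestamp_s,view,label,x,y,w,h,confidence", path)
  expect_warning(got <- read_detections(path), "empty")
  expect_equal(nrow(got), 0)
})

test_that("JSON-lines streams are accepted with identical field names", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  rows <- make_stream_df("side", 0:2)
  writeLines(vapply(seq_len(nrow(rows)), function(i)
    jsonlite::toJSON(as.list(rows[i, ]), auto_unbox = TRUE), character(1)), path)
  got <- read_detections(path, view = "side")
  expect_equal(got$x, rows$x)
  expect_equal(got$label, rows$label)
})

test_that("missing timestamps are derived from the frame index and FPS", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame_index,view,label,x,y,w,h,confidence",
               "0,front,mouse,10,20,4,3,0.9",
               "15,front,mouse,11,21,4,3,0.9"), path)
  got <- read_detections(path, fps = 15)
  expect_equal(got$timestamp_s, c(0, 1))
})

test_that("select_best keeps the stated winner per frame and label", {
  base <- make_stream_df("front", frames = c(0, 0), confidence = c(0.9, 0.5))
  expect_equal(select_best(base)$confidence, 0.9)
  # tie on confidence: larger area wins
  tie <- make_stream_df("front", frames = c(0, 0), w = c(10, 20), h = 10,
                        confidence = 0.8)
  expect_equal(select_best(tie)$w, 20)
  # tie on confidence and area: lowest x wins
  tie2 <- make_stream_df("front", frames = c(0, 0), x = c(30, 10), w = 5, h = 5,
                         confidence = 0.8)
  expect_equal(select_best(tie2)$x, 10)
  expect_equal(nrow(select_best(base[0, ])), 0)
})

test_that("frame pairing matches the latency examples and counts drops", {
  f <- make_stream_df("front", 0:99)
  # identical grids: all paired 1:1
  s0 <- make_stream_df("side", 0:99)
  p0 <- pair_frames(f, s0, tolerance = 0.3)
  expect_equal(nrow(p0$pairs), 100)
  expect_equal(p0$pairs$front_frame, p0$pairs$side_frame)
  expect_equal(p0$n_unmatched_front + p0$n_unmatched_side, 0)
  # 0.2 s shift within the 0.3 s tolerance: fully paired
  s2 <- make_stream_df("side", 0:99, t_offset = 0.2)
  p2 <- pair_frames(f, s2, tolerance = 0.3)
  expect_equal(nrow(p2$pairs), 100)
  expect_true(all(abs(p2$pairs$dt) <= 0.3))
  # 1.0 s shift beyond tolerance: nothing pairs
  s10 <- make_stream_df("side", 0:99, t_offset = 100)
  p10 <- pair_frames(f, s10, tolerance = 0.3)
  expect_equal(nrow(p10$pairs), 0)
  expect_equal(p10$n_unmatched_front, 100)
  expect_equal(p10$n_unmatched_side, 100)
  expect_error(pair_frames(f, s0, tolerance = 0), class = "cagetrack_config_error")
})

test_that("pairing never exceeds the shorter stream and respects tolerance", {
  set.seed(5)
  for (i in 1:20) {
    nf <- sample(5:40, 1); ns <- sample(5:40, 1)
    f <- data.frame(frame_index = seq_len(nf) - 1,
                    timestamp_s = sort(runif(nf, 0, 10)))
    s <- data.frame(frame_index = seq_len(ns) - 1,
                    timestamp_s = sort(runif(ns, 0, 10)))
    p <- pair_frames(f, s, tolerance = 0.25)
    expect_lte(nrow(p$pairs), min(nf, ns))
    if (nrow(p$pairs)) expect_true(all(abs(p$pairs$dt) <= 0.25))
    expect_false(any(duplicated(p$pairs$side_frame)))
  }
})

test_that("hold-last gap filling repeats the last known position", {
  tr <- data.frame(frame_index = 0:2, x = c(5, NA, 9), y = c(6, NA, 10))
  got <- fill_gaps(tr, "hold_last", max_gap = 30)
  expect_equal(got$x, c(5, 5, 9))
  expect_equal(got$y, c(6, 6, 10))
  expect_equal(attr(got, "gap_report")$n_interpolated, 1)
})

test_that("linear gap filling interpolates between flanking positions", {
  tr <- data.frame(frame_index = 0:2, x = c(0, NA, 2), y = c(0, NA, 2))
  got <- fill_gaps(tr, "linear", max_gap = 30)
  expect_equal(got$x[2], 1)
  expect_equal(got$y[2], 1)
})

test_that("gaps longer than max_gap stay unknown and are reported", {
  n <- 60
  x <- rep(NA_real_, n); x[c(1, 52:60)] <- 1:10
  tr <- data.frame(frame_index = seq_len(n) - 1, x = x, y = x)
  got <- fill_gaps(tr, "hold_last", max_gap = 30)
  expect_equal(sum(is.na(got$x)), 50)   # the 50-frame gap exceeds the cap
  expect_equal(attr(got, "gap_report")$n_unknown, 50)
  expect_equal(attr(got, "gap_report")$n_missing_mouse, 50)
})

test_that("gap filling never alters observed frames; hold-last reuses observations", {
  set.seed(9)
  n <- 200
  x <- runif(n); y <- runif(n)
  miss <- runif(n) < 0.3
  x[miss] <- NA; y[miss] <- NA
  x[1] <- 0.5; y[1] <- 0.5
  tr <- data.frame(frame_index = seq_len(n) - 1, x = x, y = y)
  got <- fill_gaps(tr, "hold_last", max_gap = 10)
  expect_equal(got$x[!miss], x[!miss])
  expect_equal(got$y[!miss], y[!miss])
  filled_vals <- got$x[miss & !is.na(got$x)]
  expect_true(all(filled_vals %in% x[!miss]))   # positions are observed ones
  expect_error(fill_gaps(data.frame(frame_index = 0:1, x = NA_real_, y = NA_real_)),
               class = "cagetrack_input_error")
})

test_that("leading gaps are back-filled from the first known position", {
  tr <- data.frame(frame_index = 0:4, x = c(NA, NA, 3, NA, 5), y = c(NA, NA, 4, NA, 6))
  got <- fill_gaps(tr, "hold_last", max_gap = 10)
  expect_equal(got$x, c(3, 3, 3, 3, 5))
  got_lin <- fill_gaps(tr, "linear", max_gap = 10)
  expect_equal(got_lin$x, c(3, 3, 3, 4, 5))
})

test_that("static boxes forward-fill without a cap and error when never seen", {
  b <- data.frame(x = c(NA, 10, NA, NA, NA, NA), y = c(NA, 2, NA, NA, NA, NA),
                  w = c(NA, 30, NA, NA, NA, NA), h = c(NA, 20, NA, NA, NA, NA))
  got <- fill_static_boxes(b, "house")
  expect_equal(got$x, c(10, 10, 10, 10, 10, 10))
  empty <- data.frame(x = NA_real_, y = NA_real_, w = NA_real_, h = NA_real_)
  expect_error(fill_static_boxes(empty, "wheel"), class = "cagetrack_config_error")
})
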