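# Shared fixtures built in code.

# A tiny, fully deterministic detection stream in the standard schema.
make_stream_df <- function(view = "front", frames = 0:2, label = "mouse",
                           x = 10 + frames, y = 20 + frames, w = 4, h = 3,
                           confidence = 0.9, fps = 15, t_offset = 0) {
  data.frame(frame_index = frames, timestamp_s = frames / fps + t_offset,
             view = view, label = label, x = x, y = y, w = w, h = h,
             confidence = confidence)
}

# Zero-corruption small scenario used by several suites.
clean_scenario <- function(seed = 42, duration_s = 600, fps = 15, ...) {
  sim_scenario(seed = seed, duration_s = duration_s, fps = fps,
               miss_prob = 0, jitter_sd_px = 0, latency_offset_s = 0,
               false_box_rate = 0, wheel_noise_sd = 0, ...)
}

# Independent brute-force oracle for path length: explicit pairwise loop.
brute_force_path <- function(traj, squared = FALSE) {
  tot <- 0
  for (i in seq_len(nrow(traj) - 1)) {
    d2 <- (traj$x[i + 1] - traj$x[i])^2 + (traj$y[i + 1] - traj$y[i])^2 +
      (traj$z[i + 1] - traj$z[i])^2
    tot <- tot + if (squared) d2 else sqrt(d2)
  }
  tot
}
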