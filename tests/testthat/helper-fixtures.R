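# shared fixture builders for the test suite

# frame_sequence from a T x (H*W) row-major matrix of values
seq_from_rows <- function(rows, h, w, fs = 40, peep = 0, subject = "t") {
  tt <- nrow(rows)
  frames <- array(NA_real_, c(tt, h, w))
  for (t in seq_len(tt)) frames[t, , ] <- matrix(rows[t, ], h, w, byrow = TRUE)
  frame_sequence(frames, fs, subject, peep)
}

random_seq <- function(tt, h, w, fs = 40, peep = 0, seed = 1) {
  set.seed(seed)
  frame_sequence(array(rnorm(tt * h * w), c(tt, h, w)), fs, "t", peep)
}

# small, fast phantom for unit tests: 16x16 grid, 3 PEEP-step subsets
small_phantom_config <- function(peep_levels = seq(0, 30, by = 3),
                                 noise_sd = 0, seed = 7,
                                 step_duration_s = 16) {
  phantom_config(height = 16, width = 16, peep_levels = peep_levels,
                 noise_sd = noise_sd, seed = seed,
                 step_duration_s = step_duration_s)
}

# raised sinusoid breathing signal in [0, 1]
breathing_signal <- function(duration_s, fs = 40, rr_bpm = 30, amp = 1,
                             offset = 0) {
  t <- (seq_len(round(duration_s * fs)) - 1) / fs
  offset + amp * 0.5 * (1 - cos(2 * pi * (rr_bpm / 60) * t))
}
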