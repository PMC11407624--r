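tone_recording <- function(freqs, amps, fs = 500, dur = 10) {
  t <- (0:(dur * fs - 1)) / fs
  x <- rowSums(vapply(seq_along(freqs),
                      function(i) amps[i] * sin(2 * pi * freqs[i] * t),
                      numeric(length(t))))
  ev <- data.frame(onset = 3L * fs, trial_id = 1L, frequency = freqs[1])
  eeg_recording(matrix(x, 1), fs, "Oz", ev)
}

test_that("filtering notches the powerline and preserves the SSVEP band", {
  rec60 <- tone_recording(60, 1)
  out60 <- filter_recording(rec60)$data[1, ]
  mid <- 1001:4000                       # avoid filtfilt edge transients
  atten_db <- 20 * log10(stats::sd(rec60$data[1, mid]) /
                         stats::sd(out60[mid]))
  expect_gt(atten_db, 30)

  rec10 <- tone_recording(10, 1)
  out10 <- filter_recording(rec10)$data[1, ]
  expect_lt(abs(stats::sd(out10[mid]) / stats::sd(rec10$data[1, mid]) - 1),
            0.05)

  recdc <- tone_recording(0.0001, 0)     # constant zero + offset
  recdc$data[1, ] <- 5
  outdc <- filter_recording(recdc)$data[1, ]
  expect_lt(max(abs(outdc[mid])), 1e-6)

  expect_equal(length(out60), ncol(rec60$data))  # length preserved
  expect_error(filter_recording(eeg_recording(matrix(0, 1, 500), 100)),
               "too low")
})

test_that("segmentation windows follow the stated convention", {
  fs <- 500
  rec <- eeg_recording(matrix(seq_len(8000), 1), fs, "Oz",
                       data.frame(onset = 5000L, trial_id = 1L,
                                  frequency = 10))
  seg <- segment_trials(rec, 5)[[1]]
  # 0-based onset 5000 -> idle samples [3500, 5000), stim [5000, 7500)
  expect_equal(seg$idle[1, ], 3501:5000)
  expect_equal(seg$stim[1, ], 5001:7500)
  expect_equal(ncol(seg$idle), 3 * fs)
  expect_equal(ncol(seg$stim), 5 * fs)

  early <- eeg_recording(matrix(0, 1, 8000), fs, "Oz",
                         data.frame(onset = 100L, trial_id = 1L,
                                    frequency = 10))
  expect_error(segment_trials(early, 5), "history|surrounding")

  mixed <- eeg_recording(matrix(0, 1, 8000), fs, "Oz",
                         data.frame(onset = c(100L, 5000L),
                                    trial_id = 1:2,
                                    frequency = c(10, 10)))
  expect_warning(segs <- segment_trials(mixed, 5), "skipping trial")
  expect_length(segs, 1)
  expect_equal(segs[[1]]$trial_id, 2)

  rec20 <- cached_session()$recording
  expect_length(segment_trials(rec20, 5), 20)
})

test_that("filtering and segmenting commute on interior samples", {
  cfg <- sim_config()
  rec <- generate_session(cfg, 1, seed = 3)
  seg_after <- segment_trials(filter_recording(rec), 5)[[1]]
  raw_seg <- segment_trials(rec, 5)[[1]]
  # filter the raw stimulation window in isolation
  stim_rec <- eeg_recording(raw_seg$stim, cfg$fs, cfg$channel_labels,
                            empty_events())
  seg_only <- filter_recording(stim_rec)$data
  n <- ncol(seg_only)
  core <- (round(0.1 * n) + 1):round(0.9 * n)
  scale <- stats::sd(seg_after$stim[, core])
  expect_lt(max(abs(seg_after$stim[, core] - seg_only[, core])) / scale,
            0.05)
})

test_that("channel selection recovers the boosted channels", {
  sess <- cached_session()
  sel <- select_channels(sess$segments)
  expect_setequal(sel$selected, posterior_channels)
  expect_true(all(sel$table$p_value[match(sel$selected,
                                          sel$table$channel)] < 0.01))
  expect_lte(length(sel$selected), 8)

  expect_error(select_channels(sess$segments[1]), "at least 2")
  expect_warning(select_channels(sess$segments[1:3]), "unstable")
})

test_that("channel selection is invariant to channel order", {
  sess <- cached_session()
  perm <- c(9:16, 1:8)
  segs_perm <- lapply(sess$segments, function(s) {
    s$idle <- s$idle[perm, ]
    s$stim <- s$stim[perm, ]
    s
  })
  sel1 <- select_channels(sess$segments)
  sel2 <- select_channels(segs_perm)
  expect_setequal(sel1$selected, sel2$selected)
})

test_that("uniformly boosted channels are all significant, top-8 kept", {
  gains <- stats::setNames(rep(1, 16), default_channels)
  cfg <- sim_config(channel_gain_map = gains, ssvep_amplitude = 4,
                    alpha_amplitude = 0)
  rec <- generate_session(cfg, 8, seed = 61)
  segs <- segment_trials(filter_recording(rec), 5)
  sel <- select_channels(segs)
  expect_true(all(sel$table$p_value < 0.01))
  expect_length(sel$selected, 8)
})

test_that("per-channel false-positive rate matches the nominal level", {
  # amplitude 0: stimulation and idle windows share the same law, so each
  # channel's one-sided test should reject at about the nominal 1% rate
  n_runs <- 25
  cfg <- sim_config(ssvep_amplitude = 0)
  hits <- 0
  total <- 0
  for (r in seq_len(n_runs)) {
    rec <- generate_session(cfg, 3, seed = 700 + r)
    segs <- segment_trials(filter_recording(rec), 5)
    sel <- select_channels(segs)
    hits <- hits + sum(sel$table$p_value < 0.01)
    total <- total + nrow(sel$table)
  }
  # 99% binomial upper bound for 400 tests at p = 0.01
  expect_lte(hits, stats::qbinom(0.995, total, 0.01) + 2)
})
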