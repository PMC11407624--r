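# published frame-based duty cycles of the four target frequencies at
# 60 fps: on/off split -> rounded percentage, by bin
table2 <- list(
  "6.67" = list(frames = 9,
                bins = list(c(2, 7, 22), c(3, 6, 33), c(5, 4, 56),
                            c(6, 3, 67))),
  "7.5" = list(frames = 8,
               bins = list(c(2, 6, 25), c(3, 5, 38), c(4, 4, 50),
                           c(5, 3, 63))),
  "8.57" = list(frames = 7,
                bins = list(c(1, 6, 14), c(2, 5, 29), c(4, 3, 57),
                            c(5, 2, 71))),
  "10" = list(frames = 6,
              bins = list(c(1, 5, 17), c(2, 4, 33), c(3, 3, 50),
                          c(4, 2, 67)))
)

test_that("duty-cycle enumeration reproduces the published table", {
  for (fstr in names(table2)) {
    f <- as.numeric(fstr)
    pats <- enumerate_duty_bins(f, 60)
    expect_length(pats, table2[[fstr]]$frames - 1)
    binned <- Filter(function(p) !is.na(p$bin_label), pats)
    expect_length(binned, 4)
    got <- lapply(binned, function(p) c(p$on_frames, p$off_frames,
                                        p$duty_cycle_pct))
    expect_equal(got, table2[[fstr]]$bins)
    # bin labels come out in ascending duty order
    expect_equal(vapply(binned, `[[`, character(1), "bin_label"),
                 names(duty_cycle_bins))
  }
})

test_that("flicker patterns satisfy their structural invariants", {
  for (f in c(6.67, 7.5, 8.57, 10, 15, 30)) {
    for (p in enumerate_duty_bins(f, 60)) {
      expect_equal(p$on_frames + p$off_frames, p$frames_per_cycle)
      expect_equal(sum(p$frame_sequence), p$on_frames)
      # ON frames lead the cycle
      expect_equal(p$frame_sequence[seq_len(p$on_frames)],
                   rep(1L, p$on_frames))
      expect_equal(p$duty_cycle_pct,
                   floor(100 * p$on_frames / p$frames_per_cycle + 0.5))
    }
  }
})

test_that("design_frame_pattern picks the split inside the requested bin", {
  p <- design_frame_pattern(6.67, 60, "45-57")
  expect_equal(c(p$on_frames, p$off_frames, p$duty_cycle_pct), c(5, 4, 56))
  p <- design_frame_pattern(10, 60, "45-57")
  expect_equal(c(p$on_frames, p$off_frames, p$duty_cycle_pct), c(3, 3, 50))
  p <- design_frame_pattern(15, 60, "45-57")
  expect_equal(c(p$on_frames, p$off_frames, p$duty_cycle_pct), c(2, 2, 50))

  # 30 Hz at 60 fps has the single split 1/1 -> 50%, so low bins are empty
  expect_length(enumerate_duty_bins(30, 60), 1)
  expect_error(design_frame_pattern(30, 60, "14-25"), "no frame-based")
  # 11 Hz does not divide 60 fps
  expect_error(enumerate_duty_bins(11, 60), "not realizable")
  expect_error(enumerate_duty_bins(60, 60), "no ON/OFF split")
})

test_that("square-wave harmonics match a dense-FFT oracle", {
  M <- 65536
  for (d in seq(0.1, 0.9, by = 0.1)) {
    on <- round(d * M)
    deff <- on / M                     # exactly representable duty
    x <- c(rep(1, on), rep(0, M - on))
    oracle <- 2 * abs(stats::fft(x))[2:13] / M
    sp <- square_wave_spectrum(deff, 12)
    expect_lt(max(abs(sp$harmonic_coefficients - oracle)) / max(oracle),
              1e-6)
    expect_equal(sp$dc_term, deff)
  }
})

test_that("square-wave spectrum has the analytic degeneracies", {
  sp <- square_wave_spectrum(0.5, 8)
  expect_equal(sp$harmonic_coefficients[c(2, 4, 6, 8)], rep(0, 4),
               tolerance = 1e-12)
  expect_gt(min(sp$harmonic_coefficients[c(1, 3, 5, 7)]), 0)
  expect_equal(sp$offset, 0)           # 50% duty: symmetric waveform

  sp1 <- square_wave_spectrum(1, 8)
  expect_equal(sp1$harmonic_coefficients, rep(0, 8), tolerance = 1e-12)
  expect_equal(sp1$dc_term, 1)

  sp25 <- square_wave_spectrum(0.25, 8)
  expect_equal(sp25$harmonic_coefficients[c(4, 8)], rep(0, 2),
               tolerance = 1e-12)

  expect_error(square_wave_spectrum(0, 4), "duty_cycle")
  expect_error(square_wave_spectrum(1.2, 4), "duty_cycle")
})

test_that("visual angles match the printed icon geometry", {
  # icon areas 5.06/20.25/36/81 cm^2 viewed from 95 cm
  printed <- c("5.06" = 1.35, "20.25" = 2.69, "36" = 3.6, "81" = 5.38)
  for (a in names(printed)) {
    expect_lt(abs(icon_visual_angle(as.numeric(a), 95) - printed[[a]]),
              0.04)
  }
  expect_equal(round(icon_visual_angle(36, 95), 1), 3.6)
  expect_equal(visual_angle(0, 95), 0)
  expect_equal(visual_angle(95, 95), 45)
})

test_that("visual angle is monotone in size and distance", {
  sizes <- seq(0.5, 30, length.out = 40)
  angles <- visual_angle(sizes, 95)
  expect_true(all(diff(angles) > 0))
  dists <- seq(40, 300, length.out = 40)
  expect_true(all(diff(visual_angle(6, dists)) < 0))
  expect_error(visual_angle(6, 0), "positive")
  expect_error(visual_angle(-1, 95), "non-negative")
})

test_that("stimulus layout derives eccentricities from the offsets", {
  lay <- stimulus_layout(95, c(music = 7, navigation = 2,
                               settings = 2, temperature = 7), 20.25)
  expect_equal(lay$icon_side, 4.5)
  expect_equal(unname(lay$eccentricity_deg),
               visual_angle(c(7, 2, 2, 7), 95))
  expect_true(all(lay$eccentricity_deg >= 0))
})

test_that("stimulus SNR recovers injected power ratios within 2 dB", {
  fs <- 1000
  nper <- 4 * fs
  t <- (0:(24 * fs - 1)) / fs
  for (target_db in c(30, 70)) {
    errs <- vapply(1:20, function(s) {
      set.seed(s)
      noise <- stats::rnorm(24 * fs)
      # on-bin tone whose bin power is 10^(dB/10) times the mean noise bin
      A <- sqrt(4 * 10^(target_db / 10) / nper)
      x <- A * sin(2 * pi * 10 * t) + 0.3 * A * sin(2 * pi * 20 * t) + noise
      stimulus_snr(x, fs, 10)$fundamental_snr_db - target_db
    }, numeric(1))
    expect_lt(max(abs(errs)), 2)
  }
})

test_that("stimulus SNR handles degenerate traces", {
  fs <- 500
  t <- (0:(8 * fs - 1)) / fs
  pure <- sin(2 * pi * 10 * t)
  rep <- stimulus_snr(pure, fs, 10)
  expect_equal(rep$fundamental_snr_db, 200)  # documented ceiling
  expect_equal(rep$classification, "high")

  set.seed(1)
  # tone bin power equal to the mean noise bin power -> about 0 dB
  noise <- stats::rnorm(24 * 500)
  A <- sqrt(4 / (4 * 500))
  x <- A * sin(2 * pi * 10 * (0:(24 * 500 - 1)) / 500) + noise
  r0 <- stimulus_snr(x, 500, 10)
  # the target bin holds tone + noise, so the estimate sits near
  # 10*log10(2) when the two powers are equal
  expect_lt(abs(r0$fundamental_snr_db), 6)
  expect_equal(r0$classification, "low")

  expect_error(stimulus_snr(stats::rnorm(500), 500, 10), "4 s")
  expect_error(stimulus_snr(stats::rnorm(5000), 500, 200), "Nyquist|too low")
})
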