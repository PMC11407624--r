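test_that("Welch spectrum localizes tones and conserves power", {
  fs <- 500
  t <- (0:(5 * fs - 1)) / fs
  psd <- welch_psd(sin(2 * pi * 10 * t), fs)
  expect_equal(psd$df, 0.25)
  expect_equal(psd$freq[which.max(psd$power[1, ])], 10)

  set.seed(1)
  x <- stats::rnorm(10 * fs)
  psd <- welch_psd(x, fs)
  # flat within sampling error: compare low/high band means
  lo <- mean(psd$power[1, psd$freq > 10 & psd$freq < 50])
  hi <- mean(psd$power[1, psd$freq > 150 & psd$freq < 240])
  expect_lt(abs(lo / hi - 1), 0.1)
  # Parseval: integrated density matches time-domain variance
  expect_lt(abs(sum(psd$power[1, ]) * psd$df / stats::var(x) - 1), 0.05)

  expect_error(welch_psd(x[1:400], fs), "segment")
})

test_that("the SSVEP SNR statistic matches direct arithmetic", {
  freq <- seq(0, 30, by = 0.25)
  # flat spectrum: each term is exactly 1
  flat <- list(freq = freq, power = matrix(1, 1, length(freq)), df = 0.25)
  expect_identical(ssvep_snr(flat, 8)$snr, 2)

  set.seed(42)
  p <- stats::runif(length(freq), 0.5, 2)
  psd <- list(freq = freq, power = matrix(p, 1), df = 0.25)
  # hand-indexed oracle: f = 8 Hz -> bin 33, 2f -> bin 65 (1-based)
  expected <- 6 * p[33] / sum(p[c(30, 31, 32, 34, 35, 36)]) +
    6 * p[65] / sum(p[c(62, 63, 64, 66, 67, 68)])
  expect_equal(ssvep_snr(psd, 8)$snr, expected, tolerance = 1e-9)

  # line spectrum with empty neighbourhood hits the documented cap
  line <- rep(0, length(freq))
  line[c(33, 65)] <- 5
  capped <- ssvep_snr(list(freq = freq, power = matrix(line, 1),
                           df = 0.25), 8)
  expect_true(is.finite(capped$snr))
  expect_equal(capped$snr, 2e6)

  expect_error(ssvep_snr(flat, 14.8), "edge")
})

test_that("reference templates have the stated structure", {
  tpl <- build_reference(10, 3, 2500, 500)
  expect_equal(dim(tpl$matrix), c(6, 2500))
  t <- seq_len(2500) / 500
  expect_equal(tpl$matrix[1, ], sin(2 * pi * 10 * t))
  expect_equal(tpl$matrix[6, ], cos(2 * pi * 30 * t))
  # over integer cycles the rows are pairwise orthogonal
  g <- tcrossprod(tpl$matrix)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-6 * 2500)

  expect_equal(nrow(build_reference(10, 1, 1000, 500)$matrix), 2)
  expect_error(build_reference(10, 30, 1000, 500), "Nyquist")
})

test_that("canonical correlation behaves on known inputs", {
  tpl <- build_reference(8.57, 3, 2500, 500)
  expect_equal(cca_correlate(tpl$matrix, tpl), 1, tolerance = 1e-9)

  t <- seq_len(2500) / 500
  x <- matrix(sin(2 * pi * 8.57 * t + 0.7), 1)
  expect_gt(cca_correlate(x, tpl), 0.99)

  # independent cross-check against the reference CCA implementation
  set.seed(5)
  X <- matrix(stats::rnorm(8 * 600), 8)
  rho_pkg <- cca_correlate(X, tpl$matrix[, 1:600])
  rho_ref <- stats::cancor(t(X), t(tpl$matrix[, 1:600]))$cor[1]
  expect_equal(rho_pkg, rho_ref, tolerance = 1e-8)

  expect_error(cca_correlate(X, tpl$matrix[, 1:500]), "same number")
  expect_error(cca_correlate(X[, 1:10], tpl$matrix[, 1:10]), "few samples")
  expect_warning(cca_correlate(rbind(X, X[1, ]), tpl$matrix[, 1:600]),
                 "rank-deficient")
})

test_that("canonical correlation is invariant to per-channel affine maps", {
  set.seed(8)
  X <- matrix(stats::rnorm(6 * 800), 6)
  tpl <- build_reference(10, 2, 800, 500)
  rho <- cca_correlate(X, tpl)
  Xa <- sweep(sweep(X, 1, c(2, 0.5, 3, 10, 0.1, 7), "*"),
              1, c(-1, 4, 0, 2, 5, -3), "+")
  expect_equal(cca_correlate(Xa, tpl), rho, tolerance = 1e-8)
})

test_that("classification picks the argmax with low-frequency tie-break", {
  fs <- 500
  t <- seq_len(2500) / fs
  cands <- c(6.67, 7.5, 8.57, 10)
  # a clean 8.57 Hz trial embedded in mild noise
  set.seed(2)
  stim <- matrix(rep(sin(2 * pi * 8.57 * t), 4), 4, byrow = TRUE) +
    0.05 * matrix(stats::rnorm(4 * 2500), 4)
  rownames(stim) <- c("O1", "Oz", "O2", "POz")
  seg <- make_segment(stim, fs = fs, frequency = 8.57)
  res <- classify_cca(list(seg), cands, 5)
  expect_equal(res$detected_frequency, 8.57)
  expect_equal(res$true_frequency, 8.57)
  expect_named(res, c("trial_id", "block", "true_frequency",
                      "detected_frequency", "method", "window_length",
                      paste0("score_", cands)))

  # tie-break: equal scores resolve to the lowest candidate
  expect_equal(ssvepbmi:::argmax_frequency(matrix(c(1, 1, 1, 1), 1), cands),
               6.67)
  expect_equal(ssvepbmi:::argmax_frequency(
    matrix(c(0.2, 0.9, 0.3, 0.1), 1), cands), 7.5)

  expect_error(classify_cca(list(seg), cands, 6), "exceeds")
})

test_that("filter bank configuration implements the weight rule", {
  bank <- filter_bank_config()
  expect_equal(bank$weights[1], 1.25)            # 1^-1.25 + 0.25
  expect_equal(bank$weights, (1:5)^(-1.25) + 0.25)
  expect_equal(bank$starts, c(6, 12, 18, 24, 30))
  expect_error(filter_bank_config(n_subbands = 8, k = 6), "upper edge")
})

test_that("a single full-band subband reduces FBCCA to plain CCA", {
  cfg <- sim_config(ssvep_amplitude = 4)
  rec <- generate_session(cfg, 2, seed = 90)
  segs <- segment_trials(filter_recording(rec), 5)
  cands <- cfg$target_frequencies
  bank1 <- filter_bank_config(n_subbands = 1, k = 4, f_max = 40,
                              margin = 2)
  rc <- classify_cca(segs, cands, 3, channels = posterior_channels)
  rf <- fbcca_classify(segs, cands, 3, bank = bank1,
                       channels = posterior_channels)
  # with a single weight-dominant full-band subband the ranking of the
  # (squared) correlations matches plain CCA on every trial
  expect_equal(rf$detected_frequency, rc$detected_frequency)
  sc <- as.matrix(rc[, paste0("score_", cands)])
  sf <- as.matrix(rf[, paste0("score_", cands)])
  expect_gt(stats::cor(sqrt(as.vector(sf)), as.vector(sc)), 0.95)
})
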