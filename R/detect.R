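#' Sinusoidal reference template for CCA frequency recognition
#'
#' Builds the 2*Nh x N matrix of sine/cosine pairs at the fundamental and
#' harmonics of a candidate frequency, sampled at `t = 1/fs, 2/fs, ...,
#' N/fs`.
#'
#' @param f candidate frequency, Hz.
#' @param Nh number of harmonics (default 3: fundamental, 2nd, 3rd).
#' @param N number of samples.
#' @param fs sampling rate, Hz; `Nh * f` must be below Nyquist.
#' @return A `reference_template`: list with `f`, `Nh`, `N`, `fs` and
#'   `matrix` (rows sin(2*pi*n*f*t), cos(2*pi*n*f*t) for n = 1..Nh).
#' @export
build_reference <- function(f, Nh = 3, N, fs) {
  if (Nh * f >= fs / 2) {
    stop("harmonic ", Nh, " of ", f, " Hz exceeds the Nyquist rate",
         call. = FALSE)
  }
  t <- seq_len(N) / fs
  rows <- lapply(seq_len(Nh), function(n) {
    rbind(sin(2 * pi * n * f * t), cos(2 * pi * n * f * t))
  })
  structure(
    list(f = f, Nh = Nh, N = N, fs = fs, matrix = do.call(rbind, rows)),
    class = "reference_template"
  )
}

#' Largest canonical correlation between an EEG window and a template
#'
#' Centers both variable sets, orthonormalizes them by QR decomposition
#' and takes the largest singular value of the cross-product of the Q
#' bases -- the first canonical correlation. Rank-deficient inputs fall
#' back to their effective rank with a warning.
#'
#' @param eeg_window channels x samples matrix.
#' @param template a [build_reference()] template (or a plain matrix with
#'   the same orientation) with matching sample count.
#' @return The first canonical correlation, in `[0, 1]`.
#' @export
cca_correlate <- function(eeg_window, template) {
  Y <- if (inherits(template, "reference_template")) template$matrix
       else template
  if (ncol(eeg_window) != ncol(Y)) {
    stop("EEG window and template must have the same number of samples",
         call. = FALSE)
  }
  if (ncol(eeg_window) <= nrow(eeg_window) + nrow(Y)) {
    stop("too few samples for the joint dimensionality of the two sets",
         call. = FALSE)
  }
  first_canonical_correlation(t(eeg_window), t(Y))
}

first_canonical_correlation <- function(X, Y) {
  X <- scale(X, center = TRUE, scale = FALSE)
  Y <- scale(Y, center = TRUE, scale = FALSE)
  qx <- qr(X)
  qy <- qr(Y)
  if (qx$rank < ncol(X) || qy$rank < ncol(Y)) {
    warning("rank-deficient input to CCA; using effective rank",
            call. = FALSE)
  }
  Qx <- qr.Q(qx)[, seq_len(max(qx$rank, 1)), drop = FALSE]
  Qy <- qr.Q(qy)[, seq_len(max(qy$rank, 1)), drop = FALSE]
  d <- svd(crossprod(Qx, Qy), nu = 0, nv = 0)$d
  min(max(d[1], 0), 1)
}

# scores matrix (trials x candidates) -> detected frequency with ties
# broken toward the lowest candidate
argmax_frequency <- function(scores, candidates) {
  apply(scores, 1, function(s) {
    best <- which(s == max(s))
    candidates[min(best)]
  })
}

detection_result <- function(segments, scores, candidates, method,
                             window_length) {
  stopifnot(all(is.finite(scores)))
  colnames(scores) <- paste0("score_", candidates)
  data.frame(
    trial_id = vapply(segments, `[[`, numeric(1), "trial_id"),
    block = vapply(segments, `[[`, numeric(1), "block"),
    true_frequency = vapply(segments, `[[`, numeric(1), "frequency"),
    detected_frequency = argmax_frequency(scores, candidates),
    method = method,
    window_length = window_length,
    scores,
    row.names = NULL
  )
}

crop_window <- function(seg, window_length) {
  n <- round(window_length * seg$fs)
  if (n > ncol(seg$stim)) {
    stop("window_length exceeds the stimulation window", call. = FALSE)
  }
  seg$stim[, seq_len(n), drop = FALSE]
}

subset_channels <- function(x, channels) {
  if (is.null(channels)) return(x)
  if (inherits(channels, "channel_selection")) channels <- channels$selected
  x[channels, , drop = FALSE]
}

#' Classify trials by standard CCA frequency recognition
#'
#' For each trial, computes the first canonical correlation between the
#' stimulation window (cropped to `window_length`) and the sinusoidal
#' reference template of every candidate frequency; the candidate with
#' the highest correlation is the detected frequency, ties broken toward
#' the lowest candidate.
#'
#' @param segments list of `trial_segment`s.
#' @param candidate_frequencies candidate frequencies in Hz.
#' @param window_length analysis window in seconds (from onset).
#' @param Nh harmonics in the reference templates (default 3).
#' @param channels optional channel labels/indices (or a
#'   [select_channels()] result) to restrict the analysis to.
#' @return A data.frame with one row per trial: ids, true and detected
#'   frequency, method, window length and the per-candidate scores.
#' @export
classify_cca <- function(segments, candidate_frequencies, window_length,
                         Nh = 3, channels = NULL) {
  fs <- segments[[1]]$fs
  N <- round(window_length * fs)
  templates <- lapply(candidate_frequencies, build_reference,
                      Nh = Nh, N = N, fs = fs)
  scores <- t(vapply(segments, function(seg) {
    X <- subset_channels(crop_window(seg, window_length), channels)
    vapply(templates, function(tpl) cca_correlate(X, tpl), numeric(1))
  }, numeric(length(candidate_frequencies))))
  detection_result(segments, scores, candidate_frequencies, "cca",
                   window_length)
}

#' Classify trials by spectral SSVEP SNR (PSDA)
#'
#' Scores each candidate frequency by the mean SSVEP SNR statistic over
#' the analysis channels of the trial's stimulation window and detects
#' the candidate with the highest SNR.
#'
#' @inheritParams classify_cca
#' @export
classify_psda <- function(segments, candidate_frequencies, window_length,
                          channels = NULL) {
  scores <- t(vapply(segments, function(seg) {
    X <- subset_channels(crop_window(seg, window_length), channels)
    psd <- welch_psd(X, seg$fs)
    vapply(candidate_frequencies,
           function(f) ssvep_snr(psd, f)$snr, numeric(1))
  }, numeric(length(candidate_frequencies))))
  detection_result(segments, scores, candidate_frequencies, "psda",
                   window_length)
}

#' Filter-bank configuration for FBCCA
#'
#' The n-th subband passes `n * k` Hz up to a common upper edge, with a
#' transition margin added to both sides of each passband when the
#' zero-phase Chebyshev Type I band-passes are designed. Subband scores
#' are combined with weights `w(n) = n^-a + b`.
#'
#' @param n_subbands number of subbands (default 5).
#' @param k start spacing in Hz (default 6; subband n starts at `n * k`).
#' @param f_max common upper passband edge, Hz (default 40).
#' @param margin transition bandwidth added to both sides, Hz (default 2).
#' @param a,b weight parameters (defaults 1.25 and 0.25).
#' @param ripple_db passband ripple of the Chebyshev design (default 0.5).
#' @param order Chebyshev prototype order (default 4).
#' @return A `filter_bank_config` list, including the `weights` vector.
#' @export
filter_bank_config <- function(n_subbands = 5, k = 6, f_max = 40,
                               margin = 2, a = 1.25, b = 0.25,
                               ripple_db = 0.5, order = 4) {
  starts <- seq_len(n_subbands) * k
  if (any(starts >= f_max)) {
    stop("subband start frequencies must stay below the upper edge ",
         f_max, " Hz", call. = FALSE)
  }
  structure(
    list(n_subbands = n_subbands, k = k, f_max = f_max, margin = margin,
         starts = starts, weights = seq_len(n_subbands)^(-a) + b,
         a = a, b = b, ripple_db = ripple_db, order = order),
    class = "filter_bank_config"
  )
}

bank_filters <- function(bank, fs) {
  nyq <- fs / 2
  lapply(bank$starts, function(lo) {
    edges <- c(max(lo - bank$margin, 1), min(bank$f_max + bank$margin,
                                             nyq - 1))
    if (edges[1] >= edges[2]) {
      stop("invalid filter bank for sampling rate ", fs, " Hz",
           call. = FALSE)
    }
    signal::cheby1(bank$order, bank$ripple_db, edges / nyq, type = "pass")
  })
}

#' Classify trials by filter-bank CCA
#'
#' Decomposes each stimulation window into subbands with zero-phase
#' Chebyshev Type I band-passes, runs CCA per subband against each
#' candidate template, and combines the subband correlations as the
#' weighted sum of their squares; the candidate with the largest combined
#' score is detected.
#'
#' @inheritParams classify_cca
#' @param bank a [filter_bank_config()].
#' @export
fbcca_classify <- function(segments, candidate_frequencies, window_length,
                           bank = filter_bank_config(), Nh = 3,
                           channels = NULL) {
  fs <- segments[[1]]$fs
  N <- round(window_length * fs)
  templates <- lapply(candidate_frequencies, build_reference,
                      Nh = Nh, N = N, fs = fs)
  filters <- bank_filters(bank, fs)
  scores <- t(vapply(segments, function(seg) {
    X <- subset_channels(crop_window(seg, window_length), channels)
    rho2 <- matrix(0, bank$n_subbands, length(templates))
    for (s in seq_along(filters)) {
      Xs <- t(apply(X, 1, function(x) signal::filtfilt(filters[[s]], x)))
      if (nrow(X) == 1) Xs <- matrix(Xs, nrow = 1)
      rho2[s, ] <- vapply(templates,
                          function(tpl) cca_correlate(Xs, tpl)^2,
                          numeric(1))
    }
    as.numeric(crossprod(bank$weights, rho2))
  }, numeric(length(candidate_frequencies))))
  detection_result(segments, scores, candidate_frequencies, "fbcca",
                   window_length)
}
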