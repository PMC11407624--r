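#' Welch power spectral density of a multi-channel window
#'
#' Averaged modified periodograms with 1-second Hann segments and 50%
#' overlap. Each segment is zero-padded to four times its length before
#' the transform so the frequency grid has 0.25 Hz spacing, the spacing
#' the SSVEP SNR statistic is defined on.
#'
#' @param window numeric matrix, channels x samples (a vector is treated
#'   as one channel).
#' @param fs sampling rate, Hz.
#' @param seg_s segment length in seconds (default 1).
#' @param pad_factor zero-padding factor (default 4, giving `1/seg_s /
#'   pad_factor` Hz bin spacing).
#' @return An `eeg_psd` object: list with `freq` (Hz), `power`
#'   (channels x bins, one-sided density in uV^2/Hz), `df` (bin spacing)
#'   and `fs`.
#' @export
welch_psd <- function(window, fs, seg_s = 1, pad_factor = 4) {
  if (is.vector(window)) window <- matrix(window, nrow = 1)
  nper <- round(seg_s * fs)
  if (ncol(window) < nper) {
    stop("window shorter than one ", seg_s, " s segment; ",
         "spectral resolution insufficient", call. = FALSE)
  }
  step <- nper %/% 2
  starts <- seq(1, ncol(window) - nper + 1, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nper) / (nper + 1)))  # Hann
  nfft <- nper * pad_factor
  nbin <- nfft %/% 2 + 1
  scale <- 1 / (fs * sum(w^2))
  power <- matrix(0, nrow(window), nbin)
  for (s in starts) {
    seg <- window[, s + seq_len(nper) - 1, drop = FALSE]
    seg <- seg - rowMeans(seg)
    segw <- sweep(seg, 2, w, "*")
    X <- t(apply(segw, 1, function(x) stats::fft(c(x, numeric(nfft - nper)))))
    if (nrow(window) == 1) X <- matrix(X, nrow = 1)
    power <- power + abs(X[, seq_len(nbin), drop = FALSE])^2 * scale
  }
  power <- power / length(starts)
  power[, 2:(nbin - 1)] <- 2 * power[, 2:(nbin - 1)]  # one-sided
  structure(
    list(freq = (seq_len(nbin) - 1) * fs / nfft,
         power = power, df = fs / nfft, fs = fs),
    class = "eeg_psd"
  )
}

#' SSVEP signal-to-noise ratio of a spectrum
#'
#' The SSVEP SNR statistic at target frequency `f`: the power at the
#' target bin times six, divided by the summed power of the six
#' neighbouring bins at +/-0.25, +/-0.5 and +/-0.75 Hz, plus the same
#' construction at the 2nd harmonic `2f`. On a perfectly flat spectrum
#' each term equals 1 and the statistic is exactly 2.
#'
#' @param psd an `eeg_psd` from [welch_psd()], or a list with fields
#'   `freq` and `power` (channels x bins) on a grid that contains 0.25 Hz
#'   steps.
#' @param f target frequency, Hz; `2f + 0.75` Hz must lie inside the
#'   spectrum.
#' @param channels optional channel indices or names to average over
#'   (default: all rows of `psd$power`).
#' @return List with `per_channel` (ratio per channel), `snr` (mean
#'   ratio over the selected channels) and `db` (`10 log10(snr)`). Each of
#'   the two terms is capped at 1e6 so an ideal line spectrum with empty
#'   neighbourhoods yields a finite ceiling rather than infinity.
#' @export
ssvep_snr <- function(psd, f, channels = NULL) {
  snr_term_ceiling <- 1e6
  freq <- psd$freq
  power <- psd$power
  if (is.vector(power)) power <- matrix(power, nrow = 1)
  df <- if (!is.null(psd$df)) psd$df else freq[2] - freq[1]
  step <- round(0.25 / df)
  if (abs(step * df - 0.25) > 1e-9) {
    stop("spectrum grid does not contain 0.25 Hz steps", call. = FALSE)
  }
  if (!is.null(channels)) {
    if (is.character(channels)) channels <- match(channels, rownames(power))
    power <- power[channels, , drop = FALSE]
  }
  nbin <- length(freq)
  term <- function(f0) {
    i0 <- which.min(abs(freq - f0))
    nb <- i0 + step * c(-3:-1, 1:3)
    if (any(nb < 1) || any(nb > nbin) || i0 == 1) {
      stop("target frequency ", f0,
           " Hz too close to the spectrum edge", call. = FALSE)
    }
    denom <- rowSums(power[, nb, drop = FALSE])
    num <- 6 * power[, i0]
    # zero neighbourhood power (ideal line spectrum): cap the term so the
    # statistic stays finite
    pmin(ifelse(denom > 0, num / denom, snr_term_ceiling), snr_term_ceiling)
  }
  per_channel <- term(f) + term(2 * f)
  snr <- mean(per_channel)
  list(per_channel = per_channel, snr = snr, db = 10 * log10(snr))
}
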