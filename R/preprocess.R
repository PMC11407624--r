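#' Zero-phase filtering of a recording
#'
#' Applies, per channel, a zero-phase (forward-backward) narrow IIR notch
#' at the powerline frequency followed by a zero-phase Butterworth
#' band-pass isolating the SSVEP band. Signal length is preserved.
#'
#' @param recording an [eeg_recording()].
#' @param band band-pass edges in Hz (default 4-40).
#' @param notch_hz powerline frequency (default 60).
#' @param notch_q quality factor of the notch (default 35).
#' @param order Butterworth order of the band-pass prototype (applied
#'   forward and backward, so the effective attenuation is doubled).
#' @return The filtered `eeg_recording`.
#' @export
filter_recording <- function(recording, band = c(4, 40), notch_hz = 60,
                             notch_q = 35, order = 4) {
  fs <- recording$fs
  nyq <- fs / 2
  if (fs <= 2 * max(band, notch_hz)) {
    stop("sampling rate ", fs, " Hz too low for a ", band[1], "-", band[2],
         " Hz band-pass with a ", notch_hz, " Hz notch", call. = FALSE)
  }
  notch <- iir_notch(notch_hz, fs, notch_q)
  bp <- signal::butter(order, band / nyq, type = "pass")
  out <- recording
  for (c in seq_len(nrow(recording$data))) {
    x <- signal::filtfilt(notch, recording$data[c, ])
    out$data[c, ] <- signal::filtfilt(bp, x)
  }
  out
}

# biquad notch (constrained pole-zero placement on the unit circle)
iir_notch <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  signal::Arma(b = b / a[1], a = a / a[1])
}

#' Segment a recording into idle and stimulation windows
#'
#' For each event the idle window is the 3 seconds ending at stimulation
#' onset and the stimulation window is `stimulation_length` seconds from
#' onset. Events lacking enough data on either side are skipped with a
#' warning naming the trial ids; an error is raised only if no event can
#' be segmented.
#'
#' @param recording an [eeg_recording()].
#' @param stimulation_length analysis length in seconds (<= 5).
#' @param idle_length idle baseline length in seconds (default 3).
#' @return A list of `trial_segment` objects: each has `trial_id`,
#'   `frequency`, `idle` and `stim` (channels x samples matrices sharing
#'   the parent channel order), `fs`, `block`, `condition`, `attended`.
#' @export
segment_trials <- function(recording, stimulation_length = 5,
                           idle_length = 3) {
  fs <- recording$fs
  n <- ncol(recording$data)
  n_idle <- round(idle_length * fs)
  n_stim <- round(stimulation_length * fs)
  ev <- recording$events
  if (nrow(ev) == 0) stop("recording has no events", call. = FALSE)
  ok <- ev$onset >= n_idle & (ev$onset + n_stim) <= n
  if (!any(ok)) {
    stop("no event has ", idle_length, " s of history and ",
         stimulation_length, " s of follow-on data", call. = FALSE)
  }
  if (any(!ok)) {
    warning("skipping trial(s) without enough surrounding data: ",
            paste(ev$trial_id[!ok], collapse = ", "), call. = FALSE)
  }
  lapply(which(ok), function(i) {
    onset <- ev$onset[i]
    structure(
      list(trial_id = ev$trial_id[i], frequency = ev$frequency[i],
           idle = recording$data[, (onset - n_idle + 1):onset, drop = FALSE],
           stim = recording$data[, (onset + 1):(onset + n_stim),
                                 drop = FALSE],
           fs = fs, block = ev$block[i], condition = ev$condition[i],
           attended = ev$attended[i]),
      class = "trial_segment"
    )
  })
}

#' Select channels by stimulation-induced SNR increase
#'
#' Computes the SSVEP SNR (in dB) per channel and trial for the idle and
#' stimulation windows at each trial's own target frequency, averages over
#' trials, runs a paired t-test per channel (stimulation vs idle), and
#' returns the channels significant at `alpha` ranked by mean SNR
#' increase; the top-`k` rule is applied after significance.
#'
#' @param segments list of `trial_segment`s from [segment_trials()].
#' @param alpha per-channel significance level (default 0.01).
#' @param k maximum number of channels retained (default 8).
#' @return A `channel_selection`: data.frame `table` with per-channel mean
#'   idle/stimulation SNR (dB), SNR increase, p-value and selection flag,
#'   plus `selected` (labels, ranked by decreasing SNR increase).
#' @export
select_channels <- function(segments, alpha = 0.01, k = 8) {
  n_trials <- length(segments)
  if (n_trials < 2) {
    stop("channel selection needs at least 2 trials for a paired test",
         call. = FALSE)
  }
  if (n_trials < 5) {
    warning("fewer than 5 trials; channel selection will be unstable",
            call. = FALSE)
  }
  labels <- rownames(segments[[1]]$idle)
  nchan <- nrow(segments[[1]]$idle)
  idle_db <- matrix(NA_real_, n_trials, nchan)
  stim_db <- matrix(NA_real_, n_trials, nchan)
  for (i in seq_along(segments)) {
    seg <- segments[[i]]
    f <- seg$frequency
    idle_db[i, ] <- 10 * log10(
      ssvep_snr(welch_psd(seg$idle, seg$fs), f)$per_channel)
    stim_db[i, ] <- 10 * log10(
      ssvep_snr(welch_psd(seg$stim, seg$fs), f)$per_channel)
  }
  delta <- stim_db - idle_db
  pvals <- vapply(seq_len(nchan), function(c) {
    d <- delta[, c]
    if (stats::sd(d) == 0) return(1)
    stats::t.test(stim_db[, c], idle_db[, c], paired = TRUE,
                  alternative = "greater")$p.value
  }, numeric(1))
  tab <- data.frame(
    channel = labels,
    snr_idle_db = colMeans(idle_db),
    snr_stim_db = colMeans(stim_db),
    snr_increase_db = colMeans(delta),
    p_value = pvals
  )
  sig <- which(pvals < alpha)
  ranked <- sig[order(tab$snr_increase_db[sig], decreasing = TRUE)]
  keep <- ranked[seq_len(min(k, length(ranked)))]
  tab$selected <- seq_len(nchan) %in% keep
  structure(
    list(table = tab,
         selected = labels[keep[order(keep)]],
         alpha = alpha, k = k),
    class = "channel_selection"
  )
}

#' @export
print.channel_selection <- function(x, ...) {
  cat("<channel_selection>", length(x$selected), "channels:",
      paste(x$selected, collapse = " "), "\n")
  invisible(x)
}
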