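#' Default 10-20 montage of the simulated headset
#'
#' Sixteen channel labels covering frontal, central, parietal,
#' parieto-occipital, occipital and temporo-parietal sites.
#' @export
default_channels <- c("Fz", "Cz", "CPz", "P1", "Pz", "P2", "PO3", "POz",
                      "PO4", "PO7", "PO8", "O1", "Oz", "O2", "TP9", "TP10")

#' The eight posterior channels carrying most SSVEP energy
#' @export
posterior_channels <- c("PO3", "POz", "PO4", "PO7", "O1", "Oz", "O2", "PO8")

default_gain_map <- function(channel_labels = default_channels) {
  g <- stats::setNames(rep(0.3, length(channel_labels)), channel_labels)
  g[names(g) %in% c("O1", "Oz", "O2")] <- 1.0
  g[names(g) %in% c("PO3", "POz", "PO4", "PO7", "PO8")] <- 0.8
  g[names(g) %in% c("P1", "Pz", "P2", "CPz")] <- 0.3
  g[names(g) %in% c("Cz")] <- 0.15
  g[names(g) %in% c("Fz")] <- 0.05
  g[names(g) %in% c("TP9", "TP10")] <- 0.1
  g
}

#' Configuration of the synthetic SSVEP EEG generator
#'
#' Defines the study conditions emulated by the simulator: a 16-channel
#' 500 Hz recording with 9-second trials (2 s cue + 1 s fade = 3 s of
#' pre-onset idle background, 5 s of flicker, 1 s post fade), SSVEP energy
#' at the target frequency and its 2nd/3rd harmonics concentrated over
#' occipital and parieto-occipital sites, 1/f^gamma background EEG,
#' a stochastic ~10 Hz alpha intrusion, and 60 Hz line noise.
#'
#' @param target_frequencies candidate flicker frequencies in Hz.
#' @param fs sampling rate, Hz.
#' @param channel_labels channel names (10-20 system).
#' @param ssvep_amplitude peak amplitude in microvolts of the SSVEP
#'   fundamental at a gain-1 channel.
#' @param harmonic_decay relative amplitudes of fundamental, 2nd and 3rd
#'   harmonic.
#' @param channel_gain_map named per-channel multiplier applied to the
#'   SSVEP (and alpha) components; posterior sites high, frontal low.
#' @param background_gamma spectral exponent of the 1/f^gamma background.
#' @param background_rms RMS of the background process, microvolts.
#' @param alpha_amplitude RMS of the ~10 Hz alpha intrusion at a gain-1
#'   channel, microvolts (bandwidth about 1 Hz).
#' @param line_amplitude peak amplitude of the 60 Hz line component,
#'   microvolts.
#' @param cue_s,fade_s,flicker_s,post_s trial phase durations in seconds;
#'   cue + fade form the pre-onset idle span and must total at least 3 s.
#' @param stimulus_snr_condition `"high"` (clean rendering) or `"low"`
#'   (adds a 10 Hz competitor and jittered sidebands, see
#'   [inject_condition()]).
#' @param inattentive_prob per-trial probability that the simulated
#'   participant disengages (SSVEP scaled by `inattentive_factor`).
#' @param inattentive_factor amplitude multiplier (< 1) on inattentive
#'   trials.
#' @param competitor_amplitude,sideband_amplitude microvolt amplitudes of
#'   the low-SNR condition components.
#' @param max_channel_lag_ms upper bound of the fixed per-channel SSVEP
#'   lag, milliseconds.
#' @return A `sim_config` list.
#' @export
sim_config <- function(target_frequencies = c(6.67, 7.5, 8.57, 10),
                       fs = 500,
                       channel_labels = default_channels,
                       ssvep_amplitude = 2,
                       harmonic_decay = c(1, 0.5, 0.25),
                       channel_gain_map = default_gain_map(channel_labels),
                       background_gamma = 1.5,
                       background_rms = 10,
                       alpha_amplitude = 3,
                       line_amplitude = 2,
                       cue_s = 2, fade_s = 1, flicker_s = 5, post_s = 1,
                       stimulus_snr_condition = c("high", "low"),
                       inattentive_prob = 0,
                       inattentive_factor = 0.2,
                       competitor_amplitude = 3,
                       sideband_amplitude = 7,
                       max_channel_lag_ms = 10) {
  stimulus_snr_condition <- match.arg(stimulus_snr_condition)
  stopifnot(length(harmonic_decay) == 3, fs > 0,
            all(target_frequencies > 0),
            cue_s + fade_s >= 3)
  if (max(target_frequencies) * 3 >= fs / 2) {
    stop("3rd harmonic of a target frequency exceeds the Nyquist rate",
         call. = FALSE)
  }
  if (is.null(names(channel_gain_map)) ||
      !setequal(names(channel_gain_map), channel_labels)) {
    stop("channel_gain_map must be named by the channel labels",
         call. = FALSE)
  }
  structure(
    list(target_frequencies = target_frequencies, fs = fs,
         channel_labels = channel_labels,
         ssvep_amplitude = ssvep_amplitude,
         harmonic_decay = harmonic_decay,
         channel_gain_map = channel_gain_map[channel_labels],
         background_gamma = background_gamma,
         background_rms = background_rms,
         alpha_amplitude = alpha_amplitude,
         line_amplitude = line_amplitude,
         cue_s = cue_s, fade_s = fade_s, flicker_s = flicker_s,
         post_s = post_s,
         stimulus_snr_condition = stimulus_snr_condition,
         inattentive_prob = inattentive_prob,
         inattentive_factor = inattentive_factor,
         competitor_amplitude = competitor_amplitude,
         sideband_amplitude = sideband_amplitude,
         max_channel_lag_ms = max_channel_lag_ms),
    class = "sim_config"
  )
}

# 1/f^gamma background noise via inverse-FFT spectral shaping, scaled to a
# target RMS. Frequencies below 0.5 Hz share the 0.5 Hz magnitude so the
# low end does not blow up.
colored_noise <- function(n, fs, gamma, rms) {
  white <- stats::rnorm(n)
  X <- stats::fft(white)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)              # fold to two-sided frequencies
  shape <- pmax(f, 0.5)^(-gamma / 2)
  shape[1] <- 0                     # zero mean
  x <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  x * rms / stats::sd(x)
}

# narrow-band stochastic oscillation: white noise band-passed around
# center (bandwidth bw), scaled to a target RMS
narrowband_noise <- function(n, fs, center, bw, rms) {
  lo <- max(center - bw / 2, 0.5) / (fs / 2)
  hi <- min(center + bw / 2, fs / 2 - 1) / (fs / 2)
  flt <- signal::butter(2, c(lo, hi), type = "pass")
  x <- signal::filtfilt(flt, stats::rnorm(n))
  x * rms / stats::sd(x)
}

trial_pitch_s <- function(config) {
  config$cue_s + config$fade_s + config$flicker_s + config$post_s
}

# sum of SSVEP harmonics for one channel over a stimulation span
ssvep_waveform <- function(t, f, amplitude, decay, phases, lag) {
  s <- 0
  for (h in 1:3) {
    s <- s + amplitude * decay[h] * sin(2 * pi * h * f * (t - lag) + phases[h])
  }
  s
}

#' Generate a synthetic SSVEP session
#'
#' Simulates `n_trials_per_frequency` blocks of trials, each block
#' presenting every target frequency once in a seeded random order. Trials
#' are laid out back to back (9 s pitch by default) so that every onset has
#' at least 3 s of pre-onset idle background. The pure SSVEP component is
#' kept alongside the data (attribute `"ssvep"`) so conditions that scale
#' or remove it can be applied afterwards.
#'
#' @param config a [sim_config()].
#' @param n_trials_per_frequency blocks to simulate (>= 1).
#' @param seed integer seed; identical seed and config give bit-identical
#'   output.
#' @return An [eeg_recording()] with one event per trial and attributes
#'   `"ssvep"` (channels x samples pure SSVEP component) and
#'   `"channel_gain"`.
#' @export
generate_session <- function(config, n_trials_per_frequency, seed) {
  stopifnot(inherits(config, "sim_config"), n_trials_per_frequency >= 1)
  set.seed(seed)
  fs <- config$fs
  nchan <- length(config$channel_labels)
  freqs <- config$target_frequencies
  order_tbl <- do.call(rbind, lapply(seq_len(n_trials_per_frequency),
    function(b) data.frame(block = b,
                           frequency = freqs[sample.int(length(freqs))])))
  n_trials <- nrow(order_tbl)
  pitch <- round(trial_pitch_s(config) * fs)
  pre <- round((config$cue_s + config$fade_s) * fs)
  stim_len <- round(config$flicker_s * fs)
  n <- n_trials * pitch

  gains <- config$channel_gain_map
  lags <- stats::runif(nchan, 0, config$max_channel_lag_ms / 1000)

  data <- matrix(0, nchan, n)
  for (c in seq_len(nchan)) {
    data[c, ] <- colored_noise(n, fs, config$background_gamma,
                               config$background_rms) +
      gains[c] * narrowband_noise(n, fs, 10, 1, config$alpha_amplitude)
  }
  line_phase <- stats::runif(1, 0, 2 * pi)
  tt <- (seq_len(n) - 1) / fs
  line <- config$line_amplitude * sin(2 * pi * 60 * tt + line_phase)
  data <- sweep(data, 2, line, "+")

  ssvep <- matrix(0, nchan, n)
  attended <- stats::runif(n_trials) >= config$inattentive_prob
  onsets <- (seq_len(n_trials) - 1) * pitch + pre
  for (i in seq_len(n_trials)) {
    f <- order_tbl$frequency[i]
    phases <- stats::runif(3, 0, 2 * pi)
    amp <- config$ssvep_amplitude *
      if (attended[i]) 1 else config$inattentive_factor
    idx <- onsets[i] + seq_len(stim_len)
    t <- (idx - 1) / fs
    for (c in seq_len(nchan)) {
      ssvep[c, idx] <- gains[c] *
        ssvep_waveform(t, f, amp, config$harmonic_decay, phases, lags[c])
    }
  }
  data <- data + ssvep

  events <- data.frame(
    onset = as.integer(onsets), trial_id = seq_len(n_trials),
    frequency = order_tbl$frequency, block = order_tbl$block,
    condition = config$stimulus_snr_condition,
    attended = attended
  )
  rec <- eeg_recording(data, fs, config$channel_labels, events)
  attr(rec, "ssvep") <- ssvep
  attr(rec, "channel_gain") <- gains
  if (config$stimulus_snr_condition == "low") {
    rec <- inject_condition(rec, "low_snr",
                            competitor_amplitude = config$competitor_amplitude,
                            sideband_amplitude = config$sideband_amplitude)
  }
  rec
}

#' Generate a single synthetic trial
#'
#' @inheritParams generate_session
#' @param target_frequency the trial's target frequency (must be one of
#'   `config$target_frequencies`).
#' @param seed integer seed.
#' @return An [eeg_recording()] with a single event.
#' @export
generate_trial <- function(config, target_frequency, seed) {
  if (!any(abs(config$target_frequencies - target_frequency) < 1e-9)) {
    stop("target_frequency must be one of config$target_frequencies",
         call. = FALSE)
  }
  cfg <- config
  cfg$target_frequencies <- target_frequency
  generate_session(cfg, 1, seed)
}

#' Apply a stimulus-SNR or attention condition to a recording
#'
#' `"low_snr"` emulates an imprecisely rendered stimulus: during each
#' stimulation span a 10 Hz competing component plus jittered sidebands
#' around the trial's target frequency and (at 70% amplitude) around its
#' 2nd harmonic -- offsets drawn uniformly from 0.8-1.6 Hz, the shoulder
#' of the SNR statistic's neighbourhood where they act as spectral noise
#' -- are added with the posterior channel topography. An imprecise
#' rendering degrades the harmonic as well as the fundamental.
#' `"inattentive"` rescales the stored SSVEP component of a random subset
#' of trials by `factor` and flags them `attended = FALSE`.
#' `"high_snr"` only relabels the events.
#'
#' @param recording an [eeg_recording()] produced by [generate_session()].
#' @param condition `"low_snr"`, `"high_snr"` or `"inattentive"`.
#' @param inattentive_fraction fraction of trials to disengage (used by
#'   `"inattentive"`).
#' @param factor SSVEP amplitude multiplier for inattentive trials.
#' @param competitor_amplitude,sideband_amplitude microvolt amplitudes of
#'   the low-SNR components.
#' @param seed optional seed controlling the condition's own randomness;
#'   when `NULL` the current RNG stream is used.
#' @return The modified `eeg_recording`.
#' @export
inject_condition <- function(recording,
                             condition = c("low_snr", "high_snr",
                                           "inattentive"),
                             inattentive_fraction = 1,
                             factor = 0.2,
                             competitor_amplitude = 3,
                             sideband_amplitude = 7,
                             seed = NULL) {
  if (is.character(condition) &&
      !condition[1] %in% c("low_snr", "high_snr", "inattentive")) {
    stop("unknown condition label: ", condition[1], call. = FALSE)
  }
  condition <- match.arg(condition)
  if (nrow(recording$events) == 0) {
    stop("recording has no events", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  fs <- recording$fs
  stim_len <- round(5 * fs)
  gains <- attr(recording, "channel_gain")
  if (is.null(gains)) {
    gains <- stats::setNames(rep(1, nrow(recording$data)),
                             recording$channel_labels)
  }

  if (condition == "high_snr") {
    recording$events$condition <- "high"
    return(recording)
  }

  if (condition == "low_snr") {
    for (i in seq_len(nrow(recording$events))) {
      ev <- recording$events[i, ]
      idx <- ev$onset + seq_len(stim_len)
      t <- (idx - 1) / fs
      offs <- stats::runif(4, 1, 2)
      comps <- competitor_amplitude *
        sin(2 * pi * 10 * t + stats::runif(1, 0, 2 * pi)) +
        sideband_amplitude *
          sin(2 * pi * (ev$frequency + offs[1]) * t +
              stats::runif(1, 0, 2 * pi)) +
        sideband_amplitude *
          sin(2 * pi * (ev$frequency - offs[2]) * t +
              stats::runif(1, 0, 2 * pi)) +
        0.7 * sideband_amplitude *
          sin(2 * pi * (2 * ev$frequency + offs[3]) * t +
              stats::runif(1, 0, 2 * pi)) +
        0.7 * sideband_amplitude *
          sin(2 * pi * (2 * ev$frequency - offs[4]) * t +
              stats::runif(1, 0, 2 * pi))
      recording$data[, idx] <- recording$data[, idx] +
        outer(unname(gains), comps)
    }
    recording$events$condition <- "low"
    return(recording)
  }

  # inattentive
  stopifnot(inattentive_fraction >= 0, inattentive_fraction <= 1)
  n_trials <- nrow(recording$events)
  n_off <- round(inattentive_fraction * n_trials)
  if (n_off == 0) {
    recording$events$condition <- "inattentive_0"
    return(recording)
  }
  ssvep <- attr(recording, "ssvep")
  if (is.null(ssvep)) {
    stop("recording lacks the stored SSVEP component; ",
         "inattention can only be injected into simulated recordings",
         call. = FALSE)
  }
  off_trials <- sample(n_trials, n_off)
  for (i in off_trials) {
    idx <- recording$events$onset[i] + seq_len(stim_len)
    recording$data[, idx] <- recording$data[, idx] -
      (1 - factor) * ssvep[, idx]
    ssvep[, idx] <- factor * ssvep[, idx]
  }
  recording$events$attended[off_trials] <- FALSE
  recording$events$condition <- "inattentive"
  attr(recording, "ssvep") <- ssvep
  recording
}
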