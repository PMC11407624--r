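#' Duty-cycle bins used for frame-based flicker design
#'
#' Closed percentage intervals grouping the realizable frame-based duty
#' cycles of the four target frequencies on a 60 fps display. Membership is
#' decided on the duty cycle rounded half-up to an integer percent.
#'
#' @format A named list of length-2 numeric vectors `c(lo, hi)` in percent.
#' @export
duty_cycle_bins <- list(
  "14-25" = c(14, 25),
  "28-38" = c(28, 38),
  "45-57" = c(45, 57),
  "62-72" = c(62, 72)
)

# round half-up (base round() is round-half-even; 37.5 must map to 38)
round_half_up <- function(x) floor(x + 0.5)

# frames per cycle for a target frequency at a given refresh rate; the
# nominal frequencies (e.g. 6.67 Hz) are rounded divisors of 60 fps, so a
# small relative tolerance on the realized frequency is allowed.
frames_per_cycle <- function(target_frequency, frame_rate, rel_tol = 0.005) {
  stopifnot(target_frequency > 0, frame_rate > 0)
  m <- round(frame_rate / target_frequency)
  if (m < 1 || abs(frame_rate / m - target_frequency) / target_frequency > rel_tol) {
    stop("target frequency ", target_frequency,
         " Hz is not realizable at ", frame_rate,
         " fps (frames per cycle would be non-integer)", call. = FALSE)
  }
  m
}

new_flicker_pattern <- function(target_frequency, frame_rate, on, off) {
  m <- on + off
  duty <- round_half_up(100 * on / m)
  bin <- NA_character_
  for (nm in names(duty_cycle_bins)) {
    rng <- duty_cycle_bins[[nm]]
    if (duty >= rng[1] && duty <= rng[2]) {
      bin <- nm
      break
    }
  }
  structure(
    list(
      target_frequency = target_frequency,
      frame_rate = frame_rate,
      frames_per_cycle = m,
      on_frames = on,
      off_frames = off,
      duty_cycle_pct = duty,
      bin_label = bin,
      frame_sequence = c(rep(1L, on), rep(0L, off))
    ),
    class = "flicker_pattern"
  )
}

#' @export
print.flicker_pattern <- function(x, ...) {
  cat(sprintf(
    "<flicker_pattern> %.4g Hz @ %g fps: %d/%d frames on/off (duty %d%%, bin %s)\n",
    x$target_frequency, x$frame_rate, x$on_frames, x$off_frames,
    x$duty_cycle_pct, ifelse(is.na(x$bin_label), "unbinned", x$bin_label)
  ))
  invisible(x)
}

#' Enumerate all frame-based duty cycles of a flicker frequency
#'
#' A display running at `frame_rate` frames per second can realize
#' `target_frequency` only as an integer number of frames per flicker
#' cycle; every split of that cycle into a leading block of ON frames and a
#' trailing block of OFF frames yields one realizable duty cycle. Each
#' split is assigned to one of the four duty-cycle bins (closed intervals
#' on the rounded integer percentage) or reported as unbinned.
#'
#' @param target_frequency flicker frequency in Hz.
#' @param frame_rate display refresh rate in frames per second.
#' @return A list of [flicker_pattern][design_frame_pattern] objects, one
#'   per ON/OFF split, ordered by increasing ON frames.
#' @examples
#' pats <- enumerate_duty_bins(8.57, 60)
#' sapply(pats, function(p) p$duty_cycle_pct)
#' @export
enumerate_duty_bins <- function(target_frequency, frame_rate) {
  m <- frames_per_cycle(target_frequency, frame_rate)
  if (m < 2) {
    stop("frames per cycle is ", m,
         "; no ON/OFF split exists for this frequency", call. = FALSE)
  }
  lapply(seq_len(m - 1), function(on) {
    new_flicker_pattern(target_frequency, frame_rate, on, m - on)
  })
}

#' Design the frame pattern realizing a frequency inside a duty-cycle bin
#'
#' Selects, among all frame-based realizations of `target_frequency` at
#' `frame_rate`, the one whose rounded duty cycle falls inside the
#' requested bin. ON frames lead each cycle.
#'
#' @inheritParams enumerate_duty_bins
#' @param requested_bin bin label, one of `names(duty_cycle_bins)`
#'   (`"14-25"`, `"28-38"`, `"45-57"`, `"62-72"`).
#' @return A `flicker_pattern`: a list with the realized frequency, frames
#'   per cycle, ON/OFF frame counts, rounded duty cycle percentage, bin
#'   label and the binary per-frame sequence of one cycle.
#' @examples
#' design_frame_pattern(6.67, 60, "45-57") # five on, four off -> 56%
#' @export
design_frame_pattern <- function(target_frequency, frame_rate, requested_bin) {
  requested_bin <- match.arg(requested_bin, names(duty_cycle_bins))
  pats <- enumerate_duty_bins(target_frequency, frame_rate)
  hit <- Filter(function(p) identical(p$bin_label, requested_bin), pats)
  if (length(hit) == 0) {
    stop("no frame-based duty cycle of ", target_frequency, " Hz at ",
         frame_rate, " fps falls in bin [", requested_bin, "]",
         call. = FALSE)
  }
  hit[[1]]
}

#' Fourier spectrum of a rectangular (square-wave) flicker waveform
#'
#' For a unit-amplitude periodic pulse that is ON for a fraction
#' `duty_cycle` of each period, returns the DC term and the amplitude
#' magnitudes of the first `n_harmonics` harmonics of its Fourier series:
#' dc = d and |A_n| = 2|sin(n pi d)| / (n pi). At 50% duty all even
#' harmonics vanish, which is why balanced flicker concentrates energy at
#' odd multiples of the target frequency.
#'
#' @param duty_cycle ON fraction of the cycle, in (0, 1].
#' @param n_harmonics number of harmonics to return (>= 1).
#' @return A `square_wave_spectrum`: list with `duty_cycle`, `dc_term`
#'   (a0/2), `harmonic_coefficients` (magnitudes for harmonics
#'   1..n_harmonics), and the equivalent half-period/offset
#'   parameterization `half_period` (L = 1/2) and `offset`
#'   (Delta = (2d - 1) L, zero at 50% duty).
#' @examples
#' sp <- square_wave_spectrum(0.5, 6)
#' sp$harmonic_coefficients[c(2, 4, 6)] # even harmonics are absent
#' @export
square_wave_spectrum <- function(duty_cycle, n_harmonics) {
  if (!is.numeric(duty_cycle) || length(duty_cycle) != 1 ||
      duty_cycle <= 0 || duty_cycle > 1) {
    stop("duty_cycle must be a single value in (0, 1]", call. = FALSE)
  }
  stopifnot(n_harmonics >= 1)
  n <- seq_len(n_harmonics)
  amp <- 2 * abs(sin(n * pi * duty_cycle)) / (n * pi)
  structure(
    list(
      duty_cycle = duty_cycle,
      dc_term = duty_cycle,
      harmonic_coefficients = amp,
      half_period = 0.5,
      offset = (2 * duty_cycle - 1) * 0.5
    ),
    class = "square_wave_spectrum"
  )
}

#' Visual angle subtended at the eye
#'
#' Angle in degrees subtended by a length `size_or_offset` viewed
#' frontally from `viewer_distance`: `atan(length / distance)`. Used both
#' for icon eccentricity (offset of an icon centre from the fixation
#' point) and for the full-side angle of a square icon.
#'
#' @param size_or_offset length in cm (icon side, or offset from fixation).
#' @param viewer_distance distance from the eye to the display plane in cm.
#' @return angle in degrees.
#' @seealso [icon_visual_angle()] for square icons given their area.
#' @examples
#' visual_angle(6, 95)   # 6 cm side at 95 cm -> 3.6 degrees
#' visual_angle(95, 95)  # 45 degrees
#' @export
visual_angle <- function(size_or_offset, viewer_distance) {
  if (any(viewer_distance <= 0)) {
    stop("viewer_distance must be positive", call. = FALSE)
  }
  if (any(size_or_offset < 0)) {
    stop("size_or_offset must be non-negative", call. = FALSE)
  }
  atan(size_or_offset / viewer_distance) * 180 / pi
}

#' @rdname visual_angle
#' @param icon_area area of a square icon in cm^2; the subtended angle is
#'   computed from its side length `sqrt(icon_area)`.
#' @export
icon_visual_angle <- function(icon_area, viewer_distance) {
  visual_angle(sqrt(icon_area), viewer_distance)
}

#' Stimulus layout geometry
#'
#' Describes the on-screen arrangement of the flicker icons and derives
#' per-icon eccentricities and subtended angles from the viewing distance.
#'
#' @param viewer_distance distance d1 from the eye to the screen, cm.
#' @param icon_offsets named numeric vector of per-icon offsets d2 from the
#'   fixation point, cm.
#' @param icon_area icon area in cm^2.
#' @param array_configuration `"1x4"` or `"2x2"`.
#' @param location `"center"` or `"bottom"`.
#' @return A `stimulus_layout` list with the inputs plus `icon_side` (cm),
#'   `eccentricity_deg` (per icon) and `icon_angle_deg`.
#' @export
stimulus_layout <- function(viewer_distance, icon_offsets, icon_area,
                            array_configuration = c("1x4", "2x2"),
                            location = c("center", "bottom")) {
  array_configuration <- match.arg(array_configuration)
  location <- match.arg(location)
  side <- sqrt(icon_area)
  structure(
    list(
      viewer_distance = viewer_distance,
      icon_offsets = icon_offsets,
      icon_area = icon_area,
      icon_side = side,
      array_configuration = array_configuration,
      location = location,
      eccentricity_deg = visual_angle(icon_offsets, viewer_distance),
      icon_angle_deg = visual_angle(side, viewer_distance)
    ),
    class = "stimulus_layout"
  )
}

#' Signal-to-noise ratio of a rendered flicker stimulus
#'
#' Measures, from a photodiode-style luminance trace, how cleanly the
#' target flicker frequency was rendered. Periodograms of 4-second
#' rectangular segments (50% overlap) are averaged, giving an exact
#' 0.25 Hz frequency grid with a stable noise floor; SNR at the
#' fundamental (and at the 2nd harmonic) is
#' `10 log10(P_signal / P_noise)` with the signal power taken at the
#' target bin and the noise power as the mean of the six neighbouring
#' bins at +/-0.25, +/-0.5, +/-0.75 Hz, excluding the target and harmonic
#' bins themselves.
#'
#' @param luminance_trace numeric vector, luminance samples.
#' @param fs sampling rate of the trace in Hz; must exceed 4x the target
#'   frequency so the 2nd harmonic is resolvable.
#' @param target_frequency flicker frequency in Hz.
#' @param high_snr_threshold dB level above which the stimulus is
#'   classified as a high-SNR rendering (default 50 dB, midway between
#'   the nominal 30 dB and 70 dB conditions).
#' @param snr_ceiling reported ceiling in dB when the neighbourhood noise
#'   power is exactly zero (ideal noiseless tone).
#' @return A `stimulus_snr_report` list: `fundamental_snr_db`,
#'   `second_harmonic_snr_db`, `classification` (`"low"`/`"high"`), and the
#'   periodogram used (`freq`, `power`).
#' @export
stimulus_snr <- function(luminance_trace, fs, target_frequency,
                         high_snr_threshold = 50, snr_ceiling = 200) {
  if (length(luminance_trace) < 4 * fs) {
    stop("luminance trace shorter than 4 s; cannot resolve 0.25 Hz bins",
         call. = FALSE)
  }
  if (fs <= 4 * target_frequency) {
    stop("sampling rate too low to resolve the 2nd harmonic", call. = FALSE)
  }
  nper <- 4 * fs
  starts <- seq(1, length(luminance_trace) - nper + 1, by = nper %/% 2)
  spec <- 0
  for (s in starts) {
    x <- luminance_trace[s + seq_len(nper) - 1]
    x <- x - mean(x)
    spec <- spec + abs(stats::fft(x))^2 / nper
  }
  spec <- spec / length(starts)
  df <- fs / nper                       # exactly 0.25 Hz
  nbin <- nper %/% 2
  power <- spec[seq_len(nbin)]          # one-sided, bin i -> (i-1)*df Hz
  freq <- (seq_len(nbin) - 1) * df
  step <- round(0.25 / df)

  band_snr <- function(f0) {
    i0 <- which.min(abs(freq - f0))
    nb <- i0 + step * c(-3:-1, 1:3)
    excl <- c(i0, which.min(abs(freq - 2 * target_frequency)),
              which.min(abs(freq - target_frequency)))
    nb <- setdiff(nb, excl)
    nb <- nb[nb >= 1 & nb <= nbin]
    p_noise <- mean(power[nb])
    if (p_noise <= 0) return(snr_ceiling)
    min(10 * log10(power[i0] / p_noise), snr_ceiling)
  }

  fund <- band_snr(target_frequency)
  harm2 <- band_snr(2 * target_frequency)
  structure(
    list(
      fundamental_snr_db = fund,
      second_harmonic_snr_db = harm2,
      classification = if (fund >= high_snr_threshold) "high" else "low",
      freq = freq,
      power = power
    ),
    class = "stimulus_snr_report"
  )
}
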