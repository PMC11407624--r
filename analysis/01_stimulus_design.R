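#!/usr/bin/env Rscript
# Stimulus design: which flicker frequencies and duty cycles a 60 fps
# display can realize, what their square-wave spectra look like, and the
# viewing geometry of the icon layout. Writes tables under
# results/stimulus/.

suppressPackageStartupMessages(library(ssvepbmi))
out <- "results/stimulus"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

frequencies <- c(6.67, 7.5, 8.57, 10)

## frame-based duty cycles ---------------------------------------------------
duty <- do.call(rbind, lapply(frequencies, function(f) {
  do.call(rbind, lapply(enumerate_duty_bins(f, 60), function(p) {
    data.frame(frequency = f, frames = p$frames_per_cycle,
               on = p$on_frames, off = p$off_frames,
               duty_pct = p$duty_cycle_pct,
               bin = ifelse(is.na(p$bin_label), "unbinned", p$bin_label))
  }))
}))
write.csv(duty, file.path(out, "duty_cycles.csv"), row.names = FALSE)
cat("Frame-based duty cycles at 60 fps (", nrow(duty), "splits,",
    sum(duty$bin != "unbinned"), "binned):\n")
print(duty[duty$bin != "unbinned", ], row.names = FALSE)

## square-wave harmonic content ----------------------------------------------
spectra <- do.call(rbind, lapply(c(0.14, 0.25, 0.33, 0.5, 0.56, 0.67),
  function(d) {
    sp <- square_wave_spectrum(d, 6)
    data.frame(duty = d, dc = sp$dc_term,
               h = 1:6, amplitude = sp$harmonic_coefficients)
  }))
write.csv(spectra, file.path(out, "square_wave_spectra.csv"),
          row.names = FALSE)
cat("\nFundamental amplitude peaks at 50% duty:",
    sprintf("%.3f", max(spectra$amplitude[spectra$h == 1])),
    "(2/pi); even harmonics vanish there.\n")

## viewing geometry -----------------------------------------------------------
sizes <- c(5.06, 20.25, 36, 81)
geom <- data.frame(area_cm2 = sizes, side_cm = sqrt(sizes),
                   angle_deg = round(icon_visual_angle(sizes, 95), 2))
write.csv(geom, file.path(out, "icon_geometry.csv"), row.names = FALSE)
cat("\nIcon subtended angles at 95 cm viewing distance:\n")
print(geom, row.names = FALSE)

lay <- stimulus_layout(95, c(music = 7, navigation = 2, settings = 2,
                             temperature = 7), 20.25)
cat("1x4 icon eccentricities (deg):",
    sprintf("%.1f", lay$eccentricity_deg), "\n")

## rendered-stimulus SNR on synthetic luminance traces ------------------------
fs <- 1000
t <- (0:(24 * fs - 1)) / fs
set.seed(1)
clean <- sin(2 * pi * 10 * t) + 0.5 * sin(2 * pi * 20 * t) +
  1e-3 * rnorm(length(t))
dirty <- clean + 0.05 * sin(2 * pi * 7.5 * t) + 0.03 * rnorm(length(t))
snr <- data.frame(
  trace = c("clean", "dirty"),
  fundamental_db = c(stimulus_snr(clean, fs, 10)$fundamental_snr_db,
                     stimulus_snr(dirty, fs, 10)$fundamental_snr_db),
  second_harmonic_db = c(stimulus_snr(clean, fs, 10)$second_harmonic_snr_db,
                         stimulus_snr(dirty, fs, 10)$second_harmonic_snr_db),
  class = c(stimulus_snr(clean, fs, 10)$classification,
            stimulus_snr(dirty, fs, 10)$classification))
write.csv(snr, file.path(out, "stimulus_snr.csv"), row.names = FALSE)
cat("\nRendered-stimulus SNR (10 Hz flicker):\n")
print(snr, row.names = FALSE)
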