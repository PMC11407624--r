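#!/usr/bin/env Rscript
# Stimulus-property comparisons on synthetic sessions: high vs low
# stimulus SNR, SSVEP amplitude sweep, FBCCA vs CCA on harmonic-rich
# trials, and the cost of inattention. Writes under results/conditions/.

suppressPackageStartupMessages(library(ssvepbmi))
out <- "results/conditions"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
cands <- c(6.67, 7.5, 8.57, 10)
windows <- 1:5

session_segments <- function(cfg, blocks, seed) {
  segment_trials(filter_recording(generate_session(cfg, blocks, seed)), 5)
}
acc_curve <- function(segs, wl = windows) {
  vapply(wl, function(w) {
    r <- classify_cca(segs, cands, w, channels = posterior_channels)
    100 * mean(r$true_frequency == r$detected_frequency)
  }, numeric(1))
}

## high vs low stimulus SNR ---------------------------------------------------
hi_segs <- session_segments(sim_config(stimulus_snr_condition = "high"),
                            13, 31)
lo_segs <- session_segments(sim_config(stimulus_snr_condition = "low"),
                            13, 31)
snr_of <- function(segs) vapply(segs, function(s)
  ssvep_snr(welch_psd(s$stim, s$fs), s$frequency,
            channels = posterior_channels)$db, numeric(1))
hi_acc <- acc_curve(hi_segs); lo_acc <- acc_curve(lo_segs)
curve <- data.frame(window_s = windows, high_snr_pct = hi_acc,
                    low_snr_pct = lo_acc)
write.csv(curve, file.path(out, "snr_condition_curves.csv"),
          row.names = FALSE)
cat("Accuracy over window length, high vs low stimulus SNR:\n")
print(curve, row.names = FALSE)
cat(sprintf("Mean spectral SNR: high %.2f dB, low %.2f dB (drop %.2f dB)\n",
            mean(snr_of(hi_segs)), mean(snr_of(lo_segs)),
            mean(snr_of(hi_segs)) - mean(snr_of(lo_segs))))
cmp <- compare_conditions(snr_of(lo_segs), snr_of(hi_segs),
                          labels = c("low", "high"))
cat(sprintf("Paired per-trial comparison: %s, p = %.3g %s\n\n",
            cmp$test, cmp$p_value, cmp$stars))

## amplitude sweep -------------------------------------------------------------
amps <- c(0, 0.5, 1, 2, 4)
sweep_acc <- vapply(seq_along(amps), function(i) {
  segs <- session_segments(sim_config(ssvep_amplitude = amps[i]), 10,
                           100 + i)
  acc_curve(segs, 5)
}, numeric(1))
write.csv(data.frame(amplitude_uv = amps, accuracy_pct = sweep_acc),
          file.path(out, "amplitude_sweep.csv"), row.names = FALSE)
cat("CCA accuracy (5 s) vs SSVEP amplitude (uV):\n")
print(data.frame(amplitude = amps, accuracy = sweep_acc),
      row.names = FALSE)
cat("Accuracy rises from chance (25%) to ceiling with amplitude.\n\n")

## FBCCA vs CCA on harmonic-rich trials ----------------------------------------
segs <- session_segments(sim_config(ssvep_amplitude = 1.5,
                                    harmonic_decay = c(1, 0.9, 0.7)),
                         25, 555)
fb_cca <- do.call(rbind, lapply(c(1.5, 3), function(w) {
  rc <- classify_cca(segs, cands, w, channels = posterior_channels)
  rf <- fbcca_classify(segs, cands, w, channels = posterior_channels)
  data.frame(window_s = w,
             cca_pct = 100 * mean(rc$true_frequency ==
                                  rc$detected_frequency),
             fbcca_pct = 100 * mean(rf$true_frequency ==
                                    rf$detected_frequency))
}))
write.csv(fb_cca, file.path(out, "fbcca_vs_cca.csv"), row.names = FALSE)
cat("FBCCA vs CCA on a harmonic-rich session (100 trials):\n")
print(fb_cca, row.names = FALSE)
cat("The filter bank exploits harmonic energy at short windows.\n\n")

## inattention ------------------------------------------------------------------
rec <- generate_session(sim_config(), 13, 12)
rec_in <- inject_condition(rec, "inattentive", inattentive_fraction = 0.5,
                           factor = 0.2, seed = 13)
segs_in <- segment_trials(filter_recording(rec_in), 5)
att <- vapply(segs_in, `[[`, logical(1), "attended")
res <- classify_cca(segs_in, cands, 5, channels = posterior_channels)
acc_att <- 100 * mean((res$true_frequency ==
                       res$detected_frequency)[att])
acc_in <- 100 * mean((res$true_frequency ==
                      res$detected_frequency)[!att])
cat(sprintf("Attended trials: %.1f%%; inattentive trials (amplitude x0.2): %.1f%%\n",
            acc_att, acc_in))
write.csv(data.frame(group = c("attended", "inattentive"),
                     accuracy_pct = c(acc_att, acc_in)),
          file.path(out, "inattention.csv"), row.names = FALSE)
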