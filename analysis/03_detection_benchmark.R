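#!/usr/bin/env Rscript
# Detection benchmark: run the full pipeline (filter -> segment -> channel
# selection -> PSDA/CCA/FBCCA over a window grid) on a seeded synthetic
# session and tabulate accuracy, ITR and confusion. Writes under
# results/detection/.

suppressPackageStartupMessages(library(ssvepbmi))

cfg <- pipeline_config(n_trials_per_frequency = 10,
                       window_grid = seq(0.5, 5, by = 0.5),
                       seed = 1,
                       out_dir = "results/detection")
run <- run_pipeline(cfg)

cat("Selected channels:", run$channels$selected, "\n\n")
cat("Accuracy (%) by method and window length:\n")
wide <- reshape(run$summary[, c("method", "window_length", "accuracy_pct")],
                idvar = "window_length", timevar = "method",
                direction = "wide")
names(wide) <- sub("accuracy_pct\\.", "", names(wide))
print(wide, row.names = FALSE, digits = 3)

cat("\nCCA confusion matrix at 5 s (rows = true Hz):\n")
print(run$confusion$cca)

best <- run$summary[run$summary$method == "cca", ]
cat(sprintf("\nCCA reaches %.1f%% at %g s (ITR %.1f bits/min); accuracy rises with window length, as expected for correlation-based SSVEP detection.\n",
            max(best$accuracy_pct),
            best$window_length[which.max(best$accuracy_pct)],
            best$itr_bits_min[which.max(best$accuracy_pct)]))
cat("Artifacts in results/detection/ (config hash ",
    run$config_hash, ")\n", sep = "")
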