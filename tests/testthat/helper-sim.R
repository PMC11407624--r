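# shared fixtures, built once per test run

# wrap raw matrices as a trial segment (for constructed-data tests)
make_segment <- function(stim, idle = NULL, fs = 500, frequency = 10,
                         trial_id = 1, block = 1) {
  if (is.null(idle)) idle <- matrix(0, nrow(stim), round(3 * fs))
  structure(
    list(trial_id = trial_id, frequency = frequency, idle = idle,
         stim = stim, fs = fs, block = block, condition = "default",
         attended = TRUE),
    class = "trial_segment"
  )
}

# a default-condition session reused across test files
.cache <- new.env(parent = emptyenv())
cached_session <- function() {
  if (is.null(.cache$session)) {
    cfg <- sim_config()
    rec <- generate_session(cfg, 5, seed = 20260920)
    segs <- segment_trials(filter_recording(rec), 5)
    .cache$session <- list(config = cfg, recording = rec, segments = segs)
  }
  .cache$session
}

session_accuracy <- function(segments, candidates, window_length,
                             method = "cca", ...) {
  res <- switch(method,
    cca = classify_cca(segments, candidates, window_length,
                       channels = posterior_channels, ...),
    fbcca = fbcca_classify(segments, candidates, window_length,
                           channels = posterior_channels, ...),
    psda = classify_psda(segments, candidates, window_length,
                         channels = posterior_channels))
  mean(res$true_frequency == res$detected_frequency)
}
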