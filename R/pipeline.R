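#' Pipeline configuration
#'
#' Bundles every stage's settings: the simulation (or input recording),
#' filtering, channel selection, the detection methods with their window
#' grid, and the output location. Fully serializable to YAML/JSON; a
#' run's effective configuration and hash are written alongside its
#' outputs.
#'
#' @param simulation a [sim_config()] (used when `input_prefix` is NULL).
#' @param n_trials_per_frequency blocks to simulate.
#' @param input_prefix optional path prefix of a stored recording to
#'   analyse instead of simulating.
#' @param methods detection methods to run.
#' @param window_grid analysis window lengths in seconds.
#' @param filter_band band-pass edges, Hz.
#' @param notch_hz powerline notch frequency, Hz.
#' @param selection_alpha,selection_k channel-selection parameters.
#' @param bank a [filter_bank_config()] for FBCCA.
#' @param Nh harmonics for the CCA reference templates.
#' @param seed integer seed for the whole run.
#' @param out_dir optional output directory; created if missing.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulation = sim_config(),
                            n_trials_per_frequency = 5,
                            input_prefix = NULL,
                            methods = c("psda", "cca", "fbcca"),
                            window_grid = seq(0.5, 5, by = 0.5),
                            filter_band = c(4, 40),
                            notch_hz = 60,
                            selection_alpha = 0.01,
                            selection_k = 8,
                            bank = filter_bank_config(),
                            Nh = 3,
                            seed = 1,
                            out_dir = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  structure(
    list(simulation = simulation,
         n_trials_per_frequency = n_trials_per_frequency,
         input_prefix = input_prefix, methods = methods,
         window_grid = window_grid, filter_band = filter_band,
         notch_hz = notch_hz, selection_alpha = selection_alpha,
         selection_k = selection_k, bank = bank, Nh = Nh, seed = seed,
         out_dir = out_dir),
    class = "pipeline_config"
  )
}

# 32-bit FNV-1a hash of the serialized configuration, reported in every
# output table so runs can be traced back to their settings
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(unclass(config)), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    # xor on the low byte only (b < 256); keeps h a double within 2^32
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # 32-bit modular multiply split into 16-bit halves (doubles lose
    # precision beyond 2^53)
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (((h1 * 16777619) %% 65536) * 65536 + h0 * 16777619) %% 4294967296
  }
  # format as hex from the two 16-bit halves (h is a double)
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Read / write a pipeline configuration as YAML
#' @param config a [pipeline_config()].
#' @param path file path.
#' @export
write_pipeline_config <- function(config, path) {
  out <- rapply(unclass(config), unclass, how = "replace")
  # yaml drops names of atomic vectors; store the gain map as a mapping
  out$simulation$channel_gain_map <-
    as.list(config$simulation$channel_gain_map)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim <- do.call(sim_config, c(
    raw$simulation[setdiff(names(raw$simulation),
                           c("channel_gain_map", "harmonic_decay"))],
    list(channel_gain_map = unlist(raw$simulation$channel_gain_map),
         harmonic_decay = unlist(raw$simulation$harmonic_decay))))
  bank <- do.call(filter_bank_config,
                  raw$bank[c("n_subbands", "k", "f_max", "margin", "a",
                             "b", "ripple_db", "order")])
  pipeline_config(
    simulation = sim,
    n_trials_per_frequency = raw$n_trials_per_frequency,
    input_prefix = raw$input_prefix,
    methods = unlist(raw$methods),
    window_grid = unlist(raw$window_grid),
    filter_band = unlist(raw$filter_band),
    notch_hz = raw$notch_hz,
    selection_alpha = raw$selection_alpha,
    selection_k = raw$selection_k,
    bank = bank, Nh = raw$Nh, seed = raw$seed,
    out_dir = raw$out_dir
  )
}

#' Run the full SSVEP analysis pipeline
#'
#' Simulate (or load) a session, filter it, segment trials, select
#' channels by stimulation-induced SNR, classify every trial with each
#' requested method over the window grid (PSDA is skipped for windows
#' shorter than its 1 s spectral resolution), and evaluate. When `out_dir`
#' is set, writes the per-trial results, summary, confusion matrices and
#' a JSON run manifest (seed, configuration hash, package version).
#'
#' @param config a [pipeline_config()].
#' @return A list: `summary` ([accuracy_over_time()] table), `results`
#'   (per-trial rows across methods and window lengths), `confusion`
#'   (per-method confusion matrices at the longest window), `channels`
#'   (the [select_channels()] result), `recording`, and `config_hash`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  hash <- config_hash(config)
  recording <- if (is.null(config$input_prefix)) {
    generate_session(config$simulation, config$n_trials_per_frequency,
                     config$seed)
  } else {
    read_recording(config$input_prefix)
  }
  candidates <- sort(unique(recording$events$frequency))

  filtered <- filter_recording(recording, band = config$filter_band,
                               notch_hz = config$notch_hz)
  segments <- segment_trials(filtered, stimulation_length = 5)
  channels <- select_channels(segments, alpha = config$selection_alpha,
                              k = config$selection_k)

  results <- list()
  for (wl in config$window_grid) {
    for (m in config$methods) {
      # PSDA needs a full 1 s Welch segment; shorter windows have no
      # spectrum at the statistic's resolution
      if (m == "psda" && wl < 1) next
      res <- switch(m,
        psda = classify_psda(segments, candidates, wl,
                             channels = channels),
        cca = classify_cca(segments, candidates, wl, Nh = config$Nh,
                           channels = channels),
        fbcca = fbcca_classify(segments, candidates, wl,
                               bank = config$bank, Nh = config$Nh,
                               channels = channels))
      results[[length(results) + 1]] <- res
    }
  }
  results <- do.call(rbind, results)
  results$config_hash <- hash
  summary <- accuracy_over_time(results)
  summary$config_hash <- hash
  wl_max <- max(config$window_grid)
  confusion <- lapply(stats::setNames(config$methods, config$methods),
    function(m) {
      confusion_matrix(results[results$method == m &
                               results$window_length == wl_max, ],
                       candidates)
    })

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(results, file.path(config$out_dir, "trial_results.csv"),
                     row.names = FALSE)
    utils::write.csv(summary, file.path(config$out_dir, "summary.csv"),
                     row.names = FALSE)
    for (m in names(confusion)) {
      utils::write.csv(confusion[[m]],
                       file.path(config$out_dir,
                                 paste0("confusion_", m, ".csv")))
    }
    utils::write.csv(channels$table,
                     file.path(config$out_dir, "channel_selection.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(config_hash = hash, seed = config$seed,
           package_version = as.character(utils::packageVersion("ssvepbmi")),
           r_version = R.version.string,
           selected_channels = channels$selected,
           methods = config$methods, window_grid = config$window_grid),
      file.path(config$out_dir, "run_manifest.json"),
      auto_unbox = TRUE, digits = NA)
    write_pipeline_config(config, file.path(config$out_dir, "config.yaml"))
  }

  list(summary = summary, results = results, confusion = confusion,
       channels = channels, recording = recording, config_hash = hash)
}
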