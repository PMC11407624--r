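#' Multi-channel EEG recording
#'
#' Container for a continuous EEG recording: a channels x samples matrix in
#' microvolts, the sampling rate, 10-20 channel labels, and an event table
#' marking stimulation onsets.
#'
#' @param data numeric matrix, channels x samples, in microvolts; rownames
#'   are taken as channel labels when `channel_labels` is missing.
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector of unique channel names.
#' @param events data.frame with columns `onset` (0-based sample index of
#'   stimulation onset), `trial_id`, `frequency` (true target in Hz), and
#'   optionally `block`, `condition`, `attended`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_labels = rownames(data),
                          events = empty_events()) {
  stopifnot(is.matrix(data), is.numeric(data), fs > 0)
  if (is.null(channel_labels)) {
    channel_labels <- paste0("ch", seq_len(nrow(data)))
  }
  if (length(channel_labels) != nrow(data)) {
    stop("channel_labels length must equal nrow(data)", call. = FALSE)
  }
  if (anyDuplicated(channel_labels)) {
    stop("channel labels must be unique", call. = FALSE)
  }
  events <- validate_events(events, n_samples = ncol(data), fs = fs)
  rownames(data) <- channel_labels
  structure(
    list(data = data, fs = fs, channel_labels = channel_labels,
         events = events),
    class = "eeg_recording"
  )
}

empty_events <- function() {
  data.frame(onset = integer(), trial_id = integer(), frequency = numeric(),
             block = integer(), condition = character(),
             attended = logical())
}

validate_events <- function(events, n_samples, fs) {
  stopifnot(is.data.frame(events))
  required <- c("onset", "trial_id", "frequency")
  missing_cols <- setdiff(required, names(events))
  if (length(missing_cols)) {
    stop("event table lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"block" %in% names(events)) events$block <- seq_len(nrow(events))
  if (!"condition" %in% names(events)) events$condition <- "default"
  if (!"attended" %in% names(events)) events$attended <- TRUE
  if (anyDuplicated(events$trial_id)) {
    stop("trial ids must be unique", call. = FALSE)
  }
  if (nrow(events) && any(events$onset + 5 * fs > n_samples)) {
    stop("every onset must leave room for 5 s of stimulation", call. = FALSE)
  }
  events
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
    nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs, nrow(x$events)))
  cat("  channels:", paste(x$channel_labels, collapse = " "), "\n")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param recording an `eeg_recording`.
#' @export
recording_duration <- function(recording) {
  ncol(recording$data) / recording$fs
}

#' Write / read a recording as a plain-text container
#'
#' The container is three sidecar files sharing a prefix:
#' `<prefix>_data.csv` (samples x channels, header = channel labels),
#' `<prefix>_events.csv`, and `<prefix>_meta.json` (sampling rate, units).
#'
#' @param recording an `eeg_recording`.
#' @param prefix path prefix (directory must exist).
#' @return `write_recording` returns the prefix invisibly;
#'   `read_recording` returns an `eeg_recording`.
#' @export
write_recording <- function(recording, prefix) {
  stopifnot(inherits(recording, "eeg_recording"))
  utils::write.csv(as.data.frame(t(recording$data)),
                   paste0(prefix, "_data.csv"), row.names = FALSE)
  utils::write.csv(recording$events, paste0(prefix, "_events.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(fs = recording$fs, units = "uV",
         channel_labels = recording$channel_labels),
    paste0(prefix, "_meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_recording
#' @param format input format; only `"delimited"` (the package's text
#'   container) is supported. European Data Format files are not parsed by
#'   this package.
#' @export
read_recording <- function(prefix, format = c("delimited", "edf")) {
  format <- match.arg(format)
  if (format == "edf") {
    stop("European Data Format input is not supported by this package; ",
         "convert to the delimited container (data/events/meta files)",
         call. = FALSE)
  }
  data_path <- paste0(prefix, "_data.csv")
  events_path <- paste0(prefix, "_events.csv")
  meta_path <- paste0(prefix, "_meta.json")
  if (!file.exists(data_path)) {
    stop("missing data file: ", data_path, call. = FALSE)
  }
  if (!file.exists(events_path)) {
    stop("missing event table: ", events_path,
         " (a recording without events cannot be analysed)", call. = FALSE)
  }
  if (!file.exists(meta_path)) {
    stop("missing metadata file: ", meta_path,
         " (sampling rate unknown)", call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$fs)) stop("metadata lacks field: fs", call. = FALSE)
  dat <- utils::read.csv(data_path, check.names = FALSE)
  events <- utils::read.csv(events_path)
  eeg_recording(t(as.matrix(dat)), fs = meta$fs,
                channel_labels = colnames(dat), events = events)
}
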