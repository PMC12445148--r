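#' Multichannel EEG container
#'
#' Channels-by-samples matrix with a sample rate, channel labels, an event
#' table, and a `meta` list describing the paradigm grid (samples per token,
#' tokens per cycle, cycles per trial, samples per melody beat) needed by
#' the timescale-specific epoching.
#'
#' @param data numeric matrix, channels x samples (microvolts).
#' @param sample_rate_hz sampling rate.
#' @param channel_labels character vector, one per row of `data`.
#' @param events tibble of events; must contain at least `sample` and
#'   `kind`, with `sample` sorted and within the recording.
#' @param mastoid_labels labels of the mastoid reference channels.
#' @param meta named list of paradigm constants.
#' @return an object of class `eeg_data`.
#' @export
eeg_data <- function(data, sample_rate_hz, channel_labels,
                     events = tibble(sample = integer(), kind = character()),
                     mastoid_labels = c("M1", "M2"), meta = list()) {
  stopifnot(is.matrix(data), nrow(data) == length(channel_labels))
  events <- as_tibble(events)
  if (nrow(events)) {
    if (is.unsorted(events$sample)) {
      events <- events[order(events$sample), ]
    }
    if (any(events$sample < 1) || any(events$sample > ncol(data))) {
      abort("event samples must lie within the recording")
    }
  }
  structure(
    list(data = data, sample_rate_hz = sample_rate_hz,
         channel_labels = channel_labels, events = events,
         mastoid_labels = mastoid_labels, meta = meta),
    class = "eeg_data"
  )
}

#' @export
print.eeg_data <- function(x, ...) {
  cat(sprintf(
    "<eeg_data: %d channels x %d samples @ %g Hz (%.1f s), %d events>\n",
    nrow(x$data), ncol(x$data), x$sample_rate_hz,
    ncol(x$data) / x$sample_rate_hz, nrow(x$events)
  ))
  invisible(x)
}

#' @export
dim.eeg_data <- function(x) dim(x$data)

scalp_channels <- function(eeg) {
  setdiff(seq_along(eeg$channel_labels),
          match(eeg$mastoid_labels, eeg$channel_labels))
}

#' Write an EEG recording as plain-text files
#'
#' Data go to `<stem>_data.csv` (channels as columns) and events to
#' `<stem>_events.csv`; the sample rate and labels are stored in
#' `<stem>_meta.yaml`.  Intended for interoperability and small fixtures,
#' not bulk storage.
#'
#' @param eeg an [eeg_data()].
#' @param stem path stem.
#' @return `stem`, invisibly.
#' @export
write_eeg_csv <- function(eeg, stem) {
  utils::write.csv(as.data.frame(t(eeg$data)), paste0(stem, "_data.csv"),
                   row.names = FALSE)
  utils::write.csv(eeg$events, paste0(stem, "_events.csv"), row.names = FALSE)
  yaml::write_yaml(
    list(sample_rate_hz = eeg$sample_rate_hz,
         channel_labels = eeg$channel_labels,
         mastoid_labels = eeg$mastoid_labels,
         meta = eeg$meta),
    paste0(stem, "_meta.yaml")
  )
  invisible(stem)
}

#' Read an EEG recording written by [write_eeg_csv()]
#' @param stem path stem used when writing.
#' @return an [eeg_data()].
#' @export
read_eeg_csv <- function(stem) {
  d <- t(as.matrix(utils::read.csv(paste0(stem, "_data.csv"))))
  ev <- as_tibble(utils::read.csv(paste0(stem, "_events.csv")))
  m <- yaml::read_yaml(paste0(stem, "_meta.yaml"))
  eeg_data(unname(d), m$sample_rate_hz, unlist(m$channel_labels), ev,
           unlist(m$mastoid_labels), m$meta)
}
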