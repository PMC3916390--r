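#' Construct a continuous multichannel recording
#'
#' @param data Channels x samples numeric matrix (microvolt).
#' @param sfreq Sampling rate in Hz.
#' @param channel_names Character vector, one per row of `data`.
#' @param events `data.frame` with columns `sample` (1-based index),
#'   `label`, `trial_id`.
#' @param log Named list of processing provenance entries.
#' @return A `continuous_recording`.
#' @export
continuous_recording <- function(data, sfreq, channel_names,
                                 events = NULL, log = list()) {
  stopifnot(is.matrix(data), sfreq > 0, nrow(data) == length(channel_names))
  if (is.null(events))
    events <- data.frame(sample = integer(0), label = character(0),
                         trial_id = character(0), stringsAsFactors = FALSE)
  if (nrow(events) > 0 &&
      (any(events$sample < 1) || any(events$sample > ncol(data))))
    stopf("continuous_recording: event sample indices outside data range")
  rownames(data) <- channel_names
  structure(list(data = data, sfreq = sfreq, channel_names = channel_names,
                 events = events, log = log),
            class = "continuous_recording")
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat(sprintf("<continuous_recording> %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(x$data), ncol(x$data), x$sfreq, ncol(x$data) / x$sfreq,
              nrow(x$events)))
  invisible(x)
}

# append a provenance entry
log_step <- function(log, stage, params) {
  log[[length(log) + 1L]] <- c(list(stage = stage), params)
  log
}

#' Write a recording or epoch set's metadata sidecar as JSON
#'
#' The numeric arrays live in the in-memory object (or a TSV written by
#' the caller); the sidecar captures channel names, sampling rate, the
#' event/trial table and the processing log so a run is reconstructible.
#'
#' @param x A `continuous_recording` or `epoch_set`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_sidecar_json <- function(x, path) {
  meta <- list(
    class = class(x)[1],
    sfreq = x$sfreq,
    channel_names = x$channel_names,
    log = x$log
  )
  if (!is.null(x$events)) meta$events <- x$events
  if (!is.null(x$trials)) meta$trials <- x$trials
  if (!is.null(x$t0)) meta$t0 <- x$t0
  if (!is.null(x$lock)) meta$lock <- x$lock
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
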