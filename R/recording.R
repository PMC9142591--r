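# Containers for continuous multichannel EEG and trial event tables.

#' Continuous multichannel recording
#'
#' A continuous EEG/EOG recording: a channels-by-time matrix of amplitudes in
#' microvolts, a sampling rate, and a role (`"EEG"` or `"EOG"`) per channel.
#'
#' @param samples Numeric matrix, channels x time, in microvolts. Row names,
#'   if present, must agree with `channel_labels`.
#' @param rate Sampling rate in Hz.
#' @param channel_labels Character vector of unique channel names.
#' @param channel_roles Character vector, one of `"EEG"` or `"EOG"` per
#'   channel.
#' @return An object of class `continuous_recording`.
#' @export
continuous_recording <- function(samples, rate = 500,
                                 channel_labels = rownames(samples),
                                 channel_roles = NULL) {
  samples <- as.matrix(samples)
  if (is.null(channel_labels))
    stop("channel_labels are required when `samples` has no row names")
  if (is.null(channel_roles))
    channel_roles <- ifelse(grepl("^EOG", channel_labels), "EOG", "EEG")
  stopifnot(is.numeric(samples), rate > 0,
            length(channel_labels) == nrow(samples),
            length(channel_roles) == nrow(samples))
  if (anyDuplicated(channel_labels))
    stop("channel labels must be unique")
  if (!all(channel_roles %in% c("EEG", "EOG")))
    stop("channel roles must be 'EEG' or 'EOG'")
  rownames(samples) <- channel_labels
  structure(list(samples = samples, rate = rate,
                 channel_labels = channel_labels,
                 channel_roles = channel_roles),
            class = "continuous_recording")
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat(sprintf("<continuous_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$rate,
              ncol(x$samples) / x$rate))
  cat("  channels:", paste(sprintf("%s[%s]", x$channel_labels,
                                   x$channel_roles), collapse = " "), "\n")
  invisible(x)
}

# Subset a recording to the given channel labels (order preserved as given).
subset_channels <- function(recording, labels) {
  idx <- match(labels, recording$channel_labels)
  if (anyNA(idx)) stop("unknown channel(s): ",
                       paste(labels[is.na(idx)], collapse = ", "))
  continuous_recording(recording$samples[idx, , drop = FALSE],
                       rate = recording$rate,
                       channel_labels = recording$channel_labels[idx],
                       channel_roles = recording$channel_roles[idx])
}

# Validate an event table: one row per trial with stimulus onset (sample
# index), condition label, response category and reaction time in seconds.
validate_events <- function(events, require_response = TRUE) {
  if (!is.data.frame(events)) stop("events must be a data.frame")
  needed <- c("onset_sample", "condition")
  if (require_response) needed <- c(needed, "response")
  missing <- setdiff(needed, names(events))
  if (length(missing))
    stop("event table is missing column(s): ", paste(missing, collapse = ", "))
  if (require_response &&
      !all(events$response %in% c("correct", "incorrect", "none")))
    stop("response must be one of 'correct', 'incorrect', 'none'")
  invisible(events)
}

#' Read or write a continuous recording as tab-separated text
#'
#' One column per channel; metadata (`rate`, channel roles) is carried in
#' `#`-prefixed header lines so a recording round-trips losslessly through
#' plain text.
#'
#' @param recording A [continuous_recording].
#' @param path File path.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns a [continuous_recording].
#' @export
write_recording <- function(recording, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# rate=%g", recording$rate),
               sprintf("# roles=%s", paste(recording$channel_roles,
                                           collapse = ","))), con)
  utils::write.table(t(recording$samples), con, sep = "\t", row.names = FALSE,
                     col.names = recording$channel_labels, quote = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  header <- readLines(path, n = 2)
  rate <- as.numeric(sub("# rate=", "", header[1], fixed = TRUE))
  roles <- strsplit(sub("# roles=", "", header[2], fixed = TRUE), ",")[[1]]
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           check.names = FALSE)
  continuous_recording(t(as.matrix(tab)), rate = rate,
                       channel_labels = colnames(tab), channel_roles = roles)
}

#' Read or write a trial event table as tab-separated text
#'
#' Columns: `onset_sample`, `condition`, `response` (correct | incorrect |
#' none) and `rt_seconds` (NA when no response was given).
#'
#' @param events Event table (`data.frame`).
#' @param path File path.
#' @return `write_events` returns `path` invisibly; `read_events` a
#'   `data.frame`.
#' @export
write_events <- function(events, path) {
  validate_events(events)
  utils::write.table(events, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  validate_events(ev)
  ev
}
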