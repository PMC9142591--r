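# Preprocessing chain: zero-phase band-pass -> channel drop -> EOG
# regression -> detrend -> epoch -> baseline correction -> amplitude
# rejection -> response selection. The order is fixed; preprocess_subject()
# runs the whole chain.

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a 4th-order Butterworth band-pass forward and backward
#' (zero-phase, no group delay) to every channel. The channel mean is removed
#' before filtering to limit edge transients.
#'
#' @param recording A [continuous_recording].
#' @param low,high Band edges in Hz; `0 < low < high < rate/2`.
#' @return The filtered [continuous_recording].
#' @export
bandpass <- function(recording, low = 1, high = 25) {
  stopifnot(inherits(recording, "continuous_recording"))
  rate <- recording$rate
  if (!(low > 0 && low < high && high < rate / 2))
    stop("invalid band: need 0 < low < high < rate/2")
  # cascade of high-pass and low-pass sections: numerically safer than a
  # single transfer-function band-pass when the low edge is far below Nyquist
  hp <- signal::butter(4, low / (rate / 2), type = "high")
  lp <- signal::butter(4, high / (rate / 2), type = "low")
  out <- recording$samples
  for (i in seq_len(nrow(out))) {
    x <- out[i, ] - mean(out[i, ])
    x <- signal::filtfilt(hp, x)
    out[i, ] <- signal::filtfilt(lp, x)
  }
  continuous_recording(out, rate = rate,
                       channel_labels = recording$channel_labels,
                       channel_roles = recording$channel_roles)
}

#' Regress ocular activity out of the scalp channels
#'
#' The EOG channels are band-pass filtered (1-7 Hz by default) and then
#' jointly regressed out of every scalp channel by least squares on the
#' continuous signals: each scalp channel is replaced by its residual after
#' projecting out the filtered EOG regressors (plus an intercept). The
#' residual is uncorrelated with the regressors by construction, and the
#' projection can only reduce channel variance. Zero-variance EOG regressors
#' are skipped with a warning.
#'
#' @param eeg A [continuous_recording] of scalp channels.
#' @param eog A [continuous_recording] of EOG channels (same length).
#' @param eog_band Band in Hz applied to the EOG channels before regression;
#'   use `NULL` if the EOG is already filtered.
#' @return The cleaned scalp [continuous_recording].
#' @export
regress_out_eog <- function(eeg, eog, eog_band = c(1, 7)) {
  stopifnot(inherits(eeg, "continuous_recording"),
            inherits(eog, "continuous_recording"),
            ncol(eeg$samples) == ncol(eog$samples))
  if (!is.null(eog_band)) eog <- bandpass(eog, eog_band[1], eog_band[2])
  regressors <- t(eog$samples)
  keep <- apply(regressors, 2, stats::sd) > 0
  if (!all(keep))
    warning("skipping zero-variance EOG regressor(s): ",
            paste(colnames(regressors)[!keep], collapse = ", "))
  out <- eeg$samples
  if (any(keep)) {
    X <- cbind(1, regressors[, keep, drop = FALSE])
    coefs <- solve(crossprod(X), crossprod(X, t(eeg$samples)))
    out <- eeg$samples - t(X %*% coefs)
  }
  continuous_recording(out, rate = eeg$rate,
                       channel_labels = eeg$channel_labels,
                       channel_roles = eeg$channel_roles)
}

#' Remove the linear trend from every channel
#'
#' Least-squares line (intercept + slope) removed per channel.
#'
#' @param recording A [continuous_recording].
#' @return The detrended [continuous_recording].
#' @export
detrend_recording <- function(recording) {
  stopifnot(inherits(recording, "continuous_recording"))
  n <- ncol(recording$samples)
  tc <- seq_len(n) - (n + 1) / 2
  slopes <- drop(recording$samples %*% tc) / sum(tc^2)
  out <- recording$samples - rowMeans(recording$samples) - outer(slopes, tc)
  continuous_recording(out, rate = recording$rate,
                       channel_labels = recording$channel_labels,
                       channel_roles = recording$channel_roles)
}

#' Cut stimulus-locked epochs from a continuous recording
#'
#' One epoch per event on the half-open window `[window[1], window[2])` ms
#' around stimulus onset (500 samples for the default [-200, 800) ms window
#' at 500 Hz). Events whose window falls outside the recording are dropped
#' and counted.
#'
#' @param recording A [continuous_recording].
#' @param events Event table with an `onset_sample` column.
#' @param window Epoch window in ms relative to onset.
#' @return An object of class `epoch_set`: `data` (trials x channels x time),
#'   `times` (ms), `trial_index` (row of `events` per epoch), rejection masks
#'   `amplitude_rejected` / `response_rejected`, and `n_dropped_edge`.
#' @export
epoch_recording <- function(recording, events, window = c(-200, 800)) {
  stopifnot(inherits(recording, "continuous_recording"))
  validate_events(events, require_response = FALSE)
  rate <- recording$rate
  times <- epoch_times(window, rate)
  offs <- round(window[1] / 1000 * rate) + seq_along(times) - 1
  n_samp <- ncol(recording$samples)
  ok <- events$onset_sample + offs[1] >= 1 &
    events$onset_sample + offs[length(offs)] <= n_samp
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    message(n_dropped, " trial(s) dropped: epoch window outside recording")
  trial_index <- which(ok)
  nt <- length(trial_index)
  nc <- nrow(recording$samples)
  data <- array(0, dim = c(nt, nc, length(times)))
  if (nt > 0) {
    idx <- outer(events$onset_sample[trial_index], offs, "+")
    for (ch in seq_len(nc)) {
      data[, ch, ] <- recording$samples[ch, ][idx]
    }
  }
  structure(list(data = data, times = times, rate = rate,
                 channels = recording$channel_labels,
                 roles = recording$channel_roles,
                 trial_index = trial_index,
                 amplitude_rejected = rep(FALSE, nt),
                 response_rejected = rep(FALSE, nt),
                 n_dropped_edge = n_dropped),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples [%g, %g) ms\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              x$times[1], x$times[length(x$times)] + 1000 / x$rate))
  cat(sprintf("  rejected: %d amplitude, %d response; retained %d\n",
              sum(x$amplitude_rejected), sum(x$response_rejected),
              sum(retained_trials(x))))
  invisible(x)
}

#' Trials surviving all rejection masks
#'
#' @param epochs An `epoch_set`.
#' @return Logical vector, one entry per epoch.
#' @export
retained_trials <- function(epochs) {
  !epochs$amplitude_rejected & !epochs$response_rejected
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean over the baseline window
#' (half-open, `[-200, 0)` ms by default) from the whole epoch.
#'
#' @param epochs An `epoch_set`.
#' @param baseline Baseline window in ms; must lie within the epoch window.
#' @return The corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs, baseline = c(-200, 0)) {
  stopifnot(inherits(epochs, "epoch_set"))
  idx <- window_index(epochs$times, baseline)
  if (length(idx) == 0 || baseline[1] < epochs$times[1] ||
      baseline[2] > epochs$times[length(epochs$times)] + 1000 / epochs$rate)
    stop("baseline window must lie within the epoch window")
  d <- dim(epochs$data)
  if (d[1] == 0) return(epochs)
  m <- rowMeans(matrix(epochs$data[, , idx], d[1] * d[2], length(idx)))
  epochs$data <- epochs$data - array(m, dim = d)
  epochs
}

#' Flag trials by amplitude criterion
#'
#' With `method = "median"` (the default), a trial is flagged when the median
#' of the signed sample values on any scalp channel lies outside
#' `[-limit, +limit]` (strict inequalities). `method = "peak"` flags a trial
#' when any single sample exceeds the limit in absolute value. EOG channels
#' are ignored.
#'
#' @param epochs An `epoch_set`.
#' @param limit Amplitude limit in microvolts.
#' @param method `"median"` or `"peak"`.
#' @return The `epoch_set` with its `amplitude_rejected` mask set.
#' @export
reject_amplitude <- function(epochs, limit = 150,
                             method = c("median", "peak")) {
  stopifnot(inherits(epochs, "epoch_set"), limit > 0)
  method <- match.arg(method)
  d <- dim(epochs$data)
  if (d[1] == 0) return(epochs)
  eeg <- which(epochs$roles == "EEG")
  flagged <- rep(FALSE, d[1])
  for (ch in eeg) {
    m <- matrix(epochs$data[, ch, ], d[1], d[3])
    stat <- if (method == "median") apply(m, 1, stats::median)
            else apply(abs(m), 1, max)
    flagged <- flagged | stat > limit | stat < -limit
  }
  epochs$amplitude_rejected <- flagged
  epochs
}

#' Keep only correct-response trials
#'
#' Sets the response mask so that only trials whose event row has
#' `response == "correct"` pass downstream.
#'
#' @param epochs An `epoch_set`.
#' @param events The event table the epochs were cut from.
#' @return The `epoch_set` with its `response_rejected` mask set.
#' @export
select_responses <- function(epochs, events) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (!"response" %in% names(events))
    stop("event table has no 'response' column")
  validate_events(events)
  epochs$response_rejected <-
    events$response[epochs$trial_index] != "correct"
  epochs
}

#' Subject inclusion thresholds
#'
#' @param min_correct A subject needs strictly more than this many correct
#'   trials.
#' @param max_bad A subject needs strictly fewer than this many
#'   incorrect-or-no-response trials.
#' @param min_iq Minimum IQ (inclusive).
#' @param amp_limit Trial amplitude limit in microvolts (carried here for
#'   reporting; applied by [reject_amplitude]).
#' @return An object of class `inclusion_rule`.
#' @export
inclusion_rule <- function(min_correct = 20, max_bad = 60, min_iq = 70,
                           amp_limit = 150) {
  stopifnot(min_correct > 0, max_bad > 0, min_iq > 0, amp_limit > 0)
  structure(list(min_correct = min_correct, max_bad = max_bad,
                 min_iq = min_iq, amp_limit = amp_limit),
            class = "inclusion_rule")
}

#' Decide whether a subject enters the analysis
#'
#' A subject is included iff they have strictly more than `min_correct`
#' correct trials, strictly fewer than `max_bad` incorrect-or-no-response
#' trials, and IQ at or above `min_iq`. Every failed criterion is listed in
#' `reasons`.
#'
#' @param events Subject event table (or `NULL` if counts are supplied).
#' @param metadata One-row data.frame (or list) with at least `iq`.
#' @param rule An [inclusion_rule].
#' @param counts Optional named list/vector with `correct` and `bad` counts,
#'   used instead of `events` (e.g. for ERP-level synthetic subjects).
#' @return A list with `included` (logical), `reasons` (character), and the
#'   counts used.
#' @export
include_subject <- function(events, metadata, rule = inclusion_rule(),
                            counts = NULL) {
  if (is.null(counts)) {
    validate_events(events)
    counts <- list(correct = sum(events$response == "correct"),
                   bad = sum(events$response != "correct"))
  }
  reasons <- character(0)
  if (!(counts$correct > rule$min_correct))
    reasons <- c(reasons, sprintf("correct trials (%d) not > %d",
                                  counts$correct, rule$min_correct))
  if (!(counts$bad < rule$max_bad))
    reasons <- c(reasons, sprintf("incorrect/no-response trials (%d) not < %d",
                                  counts$bad, rule$max_bad))
  iq <- metadata$iq
  if (!is.null(iq) && !is.na(iq) && !(iq >= rule$min_iq))
    reasons <- c(reasons, sprintf("IQ (%g) below %g", iq, rule$min_iq))
  list(included = length(reasons) == 0, reasons = reasons,
       correct = counts$correct, bad = counts$bad)
}

#' Preprocessing configuration
#'
#' @param band Scalp-channel band-pass in Hz.
#' @param eog_band EOG band-pass in Hz (applied inside the regression step).
#' @param window Epoch window in ms.
#' @param baseline Baseline window in ms.
#' @param amp_limit,amp_method Trial amplitude rejection settings
#'   (see [reject_amplitude]).
#' @param drop_channels Channel labels to drop before EOG regression (the
#'   config-driven counterpart of visual bad-channel marking).
#' @param rule An [inclusion_rule].
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(band = c(1, 25), eog_band = c(1, 7),
                              window = c(-200, 800), baseline = c(-200, 0),
                              amp_limit = 150, amp_method = "median",
                              drop_channels = character(),
                              rule = inclusion_rule()) {
  structure(list(band = band, eog_band = eog_band, window = window,
                 baseline = baseline, amp_limit = amp_limit,
                 amp_method = amp_method, drop_channels = drop_channels,
                 rule = rule),
            class = "preprocess_config")
}

#' Run the full preprocessing chain for one subject
#'
#' Fixed order: band-pass (scalp channels) -> drop listed bad channels ->
#' EOG regression -> detrend -> epoch -> baseline correction -> amplitude
#' rejection -> response selection. The per-subject report assigns every
#' rejected trial to exactly one category (edge, amplitude, or response; a
#' trial failing both amplitude and response is counted under amplitude).
#'
#' @param recording A [continuous_recording] containing both scalp and EOG
#'   channels.
#' @param events The subject's event table.
#' @param config A [preprocess_config].
#' @return A list with `epochs` (the masked `epoch_set`), `events`, and
#'   `report` (named counts).
#' @export
preprocess_subject <- function(recording, events,
                               config = preprocess_config()) {
  stopifnot(inherits(recording, "continuous_recording"),
            inherits(config, "preprocess_config"))
  validate_events(events)
  eeg_labels <- recording$channel_labels[recording$channel_roles == "EEG"]
  eeg_labels <- setdiff(eeg_labels, config$drop_channels)
  eog_labels <- recording$channel_labels[recording$channel_roles == "EOG"]
  if (length(eeg_labels) == 0 || length(eog_labels) == 0)
    stop("need at least one EEG and one EOG channel")
  eeg <- bandpass(subset_channels(recording, eeg_labels),
                  config$band[1], config$band[2])
  eeg <- regress_out_eog(eeg, subset_channels(recording, eog_labels),
                         eog_band = config$eog_band)
  eeg <- detrend_recording(eeg)
  epochs <- epoch_recording(eeg, events, config$window)
  epochs <- baseline_correct(epochs, config$baseline)
  epochs <- reject_amplitude(epochs, config$amp_limit, config$amp_method)
  epochs <- select_responses(epochs, events)
  n_amp <- sum(epochs$amplitude_rejected)
  n_resp <- sum(epochs$response_rejected & !epochs$amplitude_rejected)
  report <- c(n_trials = nrow(events),
              n_dropped_edge = epochs$n_dropped_edge,
              n_rejected_amplitude = n_amp,
              n_rejected_response = n_resp,
              n_retained = sum(retained_trials(epochs)))
  list(epochs = epochs, events = events, report = report)
}
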