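# Synthetic ERP studies with known ground truth.
#
# The generator emulates the audio-visual congruency paradigm: three stimulus
# categories presented in equal proportion, keyed responses with ~80%
# accuracy, reaction times on a lognormal scale around 1.5-1.8 s, ERP
# templates built from Gaussian component bumps (a negativity near 400 ms and
# a positivity in the 500-800 ms range), 1/f background noise, and blink
# artifacts that enter the scalp channels through frontally weighted mixing
# of the EOG process.

#' ERP component specification
#'
#' A single ERP component modelled as a Gaussian bump in time with a fixed
#' scalp topography: `amplitude * exp(-(t - center)^2 / (2 * width^2)) *
#' channel_gain`.
#'
#' @param name Component label (e.g. `"N400"`).
#' @param center_latency Peak latency in ms post-stimulus.
#' @param width Temporal spread (Gaussian SD) in ms; must be positive.
#' @param amplitude Signed peak amplitude in microvolts (negative for a
#'   negativity).
#' @param channel_gains Named numeric vector of per-channel multipliers in
#'   `[0, 1]`, one per scalp channel.
#' @return An object of class `erp_component`.
#' @export
#' @examples
#' n400 <- erp_component("N400", 400, 60, -5,
#'                       channel_gains = stats::setNames(rep(1, 6),
#'                       c("F7", "Fz", "F8", "Cz", "CP5", "Pz")))
erp_component <- function(name, center_latency, width, amplitude,
                          channel_gains) {
  stopifnot(is.character(name), length(name) == 1,
            is.numeric(width), width > 0,
            is.numeric(amplitude), length(amplitude) == 1,
            is.numeric(channel_gains))
  if (any(channel_gains < 0 | channel_gains > 1))
    stop("channel_gains must lie in [0, 1]")
  structure(list(name = name, center_latency = center_latency, width = width,
                 amplitude = amplitude, channel_gains = channel_gains),
            class = "erp_component")
}

default_amplitudes <- function() {
  a <- array(NA_real_,
             dim = c(2, 3, 2),
             dimnames = list(group = group_levels(),
                             condition = condition_levels(),
                             component = component_levels()))
  # Negativity near 400 ms: present everywhere, enhanced by incongruency in
  # the typically developing group only.
  a["ASD", , "N400"] <- c(-4, -4, -4)
  a["TD", , "N400"] <- c(-4, -6, -6)
  # Late positivity: a 2 uV incongruency effect planted in the TD group only;
  # flat across conditions in the ASD group.
  a["ASD", , "P600"] <- c(3, 3, 3)
  a["TD", , "P600"] <- c(3, 5, 5)
  a
}

default_component_params <- function() {
  list(
    N400 = list(center = 400, width = 60,
                gains = c(F7 = 0.3, Fz = 0.6, F8 = 0.3,
                          Cz = 1.0, CP5 = 0.8, Pz = 0.8)),
    P600 = list(center = 650, width = 80,
                gains = c(F7 = 0.3, Fz = 0.5, F8 = 0.3,
                          Cz = 1.0, CP5 = 0.9, Pz = 0.9))
  )
}

#' Ground truth for a synthetic ERP study
#'
#' Collects every generative parameter of a synthetic study: design sizes,
#' per-cell ERP component amplitudes, background-noise level, blink model,
#' EOG-to-scalp mixing, behavioural response model and metadata model. The
#' defaults describe the study regime the package targets: 15 vs 37 subjects,
#' three stimulus categories in equal proportion, 80 trials per category,
#' ~80% correct responses, reaction times around 1.6 s, and a 2 uV late
#' positivity incongruency effect present in the TD-like group only.
#'
#' @param n_subjects Named integer vector of subjects per group.
#' @param n_trials_per_condition Trials per stimulus category per subject.
#' @param iti Inter-trial onset asynchrony in seconds (>= 2 s so every trial
#'   has full epoch and response-window support).
#' @param rate Sampling rate in Hz.
#' @param amplitudes 3-d array `[group, condition, component]` of component
#'   peak amplitudes in microvolts.
#' @param components Per-component latency/width/topography parameters.
#' @param subject_amplitude_sd Between-subject SD of component amplitude
#'   (uV), shared across conditions within a subject.
#' @param noise_sd SD of the 1/f background process per scalp channel (uV).
#' @param blink_rate Blink events per second.
#' @param blink_amplitude Blink peak amplitude at the EOG channels (uV).
#' @param blink_duration Blink pulse duration in seconds.
#' @param eog_mixing Named numeric vector: fraction of the blink process
#'   leaking into each scalp channel (frontally weighted by default).
#' @param eog_noise_sd SD of white sensor noise on the EOG channels (uV).
#' @param p_correct Probability of a correct response per trial.
#' @param p_none_given_error Probability that a non-correct trial is a
#'   no-response trial rather than an incorrect keypress.
#' @param rt_meanlog,rt_sdlog Lognormal reaction-time parameters (seconds;
#'   RT is measured from the end of the spoken description).
#' @param iq_mean,iq_sd,iq_range Normal model (truncated to `iq_range`) for
#'   the synthetic IQ metadata used by the inclusion rule.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(n_subjects = c(ASD = 15, TD = 37),
                         n_trials_per_condition = 80,
                         iti = 2,
                         rate = 500,
                         amplitudes = default_amplitudes(),
                         components = default_component_params(),
                         subject_amplitude_sd = 1.5,
                         noise_sd = 5,
                         blink_rate = 0.25,
                         blink_amplitude = 120,
                         blink_duration = 0.3,
                         eog_mixing = c(F7 = 0.40, Fz = 0.30, F8 = 0.40,
                                        Cz = 0.15, CP5 = 0.10, Pz = 0.05),
                         eog_noise_sd = 2,
                         p_correct = 0.8,
                         p_none_given_error = 0.25,
                         rt_meanlog = log(1.65) - 0.3^2 / 2,
                         rt_sdlog = 0.3,
                         iq_mean = 100, iq_sd = 15, iq_range = c(40, 160)) {
  stopifnot(all(n_subjects >= 1), n_trials_per_condition >= 1,
            p_correct >= 0, p_correct <= 1,
            noise_sd >= 0, blink_rate >= 0, blink_duration > 0,
            all(is.finite(eog_mixing)), rate > 0, iti > 0)
  if (is.null(names(n_subjects))) names(n_subjects) <- group_levels()
  stopifnot(identical(dimnames(amplitudes)$condition, condition_levels()),
            identical(dimnames(amplitudes)$component, component_levels()))
  structure(list(n_subjects = n_subjects,
                 n_trials_per_condition = n_trials_per_condition,
                 iti = iti, rate = rate, amplitudes = amplitudes,
                 components = components,
                 subject_amplitude_sd = subject_amplitude_sd,
                 noise_sd = noise_sd, blink_rate = blink_rate,
                 blink_amplitude = blink_amplitude,
                 blink_duration = blink_duration,
                 eog_mixing = eog_mixing, eog_noise_sd = eog_noise_sd,
                 p_correct = p_correct,
                 p_none_given_error = p_none_given_error,
                 rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog,
                 iq_mean = iq_mean, iq_sd = iq_sd, iq_range = iq_range),
            class = "ground_truth")
}

#' Balanced randomized stimulus schedule
#'
#' Assigns the three stimulus categories in as close to equal proportion as
#' `n_trials` allows (counts differ by at most one) and lays trial onsets on
#' a regular grid spaced by `iti`, leaving one second of recording before the
#' first onset for epoch support.
#'
#' @param n_trials Total number of trials (>= 3).
#' @param iti Onset-to-onset interval in seconds; must be at least 2 s
#'   (epoch length plus response window).
#' @param seed Integer seed for the randomized category order.
#' @param rate Sampling rate in Hz.
#' @return An object of class `stimulus_schedule` with `onsets` (sample
#'   indices, strictly increasing) and `conditions`.
#' @export
make_schedule <- function(n_trials, iti = 2, seed = 1, rate = 500) {
  if (n_trials < 3)
    stop("invalid design: need at least 3 trials (one per condition)")
  if (iti < 2)
    stop("invalid design: iti must be >= 2 s (epoch length + response window)")
  conds <- condition_levels()
  base <- rep(conds, floor(n_trials / 3))
  rem <- n_trials - length(base)
  sequence <- with_seed(seed, {
    extra <- if (rem > 0) sample(conds, rem) else character(0)
    sample(c(base, extra))
  })
  onsets <- as.integer(round(rate + (seq_len(n_trials) - 1) * iti * rate))
  structure(list(onsets = onsets, iti = iti, conditions = sequence,
                 rate = rate, n_trials = n_trials),
            class = "stimulus_schedule")
}

#' Evaluate an ERP template on a time grid
#'
#' Sums Gaussian component bumps, scaled per channel by each component's
#' topography gains, over a millisecond time grid. Components with zero
#' amplitude contribute exactly zero.
#'
#' @param components List of [erp_component] objects (all with identically
#'   named `channel_gains`).
#' @param time_grid Numeric vector of times in ms relative to stimulus onset.
#' @return A channels x time matrix in microvolts with channel row names.
#' @export
erp_waveform <- function(components, time_grid) {
  if (inherits(components, "erp_component")) components <- list(components)
  stopifnot(length(components) >= 1)
  gains0 <- components[[1]]$channel_gains
  wave <- matrix(0, length(gains0), length(time_grid),
                 dimnames = list(names(gains0), NULL))
  for (comp in components) {
    stopifnot(length(comp$channel_gains) == length(gains0))
    if (comp$amplitude == 0) next
    bump <- comp$amplitude *
      exp(-(time_grid - comp$center_latency)^2 / (2 * comp$width^2))
    wave <- wave + outer(comp$channel_gains, bump)
  }
  wave
}

# Epoch time grid in ms: half-open [window[1], window[2]) sampled at `rate`.
epoch_times <- function(window = c(-200, 800), rate = 500) {
  seq(window[1], window[2] - 1000 / rate, by = 1000 / rate)
}

# Template (scalp channels x epoch samples) for one group x condition cell,
# optionally with per-component subject amplitude offsets.
cell_template <- function(truth, group, condition, times = epoch_times(),
                          amp_offset = c(N400 = 0, P600 = 0)) {
  comps <- lapply(component_levels(), function(cn) {
    p <- truth$components[[cn]]
    erp_component(cn, p$center, p$width,
                  truth$amplitudes[group, condition, cn] + amp_offset[cn],
                  p$gains)
  })
  erp_waveform(comps, times)
}

# Behavioural draws for one subject: response category and RT per trial.
draw_responses <- function(truth, n) {
  correct <- stats::rbinom(n, 1, truth$p_correct) == 1
  response <- ifelse(correct, "correct",
                     ifelse(stats::runif(n) < truth$p_none_given_error,
                            "none", "incorrect"))
  rt <- stats::rlnorm(n, truth$rt_meanlog, truth$rt_sdlog)
  rt[response == "none"] <- NA_real_
  data.frame(response = response, rt_seconds = rt)
}

#' Generate one subject's continuous recording and event table
#'
#' Builds the per-trial ERP template for the subject's group, adds 1/f
#' background noise on the scalp channels, runs a Poisson blink process whose
#' raised-cosine pulses appear at the EOG channels and leak into the scalp
#' channels through `truth$eog_mixing`, and draws responses and reaction
#' times. Identical `(truth, group, seed)` give byte-identical output.
#'
#' @param truth A [ground_truth].
#' @param group Group label (must index `truth$amplitudes`).
#' @param seed Integer seed.
#' @return A list with elements `recording` ([continuous_recording]) and
#'   `events` (data.frame: `onset_sample`, `condition`, `response`,
#'   `rt_seconds`).
#' @export
generate_subject <- function(truth, group, seed = 1) {
  stopifnot(inherits(truth, "ground_truth"),
            group %in% dimnames(truth$amplitudes)$group)
  rate <- truth$rate
  n_trials <- 3 * truth$n_trials_per_condition
  sched <- make_schedule(n_trials, truth$iti, seed = derive_seed(seed, 1),
                         rate = rate)
  behav <- with_seed(derive_seed(seed, 2), draw_responses(truth, n_trials))
  events <- data.frame(onset_sample = sched$onsets,
                       condition = sched$conditions,
                       response = behav$response,
                       rt_seconds = behav$rt_seconds)

  n_samp <- max(sched$onsets) + round(2 * rate)   # 0.8 s epoch + response tail
  times <- epoch_times(rate = rate)
  offs <- round(times[1] / 1000 * rate):(round(times[1] / 1000 * rate) +
                                           length(times) - 1)
  n_eeg <- length(eeg_channels())

  samples <- with_seed(derive_seed(seed, 3), {
    x <- matrix(0, length(all_channels()), n_samp,
                dimnames = list(all_channels(), NULL))
    # background: 1/f noise on scalp channels, white sensor noise on EOG
    x[1:n_eeg, ] <- t(shaped_noise(n_samp, n_eeg, sd = truth$noise_sd,
                                   rate = rate))
    x[n_eeg + 1:2, ] <- truth$eog_noise_sd *
      matrix(stats::rnorm(2 * n_samp), 2, n_samp)

    # subject-level component amplitude offsets (shared across conditions)
    amp_offset <- stats::setNames(
      stats::rnorm(2, 0, truth$subject_amplitude_sd), component_levels())
    templates <- lapply(stats::setNames(nm = condition_levels()),
                        function(cond) cell_template(truth, group, cond,
                                                     times, amp_offset))
    for (i in seq_len(n_trials)) {
      idx <- sched$onsets[i] + offs
      x[1:n_eeg, idx] <- x[1:n_eeg, idx] + templates[[sched$conditions[i]]]
    }

    # blink process: raised-cosine pulses at Poisson event times
    dur_s <- n_samp / rate
    n_blinks <- stats::rpois(1, truth$blink_rate * dur_s)
    if (n_blinks > 0) {
      blink <- numeric(n_samp)
      pulse_len <- round(truth$blink_duration * rate)
      pulse <- truth$blink_amplitude * 0.5 *
        (1 - cos(2 * pi * seq(0, 1, length.out = pulse_len)))
      starts <- sort(sample.int(n_samp - pulse_len, n_blinks, replace = TRUE))
      for (s in starts) {
        blink[s:(s + pulse_len - 1)] <- blink[s:(s + pulse_len - 1)] + pulse
      }
      x[n_eeg + 1, ] <- x[n_eeg + 1, ] + blink
      x[n_eeg + 2, ] <- x[n_eeg + 2, ] + 0.8 * blink
      mix <- truth$eog_mixing[eeg_channels()]
      x[1:n_eeg, ] <- x[1:n_eeg, ] + outer(unname(mix), blink)
    }
    x
  })

  list(recording = continuous_recording(samples, rate = rate),
       events = events)
}

#' Generate one subject's ERPs directly (epoch-level shortcut)
#'
#' For large simulation studies (type-I error, power) the continuous-signal
#' path is unnecessarily expensive: what reaches the statistics is the
#' trial-averaged, band-limited ERP. This generator draws that average
#' directly: per condition, the retained-trial count is Binomial(n_trials,
#' p_correct), and the subject ERP is the planted template plus band-limited
#' (1-25 Hz) 1/f noise with per-sample SD `noise_sd / sqrt(n_retained)`.
#' Blink artifacts are not simulated at this level (they are exercised by the
#' continuous path and its cleaning stage).
#'
#' @inheritParams generate_subject
#' @return A `subject_erp` object (see [average_erp]) with per-condition
#'   retained-trial counts and the subject's total correct/bad trial counts.
#' @export
generate_subject_erp <- function(truth, group, seed = 1) {
  stopifnot(inherits(truth, "ground_truth"),
            group %in% dimnames(truth$amplitudes)$group)
  times <- epoch_times(rate = truth$rate)
  with_seed(seed, {
    amp_offset <- stats::setNames(
      stats::rnorm(2, 0, truth$subject_amplitude_sd), component_levels())
    n_ret <- stats::rbinom(3, truth$n_trials_per_condition, truth$p_correct)
    names(n_ret) <- condition_levels()
    means <- list()
    for (cond in condition_levels()) {
      if (n_ret[cond] == 0) next
      tmpl <- cell_template(truth, group, cond, times, amp_offset)
      noise <- t(shaped_noise(length(times), length(eeg_channels()),
                              sd = truth$noise_sd / sqrt(n_ret[cond]),
                              rate = truth$rate, band = c(1, 25)))
      rownames(noise) <- eeg_channels()
      means[[cond]] <- tmpl + noise
    }
    n_total <- 3 * truth$n_trials_per_condition
    new_subject_erp(means, times = times,
                    n_trials_used = n_ret[names(means)],
                    n_correct = sum(n_ret), n_bad = n_total - sum(n_ret))
  })
}

#' Generate a complete synthetic study
#'
#' Draws every subject in every group, plus per-subject metadata (group label
#' and a synthetic IQ score from a truncated normal), deterministically from
#' a single master seed. `level = "continuous"` produces full recordings for
#' the preprocessing chain; `level = "erp"` produces subject ERPs directly
#' via [generate_subject_erp] for large simulation studies.
#'
#' @inheritParams generate_subject
#' @param level `"continuous"` or `"erp"`.
#' @return An object of class `erp_study`: `subjects` (named list),
#'   `metadata` (data.frame: `subject`, `group`, `iq`), `truth`, `level`.
#' @export
generate_study <- function(truth, seed = 1, level = c("continuous", "erp")) {
  level <- match.arg(level)
  stopifnot(inherits(truth, "ground_truth"))
  groups <- rep(names(truth$n_subjects), truth$n_subjects)
  n <- length(groups)
  ids <- sprintf("S%02d", seq_len(n))
  iq <- with_seed(derive_seed(seed, 0),
                  round(rnorm_trunc(n, truth$iq_mean, truth$iq_sd,
                                    truth$iq_range[1], truth$iq_range[2])))
  metadata <- data.frame(subject = ids, group = groups, iq = iq)
  subjects <- vector("list", n)
  names(subjects) <- ids
  for (i in seq_len(n)) {
    s <- derive_seed(seed, i)
    subjects[[i]] <- if (level == "continuous")
      generate_subject(truth, groups[i], seed = s)
    else
      generate_subject_erp(truth, groups[i], seed = s)
  }
  structure(list(subjects = subjects, metadata = metadata, truth = truth,
                 level = level, seed = seed),
            class = "erp_study")
}

#' @export
print.erp_study <- function(x, ...) {
  cat(sprintf("<erp_study> %d subjects (%s), level = %s, seed = %s\n",
              nrow(x$metadata),
              paste(sprintf("%s: %d", names(table(x$metadata$group)),
                            table(x$metadata$group)), collapse = ", "),
              x$level, format(x$seed)))
  invisible(x)
}

#' Serialize ground truth as plain-text key = value configuration
#'
#' Scalar fields are written as `key = value`; vectors as comma-separated
#' `name:value` pairs; the amplitude array as one key per
#' `group.condition.component` cell. `read_ground_truth` reverses the
#' mapping.
#'
#' @param truth A [ground_truth].
#' @param path File path.
#' @return `write_ground_truth` returns `path` invisibly; `read_ground_truth`
#'   returns a [ground_truth].
#' @export
write_ground_truth <- function(truth, path) {
  fmt_vec <- function(v) {
    if (is.null(names(v))) paste(v, collapse = ",")
    else paste(sprintf("%s:%.10g", names(v), v), collapse = ",")
  }
  lines <- character(0)
  add <- function(key, value) lines[[length(lines) + 1]] <<-
      sprintf("%s = %s", key, value)
  scalars <- c("n_trials_per_condition", "iti", "rate",
               "subject_amplitude_sd", "noise_sd", "blink_rate",
               "blink_amplitude", "blink_duration", "eog_noise_sd",
               "p_correct", "p_none_given_error", "rt_meanlog", "rt_sdlog",
               "iq_mean", "iq_sd")
  for (k in scalars) add(k, sprintf("%.10g", truth[[k]]))
  add("n_subjects", fmt_vec(truth$n_subjects))
  add("eog_mixing", fmt_vec(truth$eog_mixing))
  add("iq_range", fmt_vec(truth$iq_range))
  dn <- dimnames(truth$amplitudes)
  for (g in dn$group) for (cond in dn$condition) for (comp in dn$component)
    add(sprintf("amplitude.%s.%s.%s", g, cond, comp),
        sprintf("%.10g", truth$amplitudes[g, cond, comp]))
  for (comp in names(truth$components)) {
    p <- truth$components[[comp]]
    add(sprintf("component.%s.center", comp), sprintf("%.10g", p$center))
    add(sprintf("component.%s.width", comp), sprintf("%.10g", p$width))
    add(sprintf("component.%s.gains", comp), fmt_vec(p$gains))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- do.call(rbind, strsplit(lines, " = ", fixed = TRUE))
  vals <- stats::setNames(as.list(kv[, 2]), kv[, 1])
  parse_vec <- function(s) {
    parts <- strsplit(s, ",", fixed = TRUE)[[1]]
    if (all(grepl(":", parts, fixed = TRUE))) {
      sp <- strsplit(parts, ":", fixed = TRUE)
      stats::setNames(as.numeric(vapply(sp, `[`, "", 2)),
                      vapply(sp, `[`, "", 1))
    } else as.numeric(parts)
  }
  amps <- default_amplitudes()
  for (g in dimnames(amps)$group)
    for (cond in dimnames(amps)$condition)
      for (comp in dimnames(amps)$component)
        amps[g, cond, comp] <-
          as.numeric(vals[[sprintf("amplitude.%s.%s.%s", g, cond, comp)]])
  comps <- lapply(stats::setNames(nm = component_levels()), function(comp) {
    list(center = as.numeric(vals[[sprintf("component.%s.center", comp)]]),
         width = as.numeric(vals[[sprintf("component.%s.width", comp)]]),
         gains = parse_vec(vals[[sprintf("component.%s.gains", comp)]]))
  })
  num <- function(k) as.numeric(vals[[k]])
  ground_truth(n_subjects = parse_vec(vals$n_subjects),
               n_trials_per_condition = num("n_trials_per_condition"),
               iti = num("iti"), rate = num("rate"),
               amplitudes = amps, components = comps,
               subject_amplitude_sd = num("subject_amplitude_sd"),
               noise_sd = num("noise_sd"), blink_rate = num("blink_rate"),
               blink_amplitude = num("blink_amplitude"),
               blink_duration = num("blink_duration"),
               eog_mixing = parse_vec(vals$eog_mixing),
               eog_noise_sd = num("eog_noise_sd"),
               p_correct = num("p_correct"),
               p_none_given_error = num("p_none_given_error"),
               rt_meanlog = num("rt_meanlog"), rt_sdlog = num("rt_sdlog"),
               iq_mean = num("iq_mean"), iq_sd = num("iq_sd"),
               iq_range = parse_vec(vals$iq_range))
}

#' Write a synthetic study bundle to disk
#'
#' One recording TSV and one events TSV per subject, a metadata TSV, and the
#' ground-truth configuration, all plain text.
#'
#' @param study An `erp_study` at `level = "continuous"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "erp_study"), study$level == "continuous")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(study$subjects)) {
    write_recording(study$subjects[[id]]$recording,
                    file.path(dir, paste0(id, "_recording.tsv")))
    write_events(study$subjects[[id]]$events,
                 file.path(dir, paste0(id, "_events.tsv")))
  }
  utils::write.table(study$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  write_ground_truth(study$truth, file.path(dir, "ground_truth.cfg"))
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  metadata <- utils::read.table(file.path(dir, "metadata.tsv"), header = TRUE,
                                sep = "\t", stringsAsFactors = FALSE)
  truth_path <- file.path(dir, "ground_truth.cfg")
  truth <- if (file.exists(truth_path)) read_ground_truth(truth_path)
           else NULL
  subjects <- lapply(metadata$subject, function(id) {
    list(recording = read_recording(file.path(dir,
                                              paste0(id, "_recording.tsv"))),
         events = read_events(file.path(dir, paste0(id, "_events.tsv"))))
  })
  names(subjects) <- metadata$subject
  structure(list(subjects = subjects, metadata = metadata, truth = truth,
                 level = "continuous", seed = NA_integer_),
            class = "erp_study")
}
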