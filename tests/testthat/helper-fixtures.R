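# Fixtures built in code: small ground truths and feature matrices used
# across test files.

# A light study regime for continuous-pipeline tests: few trials, short
# recordings, no between-subject amplitude spread unless asked for.
small_truth <- function(n_trials_per_condition = 6,
                        n_subjects = c(ASD = 3, TD = 3),
                        noise_sd = 5, blink_rate = 0.25,
                        subject_amplitude_sd = 0, p_correct = 0.8, ...) {
  ground_truth(n_subjects = n_subjects,
               n_trials_per_condition = n_trials_per_condition,
               noise_sd = noise_sd, blink_rate = blink_rate,
               subject_amplitude_sd = subject_amplitude_sd,
               p_correct = p_correct, ...)
}

# Amplitude array with no group or condition effects anywhere.
flat_amplitudes <- function(n400 = -4, p600 = 3) {
  a <- erppls:::default_amplitudes()
  a[, , "N400"] <- n400
  a[, , "P600"] <- p600
  a
}

# Feature matrix of iid Gaussian rows for k cells: `per_cell` subjects per
# cell, single-condition between-subject layout.
gaussian_fm <- function(per_cell = c(8, 8), n_features = 30, sd = 1,
                        conditions = "congruent") {
  k <- length(per_cell)
  groups <- rep(paste0("G", seq_len(k)), per_cell)
  n <- length(groups)
  feature_matrix(matrix(rnorm(n * n_features, sd = sd), n, n_features),
                 subjects = sprintf("S%03d", seq_len(n)),
                 groups = groups,
                 conditions = rep(conditions, n))
}

# Repeated-measures feature matrix: each subject appears once per condition,
# rows grouped by condition cell; optional per-condition mean shifts.
within_fm <- function(n_subjects = 10, conditions = c("A", "B", "C"),
                      n_features = 20, sd = 1,
                      shifts = rep(0, length(conditions))) {
  ids <- sprintf("S%03d", seq_len(n_subjects))
  blocks <- lapply(seq_along(conditions), function(j) {
    matrix(rnorm(n_subjects * n_features, mean = shifts[j], sd = sd),
           n_subjects, n_features)
  })
  feature_matrix(do.call(rbind, blocks),
                 subjects = rep(ids, length(conditions)),
                 groups = "G1",
                 conditions = rep(conditions, each = n_subjects))
}

# A tiny noise-only continuous recording with both EEG and EOG channels.
noise_recording <- function(n_seconds = 10, rate = 500, sd = 5, seed = 1) {
  n <- n_seconds * rate
  set.seed(seed)
  continuous_recording(matrix(rnorm(8 * n, sd = sd), 8, n,
                              dimnames = list(erppls:::all_channels(), NULL)),
                       rate = rate)
}
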