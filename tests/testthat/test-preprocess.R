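# Preprocessing chain: filtering, ocular regression, detrending, epoching,
# baseline correction, rejection masks, inclusion rule.

single_channel <- function(x, rate = 500, label = "Fz", role = "EEG") {
  continuous_recording(matrix(x, 1), rate = rate, channel_labels = label,
                       channel_roles = role)
}

test_that("band-pass keeps the passband and rejects stopband and DC", {
  rate <- 500
  t <- seq_len(10 * rate) / rate
  mid <- (2 * rate):(8 * rate)   # avoid filter edges

  in_band <- sin(2 * pi * 10 * t)
  out <- bandpass(single_channel(in_band))$samples[1, ]
  expect_lt(abs(sd(out[mid]) / sd(in_band[mid]) - 1), 0.05)

  stopband <- sin(2 * pi * 50 * t)   # one octave above the 25 Hz edge
  out50 <- bandpass(single_channel(stopband))$samples[1, ]
  expect_lt(sd(out50[mid]) / sd(stopband[mid]), 0.1)

  dc <- rep(100, length(t))
  outdc <- bandpass(single_channel(dc))$samples[1, ]
  expect_lt(max(abs(outdc)), 1)

  expect_error(bandpass(single_channel(in_band), 25, 1), "invalid band")
  expect_error(bandpass(single_channel(in_band), 1, 400), "invalid band")
})

test_that("zero-phase filtering does not shift component latency", {
  rate <- 500
  t_ms <- (seq_len(6 * rate) / rate) * 1000
  bump <- -5 * exp(-(t_ms - 3000)^2 / (2 * 60^2))
  out <- bandpass(single_channel(bump))$samples[1, ]
  expect_equal(which.min(out), which.min(bump), tolerance = 0)
})

test_that("EOG regression is exact for purely linear contamination", {
  set.seed(42)
  n <- 5000
  eog <- continuous_recording(matrix(rnorm(2 * n, sd = 40), 2, n,
                                     dimnames = list(c("EOG1", "EOG2"), NULL)),
                              channel_roles = c("EOG", "EOG"))
  filt <- bandpass(eog, 1, 7)
  clean0 <- matrix(rnorm(3 * n, sd = 5), 3, n)
  # make the clean signal exactly orthogonal to intercept + regressors
  X <- cbind(1, t(filt$samples))
  clean <- clean0 - t(X %*% solve(crossprod(X), crossprod(X, t(clean0))))
  contaminated <- clean + 0.3 * t(X[, 2:3] %*% matrix(1, 2, 3))
  eeg <- continuous_recording(contaminated, channel_labels = c("Fz", "Cz", "Pz"),
                              channel_roles = rep("EEG", 3))
  out <- regress_out_eog(eeg, eog)
  expect_lt(max(abs(out$samples - clean)), 1e-8)
  # residuals are uncorrelated with the filtered regressors
  for (ch in 1:3)
    expect_lt(max(abs(cor(out$samples[ch, ], t(filt$samples)))), 1e-10)
})

test_that("EOG regression leaves orthogonal signals alone and never adds variance", {
  set.seed(7)
  n <- 4000
  eog_sig <- matrix(rnorm(2 * n, sd = 30), 2, n,
                    dimnames = list(c("EOG1", "EOG2"), NULL))
  eog <- continuous_recording(eog_sig, channel_roles = c("EOG", "EOG"))
  filt <- bandpass(eog, 1, 7)
  X <- cbind(1, t(filt$samples))
  raw <- matrix(rnorm(2 * n, sd = 5), 2, n)
  ortho <- raw - t(X %*% solve(crossprod(X), crossprod(X, t(raw))))
  eeg <- continuous_recording(ortho, channel_labels = c("Fz", "Cz"),
                              channel_roles = c("EEG", "EEG"))
  out <- regress_out_eog(eeg, eog)
  expect_lt(max(abs(out$samples - ortho)), 1e-8)

  eeg2 <- continuous_recording(raw, channel_labels = c("Fz", "Cz"),
                               channel_roles = c("EEG", "EEG"))
  out2 <- regress_out_eog(eeg2, eog)
  expect_true(all(apply(out2$samples, 1, var) <= apply(raw, 1, var) + 1e-12))
})

test_that("zero-variance EOG regressors are skipped with a warning", {
  set.seed(8)
  n <- 2000
  eog <- continuous_recording(rbind(EOG1 = rep(0, n),
                                    EOG2 = rnorm(n, sd = 30)),
                              channel_roles = c("EOG", "EOG"))
  eeg <- continuous_recording(matrix(rnorm(n, sd = 5), 1, n),
                              channel_labels = "Fz", channel_roles = "EEG")
  expect_warning(out <- regress_out_eog(eeg, eog, eog_band = NULL),
                 "zero-variance")
  expect_equal(dim(out$samples), dim(eeg$samples))
})

test_that("detrending removes lines exactly and leaves noise nearly intact", {
  n <- 1000
  ramp <- single_channel(seq(0, 10, length.out = n))
  expect_lt(max(abs(detrend_recording(ramp)$samples)), 1e-10)

  const <- single_channel(rep(5, n))
  expect_lt(max(abs(detrend_recording(const)$samples)), 1e-12)

  set.seed(3)
  noise <- rnorm(n)
  got <- detrend_recording(single_channel(noise))$samples[1, ]
  fit <- lm(noise ~ seq_len(n))
  expect_equal(got, unname(residuals(fit)), tolerance = 1e-10)
  slope <- coef(lm(got ~ seq_len(n)))[2]
  expect_lt(abs(slope), 1e-12)
})

test_that("epoching aligns to onsets and drops unsupported trials", {
  rate <- 500
  n <- 4000
  x <- matrix(0, 2, n, dimnames = list(c("Fz", "EOG1"), NULL))
  onsets <- c(600, 1500, 2500, n - 50)
  x[1, onsets[1:3]] <- c(7, 8, 9)
  rec <- continuous_recording(x, rate = rate)
  ev <- data.frame(onset_sample = onsets,
                   condition = "congruent",
                   response = "correct", rt_seconds = 1.5)
  expect_message(ep <- epoch_recording(rec, ev), "1 trial\\(s\\) dropped")
  expect_equal(dim(ep$data), c(3, 2, 500))
  expect_equal(ep$n_dropped_edge, 1)
  t0 <- which(ep$times == 0)
  expect_equal(ep$data[, 1, t0], c(7, 8, 9))

  ev_ok <- data.frame(onset_sample = seq(600, 3000, by = 300),
                      condition = "congruent", response = "correct",
                      rt_seconds = 1)
  ep_ok <- epoch_recording(rec, ev_ok)
  expect_equal(dim(ep_ok$data)[1], nrow(ev_ok))
  expect_equal(dim(ep_ok$data)[3], 500)

  empty <- epoch_recording(rec, ev_ok[0, ])
  expect_equal(dim(empty$data)[1], 0)
})

test_that("baseline correction zeroes the baseline window and is idempotent", {
  rate <- 500
  rec <- noise_recording(20, seed = 4)
  ev <- data.frame(onset_sample = seq(600, 9000, by = 600),
                   condition = "congruent", response = "correct",
                   rt_seconds = 1)
  ep <- baseline_correct(epoch_recording(rec, ev))
  idx <- which(ep$times >= -200 & ep$times < 0)
  base_means <- apply(ep$data[, , idx, drop = FALSE], c(1, 2), mean)
  expect_lt(max(abs(base_means)), 1e-10)

  again <- baseline_correct(ep)
  expect_lt(max(abs(again$data - ep$data)), 1e-10)

  # constant-offset epoch collapses to zero; template + offset recovers it
  ep2 <- ep
  ep2$data[1, 1, ] <- 10
  ep2 <- baseline_correct(ep2)
  expect_lt(max(abs(ep2$data[1, 1, ])), 1e-12)
  tmpl <- sin(seq(0, 3 * pi, length.out = 500))
  tmpl <- tmpl - mean(tmpl[idx])
  ep3 <- ep
  ep3$data[2, 2, ] <- tmpl + 10
  ep3 <- baseline_correct(ep3)
  expect_equal(ep3$data[2, 2, ], tmpl, tolerance = 1e-10)

  expect_error(baseline_correct(ep, c(-400, 0)), "baseline")
})

test_that("median amplitude rule flags exactly the constructed outliers", {
  nt <- 10
  data <- array(0, dim = c(nt, 2, 500))
  offsets <- rep(0, nt)
  offsets[c(2, 5, 9)] <- c(200, -180, 151)
  for (i in seq_len(nt)) data[i, 1, ] <- offsets[i]
  ep <- structure(list(data = data, times = erppls:::epoch_times(),
                       rate = 500, channels = c("Fz", "EOG1"),
                       roles = c("EEG", "EOG"),
                       trial_index = seq_len(nt),
                       amplitude_rejected = rep(FALSE, nt),
                       response_rejected = rep(FALSE, nt),
                       n_dropped_edge = 0),
                  class = "epoch_set")
  out <- reject_amplitude(ep, 150)
  expect_equal(which(out$amplitude_rejected), c(2, 5, 9))

  # an EOG-channel excursion must not flag the trial
  ep$data[3, 2, ] <- 500
  out2 <- reject_amplitude(ep, 150)
  expect_false(out2$amplitude_rejected[3])

  # boundary: a median of exactly +150 is retained (strict inequality)
  ep$data[4, 1, ] <- 150
  out3 <- reject_amplitude(ep, 150)
  expect_false(out3$amplitude_rejected[4])

  # peak method flags single-sample excursions the median rule passes
  ep$data[6, 1, ] <- 0
  ep$data[6, 1, 250] <- 400
  expect_false(reject_amplitude(ep, 150)$amplitude_rejected[6])
  expect_true(reject_amplitude(ep, 150, method = "peak")$amplitude_rejected[6])
})

test_that("response selection keeps only correct trials", {
  rec <- noise_recording(20, seed = 5)
  resp <- c(rep("correct", 7), "incorrect", "none", "incorrect")
  ev <- data.frame(onset_sample = seq(600, 6000, by = 600),
                   condition = "congruent", response = resp,
                   rt_seconds = ifelse(resp == "none", NA, 1.2))
  ep <- select_responses(epoch_recording(rec, ev), ev)
  expect_equal(sum(!ep$response_rejected), 7)
  expect_identical(ep$response_rejected, resp != "correct")

  ev_bad <- ev[, c("onset_sample", "condition")]
  expect_error(select_responses(epoch_recording(rec, ev), ev_bad),
               "response")
})

test_that("inclusion boundaries are strict and reasons are complete", {
  rule <- inclusion_rule()
  mk_events <- function(correct, bad) {
    data.frame(onset_sample = seq_len(correct + bad),
               condition = "congruent",
               response = c(rep("correct", correct), rep("incorrect", bad)),
               rt_seconds = 1)
  }
  ok <- include_subject(mk_events(82, 19), list(iq = 96), rule)
  expect_true(ok$included)
  expect_length(ok$reasons, 0)

  at20 <- include_subject(mk_events(20, 5), list(iq = 100), rule)
  expect_false(at20$included)
  expect_match(at20$reasons, "correct", all = FALSE)

  at60 <- include_subject(mk_events(50, 60), list(iq = 100), rule)
  expect_false(at60$included)

  just_in <- include_subject(mk_events(21, 59), list(iq = 70), rule)
  expect_true(just_in$included)

  low_iq <- include_subject(mk_events(15, 60), list(iq = 69), rule)
  expect_false(low_iq$included)
  expect_length(low_iq$reasons, 3)
})

test_that("the full chain reports every rejected trial in one category", {
  truth <- small_truth(n_trials_per_condition = 10)
  sub <- generate_subject(truth, "ASD", seed = 31)
  pp <- preprocess_subject(sub$recording, sub$events)
  r <- pp$report
  expect_equal(unname(r["n_trials"]),
               unname(r["n_dropped_edge"] + r["n_rejected_amplitude"] +
                        r["n_rejected_response"] + r["n_retained"]))
  expect_equal(sum(retained_trials(pp$epochs)), unname(r["n_retained"]))
})

test_that("a config-driven channel drop list removes channels before regression", {
  truth <- small_truth(n_trials_per_condition = 5)
  sub <- generate_subject(truth, "TD", seed = 12)
  pp <- preprocess_subject(sub$recording, sub$events,
                           preprocess_config(drop_channels = c("F7", "F8")))
  expect_setequal(pp$epochs$channels, setdiff(erppls:::eeg_channels(),
                                              c("F7", "F8")))
})
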