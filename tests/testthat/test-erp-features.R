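# ERP averaging, component windows, feature matrices, behavioural summary.

make_epochs <- function(data, conditions, responses = NULL,
                        channels = c("Fz", "Cz")) {
  nt <- dim(data)[1]
  if (is.null(responses)) responses <- rep("correct", nt)
  ep <- structure(list(data = data, times = erppls:::epoch_times(),
                       rate = 500, channels = channels,
                       roles = rep("EEG", length(channels)),
                       trial_index = seq_len(nt),
                       amplitude_rejected = rep(FALSE, nt),
                       response_rejected = rep(FALSE, nt),
                       n_dropped_edge = 0),
                  class = "epoch_set")
  ev <- data.frame(onset_sample = seq_len(nt) * 1000,
                   condition = conditions, response = responses,
                   rt_seconds = 1)
  list(epochs = ep, events = ev)
}

test_that("averaging is the arithmetic mean over retained trials only", {
  data <- array(0, dim = c(4, 2, 500))
  data[1, , ] <- 1; data[2, , ] <- 3; data[3, , ] <- 100; data[4, , ] <- 7
  fx <- make_epochs(data, conditions = rep("congruent", 4))

  # two identical trials average to the trial itself
  fx2 <- make_epochs(data[c(1, 1), , , drop = FALSE], rep("congruent", 2))
  erp2 <- average_erp(fx2$epochs, fx2$events)
  expect_true(all(erp2$means[["congruent"]] == 1))

  # masked trials do not influence the mean
  fx$epochs$amplitude_rejected[3] <- TRUE
  erp <- average_erp(fx$epochs, fx$events)
  expect_true(all(erp$means[["congruent"]] == mean(c(1, 3, 7))))
  expect_equal(erp$n_trials_used[["congruent"]], 3)

  # zero retained trials in a condition: absent, not zero
  fx3 <- make_epochs(data, conditions = c("congruent", "congruent",
                                          "incongruent-semantic",
                                          "incongruent-semantic"),
                     responses = c("correct", "correct", "incorrect", "none"))
  ep3 <- select_responses(fx3$epochs, fx3$events)
  erp3 <- average_erp(ep3, fx3$events)
  expect_named(erp3$means, "congruent")

  # all conditions empty is a subject-level error
  fx4 <- make_epochs(data, rep("congruent", 4), responses = rep("none", 4))
  ep4 <- select_responses(fx4$epochs, fx4$events)
  expect_error(average_erp(ep4, fx4$events), "excluded")
})

test_that("trial-averaged ERPs converge to the template", {
  set.seed(77)
  n <- 400
  tmpl <- 5 * sin(seq(0, 2 * pi, length.out = 500))
  data <- array(rnorm(n * 1 * 500, sd = 8), dim = c(n, 1, 500))
  data <- data + rep(tmpl, each = n)
  fx <- make_epochs(data, rep("congruent", n), channels = "Cz")
  erp <- average_erp(fx$epochs, fx$events)
  se <- 8 / sqrt(n)
  expect_true(all(abs(erp$means[["congruent"]][1, ] - tmpl) < 4 * se))
})

test_that("component windows map to exactly 150 half-open samples", {
  n400 <- component_window("N400")
  p600 <- component_window("P600")
  expect_equal(c(n400$start, n400$end), c(200, 500))
  expect_equal(c(p600$start, p600$end), c(500, 800))

  data <- array(rnorm(2 * 2 * 500), dim = c(2, 2, 500))
  fx <- make_epochs(data, rep("congruent", 2))
  erp <- average_erp(fx$epochs, fx$events)
  v400 <- extract_window(erp, n400, "Cz", "congruent")
  v600 <- extract_window(erp, p600, "Cz", "congruent")
  expect_length(v400, 150)
  expect_length(v600, 150)
  expect_length(extract_window(erp, c(-200, 0), "Cz", "congruent"), 100)

  # windowing is pure indexing: concatenation reproduces [200, 800) exactly
  full <- erp$means[["congruent"]]["Cz", erp$times >= 200 & erp$times < 800]
  expect_equal(c(v400, v600), unname(full))

  expect_error(extract_window(erp, n400, "Oz", "congruent"), "channel")
  expect_error(extract_window(erp, n400, "Cz", "incongruent-semantic"),
               "condition")
})

make_erps <- function(n_by_group, conditions = erppls:::condition_levels(),
                      seed = 1) {
  set.seed(seed)
  ids <- sprintf("S%02d", seq_len(sum(n_by_group)))
  groups <- rep(names(n_by_group), n_by_group)
  erps <- lapply(seq_along(ids), function(i) {
    means <- lapply(stats::setNames(nm = conditions), function(cond) {
      m <- matrix(rnorm(6 * 500), 6, 500,
                  dimnames = list(erppls:::eeg_channels(), NULL))
      m
    })
    erppls:::new_subject_erp(means, times = erppls:::epoch_times(),
                             n_trials_used = stats::setNames(
                               rep(50L, length(conditions)), conditions))
  })
  names(erps) <- ids
  list(erps = erps,
       metadata = data.frame(subject = ids, group = groups, iq = 100))
}

test_that("feature matrices have the design-implied shape and order", {
  fx <- make_erps(c(ASD = 15, TD = 37))
  incong <- setdiff(erppls:::condition_levels(), "congruent")

  cells4 <- data.frame(group = rep(c("ASD", "TD"), each = 2),
                       condition = rep(incong, 2))
  fm4 <- build_feature_matrix(fx$erps, cells4, component_window("N400"),
                              "Cz", fx$metadata)
  expect_equal(dim(fm4$values), c(104, 150))
  expect_equal(unname(fm4$cell_sizes), c(15, 15, 37, 37))
  expect_equal(fm4$row_labels$cell, rep(fm4$cell_levels, fm4$cell_sizes))

  cells3 <- data.frame(group = "TD", condition = erppls:::condition_levels())
  fm3 <- build_feature_matrix(fx$erps, cells3, component_window("P600"),
                              "Pz", fx$metadata)
  expect_equal(dim(fm3$values), c(111, 150))

  cells_bad <- data.frame(group = "HC", condition = "congruent")
  expect_error(build_feature_matrix(fx$erps, cells_bad,
                                    component_window("N400"), "Cz",
                                    fx$metadata),
               "HC:congruent")
})

test_that("PLS statistics are invariant to within-cell subject order", {
  fx <- make_erps(c(ASD = 5, TD = 6), seed = 3)
  cells <- data.frame(group = c("ASD", "TD"), condition = "congruent")
  fm <- build_feature_matrix(fx$erps, cells, component_window("N400"), "Cz",
                             fx$metadata)
  # shuffle subjects within each group in the metadata/input order
  shuf_meta <- fx$metadata[c(sample(1:5), 5 + sample(1:6)), ]
  fm_shuf <- build_feature_matrix(fx$erps, cells, component_window("N400"),
                                  "Cz", shuf_meta)
  expect_equal(sort(fm_shuf$row_labels$subject), sort(fm$row_labels$subject))
  s1 <- mean_centered_pls(fm, permutation_scheme("between", 50, seed = 2))
  s2 <- mean_centered_pls(fm_shuf, permutation_scheme("between", 50, seed = 2))
  expect_equal(s1$singular_values, s2$singular_values)
  expect_equal(s1$observed_statistic, s2$observed_statistic)
})

test_that("behavioural summary mirrors the per-cell descriptives", {
  conds <- erppls:::condition_levels()
  ev_all_correct <- data.frame(onset_sample = 1:30,
                               condition = rep(conds, each = 10),
                               response = "correct", rt_seconds = 1.5)
  events_list <- list(S01 = ev_all_correct, S02 = ev_all_correct)
  meta <- data.frame(subject = c("S01", "S02"), group = "TD")
  s <- behavioral_summary(events_list, meta)
  expect_equal(nrow(s), 3)
  expect_true(all(s$pct_correct_mean == 100))
  expect_true(all(s$rt_mean == 1.5))
  expect_true(all(s$rt_sd == 0))
  expect_true(all(s$trials_mean == 10))

  # no responded trials in a cell: RT absent, not zero
  ev_none <- ev_all_correct
  ev_none$response <- "none"
  ev_none$rt_seconds <- NA
  s2 <- behavioral_summary(list(S01 = ev_none),
                           data.frame(subject = "S01", group = "ASD"))
  expect_true(all(is.na(s2$rt_mean)))
  expect_true(all(s2$pct_correct_mean == 0))
})

test_that("synthetic behavioural accuracy matches the generative rate", {
  truth <- small_truth(n_trials_per_condition = 30,
                       n_subjects = c(ASD = 2, TD = 2))
  reps <- 6
  fracs <- numeric(reps)
  for (r in seq_len(reps)) {
    st <- generate_study(truth, seed = 100 + r)
    events_list <- lapply(st$subjects, `[[`, "events")
    s <- behavioral_summary(events_list, st$metadata)
    fracs[r] <- mean(s$pct_correct_mean)
  }
  n_total <- reps * 4 * 90
  ci <- 100 * qbinom(c(0.0005, 0.9995), n_total, 0.8) / n_total
  expect_gt(mean(fracs), ci[1])
  expect_lt(mean(fracs), ci[2])
})
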