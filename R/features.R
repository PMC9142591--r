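# Per-subject ERPs, component feature windows, feature matrices, and
# behavioural summaries.

new_subject_erp <- function(means, times, n_trials_used,
                            n_correct = NA_integer_, n_bad = NA_integer_) {
  structure(list(means = means, times = times,
                 n_trials_used = n_trials_used,
                 n_correct = n_correct, n_bad = n_bad),
            class = "subject_erp")
}

#' @export
print.subject_erp <- function(x, ...) {
  cat("<subject_erp>", length(x$means), "condition(s):",
      paste(sprintf("%s (n=%d)", names(x$means), x$n_trials_used),
            collapse = ", "), "\n")
  invisible(x)
}

#' Average retained epochs into per-condition ERPs
#'
#' Arithmetic mean over retained trials (those passing both the amplitude and
#' the response mask), per condition and channel. Conditions with no retained
#' trials are reported as absent rather than as zero waveforms.
#'
#' @param epochs An `epoch_set`.
#' @param events The event table the epochs were cut from (supplies the
#'   condition label per trial).
#' @return A `subject_erp`: named list `means` of channels x time matrices
#'   (one per condition present), the time grid, and retained-trial counts.
#' @export
average_erp <- function(epochs, events) {
  stopifnot(inherits(epochs, "epoch_set"))
  keep <- retained_trials(epochs)
  conditions <- events$condition[epochs$trial_index]
  means <- list()
  n_used <- integer(0)
  for (cond in unique(conditions)) {
    idx <- which(keep & conditions == cond)
    if (length(idx) == 0) next
    m <- colMeans(epochs$data[idx, , , drop = FALSE])
    rownames(m) <- epochs$channels
    means[[cond]] <- m
    n_used[cond] <- length(idx)
  }
  if (length(means) == 0)
    stop("no condition has any retained trial; subject should be excluded")
  new_subject_erp(means, times = epochs$times, n_trials_used = n_used,
                  n_correct = sum(events$response == "correct"),
                  n_bad = sum(events$response != "correct"))
}

#' A-priori ERP component window
#'
#' The two analysis windows are fixed a priori: the N400 window spans
#' `[200, 500)` ms and the P600 window `[500, 800)` ms post-stimulus. Both
#' windows are half-open so that each maps to exactly 150 samples at 500 Hz
#' and they share no boundary sample.
#'
#' @param name `"N400"` or `"P600"`.
#' @return An object of class `component_window` with `name`, `start`, `end`.
#' @export
component_window <- function(name = c("N400", "P600")) {
  name <- match.arg(name)
  w <- switch(name, N400 = c(200, 500), P600 = c(500, 800))
  structure(list(name = name, start = w[1], end = w[2]),
            class = "component_window")
}

as_window <- function(window) {
  if (inherits(window, "component_window")) c(window$start, window$end)
  else {
    stopifnot(is.numeric(window), length(window) == 2)
    window
  }
}

#' Extract a component window as a feature vector
#'
#' Returns the ERP samples of one channel and condition on the half-open
#' window `[start, end)`: exactly 150 features for the N400 or P600 window at
#' 500 Hz.
#'
#' @param erp A `subject_erp`.
#' @param window A [component_window] or numeric `c(start, end)` in ms.
#' @param channel Channel label.
#' @param condition Condition label (must be present in the ERP).
#' @return Numeric feature vector in microvolts.
#' @export
extract_window <- function(erp, window, channel, condition) {
  stopifnot(inherits(erp, "subject_erp"))
  if (!condition %in% names(erp$means))
    stop("condition '", condition, "' not present in this subject's ERP")
  m <- erp$means[[condition]]
  if (!channel %in% rownames(m))
    stop("unknown channel: ", channel)
  idx <- window_index(erp$times, as_window(window))
  unname(m[channel, idx])
}

#' Construct a feature matrix from raw components
#'
#' Low-level constructor used by [build_feature_matrix] and by simulation
#' code that already has the feature rows in hand. Rows must be grouped
#' contiguously by design cell in `cell_levels` order.
#'
#' @param values Numeric matrix, one row per subject-by-cell observation.
#' @param subjects,groups,conditions Vectors (length `nrow(values)`) labelling
#'   each row.
#' @param cell_levels Declared cell order; defaults to order of appearance of
#'   `group:condition`.
#' @param window,channel Provenance of the features (informational).
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, subjects, groups, conditions,
                           cell_levels = NULL, window = c(NA, NA),
                           channel = NA_character_) {
  values <- as.matrix(values)
  subjects <- rep_len(subjects, nrow(values))
  groups <- rep_len(groups, nrow(values))
  conditions <- rep_len(conditions, nrow(values))
  cell <- paste(groups, conditions, sep = ":")
  if (is.null(cell_levels)) cell_levels <- unique(cell)
  if (!all(cell %in% cell_levels))
    stop("row cell labels outside the declared cell levels")
  sizes <- table(factor(cell, levels = cell_levels))
  if (any(sizes == 0))
    stop("empty design cell: ",
         paste(cell_levels[sizes == 0], collapse = ", "))
  rownames(values) <- NULL
  structure(list(values = values,
                 row_labels = data.frame(subject = subjects, group = groups,
                                         condition = conditions, cell = cell),
                 cell_levels = cell_levels,
                 cell_sizes = stats::setNames(as.integer(sizes), cell_levels),
                 window = window, channel = channel),
            class = "feature_matrix")
}

#' Stack subjects into a design-cell feature matrix
#'
#' Rows are subjects grouped contiguously by design cell, in the declared
#' cell order; columns are the component-window samples (150 features for the
#' standard windows). Every requested cell must contain at least two
#' subjects.
#'
#' @param erps Named list of `subject_erp` objects (names are subject ids).
#' @param cells data.frame with columns `group` and `condition`, one row per
#'   design cell, in the order the cells should appear.
#' @param window A [component_window] or numeric window in ms.
#' @param channel Channel label.
#' @param metadata data.frame with columns `subject` and `group` giving each
#'   subject's group.
#' @return An object of class `feature_matrix`: `values` (rows x features),
#'   `row_labels` (subject, group, condition, cell), `cell_levels`,
#'   `cell_sizes`.
#' @export
build_feature_matrix <- function(erps, cells, window, channel, metadata) {
  stopifnot(is.data.frame(cells), all(c("group", "condition") %in% names(cells)),
            is.data.frame(metadata),
            all(c("subject", "group") %in% names(metadata)))
  cell_labels <- paste(cells$group, cells$condition, sep = ":")
  if (anyDuplicated(cell_labels)) stop("duplicate design cells requested")
  rows <- list()
  labels <- list()
  sizes <- integer(length(cell_labels))
  for (j in seq_along(cell_labels)) {
    g <- cells$group[j]; cond <- cells$condition[j]
    ids <- metadata$subject[metadata$group == g]
    ids <- ids[vapply(ids, function(id) {
      !is.null(erps[[id]]) && cond %in% names(erps[[id]]$means)
    }, logical(1))]
    if (length(ids) < 2)
      stop("design cell ", cell_labels[j], " has fewer than 2 subjects (",
           length(ids), ")")
    block <- t(vapply(ids,
                      function(id) extract_window(erps[[id]], window, channel,
                                                  cond),
                      numeric(length(window_index(erps[[ids[1]]]$times,
                                                  as_window(window))))))
    rows[[j]] <- block
    sizes[j] <- length(ids)
    labels[[j]] <- data.frame(subject = ids, group = g, condition = cond,
                              cell = cell_labels[j])
  }
  values <- do.call(rbind, rows)
  row_labels <- do.call(rbind, labels)
  feature_matrix(values, row_labels$subject, row_labels$group,
                 row_labels$condition, cell_levels = cell_labels,
                 window = as_window(window), channel = channel)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d x %d (%s, [%g, %g) ms)\n",
              nrow(x$values), ncol(x$values), x$channel,
              x$window[1], x$window[2]))
  cat("  cells:", paste(sprintf("%s (n=%d)", x$cell_levels, x$cell_sizes),
                        collapse = ", "), "\n")
  invisible(x)
}

#' Behavioural summary by group and condition
#'
#' Per design cell: number of subjects, mean and SD across subjects of the
#' per-subject trial count, correct-trial count, percent correct, and mean
#' reaction time over correct trials (seconds). Subjects with no responded
#' trials in a cell contribute no RT value.
#'
#' @param events_list Named list of per-subject event tables.
#' @param metadata data.frame with `subject` and `group`.
#' @return data.frame, one row per group x condition.
#' @export
behavioral_summary <- function(events_list, metadata) {
  out <- list()
  for (g in unique(metadata$group)) {
    ids <- metadata$subject[metadata$group == g]
    for (cond in condition_levels()) {
      per <- lapply(ids, function(id) {
        ev <- events_list[[id]]
        ev <- ev[ev$condition == cond, , drop = FALSE]
        n <- nrow(ev)
        ncor <- sum(ev$response == "correct")
        rts <- ev$rt_seconds[ev$response == "correct" & !is.na(ev$rt_seconds)]
        data.frame(n = n, ncor = ncor,
                   pct = if (n > 0) 100 * ncor / n else NA_real_,
                   rt = if (length(rts) > 0) mean(rts) else NA_real_)
      })
      per <- do.call(rbind, per)
      out[[length(out) + 1]] <- data.frame(
        group = g, condition = cond, n_subjects = length(ids),
        trials_mean = mean(per$n), trials_sd = stats::sd(per$n),
        correct_mean = mean(per$ncor), correct_sd = stats::sd(per$ncor),
        pct_correct_mean = mean(per$pct, na.rm = TRUE),
        pct_correct_sd = stats::sd(per$pct[!is.na(per$pct)]),
        rt_mean = if (all(is.na(per$rt))) NA_real_
                  else mean(per$rt, na.rm = TRUE),
        rt_sd = if (all(is.na(per$rt))) NA_real_
                else stats::sd(per$rt[!is.na(per$rt)]))
    }
  }
  do.call(rbind, out)
}

#' Plot a subject or grand-average ERP
#'
#' A minimal waveform plot: one trace per condition for a single channel,
#' with the N400 and P600 analysis windows shaded.
#'
#' @param x A `subject_erp`.
#' @param channel Channel label to plot.
#' @param ... Passed to [graphics::matplot].
#' @return `x`, invisibly.
#' @export
plot.subject_erp <- function(x, channel = "Cz", ...) {
  conds <- names(x$means)
  y <- sapply(conds, function(cond) x$means[[cond]][channel, ])
  graphics::matplot(x$times, y, type = "l", lty = 1,
                    xlab = "time (ms)", ylab = "amplitude (uV)",
                    main = channel, ...)
  graphics::abline(v = c(200, 500, 800), lty = 3, col = "grey40")
  graphics::abline(h = 0, v = 0, col = "grey70")
  graphics::legend("topleft", legend = conds, lty = 1,
                   col = seq_along(conds), bty = "n", cex = 0.8)
  invisible(x)
}
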