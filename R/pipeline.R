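# Study-level orchestration: the condition-differences battery and the
# group-differences battery across electrodes and components, and the
# wide-format report.

#' Study design declaration
#'
#' @param groups Group labels (2 for the standard design).
#' @param conditions Condition labels; the standard design has one congruent
#'   and two incongruent categories.
#' @param electrodes Scalp electrode labels (6 for the standard montage).
#' @param components ERP component names (see [component_window]).
#' @return An object of class `study_design`.
#' @export
study_design <- function(groups = group_levels(),
                         conditions = condition_levels(),
                         electrodes = eeg_channels(),
                         components = component_levels()) {
  structure(list(groups = groups, conditions = conditions,
                 electrodes = electrodes, components = components),
            class = "study_design")
}

new_analysis_plan <- function(entries, battery) {
  structure(list(entries = entries, battery = battery),
            class = "analysis_plan")
}

#' @export
print.analysis_plan <- function(x, ...) {
  cat(sprintf("<analysis_plan> %s battery: %d analyses\n", x$battery,
              length(x$entries)))
  invisible(x)
}

#' Plan the condition-differences battery
#'
#' One Mean-Centered PLS per group x component x electrode, each over the
#' three stimulus categories within that group (3 design cells), with
#' within-subject permutations. The standard design (2 groups, 2 components,
#' 6 electrodes) yields 24 analyses.
#'
#' @param design A [study_design]; must declare all three conditions.
#' @return An `analysis_plan`.
#' @export
plan_condition_battery <- function(design = study_design()) {
  stopifnot(inherits(design, "study_design"))
  missing <- setdiff(condition_levels(), design$conditions)
  if (length(missing))
    stop("design is missing condition(s): ", paste(missing, collapse = ", "))
  entries <- list()
  for (g in design$groups)
    for (comp in design$components)
      for (el in design$electrodes)
        entries[[length(entries) + 1]] <- list(
          battery = "conditions", analysis = "mean-centered",
          comparison = paste(g, "conditions"),
          group = g, component = comp, electrode = el,
          cells = data.frame(group = g, condition = design$conditions),
          contrast = NULL, mode = "within")
  new_analysis_plan(entries, "conditions")
}

#' Plan the group-differences battery
#'
#' One analysis per condition set (congruent; incongruent) x component x
#' electrode, with between-subject permutations: 24 analyses for the
#' standard design. Congruent entries compare the two groups (2 cells, with
#' the (1, -1) contrast); incongruent entries span 2 groups x 2 incongruent
#' sub-categories (4 cells, ordered ASD-semantic, ASD-pragmatic, TD-semantic,
#' TD-pragmatic) with the configured a-priori contrast.
#'
#' @param design A [study_design].
#' @param analysis `"contrast"` (a-priori contrasts, the default) or
#'   `"mean-centered"` (data-driven).
#' @param incongruent_contrast Contrast vector for the 4-cell incongruent
#'   analyses, or the name of a [contrast_presets] entry.
#' @param congruent_contrast Contrast vector for the 2-cell congruent
#'   analyses.
#' @return An `analysis_plan`.
#' @export
plan_group_battery <- function(design = study_design(),
                               analysis = c("contrast", "mean-centered"),
                               incongruent_contrast = "incongruent_printed",
                               congruent_contrast = contrast_presets()$congruent) {
  stopifnot(inherits(design, "study_design"))
  analysis <- match.arg(analysis)
  if (length(design$groups) != 2)
    stop("group battery needs exactly 2 groups")
  missing <- setdiff(condition_levels(), design$conditions)
  if (length(missing))
    stop("design is missing condition(s): ", paste(missing, collapse = ", "))
  if (is.character(incongruent_contrast))
    incongruent_contrast <- contrast_presets()[[incongruent_contrast]]
  incong <- setdiff(condition_levels(), "congruent")
  cell_sets <- list(
    congruent = data.frame(group = design$groups, condition = "congruent"),
    incongruent = data.frame(group = rep(design$groups, each = 2),
                             condition = rep(incong, 2)))
  contrasts <- list(congruent = congruent_contrast,
                    incongruent = incongruent_contrast)
  entries <- list()
  for (cset in names(cell_sets))
    for (comp in design$components)
      for (el in design$electrodes)
        entries[[length(entries) + 1]] <- list(
          battery = "groups", analysis = analysis,
          comparison = paste(design$groups[1], "vs", design$groups[2], cset),
          condition_set = cset, component = comp, electrode = el,
          cells = cell_sets[[cset]],
          contrast = if (analysis == "contrast") contrasts[[cset]] else NULL,
          mode = "between")
  new_analysis_plan(entries, "groups")
}

#' Preprocess every subject of a study and apply the inclusion rule
#'
#' For continuous-level studies each subject runs through
#' [preprocess_subject] and [average_erp]; ERP-level studies pass through
#' unchanged (their retained-trial counts were drawn at generation). Subjects
#' failing the inclusion rule are excluded with their reasons recorded.
#'
#' @param study An `erp_study` (see [generate_study]).
#' @param config A [preprocess_config].
#' @return A list of class `preprocessed_study`: `erps` (named list of
#'   `subject_erp` for included subjects), `metadata` (included rows),
#'   `exclusions` (data.frame subject/reasons), `reports`.
#' @export
preprocess_study <- function(study, config = preprocess_config()) {
  stopifnot(inherits(study, "erp_study"))
  erps <- list()
  reports <- list()
  excl <- list()
  for (i in seq_len(nrow(study$metadata))) {
    id <- study$metadata$subject[i]
    meta <- study$metadata[i, ]
    if (study$level == "continuous") {
      sub <- study$subjects[[id]]
      pp <- preprocess_subject(sub$recording, sub$events, config)
      decision <- include_subject(sub$events, meta, config$rule)
      reports[[id]] <- pp$report
      erp <- try(average_erp(pp$epochs, pp$events), silent = TRUE)
      if (inherits(erp, "try-error")) {
        decision$included <- FALSE
        decision$reasons <- c(decision$reasons, "no retained trials")
        erp <- NULL
      }
    } else {
      erp <- study$subjects[[id]]
      decision <- include_subject(NULL, meta, config$rule,
                                  counts = list(correct = erp$n_correct,
                                                bad = erp$n_bad))
    }
    if (decision$included) {
      erps[[id]] <- erp
    } else {
      excl[[length(excl) + 1]] <-
        data.frame(subject = id,
                   reasons = paste(decision$reasons, collapse = "; "))
      message("subject ", id, " excluded: ",
              paste(decision$reasons, collapse = "; "))
    }
  }
  exclusions <- if (length(excl)) do.call(rbind, excl)
                else data.frame(subject = character(0), reasons = character(0))
  structure(list(erps = erps,
                 metadata = study$metadata[study$metadata$subject %in%
                                             names(erps), ],
                 exclusions = exclusions, reports = reports,
                 config = config),
            class = "preprocessed_study")
}

#' Execute an analysis plan
#'
#' Runs every planned analysis through the PLS stage. Per-analysis seeds are
#' derived from the master seed by the fixed counter scheme of
#' [derive_seed] (counter = position in the plan), so any single analysis can
#' be re-run in isolation. Accepts either a raw `erp_study` (preprocessed
#' here) or an already [preprocess_study] result.
#'
#' @param plan An `analysis_plan`.
#' @param study An `erp_study` or `preprocessed_study`.
#' @param seed Master analysis seed.
#' @param n_perm Permutations per analysis (1000 by default).
#' @param config A [preprocess_config] (used when `study` is raw).
#' @param alpha Significance level used for flagging.
#' @return A `report_table` data.frame: one row per analysis with the
#'   observed statistic, permutation p-value and significance flag; carries
#'   `alpha`, `n_perm`, `seed` and the exclusion table as attributes.
#' @export
run_plan <- function(plan, study, seed = 1, n_perm = 1000,
                     config = preprocess_config(), alpha = 0.05) {
  stopifnot(inherits(plan, "analysis_plan"))
  prep <- if (inherits(study, "preprocessed_study")) study
          else preprocess_study(study, config)
  rows <- list()
  results <- list()
  for (i in seq_along(plan$entries)) {
    e <- plan$entries[[i]]
    fm <- build_feature_matrix(prep$erps, e$cells,
                               component_window(e$component), e$electrode,
                               prep$metadata)
    scheme <- permutation_scheme(e$mode, n_perm = n_perm,
                                 seed = derive_seed(seed, i))
    res <- if (e$analysis == "mean-centered") mean_centered_pls(fm, scheme)
           else contrast_pls(fm, e$contrast, scheme)
    results[[i]] <- res
    rows[[i]] <- data.frame(
      battery = e$battery, comparison = e$comparison,
      component = e$component, electrode = e$electrode,
      analysis = e$analysis, mode = e$mode,
      n_cells = length(fm$cell_levels), n_rows = nrow(fm$values),
      observed = res$observed_statistic, p_value = res$p_value,
      significant = res$p_value < alpha)
  }
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  attr(out, "exclusions") <- prep$exclusions
  attr(out, "results") <- results
  class(out) <- c("report_table", "data.frame")
  out
}

#' Write an analysis report
#'
#' Wide tab-separated table with one row per (battery, comparison, component)
#' and electrodes as columns (p-values), plus parallel `<electrode>_sig`
#' flags at the chosen significance level, and a JSON sidecar with
#' provenance (seed, permutations, alpha, adjustment mode, package version,
#' configuration hash).
#'
#' @param table A `report_table` from [run_plan].
#' @param path Output TSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @param alpha Significance level for flagging.
#' @param adjust `"none"` (per-analysis permutation p-values, the default) or
#'   `"BH"` for Benjamini-Hochberg adjustment across the table's analyses.
#' @param electrodes Column order for electrodes.
#' @return Invisibly, the wide data.frame written.
#' @export
write_report <- function(table, path, alpha = attr(table, "alpha") %||% 0.05,
                         adjust = c("none", "BH"),
                         electrodes = eeg_channels()) {
  adjust <- match.arg(adjust)
  stopifnot(is.data.frame(table))
  p <- if (adjust == "BH") stats::p.adjust(table$p_value, "BH")
       else table$p_value
  table$p_flagged <- p < alpha
  keys <- unique(table[, c("battery", "comparison", "component")])
  electrodes <- intersect(electrodes, unique(table$electrode))
  wide <- keys
  for (el in electrodes) {
    wide[[el]] <- NA_real_
    wide[[paste0(el, "_sig")]] <- NA
  }
  for (r in seq_len(nrow(keys))) {
    sel <- table$battery == keys$battery[r] &
      table$comparison == keys$comparison[r] &
      table$component == keys$component[r]
    for (el in electrodes) {
      row <- table[sel & table$electrode == el, ]
      if (nrow(row) == 1) {
        wide[r, el] <- row$p_value
        wide[r, paste0(el, "_sig")] <- row$p_flagged
      }
    }
  }
  utils::write.table(wide, path, sep = "\t", row.names = FALSE, quote = FALSE)
  sidecar <- list(
    seed = attr(table, "seed"), n_perm = attr(table, "n_perm"),
    alpha = alpha, adjust = adjust,
    package_version = as.character(utils::packageVersion("erppls")),
    n_analyses = nrow(table),
    config_hash = unname(config_hash(list(alpha = alpha, adjust = adjust,
                                          n_perm = attr(table, "n_perm"),
                                          seed = attr(table, "seed")))),
    created = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(wide)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# md5 of a canonical JSON rendering of a configuration list
config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tf)
  tools::md5sum(tf)
}
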