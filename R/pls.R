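# Mean-Centered and Contrast PLS on design-cell feature matrices, with
# permutation tests for the significance of the overall contrast.
#
# Both variants operate on the k x p matrix of design-cell mean feature
# vectors after grand-mean (column) centering. Mean-Centered PLS extracts
# data-driven contrasts as the left singular vectors of that matrix;
# Contrast PLS projects it onto an a-priori unit contrast. In either case a
# single statistic (first singular value, or the norm of the projected
# salience) is referred to a permutation null, giving one p-value per
# contrast for all features at once.

#' Permutation scheme for PLS significance testing
#'
#' `mode = "between"` permutes each subject's group label across subjects
#' (keeping the subject's condition structure intact) and suits group
#' comparisons; `mode = "within"` permutes condition labels within each
#' subject and suits repeated-measures condition comparisons.
#'
#' @param mode `"between"` or `"within"`.
#' @param n_perm Number of permutations (1000 by default).
#' @param seed Integer seed for the permutation stream.
#' @return An object of class `permutation_scheme`.
#' @export
permutation_scheme <- function(mode = c("between", "within"), n_perm = 1000,
                               seed = 1) {
  mode <- match.arg(mode)
  if (!(is.numeric(n_perm) && n_perm >= 1))
    stop("n_perm must be >= 1")
  structure(list(mode = mode, n_perm = as.integer(n_perm),
                 seed = as.integer(seed)),
            class = "permutation_scheme")
}

#' A-priori design contrast
#'
#' @param weights Numeric vector, one weight per design cell; not all zero.
#'   Stored both as given and normalized to unit Euclidean norm.
#' @return An object of class `design_contrast`.
#' @export
design_contrast <- function(weights) {
  stopifnot(is.numeric(weights), length(weights) >= 2)
  if (all(weights == 0)) stop("contrast must not be all-zero")
  structure(list(weights = weights,
                 normalized = weights / sqrt(sum(weights^2))),
            class = "design_contrast")
}

#' Named contrast presets for the group analyses
#'
#' `congruent` is the two-group contrast (1, -1). For the four-cell
#' incongruent analysis (cells ordered ASD-semantic, ASD-pragmatic,
#' TD-semantic, TD-pragmatic) two presets ship: `incongruent_printed`, the
#' literal (1, 1, -1, 1) vector, and `incongruent_symmetric`, the
#' sign-balanced (1, 1, -1, -1) variant.
#'
#' @return Named list of numeric contrast vectors.
#' @export
contrast_presets <- function() {
  list(congruent = c(1, -1),
       incongruent_printed = c(1, 1, -1, 1),
       incongruent_symmetric = c(1, 1, -1, -1))
}

# cell index (integer, in declared level order) for a feature matrix
.fm_cell_index <- function(fm) match(fm$row_labels$cell, fm$cell_levels)

# k x p matrix of cell means from a values matrix and integer cell index
.cell_mean_matrix <- function(values, cell, k) {
  sizes <- tabulate(cell, k)
  if (any(sizes == 0)) stop("empty design cell")
  M <- rowsum(values, cell)
  M / sizes
}

#' Design-cell mean matrix
#'
#' Row j is the mean feature vector over the subjects of cell j, in declared
#' cell order.
#'
#' @param fm A `feature_matrix` (see [build_feature_matrix]).
#' @return A k x p numeric matrix with cell labels as row names.
#' @export
cell_means <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  M <- .cell_mean_matrix(fm$values, .fm_cell_index(fm),
                         length(fm$cell_levels))
  rownames(M) <- fm$cell_levels
  M
}

#' Grand-mean centering of a cell-mean matrix
#'
#' Removes the column (per-feature) mean across the k cell rows, so that the
#' centered column sums are zero.
#'
#' @param M A k x p cell-mean matrix with k >= 2.
#' @return The centered matrix.
#' @export
mean_center <- function(M) {
  if (nrow(M) < 2) stop("mean centering needs at least 2 design cells")
  sweep(M, 2, colMeans(M))
}

# statistics referred to the permutation null ------------------------------

stat_first_singular <- function(values, cell, k) {
  M <- .cell_mean_matrix(values, cell, k)
  Mc <- M - rep(colMeans(M), each = k)
  ev <- eigen(tcrossprod(Mc), symmetric = TRUE, only.values = TRUE)$values
  sqrt(max(ev[1], 0))
}

make_stat_contrast <- function(w) {
  force(w)
  function(values, cell, k) {
    M <- .cell_mean_matrix(values, cell, k)
    Mc <- M - rep(colMeans(M), each = k)
    sqrt(sum(drop(crossprod(Mc, w))^2))
  }
}

#' Permutation test for a design-cell statistic
#'
#' Recomputes `statistic_fn` under label permutations of the feature matrix.
#' In `"between"` mode the subjects' group labels are permuted across
#' subjects while each subject keeps its conditions; in `"within"` mode each
#' subject's condition labels are permuted among that subject's own rows.
#' The p-value uses the add-one rule `(1 + #\{null >= observed\}) /
#' (1 + n_perm)`, so it is never exactly zero.
#'
#' @param fm A `feature_matrix`.
#' @param statistic_fn Function `(values, cell, k) -> scalar`, where `cell`
#'   is the integer cell index per row and `k` the number of cells.
#' @param scheme A [permutation_scheme].
#' @return List with `observed`, `null_distribution`, `p_value`.
#' @export
permutation_test <- function(fm, statistic_fn, scheme = permutation_scheme()) {
  stopifnot(inherits(fm, "feature_matrix"),
            inherits(scheme, "permutation_scheme"))
  k <- length(fm$cell_levels)
  cell0 <- .fm_cell_index(fm)
  observed <- statistic_fn(fm$values, cell0, k)

  rl <- fm$row_labels
  subjects <- unique(rl$subject)
  subj_of_row <- match(rl$subject, subjects)
  group_of_subj <- rl$group[match(subjects, rl$subject)]
  groups_u <- unique(rl$group)
  conds_u <- unique(rl$condition)
  cond_of_row <- match(rl$condition, conds_u)
  group_idx_of_subj <- match(group_of_subj, groups_u)
  # cell lookup by (group, condition); NA for combinations outside the design
  lookup <- matrix(match(outer(groups_u, conds_u, paste, sep = ":"),
                         fm$cell_levels),
                   nrow = length(groups_u))
  rows_of_subj <- split(seq_len(nrow(rl)), subj_of_row)

  null <- with_seed(scheme$seed, {
    vapply(seq_len(scheme$n_perm), function(i) {
      if (scheme$mode == "between") {
        new_group <- group_idx_of_subj[sample.int(length(subjects))]
        cell <- lookup[cbind(new_group[subj_of_row], cond_of_row)]
      } else {
        new_cond <- cond_of_row
        for (rows in rows_of_subj) {
          if (length(rows) > 1)
            new_cond[rows] <- new_cond[rows][sample.int(length(rows))]
        }
        cell <- lookup[cbind(group_idx_of_subj[subj_of_row], new_cond)]
      }
      if (anyNA(cell))
        stop("permutation produced a cell outside the declared design")
      statistic_fn(fm$values, cell, k)
    }, numeric(1))
  })
  list(observed = observed, null_distribution = null,
       p_value = (1 + sum(null >= observed)) / (1 + scheme$n_perm))
}

new_pls_result <- function(type, fm, singular_values, design_saliences,
                           feature_saliences, observed, null, p_value,
                           scheme, contrast = NULL) {
  structure(list(type = type, singular_values = singular_values,
                 design_saliences = design_saliences,
                 feature_saliences = feature_saliences,
                 observed_statistic = observed,
                 null_distribution = null, p_value = p_value,
                 scheme = scheme, contrast = contrast,
                 cell_levels = fm$cell_levels, cell_sizes = fm$cell_sizes,
                 channel = fm$channel, window = fm$window),
            class = "pls_result")
}

#' @export
print.pls_result <- function(x, ...) {
  cat(sprintf("<pls_result> %s PLS, %d cells (%s)\n", x$type,
              length(x$cell_levels), paste(x$cell_levels, collapse = ", ")))
  cat(sprintf("  observed statistic %.4g, p = %.4g (%s, %d permutations)\n",
              x$observed_statistic, x$p_value, x$scheme$mode,
              x$scheme$n_perm))
  invisible(x)
}

#' Mean-Centered PLS with permutation test
#'
#' Singular value decomposition of the grand-mean-centered cell-mean matrix.
#' The left singular vectors are the data-driven overall contrasts across
#' design cells (design saliences), the right singular vectors the feature
#' saliences. The tested statistic is the first (largest) singular value;
#' significance comes from [permutation_test]. Design saliences are
#' sign-fixed so that each column's largest-magnitude element is positive.
#'
#' @param fm A `feature_matrix` with at least 2 design cells.
#' @param scheme A [permutation_scheme].
#' @return A `pls_result`.
#' @export
mean_centered_pls <- function(fm, scheme = permutation_scheme("within")) {
  stopifnot(inherits(fm, "feature_matrix"))
  k <- length(fm$cell_levels)
  if (k < 2) stop("mean-centered PLS needs at least 2 design cells")
  Mc <- mean_center(cell_means(fm))
  sv <- svd(Mc)
  for (j in seq_along(sv$d)) {
    i0 <- which.max(abs(sv$u[, j]))
    if (sv$u[i0, j] < 0) {
      sv$u[, j] <- -sv$u[, j]
      sv$v[, j] <- -sv$v[, j]
    }
  }
  observed <- sv$d[1]
  if (observed < 1e-12) {
    warning("centered cell means are all zero; p-value set to 1")
    return(new_pls_result("mean-centered", fm, sv$d, sv$u, sv$v, observed,
                          numeric(0), 1.0, scheme))
  }
  pt <- permutation_test(fm, stat_first_singular, scheme)
  new_pls_result("mean-centered", fm, sv$d, sv$u, sv$v, pt$observed,
                 pt$null_distribution, pt$p_value, scheme)
}

#' Contrast PLS with permutation test
#'
#' Projects the grand-mean-centered cell-mean matrix onto an a-priori unit
#' contrast across design cells. The feature salience is `t(M_c) %*% c`; the
#' tested statistic is its Euclidean norm, referred to the same permutation
#' null as the mean-centered variant.
#'
#' @param fm A `feature_matrix`.
#' @param contrast A [design_contrast] or numeric vector of length k.
#' @param scheme A [permutation_scheme].
#' @return A `pls_result`.
#' @export
contrast_pls <- function(fm, contrast,
                         scheme = permutation_scheme("between")) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (!inherits(contrast, "design_contrast"))
    contrast <- design_contrast(contrast)
  k <- length(fm$cell_levels)
  if (length(contrast$weights) != k)
    stop("contrast length (", length(contrast$weights),
         ") does not match the number of design cells (", k, ")")
  w <- contrast$normalized
  Mc <- mean_center(cell_means(fm))
  fs <- drop(crossprod(Mc, w))
  observed <- sqrt(sum(fs^2))
  pt <- permutation_test(fm, make_stat_contrast(w), scheme)
  new_pls_result("contrast", fm, NULL, matrix(w, ncol = 1),
                 matrix(fs, ncol = 1), pt$observed, pt$null_distribution,
                 pt$p_value, scheme, contrast = contrast)
}
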