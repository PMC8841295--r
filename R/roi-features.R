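#' Extract a subject's ROI feature matrix from fitted tensor maps
#'
#' Arranges the in-mask voxel values of a fitted tensor (or scalar) map as a
#' components x voxels matrix. Columns enumerate mask voxels in a fixed grid
#' scan order (the first grid axis varying fastest), so all subjects fitted
#' on one cohort mask share an identical voxel ordering and the feature
#' spaces align column-by-column.
#'
#' @param fit A [fit_volume()] result.
#' @param mask 3-D mask on the fit grid (the cohort-wide union mask).
#' @param tensor_kind One of `"DT"` (6 x V), `"KT"` (15 x V), `"FA"`, `"MD"`,
#'   `"MK"` (1 x V scalar maps).
#' @param n_directions Quadrature directions used when `tensor_kind = "MK"`.
#' @return A list of class `"subject_feature_matrix"` with `kind`, `matrix`
#'   and `voxel_index`.
#' @export
extract_subject_matrix <- function(fit, mask, tensor_kind = c("DT", "KT", "FA", "MD", "MK"),
                                   n_directions = 256) {
  stopifnot(inherits(fit, "tensor_fit"))
  tensor_kind <- match.arg(tensor_kind)
  dm <- dim(mask)
  if (length(dm) != 3 || any(dm != fit$dim)) {
    stop("grid mismatch: mask dimensions do not match the fitted maps")
  }
  idx <- which(as.logical(mask) & !is.na(mask))
  nvox <- prod(fit$dim)
  take <- function(map, ncomp) {
    m <- matrix(0, ncomp, length(idx))
    for (k in seq_len(ncomp)) m[k, ] <- map[idx + (k - 1) * nvox]
    m
  }
  mat <- switch(tensor_kind,
    DT = {
      m <- take(fit$d, 6); rownames(m) <- .dt_names; m
    },
    KT = {
      m <- take(fit$w, 15); rownames(m) <- .kt_names; m
    },
    {
      sm <- scalar_maps(fit, which = tolower(tensor_kind), n_directions = n_directions)[[1]]
      v <- sm[idx]
      v[is.na(v)] <- 0
      matrix(v, 1, length(idx), dimnames = list(tensor_kind, NULL))
    }
  )
  structure(
    list(kind = tensor_kind, matrix = mat, voxel_index = idx),
    class = "subject_feature_matrix"
  )
}

#' Remove rows and columns that are zero in every subject
#'
#' Prunes, cohort-wide, exactly those feature-matrix rows (tensor
#' components) and columns (voxels) whose entries are zero (|x| <= atol) in
#' every subject, so all subjects keep an identical feature space. Survivors
#' are never reordered.
#'
#' @param cohort List of `subject_feature_matrix` objects (or plain
#'   matrices) of identical shape and kind.
#' @param atol Absolute tolerance for "zero"; the default 0 prunes only
#'   exact zeros, which is what out-of-mask voxels hold by construction.
#' @return A list with `cohort` (pruned matrices), `kept_rows` and
#'   `kept_cols` (surviving indices into the original matrix).
#' @export
prune_zero_rows_columns <- function(cohort, atol = 0) {
  stopifnot(length(cohort) >= 1)
  mats <- lapply(cohort, function(s) if (inherits(s, "subject_feature_matrix")) s$matrix else s)
  d1 <- dim(mats[[1]])
  if (!all(vapply(mats, function(m) all(dim(m) == d1), logical(1)))) {
    stop("all subjects must share one feature-matrix shape")
  }
  nonzero_row <- Reduce(`|`, lapply(mats, function(m) apply(abs(m) > atol, 1, any)))
  nonzero_col <- Reduce(`|`, lapply(mats, function(m) apply(abs(m) > atol, 2, any)))
  kept_rows <- which(nonzero_row)
  kept_cols <- which(nonzero_col)
  if (length(kept_rows) == 0 || length(kept_cols) == 0) {
    stop("empty features: every row or every column is all-zero across the cohort")
  }
  pruned <- lapply(seq_along(cohort), function(i) {
    m <- mats[[i]][kept_rows, kept_cols, drop = FALSE]
    if (inherits(cohort[[i]], "subject_feature_matrix")) {
      out <- cohort[[i]]
      out$matrix <- m
      out$voxel_index <- out$voxel_index[kept_cols]
      out
    } else {
      m
    }
  })
  names(pruned) <- names(cohort)
  list(cohort = pruned, kept_rows = kept_rows, kept_cols = kept_cols)
}

#' Flatten a feature matrix to one subject vector
#'
#' Deterministic row-major flatten: tensor components form the outer loop
#' and voxels the inner loop, so two subjects' vectors align
#' feature-by-feature whenever their matrices do.
#'
#' @param x A `subject_feature_matrix` or plain matrix.
#' @return Numeric vector of length components * voxels.
#' @export
flatten_features <- function(x) {
  m <- if (inherits(x, "subject_feature_matrix")) x$matrix else x
  stopifnot(is.matrix(m))
  as.numeric(t(m))
}

#' Per-subject summary statistics of cohort feature matrices
#'
#' Computes, for each subject, the maximum, minimum and average of all
#' feature-matrix entries -- the per-subject summaries on which two-group
#' tensor comparisons are run.
#'
#' @param cohort List of `subject_feature_matrix` objects or matrices.
#' @param labels Group labels, one per subject (two levels).
#' @return A data frame of class `"cohort_summary"` with columns `subject`,
#'   `group`, `max`, `min`, `avg`.
#' @export
cohort_summary <- function(cohort, labels) {
  stopifnot(length(cohort) == length(labels))
  mats <- lapply(cohort, function(s) if (inherits(s, "subject_feature_matrix")) s$matrix else s)
  out <- data.frame(
    subject = if (is.null(names(cohort))) seq_along(cohort) else names(cohort),
    group = as.character(labels),
    max = vapply(mats, max, numeric(1)),
    min = vapply(mats, min, numeric(1)),
    avg = vapply(mats, mean, numeric(1)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' Two-group tests on per-subject summary statistics
#'
#' Runs, per statistic (max, min, avg), a Welch two-sided independent-samples
#' t-test and a one-way ANOVA across groups. With exactly two groups the
#' ANOVA F statistic equals the square of the pooled-variance t statistic.
#'
#' @param summary A [cohort_summary()] data frame with exactly two groups of
#'   at least two subjects each.
#' @return Data frame with one row per statistic: Welch `t`, `df`,
#'   `p_t`, ANOVA `f` and `p_f`.
#' @export
cohort_summary_tests <- function(summary) {
  stopifnot(inherits(summary, "data.frame"))
  groups <- unique(summary$group)
  if (length(groups) != 2) stop("exactly two groups are required")
  sizes <- table(summary$group)
  if (any(sizes < 2)) stop("each group needs >= 2 subjects")
  stats_names <- c("max", "min", "avg")
  rows <- lapply(stats_names, function(st) {
    v <- summary[[st]]
    g <- factor(summary$group)
    tt <- stats::t.test(v ~ g, var.equal = FALSE)
    av <- stats::anova(stats::aov(v ~ g))
    data.frame(
      statistic = st,
      t = unname(tt$statistic), df = unname(tt$parameter), p_t = tt$p.value,
      f = av[["F value"]][1], p_f = av[["Pr(>F)"]][1],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
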