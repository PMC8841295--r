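#' Elastic-net configuration
#'
#' Parameters of the combined L1+L2 feature-selection objective
#' (1/N) ||Y - X beta||^2 + lambda * rho * ||beta||_1
#'   + lambda * (1 - rho) / 2 * ||beta||^2.
#'
#' @param lambda Non-negative penalty weight; `NULL` (default) selects it on
#'   a log-spaced grid by stratified cross-validation.
#' @param rho Mixing weight in \[0, 1\]: 1 is the pure LASSO, 0 pure ridge.
#' @param l1_budget Optional bound t on ||beta||_1; honored through the
#'   penalized (Lagrangian) form by taking the least-penalized solution on
#'   the regularization path whose L1 norm does not exceed t.
#' @param cv_folds Folds for the cross-validated lambda search.
#' @param n_lambda Grid size for the lambda path.
#' @return A list of class `"elastic_net_config"`.
#' @export
elastic_net_config <- function(lambda = NULL, rho = 0.5, l1_budget = NULL,
                               cv_folds = 5, n_lambda = 50) {
  if (!is.null(lambda) && lambda < 0) stop("lambda must be non-negative")
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]")
  if (!is.null(l1_budget) && l1_budget < 0) stop("l1_budget must be non-negative")
  stopifnot(cv_folds >= 2, n_lambda >= 2)
  structure(
    list(
      lambda = lambda, rho = rho, l1_budget = l1_budget,
      cv_folds = cv_folds, n_lambda = n_lambda
    ),
    class = "elastic_net_config"
  )
}

# Stratified fold assignment: each class is spread as evenly as possible
# across the k folds. Deterministic given the RNG state.
.stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    i <- which(y == cl)
    i <- i[sample.int(length(i))]
    fold[i] <- rep_len(seq_len(k), length(i))
  }
  fold
}

.stratified_split <- function(y, frac) {
  train <- logical(length(y))
  for (cl in unique(y)) {
    i <- which(y == cl)
    n_tr <- max(1, round(frac * length(i)))
    if (n_tr >= length(i)) n_tr <- length(i) - 1
    train[i[sample.int(length(i))][seq_len(n_tr)]] <- TRUE
  }
  if (!any(train) || all(train)) stop("split leaves a set empty")
  train
}

#' Elastic-net feature selection
#'
#' Fits the combined L1+L2 penalized regression of a 0/1 group response on
#' standardized features and selects the features with nonzero
#' coefficients. The objective maps exactly onto glmnet's parameterization
#' with `alpha = rho` and `lambda_glmnet = lambda / 2`, which is the solver
#' used. When `config$lambda` is `NULL` the penalty weight is chosen by
#' `cv_folds`-fold stratified cross-validation over a log-spaced grid.
#'
#' Constant features are dropped before fitting (they cannot be
#' standardized) and are never selected. If every grid point yields an
#' empty model a warning is raised and all features are returned as the
#' fallback selection, flagged by `empty_selection = TRUE`.
#'
#' @param x Numeric matrix, subjects x features.
#' @param y Binary labels (two levels; internally coded 0/1).
#' @param config An [elastic_net_config()].
#' @param seed Seed for the fold assignment.
#' @return List with `selected` (feature indices into `x`'s columns),
#'   `coefficients` (matching nonzero coefficients), `lambda` (penalty on
#'   the objective's scale), and `empty_selection`.
#' @export
elastic_net_select <- function(x, y, config = elastic_net_config(), seed = 1) {
  x <- as.matrix(x)
  yf <- factor(y)
  if (nlevels(yf) != 2) stop("labels must have exactly two levels")
  if (min(table(yf)) < 2) stop("need >= 2 subjects per class")
  y01 <- as.numeric(yf) - 1
  keep <- which(apply(x, 2, function(col) stats::sd(col) > 0))
  if (length(keep) == 0) stop("all features are constant")
  xk <- x[, keep, drop = FALSE]

  alpha <- config$rho
  fit_path <- function(lambda_glmnet = NULL) {
    glmnet::glmnet(
      xk, y01,
      family = "gaussian", alpha = alpha, standardize = TRUE,
      lambda = lambda_glmnet, nlambda = config$n_lambda
    )
  }

  if (!is.null(config$lambda)) {
    lam_g <- config$lambda / 2
    # descending sequence ending at the requested penalty so the solution
    # is computed exactly at it (glmnet warms along a path)
    lam_seq <- if (lam_g > 0) lam_g * c(16, 8, 4, 2, 1) else c(1e-2, 1e-3, 0)
    fit <- fit_path(lambda_glmnet = lam_seq)
    beta <- as.numeric(fit$beta[, ncol(fit$beta)])
    lam_obj <- config$lambda
  } else if (!is.null(config$l1_budget)) {
    fit <- fit_path()
    betas <- as.matrix(fit$beta)
    l1 <- colSums(abs(betas))
    ok <- which(l1 <= config$l1_budget)
    pick <- if (length(ok)) max(ok) else 1L  # path runs from strong to weak penalty
    beta <- betas[, pick]
    lam_obj <- 2 * fit$lambda[pick]
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    foldid <- .stratified_folds(y01, config$cv_folds)
    cv <- glmnet::cv.glmnet(
      xk, y01,
      family = "gaussian", alpha = alpha, standardize = TRUE,
      foldid = foldid, nlambda = config$n_lambda
    )
    beta <- as.numeric(glmnet::coef.glmnet(cv, s = "lambda.min"))[-1]
    lam_obj <- 2 * cv$lambda.min
  }

  nz <- which(beta != 0)
  if (length(nz) == 0) {
    warning("empty selection: no feature survived the penalty; falling back to all features")
    return(list(
      selected = seq_len(ncol(x)), coefficients = rep(0, ncol(x)),
      lambda = lam_obj, empty_selection = TRUE
    ))
  }
  list(
    selected = keep[nz], coefficients = beta[nz],
    lambda = lam_obj, empty_selection = FALSE
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' SVM configuration
#'
#' @param kernel `"linear"` (default; the usual choice when features far
#'   outnumber subjects) or `"rbf"`.
#' @param c Positive misclassification-tolerance parameter weighting the
#'   slack variables.
#' @param gamma RBF kernel width; `NULL` uses 1/p.
#' @return A list of class `"svm_config"`.
#' @export
svm_config <- function(kernel = c("linear", "rbf"), c = 1, gamma = NULL) {
  kernel <- match.arg(kernel)
  if (c <= 0) stop("c must be positive")
  structure(list(kernel = kernel, c = c, gamma = gamma), class = "svm_config")
}

#' Train a maximum-margin classifier and predict a test set
#'
#' Soft-margin SVM with decision rule y(x) = sign(w' phi(x) + b).
#' Continuous decision scores are retained for ROC analysis and oriented so
#' that larger scores favor the positive (second factor level, or +1)
#' class.
#'
#' @param x_train,x_test Numeric feature matrices (subjects x features).
#' @param y_train Labels with two classes present.
#' @param config An [svm_config()].
#' @return List with `predictions` (same label type as `y_train`), `scores`
#'   (decision values), and `model` (the fitted `e1071::svm` object).
#' @export
svm_train_predict <- function(x_train, y_train, x_test, config = svm_config()) {
  x_train <- as.matrix(x_train)
  x_test <- as.matrix(x_test)
  yf <- factor(y_train)
  if (nlevels(yf) < 2) stop("single-class training set: both classes must be present")
  kern <- if (config$kernel == "linear") "linear" else "radial"
  gamma <- if (is.null(config$gamma)) 1 / ncol(x_train) else config$gamma
  model <- e1071::svm(
    x = x_train, y = yf, kernel = kern, cost = config$c, gamma = gamma,
    scale = FALSE, probability = FALSE
  )
  pred <- stats::predict(model, x_test, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  scores <- as.numeric(dv[, 1])
  # e1071 reports decision values voting for the class named before the
  # slash in the column name; orient so larger favors the positive
  # (second) level
  pos <- levels(yf)[2]
  if (grepl(paste0("/", pos, "$"), colnames(dv)[1])) scores <- -scores
  out_pred <- factor(as.character(pred), levels = levels(yf))
  if (!is.factor(y_train)) {
    out_pred <- if (is.numeric(y_train)) as.numeric(as.character(out_pred)) else as.character(out_pred)
  }
  list(predictions = out_pred, scores = scores, model = model)
}

#' ROC curve coordinates
#'
#' Sweeps every threshold over the scores and returns the false- and
#' true-positive rates, from the all-negative to the all-positive operating
#' point.
#'
#' @param scores Numeric decision scores (larger favors positive).
#' @param truth Binary truth labels; the positive class is the second
#'   factor level (or the larger of two numeric values).
#' @return Data frame with `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, truth) {
  stopifnot(length(scores) == length(truth))
  tf <- factor(truth)
  if (nlevels(tf) != 2) stop("truth must have exactly two classes")
  is_pos <- tf == levels(tf)[2]
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  tp <- cumsum(is_pos[o])
  fp <- cumsum(!is_pos[o])
  # collapse tied scores to a single operating point
  last <- c(s[-1] != s[-length(s)], TRUE)
  p <- sum(is_pos)
  n <- sum(!is_pos)
  data.frame(
    threshold = c(Inf, s[last]),
    fpr = c(0, fp[last] / n),
    tpr = c(0, tp[last] / p)
  )
}

.auc_trapezoid <- function(scores, truth) {
  rc <- roc_curve(scores, truth)
  sum(diff(rc$fpr) * (utils::head(rc$tpr, -1) + utils::tail(rc$tpr, -1)) / 2)
}

#' Confusion-matrix metrics and AUC
#'
#' Computes TP/TN/FP/FN counts and the derived metrics
#' accuracy = (TP+TN)/(TP+TN+FP+FN), precision = TP/(TP+FP),
#' sensitivity = TP/(TP+FN), specificity = TN/(TN+FP). A metric with a zero
#' denominator is reported as NA (undefined), never as 0. AUC is computed
#' by trapezoidal integration of the ROC curve when scores are supplied.
#'
#' @param truth Binary truth labels.
#' @param predictions Binary predicted labels on the same coding.
#' @param scores Optional decision scores for AUC.
#' @param positive Which label is the positive class; default the second
#'   factor level (or larger numeric value).
#' @return A list of class `"classification_report"` with counts, metrics
#'   and `auc`.
#' @export
compute_metrics <- function(truth, predictions, scores = NULL, positive = NULL) {
  stopifnot(length(truth) == length(predictions))
  lev <- levels(factor(c(as.character(truth), as.character(predictions))))
  if (length(lev) > 2) stop("labels must be binary")
  if (is.null(positive)) positive <- lev[length(lev)]
  positive <- as.character(positive)
  t_pos <- as.character(truth) == positive
  p_pos <- as.character(predictions) == positive
  tp <- sum(t_pos & p_pos)
  tn <- sum(!t_pos & !p_pos)
  fp <- sum(!t_pos & p_pos)
  fn <- sum(t_pos & !p_pos)
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(
    list(
      tp = tp, tn = tn, fp = fp, fn = fn,
      accuracy = safe_div(tp + tn, tp + tn + fp + fn),
      precision = safe_div(tp, tp + fp),
      sensitivity = safe_div(tp, tp + fn),
      specificity = safe_div(tn, tn + fp),
      auc = if (is.null(scores)) NA_real_ else .auc_trapezoid(scores, factor(t_pos, c(FALSE, TRUE))),
      positive = positive
    ),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(
    "classification_report (positive = %s)\n  TP %d  TN %d  FP %d  FN %d\n", x$positive,
    x$tp, x$tn, x$fp, x$fn
  ))
  cat(sprintf(
    "  accuracy %.4f  precision %.4f  sensitivity %.4f  specificity %.4f  AUC %.4f\n",
    x$accuracy, x$precision, x$sensitivity, x$specificity, x$auc
  ))
  invisible(x)
}

# Cross-validated cost search on the training set only.
.tune_svm_cost <- function(x, y, config, cost_grid, folds, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  yf <- factor(y)
  foldid <- .stratified_folds(as.numeric(yf), folds)
  acc <- vapply(cost_grid, function(cost) {
    cfg <- svm_config(kernel = config$kernel, c = cost, gamma = config$gamma)
    correct <- 0
    for (f in seq_len(folds)) {
      tr <- foldid != f
      if (nlevels(factor(y[tr])) < 2 || !any(!tr)) next
      p <- svm_train_predict(x[tr, , drop = FALSE], y[tr], x[!tr, , drop = FALSE], cfg)
      correct <- correct + sum(as.character(p$predictions) == as.character(y[!tr]))
    }
    correct / length(y)
  }, numeric(1))
  cost_grid[which.max(acc)]
}

# Fit the full training-side pipeline: standardization, optional feature
# selection, cost tuning, final SVM. Sees only training data.
.train_pipeline <- function(x_train, y_train, selection, seed,
                            svm_cfg, cost_grid, cv_folds, enet_cfg, pca_var) {
  mu <- colMeans(x_train)
  sdev <- apply(x_train, 2, stats::sd)
  sdev[sdev == 0] <- 1
  xs <- sweep(sweep(x_train, 2, mu, "-"), 2, sdev, "/")

  sel <- seq_len(ncol(xs))
  rotation <- NULL
  enet <- NULL
  if (selection == "L1" || selection == "L1L2") {
    cfg <- enet_cfg
    cfg$rho <- if (selection == "L1") 1 else enet_cfg$rho
    enet <- elastic_net_select(xs, y_train, cfg, seed = seed)
    sel <- enet$selected
  } else if (selection == "PCA") {
    pc <- stats::prcomp(xs, center = FALSE, scale. = FALSE)
    varex <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
    ncomp <- max(1, which(varex >= pca_var)[1])
    rotation <- pc$rotation[, seq_len(ncomp), drop = FALSE]
  }

  transform <- function(x_new) {
    xn <- sweep(sweep(as.matrix(x_new), 2, mu, "-"), 2, sdev, "/")
    if (!is.null(rotation)) xn %*% rotation else xn[, sel, drop = FALSE]
  }

  xt <- transform(x_train)
  cost <- .tune_svm_cost(xt, y_train, svm_cfg, cost_grid, cv_folds, seed)
  cfg <- svm_config(kernel = svm_cfg$kernel, c = cost, gamma = svm_cfg$gamma)
  list(
    transform = transform, svm_cfg = cfg, selected = sel,
    rotation = rotation, enet = enet, cost = cost,
    n_features = ncol(xt)
  )
}

#' Run the biomarker classification experiment
#'
#' For each biomarker feature set: stratified train/test split, optional
#' feature selection fitted on the training data only (`"none"`, `"L1"`,
#' `"PCA"`, or the combined `"L1L2"` elastic net), SVM cost search by
#' stratified cross-validation on the training data, then a held-out
#' test-set report. Nothing on the test side ever reaches the fitted model,
#' which is the no-leakage contract the tests assert.
#'
#' @param features Named list of subjects x features matrices (e.g. `DT`,
#'   `KT`, `FA`, `MD`, `MK`, `FA+MK`), all row-aligned to `labels`.
#' @param labels Binary subject labels.
#' @param selection Feature-selection variant applied to every biomarker.
#' @param split Training fraction of the stratified split, or a logical
#'   vector marking the training subjects explicitly.
#' @param seed Seed driving the split, folds and selection.
#' @param svm An [svm_config()] (its cost is tuned over `cost_grid`).
#' @param cost_grid Candidate SVM costs.
#' @param cv_folds Folds for the cost search.
#' @param enet An [elastic_net_config()] for the L1/L1L2 variants.
#' @param pca_var Variance fraction retained by the PCA variant.
#' @return A list of class `"experiment_result"`: `table` (one row per
#'   biomarker with train/test accuracy, precision, sensitivity,
#'   specificity, AUC), `reports`, `details` (per-biomarker fitted
#'   pipelines), `split` (logical train indicator), `seed`.
#' @export
run_experiment <- function(features, labels,
                           selection = c("L1L2", "none", "L1", "PCA"),
                           split = 0.75, seed = 1,
                           svm = svm_config(),
                           cost_grid = 10^seq(-2, 2, length.out = 9),
                           cv_folds = 5,
                           enet = elastic_net_config(),
                           pca_var = 0.95) {
  selection <- match.arg(selection)
  stopifnot(is.list(features), length(features) >= 1)
  n <- length(labels)
  if (!all(vapply(features, nrow, integer(1)) == n)) {
    stop("every feature matrix must have one row per subject")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  train <- if (is.logical(split)) {
    stopifnot(length(split) == n)
    split
  } else {
    .stratified_split(labels, split)
  }
  if (nlevels(factor(labels[train])) < 2 || nlevels(factor(labels[!train])) < 2) {
    stop("split leaves a class empty")
  }

  reports <- list()
  details <- list()
  rows <- list()
  for (nm in names(features)) {
    x <- as.matrix(features[[nm]])
    fitted <- .train_pipeline(
      x[train, , drop = FALSE], labels[train], selection, seed,
      svm, cost_grid, cv_folds, enet, pca_var
    )
    xt_train <- fitted$transform(x[train, , drop = FALSE])
    xt_test <- fitted$transform(x[!train, , drop = FALSE])
    pr_train <- svm_train_predict(xt_train, labels[train], xt_train, fitted$svm_cfg)
    pr_test <- svm_train_predict(xt_train, labels[train], xt_test, fitted$svm_cfg)
    rep_train <- compute_metrics(labels[train], pr_train$predictions, pr_train$scores)
    rep_test <- compute_metrics(labels[!train], pr_test$predictions, pr_test$scores)
    reports[[nm]] <- rep_test
    details[[nm]] <- fitted
    rows[[nm]] <- data.frame(
      item = nm,
      train_acc = rep_train$accuracy,
      test_acc = rep_test$accuracy,
      precision = rep_test$precision,
      sensitivity = rep_test$sensitivity,
      specificity = rep_test$specificity,
      auc = rep_test$auc,
      n_features = fitted$n_features,
      cost = fitted$cost,
      stringsAsFactors = FALSE
    )
  }
  structure(
    list(
      table = do.call(rbind, rows), reports = reports, details = details,
      split = train, seed = seed, selection = selection
    ),
    class = "experiment_result"
  )
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("experiment_result (selection =", x$selection, ", seed =", x$seed, ")\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}
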