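test_that("confusion-matrix metrics match their definitions", {
  perfect <- compute_metrics(rep(c(0, 1), each = 50), rep(c(0, 1), each = 50))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)

  # hand-worked contingency table: TP 9, FP 1, TN 8, FN 2
  truth <- c(rep(1, 11), rep(0, 9))
  pred <- c(rep(1, 9), rep(0, 2), 1, rep(0, 8))
  r <- compute_metrics(truth, pred)
  expect_identical(c(r$tp, r$fp, r$tn, r$fn), c(9L, 1L, 8L, 2L))
  expect_equal(r$accuracy, 0.85)
  expect_equal(r$precision, 0.9)
  expect_equal(r$sensitivity, 9 / 11)
  expect_equal(r$specificity, 8 / 9)

  # undefined rates stay undefined
  none_pos <- compute_metrics(c(0, 0, 1), c(0, 0, 0))
  expect_true(is.na(none_pos$precision))
  all_one_class <- compute_metrics(c(1, 1, 1), c(1, 0, 1))
  expect_true(is.na(all_one_class$specificity))

  # accuracy identity: acc = (sen*P + spe*N) / (P + N)
  set.seed(51)
  t2 <- sample(0:1, 60, TRUE)
  p2 <- sample(0:1, 60, TRUE)
  r2 <- compute_metrics(t2, p2)
  P <- sum(t2 == 1)
  N <- sum(t2 == 0)
  expect_equal(r2$accuracy, (r2$sensitivity * P + r2$specificity * N) / (P + N))
})

test_that("AUC behaves as a rank statistic", {
  set.seed(52)
  sc <- rnorm(2000)
  y <- sample(0:1, 2000, TRUE)
  null_auc <- compute_metrics(y, as.numeric(sc > 0), scores = sc)$auc
  expect_equal(null_auc, 0.5, tolerance = 0.05)

  # invariance under strictly monotone transforms
  y2 <- rep(c(0, 1), each = 100)
  sc2 <- rnorm(200) + y2
  a1 <- compute_metrics(y2, as.numeric(sc2 > 0.5), scores = sc2)$auc
  a2 <- compute_metrics(y2, as.numeric(sc2 > 0.5), scores = exp(3 * sc2))$auc
  expect_equal(a1, a2, tolerance = 1e-12)
  expect_gt(a1, 0.5)

  # ROC endpoints
  rc <- roc_curve(sc2, y2)
  expect_equal(c(rc$fpr[1], rc$tpr[1]), c(0, 0))
  expect_equal(c(rc$fpr[nrow(rc)], rc$tpr[nrow(rc)]), c(1, 1))
})

test_that("SVM separates separable toys and is symmetric under label flips", {
  set.seed(53)
  x <- rbind(matrix(rnorm(8, -3), 4, 2), matrix(rnorm(8, 3), 4, 2))
  y <- rep(c(0, 1), each = 4)
  p <- svm_train_predict(x, y, x)
  expect_equal(mean(p$predictions == y), 1)
  expect_equal(compute_metrics(y, p$predictions, p$scores)$auc, 1)

  p_flip <- svm_train_predict(x, 1 - y, x)
  expect_true(all((p$predictions == 1) == (p_flip$predictions == 0)))

  expect_error(svm_train_predict(x, rep(1, 8), x), "single-class")
})

test_that("SVM solution matches an independent dual QP solver", {
  skip_if_not_installed("kernlab")
  set.seed(54)
  x <- rbind(matrix(rnorm(10, -1.5), 5, 2), matrix(rnorm(10, 1.5), 5, 2))
  y <- rep(c(-1, 1), each = 5)
  cost <- 1
  # independent route: solve the soft-margin dual
  #   max sum(alpha) - 0.5 alpha' (yy' * K) alpha, 0 <= alpha <= C, y'alpha = 0
  K <- x %*% t(x)
  sol <- kernlab::ipop(
    c = matrix(-1, 10), H = (y %*% t(y)) * K, A = t(y), b = 0,
    l = matrix(0, 10), u = matrix(cost, 10), r = 0
  )
  alpha <- kernlab::primal(sol)
  sv_oracle <- sort(which(alpha > 1e-5))
  w_oracle <- colSums(alpha * y * x)

  m <- e1071::svm(x, factor(y), kernel = "linear", cost = cost, scale = FALSE)
  expect_identical(sort(m$index), sv_oracle)
  w_fit <- colSums(m$coefs[, 1] * x[m$index, , drop = FALSE])
  # orientation of the internal label coding is arbitrary; compare up to sign
  expect_equal(abs(w_fit), abs(w_oracle), tolerance = 1e-3)
})

test_that("pure-LASSO selection matches a hand-written coordinate descent", {
  set.seed(55)
  n <- 20
  p <- 50
  x <- matrix(rnorm(n * p), n)
  # pre-standardize columns on glmnet's 1/N scale so both solvers see the
  # same predictors
  x <- scale(x, center = TRUE, scale = apply(x, 2, function(c) sqrt(mean((c - mean(c))^2))))
  x <- matrix(as.numeric(x), n, p)
  y <- as.numeric(x[, 1:3] %*% c(1, -1, 0.5) + rnorm(n, sd = 0.5) > 0)
  lambda_obj <- 0.2 # objective-scale penalty; glmnet scale is half of it
  lam_g <- lambda_obj / 2

  # independent oracle: cyclic coordinate descent on
  #   (1/(2N)) ||y - b0 - X beta||^2 + lam_g ||beta||_1
  soft <- function(z, g) sign(z) * pmax(abs(z) - g, 0)
  beta <- rep(0, p)
  b0 <- mean(y)
  for (it in 1:2000) {
    b0 <- mean(y - x %*% beta)
    for (j in 1:p) {
      r_j <- y - b0 - x %*% beta + x[, j] * beta[j]
      beta[j] <- soft(mean(x[, j] * r_j), lam_g) / mean(x[, j]^2)
    }
  }

  sel <- elastic_net_select(x, y, elastic_net_config(lambda = lambda_obj, rho = 1))
  beta_pkg <- rep(0, p)
  beta_pkg[sel$selected] <- sel$coefficients
  expect_identical(sort(sel$selected), which(abs(beta) > 1e-8))
  expect_lt(max(abs(beta_pkg - beta)), 1e-4) # solver tolerance

})

test_that("elastic net recovers planted informative features", {
  # reduced planted design (the full 20-seed version runs in acceptance)
  hits <- vapply(1:5, function(s) {
    set.seed(s + 500)
    n <- 100
    y <- rep(c(0, 1), each = n / 2)
    x <- matrix(rnorm(n * 300), n)
    x[, 1:10] <- x[, 1:10] + matrix(rep(2 * (y - 0.5), 10), n)
    sel <- elastic_net_select(x, y, elastic_net_config(), seed = s)
    mean(1:10 %in% sel$selected)
  }, numeric(1))
  expect_true(all(hits >= 0.8))

  # full shrinkage: nothing survives a huge penalty
  set.seed(56)
  x <- matrix(rnorm(200), 20)
  y <- rep(c(0, 1), 10)
  expect_warning(
    sel0 <- elastic_net_select(x, y, elastic_net_config(lambda = 1e6)),
    "empty selection"
  )
  expect_true(sel0$empty_selection)
  expect_true(all(sel0$coefficients == 0))
})

test_that("experiments are deterministic and consistent across variants", {
  set.seed(57)
  n <- 40
  y <- factor(rep(c("control", "patient"), each = n / 2))
  x <- matrix(rnorm(n * 30), n)
  x[y == "patient", 1:5] <- x[y == "patient", 1:5] + 1.5
  feats <- list(A = x)

  e1 <- run_experiment(feats, y, selection = "L1L2", seed = 9)
  e2 <- run_experiment(feats, y, selection = "L1L2", seed = 9)
  expect_identical(e1$table, e2$table)
  expect_identical(e1$details$A$selected, e2$details$A$selected)

  # experiment errors when a class cannot appear on both sides
  y_bad <- factor(rep("control", n), levels = c("control", "patient"))
  expect_error(run_experiment(feats, y_bad, seed = 1))
})

test_that("test-set labels never influence the fitted pipeline", {
  set.seed(58)
  n <- 40
  y <- factor(rep(c("control", "patient"), each = n / 2))
  x <- matrix(rnorm(n * 30), n)
  x[y == "patient", 1:5] <- x[y == "patient", 1:5] + 1.5
  # fixed explicit split: first 15 of each class train, last 5 test
  train <- rep(c(rep(TRUE, 15), rep(FALSE, 5)), 2)
  e1 <- run_experiment(list(A = x), y, selection = "L1L2", seed = 3, split = train)
  # permute the held-out labels only, under the same split
  y2 <- y
  y2[!train] <- rev(y[!train])
  e2 <- run_experiment(list(A = x), y2, selection = "L1L2", seed = 3, split = train)
  expect_identical(e1$split, e2$split)
  expect_identical(e1$details$A$selected, e2$details$A$selected)
  expect_identical(e1$details$A$cost, e2$details$A$cost)
  expect_identical(e1$table$train_acc, e2$table$train_acc)
})
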