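# builds a minimal fitted volume with planted per-voxel values
fake_fit <- function(grid, mask_idx, d_fun, w_fun) {
  nvox <- prod(grid)
  d <- array(0, c(grid, 6))
  w <- array(0, c(grid, 15))
  for (v in seq_along(mask_idx)) {
    for (k in 1:6) d[mask_idx[v] + (k - 1) * nvox] <- d_fun(v, k)
    for (k in 1:15) w[mask_idx[v] + (k - 1) * nvox] <- w_fun(v, k)
  }
  structure(
    list(
      d = d, w = w, s0 = array(1, grid), flags = array(0L, grid),
      voxel_index = mask_idx, dim = grid
    ),
    class = "tensor_fit"
  )
}

test_that("feature matrices have canonical shape and shared voxel order", {
  grid <- c(5, 4, 3)
  mask <- array(0L, grid)
  mask[c(2, 7, 12, 19, 23, 31, 35, 40, 44, 50)] <- 1L # 10 voxels
  idx <- which(mask == 1L)
  f1 <- fake_fit(grid, idx, function(v, k) v + k / 10, function(v, k) v - k / 10)
  f2 <- fake_fit(grid, idx, function(v, k) 2 * v + k, function(v, k) 2 * v - k)

  kt1 <- extract_subject_matrix(f1, mask, "KT")
  expect_identical(dim(kt1$matrix), c(15L, 10L))
  dt1 <- extract_subject_matrix(f1, mask, "DT")
  expect_identical(dim(dt1$matrix), c(6L, 10L))

  kt2 <- extract_subject_matrix(f2, mask, "KT")
  expect_identical(kt1$voxel_index, kt2$voxel_index)
  # planted value of voxel v, component k lands at [k, v] for both subjects
  expect_equal(unname(kt1$matrix[3, 7]), 7 - 0.3)
  expect_equal(unname(kt2$matrix[3, 7]), 14 - 3)

  expect_error(extract_subject_matrix(f1, array(1L, c(4, 4, 3)), "KT"), "grid mismatch")
})

test_that("zero-pruning is cohort-wide and order-preserving", {
  m1 <- matrix(1, 4, 10)
  m2 <- matrix(2, 4, 10)
  # columns 3, 6, 9 all-zero in both subjects; row 2 all-zero in both
  for (m in c("m1", "m2")) {
    x <- get(m)
    x[, c(3, 6, 9)] <- 0
    x[2, ] <- 0
    assign(m, x)
  }
  pr <- prune_zero_rows_columns(list(m1, m2))
  expect_identical(pr$kept_cols, setdiff(1:10, c(3, 6, 9)))
  expect_identical(pr$kept_rows, c(1L, 3L, 4L))
  expect_identical(dim(pr$cohort[[1]]), c(3L, 7L))

  # a column zero in only one subject survives
  m3 <- m1
  m3[, 1] <- 0
  pr2 <- prune_zero_rows_columns(list(m3, m2))
  expect_true(1 %in% pr2$kept_cols)

  # no zeros anywhere: identity
  a <- matrix(rnorm(40), 4)
  a[a == 0] <- 1
  pr3 <- prune_zero_rows_columns(list(a))
  expect_identical(pr3$cohort[[1]], a)

  # survivors keep their original order and values
  expect_identical(pr$cohort[[2]], m2[c(1, 3, 4), setdiff(1:10, c(3, 6, 9))])

  expect_error(prune_zero_rows_columns(list(matrix(0, 3, 3))), "empty features")
  expect_error(prune_zero_rows_columns(list(matrix(1, 2, 2), matrix(1, 3, 2))), "shape")
})

test_that("flattening is row-major and invertible", {
  m <- matrix(1:6, 2, 3, byrow = TRUE) # rows 1:3, 4:6
  v <- flatten_features(m)
  expect_identical(v, as.numeric(1:6)) # components outer, voxels inner
  expect_identical(matrix(v, 2, 3, byrow = TRUE), matrix(as.numeric(1:6), 2, 3, byrow = TRUE))
})

test_that("cohort summaries respect min <= avg <= max and voxel-order invariance", {
  set.seed(41)
  mats <- replicate(6, matrix(rnorm(60), 6), simplify = FALSE)
  sm <- cohort_summary(mats, rep(c("a", "b"), each = 3))
  expect_true(all(sm$min <= sm$avg & sm$avg <= sm$max))
  perm <- lapply(mats, function(m) m[, sample(ncol(m))])
  sm2 <- cohort_summary(perm, rep(c("a", "b"), each = 3))
  expect_equal(sm$max, sm2$max)
  expect_equal(sm$avg, sm2$avg)
})

test_that("two-group tests behave on degenerate and calibrated inputs", {
  # identical groups: t = 0, p = 1
  set.seed(42)
  v <- rnorm(10)
  sm <- data.frame(
    subject = 1:20, group = rep(c("a", "b"), each = 10),
    max = c(v, v) + 2, min = c(v, v) - 2, avg = c(v, v)
  )
  res <- cohort_summary_tests(sm)
  expect_equal(res$t, rep(0, 3), tolerance = 1e-12)
  expect_equal(res$p_t, rep(1, 3), tolerance = 1e-12)

  # two-group ANOVA F equals the pooled-variance t^2
  sm2 <- sm
  sm2[sm2$group == "b", c("max", "min", "avg")] <-
    sm2[sm2$group == "b", c("max", "min", "avg")] + rnorm(30, 0.5)
  res2 <- cohort_summary_tests(sm2)
  for (st in c("max", "min", "avg")) {
    tp <- t.test(sm2[[st]] ~ sm2$group, var.equal = TRUE)$statistic
    expect_equal(res2$f[res2$statistic == st], unname(tp^2), tolerance = 1e-10)
  }

  expect_error(cohort_summary_tests(sm[c(1, 11), ]), ">= 2 subjects")
  expect_error(cohort_summary_tests(transform(sm, group = "a")), "two groups")
})

test_that("published kurtosis-average group gap is detectable at cohort size", {
  # two groups drawn at the reported per-subject averages: the Welch test
  # should be overwhelmingly significant at n = 70/59
  set.seed(43)
  hits <- replicate(100, {
    a <- rnorm(70, 0.2402, 0.0441)
    b <- rnorm(59, 0.1743, 0.0089)
    sm <- data.frame(
      subject = 1:129, group = rep(c("nc", "pat"), c(70, 59)),
      max = c(a, b), min = c(a, b), avg = c(a, b)
    )
    cohort_summary_tests(sm)$p_t[3] < 0.001
  })
  expect_gte(mean(hits), 0.99)
})
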