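test_that("design matrix has the documented structure and rank", {
  sch <- default_scheme() # 2 b0 + 2 shells x 50 directions
  x <- build_design_matrix(sch)
  expect_identical(dim(x), c(102L, 22L))
  expect_identical(qr(x)$rank, 22L)

  # b = 0 rows: intercept 1, all 21 tensor columns zero
  b0 <- which(sch$bvalues == 0)
  expect_true(all(x[b0, 1] == 1))
  expect_true(all(x[b0, -1] == 0))

  # single-shell and b0-only schemes cannot separate D from W
  one_shell <- default_scheme(bvalues = 1000, n_dirs = 50)
  expect_error(build_design_matrix(one_shell), "underdetermined")
  b0_only <- gradient_scheme(rep(0, 30), matrix(0, 30, 3))
  expect_error(build_design_matrix(b0_only), "underdetermined")
})

test_that("noiseless signals round-trip through the fit", {
  set.seed(21)
  sch <- small_scheme()
  for (i in 1:10) {
    truth <- random_tensor_pair()
    sig <- exp(predict_log_signal(truth, sch))
    fit <- fit_voxel(sig, sch)
    expect_lt(
      max(abs(as.numeric(fit$d) - as.numeric(truth$d))) / max(abs(as.numeric(truth$d))),
      1e-6
    )
    expect_lt(
      max(abs(as.numeric(fit$w) - as.numeric(truth$w))) / max(abs(as.numeric(truth$w))),
      1e-6
    )
    expect_equal(fit$s0, truth$s0, tolerance = 1e-6)
    expect_length(fit$flags, 0)
  }
})

test_that("intensity scaling changes only S0", {
  set.seed(22)
  sch <- small_scheme()
  truth <- random_tensor_pair()
  sig <- exp(predict_log_signal(truth, sch))
  f1 <- fit_voxel(sig, sch)
  f2 <- fit_voxel(sig * 37.5, sch)
  expect_equal(as.numeric(f2$d), as.numeric(f1$d), tolerance = 1e-10)
  expect_equal(as.numeric(f2$w), as.numeric(f1$w), tolerance = 1e-8)
  expect_equal(f2$s0 / f1$s0, 37.5, tolerance = 1e-10)
})

test_that("degenerate and clipped voxels are flagged, not dropped", {
  sch <- small_scheme()
  # constant signal: D ~ 0 -> degenerate mean diffusivity, W reported zero
  fit <- fit_voxel(rep(100, length(sch$bvalues)), sch)
  expect_true("degenerate" %in% fit$flags)
  expect_equal(as.numeric(fit$w), rep(0, 15))

  # one zero signal: clipped flag set, fit still returned
  set.seed(23)
  truth <- random_tensor_pair()
  sig <- exp(predict_log_signal(truth, sch))
  sig[10] <- 0
  fit2 <- fit_voxel(sig, sch)
  expect_true("clipped" %in% fit2$flags)
  expect_true(all(is.finite(as.numeric(fit2$d))))

  expect_error(fit_voxel(sig[-1], sch), "length")
})

test_that("volume fitting honors the mask and detects grid mismatches", {
  set.seed(24)
  sch <- small_scheme()
  grid <- c(5, 4, 3)
  nmeas <- length(sch$bvalues)
  mask <- array(0L, grid)
  mask[2:4, 2:3, 2] <- 1L # 6 voxels
  truth <- random_tensor_pair()
  sig <- exp(predict_log_signal(truth, sch))
  vol <- array(0, c(grid, nmeas))
  nvox <- prod(grid)
  for (m in seq_len(nmeas)) vol[which(mask == 1L) + (m - 1) * nvox] <- sig[m]

  fit <- fit_volume(vol, mask, sch)
  expect_identical(length(fit$voxel_index), 6L)
  # in-mask voxels recover the planted tensors
  for (idx in fit$voxel_index) {
    pos <- arrayInd(idx, grid)
    expect_equal(fit$d[pos[1], pos[2], pos[3], ], unname(as.numeric(truth$d)),
      tolerance = 1e-8
    )
  }
  # out-of-mask voxels hold exact zeros
  out_idx <- setdiff(seq_len(nvox), fit$voxel_index)
  expect_true(all(fit$d[out_idx] == 0))
  expect_true(all(fit$w[out_idx + 14 * nvox] == 0))
  expect_true(all(fit$s0[out_idx] == 0))

  expect_warning(fit_volume(vol, array(0L, grid), sch), "empty mask")
  expect_error(fit_volume(vol, array(1L, c(4, 4, 3)), sch), "grid mismatch")
  expect_error(fit_volume(vol[, , , 1:10], mask, sch), "grid mismatch")
})

test_that("ordinary and weighted fits agree on noiseless data", {
  set.seed(25)
  sch <- small_scheme()
  truth <- random_tensor_pair()
  sig <- exp(predict_log_signal(truth, sch))
  f_w <- fit_voxel(sig, sch, fit_options(weighting = "signal"))
  f_o <- fit_voxel(sig, sch, fit_options(weighting = "ordinary"))
  expect_equal(as.numeric(f_w$d), as.numeric(f_o$d), tolerance = 1e-9)
  expect_equal(as.numeric(f_w$w), as.numeric(f_o$w), tolerance = 1e-7)
})

test_that("component estimates degrade monotonically with noise", {
  # reduced-size version of the SNR sweep (the full one runs in the
  # acceptance suite): weighted fit at SNR 50 beats SNR 10
  set.seed(26)
  sch <- small_scheme()
  rmse_at <- function(snr, n = 40) {
    errs <- vapply(seq_len(n), function(i) {
      truth <- random_tensor_pair()
      s <- exp(predict_log_signal(truth, sch))
      sigma <- truth$s0 / snr
      noisy <- sqrt((s + sigma * rnorm(length(s)))^2 + (sigma * rnorm(length(s)))^2)
      fit <- fit_voxel(noisy, sch)
      sqrt(mean((as.numeric(fit$w) - as.numeric(truth$w))^2))
    }, numeric(1))
    median(errs)
  }
  expect_lt(rmse_at(50), rmse_at(10))
})
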