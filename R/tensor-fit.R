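#' Fitting options for the linearized diffusion-kurtosis fit
#'
#' @param weighting `"signal"` (default) for one signal-weighted refinement
#'   pass after an ordinary least-squares fit, with weights equal to the
#'   squared predicted signals -- the usual antidote to the
#'   heteroscedasticity introduced by the log transform -- or `"ordinary"`
#'   for plain least squares on the log-signals.
#' @param signal_floor Positive clip value applied to non-positive signals
#'   before the log transform. `NULL` (default) uses 1e-6 times the largest
#'   signal in the voxel.
#' @param min_mean_diffusivity Threshold on Dbar^2 ((mm^2/s)^2) below which
#'   the kurtosis tensor is not rescaled; such voxels are flagged
#'   `"degenerate"` and report W = 0.
#' @param max_condition Maximum acceptable condition number of the design
#'   matrix; beyond it the fit aborts as rank-deficient.
#' @return A list of class `"fit_options"`.
#' @export
fit_options <- function(weighting = c("signal", "ordinary"),
                        signal_floor = NULL,
                        min_mean_diffusivity = 1e-12,
                        max_condition = 1e8) {
  weighting <- match.arg(weighting)
  if (!is.null(signal_floor) && signal_floor <= 0) stop("signal_floor must be positive")
  stopifnot(min_mean_diffusivity > 0, max_condition > 1)
  structure(
    list(
      weighting = weighting, signal_floor = signal_floor,
      min_mean_diffusivity = min_mean_diffusivity, max_condition = max_condition
    ),
    class = "fit_options"
  )
}

#' Design matrix of the linearized diffusion-kurtosis model
#'
#' Linearizes the log-signal model in the composite parameter vector
#' theta = (ln S0, D components, B components) with B = Dbar^2 W, which the
#' log-signal depends on linearly. Columns are: an intercept for ln S0; the
#' six diffusion monomials -b n_i n_j with index-multiset multiplicities
#' (2 on off-diagonals); and the fifteen kurtosis monomials
#' (b^2/6) n_i n_j n_k n_l with multiplicities 4, 6 and 12 on the
#' mixed-index components, so the canonical independent components are
#' recovered directly from the solution.
#'
#' @param scheme A [gradient_scheme()] with at least 22 measurements and at
#'   least two distinct nonzero b-values (one shell cannot separate D from W).
#' @return A measurements x 22 numeric matrix.
#' @export
build_design_matrix <- function(scheme) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  b <- scheme$bvalues
  n_shells <- length(unique(b[b > 0]))
  if (n_shells < 2) {
    stop("underdetermined scheme: need >= 2 distinct nonzero b-values to separate D and W")
  }
  if (length(b) < 22) {
    stop("underdetermined scheme: need >= 22 measurements for the 22 model parameters")
  }
  quad <- .dt_monomials(scheme$directions)
  quart <- .kt_monomials(scheme$directions)
  x <- cbind(1, -b * quad, (b^2 / 6) * quart)
  colnames(x) <- c("lnS0", .dt_names, paste0("B.", .kt_names))
  x
}

# Core solver shared by fit_voxel and fit_volume.
# signals: measurements x voxels matrix. Returns component matrices.
.fit_signal_matrix <- function(signals, scheme, options) {
  x <- build_design_matrix(scheme)
  sv <- svd(x, nu = 0, nv = 0)$d
  if (sv[length(sv)] <= 0 || sv[1] / sv[length(sv)] > options$max_condition) {
    stop("rank-deficient design matrix: condition number exceeds max_condition")
  }
  m <- nrow(signals)
  v <- ncol(signals)

  clipped <- logical(v)
  s <- signals
  for (j in seq_len(v)) {
    floor_j <- if (is.null(options$signal_floor)) 1e-6 * max(s[, j]) else options$signal_floor
    if (!is.finite(floor_j) || floor_j <= 0) floor_j <- .Machine$double.eps
    low <- s[, j] <= 0
    if (any(low)) {
      clipped[j] <- TRUE
      s[low, j] <- floor_j
    }
  }
  y <- log(s)

  qx <- qr(x)
  theta <- qr.coef(qx, y)               # 22 x V ordinary LS, all voxels at once
  if (v == 1) theta <- matrix(theta, ncol = 1)

  if (options$weighting == "signal") {
    pred <- x %*% theta
    for (j in seq_len(v)) {
      w <- exp(2 * pred[, j])           # squared predicted signals
      w <- w / max(w)
      xw <- x * w
      a <- crossprod(xw, x)
      bvec <- crossprod(xw, y[, j])
      th <- tryCatch(solve(a, bvec), error = function(e) NULL)
      if (!is.null(th)) theta[, j] <- th
    }
  }

  s0 <- exp(theta[1, ])
  d <- theta[2:7, , drop = FALSE]
  bcomp <- theta[8:22, , drop = FALSE]
  dbar <- colMeans(d[1:3, , drop = FALSE])
  degenerate <- dbar^2 < options$min_mean_diffusivity
  w <- bcomp
  ok <- !degenerate
  if (any(ok)) w[, ok] <- sweep(bcomp[, ok, drop = FALSE], 2, dbar[ok]^2, "/")
  if (any(degenerate)) w[, degenerate] <- 0

  rownames(d) <- .dt_names
  rownames(w) <- .kt_names
  list(s0 = s0, d = d, w = w, clipped = clipped, degenerate = degenerate)
}

#' Fit the diffusion and kurtosis tensors of one voxel
#'
#' Two-stage estimation: (i) linear (optionally signal-weighted) least
#' squares for ln S0, D and the composite B = Dbar^2 W; (ii) Dbar is
#' computed from the fitted D and W recovered as B / Dbar^2. Non-positive
#' signals are clipped to the signal floor and the voxel flagged
#' `"clipped"`; voxels with numerically vanishing Dbar are flagged
#' `"degenerate"` and report W = 0.
#'
#' @param signals Numeric vector of measured intensities, one per scheme
#'   measurement; at least one positive b = 0 signal required.
#' @param scheme A [gradient_scheme()].
#' @param options A [fit_options()].
#' @return A [tensor_pair()] carrying fit flags.
#' @export
fit_voxel <- function(signals, scheme, options = fit_options()) {
  signals <- as.numeric(signals)
  if (length(signals) != length(scheme$bvalues)) {
    stop("signals length does not match the gradient scheme")
  }
  if (!any(signals[scheme$bvalues == 0] > 0)) {
    stop("need at least one positive b = 0 signal")
  }
  fit <- .fit_signal_matrix(matrix(signals, ncol = 1), scheme, options)
  flags <- c(
    if (fit$clipped[1]) "clipped",
    if (fit$degenerate[1]) "degenerate"
  )
  tensor_pair(fit$d[, 1], fit$w[, 1], s0 = fit$s0[1], flags = as.character(flags))
}

#' Fit tensors for every voxel inside a region-of-interest mask
#'
#' Out-of-mask voxels hold exact zeros in every output map, which is what
#' downstream zero-pruning of feature matrices relies on.
#'
#' @param volume 4-D numeric array (x, y, z, measurement).
#' @param mask 3-D array (logical or 0/1) on the same grid.
#' @param scheme A [gradient_scheme()] matching the fourth dimension.
#' @param options A [fit_options()].
#' @return A list of class `"tensor_fit"` with `d` (x,y,z,6), `w` (x,y,z,15),
#'   `s0` (x,y,z), `flags` (x,y,z integer bitmask: 1 = clipped,
#'   2 = degenerate), `voxel_index` (linear indices of in-mask voxels in
#'   scan order) and `dim` (grid dimensions).
#' @export
fit_volume <- function(volume, mask, scheme, options = fit_options()) {
  dv <- dim(volume)
  if (length(dv) != 4) stop("volume must be a 4-D array")
  dm <- dim(mask)
  if (length(dm) != 3 || any(dm != dv[1:3])) {
    stop("grid mismatch: mask dimensions do not match the volume grid")
  }
  if (dv[4] != length(scheme$bvalues)) {
    stop("grid mismatch: fourth volume dimension does not match the gradient scheme")
  }
  grid <- dv[1:3]
  nvox <- prod(grid)
  idx <- which(as.logical(mask) & !is.na(mask))
  d_map <- array(0, c(grid, 6))
  w_map <- array(0, c(grid, 15))
  s0_map <- array(0, grid)
  flag_map <- array(0L, grid)
  if (length(idx) == 0) {
    warning("empty mask: no voxels fitted")
    return(structure(
      list(
        d = d_map, w = w_map, s0 = s0_map, flags = flag_map,
        voxel_index = integer(0), dim = grid
      ),
      class = "tensor_fit"
    ))
  }
  sig <- matrix(volume, nrow = nvox)[idx, , drop = FALSE]
  fit <- .fit_signal_matrix(t(sig), scheme, options)
  for (k in 1:6) d_map[idx + (k - 1) * nvox] <- fit$d[k, ]
  for (k in 1:15) w_map[idx + (k - 1) * nvox] <- fit$w[k, ]
  s0_map[idx] <- fit$s0
  flag_map[idx] <- as.integer(fit$clipped) + 2L * as.integer(fit$degenerate)
  structure(
    list(
      d = d_map, w = w_map, s0 = s0_map, flags = flag_map,
      voxel_index = idx, dim = grid
    ),
    class = "tensor_fit"
  )
}
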