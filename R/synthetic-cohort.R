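#' Design of a synthetic two-group diffusion-kurtosis cohort
#'
#' Describes a fully synthetic patient/control cohort: an ellipsoidal
#' hippocampus-like ROI of per-voxel diffusion/kurtosis tensor pairs whose
#' per-subject feature-matrix summaries are calibrated to published
#' two-group statistics, converted to noisy multi-shell signals through the
#' forward log-signal model.
#'
#' The calibration targets are the per-subject averages of the DT and KT
#' feature matrices (`dt_avg`, `kt_avg`, each `c(mean, sd)` across
#' subjects). For an isotropic kurtosis tensor at level K the 15-component
#' average is 4K/15, and for a randomly oriented diffusion tensor with mean
#' diffusivity MD the 6-component average is MD/2 in expectation, so
#' subject-level draws use K_s ~ N(15/4 * kt_avg) and
#' MD_s ~ N(2 * dt_avg).
#'
#' @param n_per_group Integer vector `c(controls, patients)`.
#' @param grid 3-D grid dimensions in voxels.
#' @param roi_semiaxes Ellipsoid semi-axes in voxels (ROI of ~500 voxels by
#'   default).
#' @param group_params Named list (`control`, `patient`) of lists with
#'   `dt_avg` (mean, sd; 1e-3 mm^2/s units are NOT folded in -- give
#'   absolute mm^2/s values) and `kt_avg` (mean, sd; dimensionless).
#'   Defaults: control dt_avg (0.5116, 0.1563)e-3, kt_avg (0.2402, 0.0441);
#'   patient dt_avg (0.7025, 0.1048)e-3, kt_avg (0.1743, 0.0089).
#' @param noise_snr Rician signal-to-noise ratio on S0 (`Inf` disables
#'   noise).
#' @param noise_model `"rician"` (magnitude MRI) or `"gaussian"`.
#' @param scheme Acquisition [gradient_scheme()]; default two shells
#'   (b = 1000, 2000 s/mm^2) of 50 directions plus 2 unweighted scans.
#' @param within_subject_frac Within-subject (voxelwise) variation of MD
#'   and K, as a fraction of the between-subject sd.
#' @param anisotropy Relative eigenvalue jitter of D (sets the FA scale;
#'   the default gives gray-matter-like FA around 0.1-0.3).
#' @param w_perturbation Relative jitter applied to the kurtosis-tensor
#'   components (0 keeps W exactly isotropic, the default).
#' @param s0 Unweighted signal level (arbitrary units).
#' @param seed Master RNG seed of the cohort.
#' @return A list of class `"cohort_design"`.
#' @export
cohort_design <- function(n_per_group = c(30, 30),
                          grid = c(15, 13, 11),
                          roi_semiaxes = c(6, 5, 4),
                          group_params = list(
                            control = list(
                              dt_avg = c(0.5116e-3, 0.1563e-3),
                              kt_avg = c(0.2402, 0.0441)
                            ),
                            patient = list(
                              dt_avg = c(0.7025e-3, 0.1048e-3),
                              kt_avg = c(0.1743, 0.0089)
                            )
                          ),
                          noise_snr = 50,
                          noise_model = c("rician", "gaussian"),
                          scheme = default_scheme(),
                          within_subject_frac = 0.2,
                          anisotropy = 0.15,
                          w_perturbation = 0,
                          s0 = 1000,
                          seed = 1) {
  noise_model <- match.arg(noise_model)
  stopifnot(length(n_per_group) == 2, all(n_per_group >= 1))
  stopifnot(length(grid) == 3, length(roi_semiaxes) == 3)
  if (any(roi_semiaxes <= 0)) stop("degenerate ROI: semi-axes must be positive")
  if (any(2 * roi_semiaxes + 1 > grid)) stop("ROI semi-axes do not fit in the grid")
  if (!(noise_snr > 0)) stop("noise_snr must be positive (use Inf to disable noise)")
  for (g in c("control", "patient")) {
    p <- group_params[[g]]
    if (is.null(p) || length(p$dt_avg) != 2 || length(p$kt_avg) != 2) {
      stop("group_params must give dt_avg and kt_avg as c(mean, sd) for ", g)
    }
    if (p$dt_avg[2] < 0 || p$kt_avg[2] < 0) stop("sds must be non-negative")
  }
  stopifnot(within_subject_frac >= 0, anisotropy >= 0, w_perturbation >= 0, s0 > 0)
  structure(
    list(
      n_per_group = as.integer(n_per_group), grid = as.integer(grid),
      roi_semiaxes = roi_semiaxes, group_params = group_params,
      noise_snr = noise_snr, noise_model = noise_model, scheme = scheme,
      within_subject_frac = within_subject_frac, anisotropy = anisotropy,
      w_perturbation = w_perturbation, s0 = s0, seed = as.integer(seed)
    ),
    class = "cohort_design"
  )
}

#' Voxelized ellipsoidal ROI mask
#'
#' Deterministic for a given design: voxel centers inside the ellipsoid
#' centered on the grid with the design's semi-axes.
#'
#' @param design A [cohort_design()].
#' @return A 3-D 0/1 integer array on the design grid.
#' @export
make_roi_mask <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  g <- design$grid
  ctr <- (g + 1) / 2
  ax <- design$roi_semiaxes
  x <- (seq_len(g[1]) - ctr[1]) / ax[1]
  y <- (seq_len(g[2]) - ctr[2]) / ax[2]
  z <- (seq_len(g[3]) - ctr[3]) / ax[3]
  r2 <- outer(outer(x^2, y^2, "+"), z^2, "+")
  array(as.integer(r2 <= 1), g)
}

# Smooth standardized random field over ROI voxel coordinates: a few
# random-direction cosine modes, normalized to zero mean and unit sd.
.smooth_field <- function(coords, n_modes = 4) {
  v <- numeric(nrow(coords))
  ext <- max(apply(coords, 2, function(c) diff(range(c))), 1)
  for (i in seq_len(n_modes)) {
    k <- stats::rnorm(3)
    k <- k / sqrt(sum(k^2)) * (2 * pi * stats::runif(1, 0.5, 1.5) / ext)
    v <- v + cos(coords %*% k + stats::runif(1, 0, 2 * pi))
  }
  s <- stats::sd(v)
  if (s == 0) return(v * 0)
  (v - mean(v)) / s
}

# Random rotation matrix (Haar-ish via QR with sign fix).
.random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Sample a subject's ground-truth tensor field
#'
#' Draws a subject-level (MD, K) pair from the group's calibrated
#' distributions, adds smooth within-ROI voxel variation, injects
#' anisotropy by jittering the eigenvalues of D around the voxel MD under a
#' random rotation (always positive-definite), and builds W as the
#' isotropic kurtosis construction
#' W_ijkl = (K/3)(d_ij d_kl + d_ik d_jl + d_il d_jk) scaled per voxel
#' (optionally perturbed by `w_perturbation`).
#'
#' @param design A [cohort_design()].
#' @param group `"control"` or `"patient"`.
#' @param subject_seed Integer seed; the field is a pure function of
#'   (design, group, subject_seed).
#' @return List with `d` (6 x V), `w` (15 x V), `s0`, `voxel_index`,
#'   `md_subject`, `k_subject`.
#' @export
sample_tensor_field <- function(design, group = c("control", "patient"), subject_seed = 1) {
  stopifnot(inherits(design, "cohort_design"))
  group <- match.arg(group)
  mask <- make_roi_mask(design)
  idx <- which(mask == 1L)
  v <- length(idx)
  pos <- arrayInd(idx, design$grid)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(subject_seed)

  p <- design$group_params[[group]]
  md_mean <- 2 * p$dt_avg[1]
  md_sd <- 2 * p$dt_avg[2]
  k_mean <- 15 / 4 * p$kt_avg[1]
  k_sd <- 15 / 4 * p$kt_avg[2]

  draw_positive <- function(mean, sd, floor) {
    for (i in 1:100) {
      val <- stats::rnorm(1, mean, sd)
      if (val > floor) return(val)
    }
    warning("rejection-resampling failed to draw a positive parameter; clamping")
    floor
  }
  md_s <- draw_positive(md_mean, md_sd, 0.05 * md_mean)
  k_s <- draw_positive(k_mean, k_sd, 0.01)

  f_md <- .smooth_field(pos)
  f_k <- .smooth_field(pos)
  md_v <- md_s + design$within_subject_frac * md_sd * f_md
  md_v <- pmax(md_v, 0.1 * md_s)
  k_v <- k_s + design$within_subject_frac * k_sd * f_k
  k_v <- pmax(k_v, 0.01)

  d <- matrix(0, 6, v)
  for (j in seq_len(v)) {
    eta <- stats::rnorm(3)
    eta <- eta - mean(eta)
    lam <- md_v[j] * (1 + design$anisotropy * eta)
    lam <- pmax(lam, 0.05 * md_v[j])
    lam <- lam * md_v[j] / mean(lam)   # preserve the voxel MD exactly
    r <- .random_rotation()
    d[, j] <- diffusion_tensor(r %*% diag(lam) %*% t(r))
  }
  w <- vapply(k_v, function(k) as.numeric(isotropic_kurtosis_tensor(k)), numeric(15))
  if (design$w_perturbation > 0) {
    w <- w * (1 + design$w_perturbation * matrix(stats::rnorm(15 * v), 15, v))
  }
  rownames(d) <- .dt_names
  rownames(w) <- .kt_names
  list(
    d = d, w = w, s0 = design$s0, voxel_index = idx,
    md_subject = md_s, k_subject = k_s
  )
}

#' Simulate one subject's noisy multi-shell signal volume
#'
#' Evaluates the forward log-signal model at every ROI voxel of the
#' subject's ground-truth field, exponentiates, and applies Rician noise at
#' the design SNR (magnitude of a complex Gaussian perturbation with sigma
#' = S0 / SNR). Out-of-mask voxels are exactly zero.
#'
#' @param design A [cohort_design()].
#' @param group `"control"` or `"patient"`.
#' @param subject_seed Integer seed (field and noise).
#' @return List with `signals` (4-D array x,y,z,measurement), `truth` (the
#'   [sample_tensor_field()] result), `mask`, `scheme`, `group`.
#' @export
simulate_subject <- function(design, group = c("control", "patient"), subject_seed = 1) {
  group <- match.arg(group)
  truth <- sample_tensor_field(design, group, subject_seed)
  mask <- make_roi_mask(design)
  idx <- truth$voxel_index
  x <- build_design_matrix(design$scheme)
  dbar2 <- colMeans(truth$d[1:3, , drop = FALSE])^2
  theta <- rbind(
    log(truth$s0),
    truth$d,
    sweep(truth$w, 2, dbar2, "*")
  )
  s <- exp(x %*% theta)   # measurements x voxels

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(subject_seed + 104729L)  # independent stream for the noise
  if (is.finite(design$noise_snr)) {
    sigma <- design$s0 / design$noise_snr
    if (design$noise_model == "rician") {
      s <- sqrt((s + sigma * matrix(stats::rnorm(length(s)), nrow(s)))^2 +
        (sigma * matrix(stats::rnorm(length(s)), nrow(s)))^2)
    } else {
      s <- s + sigma * matrix(stats::rnorm(length(s)), nrow(s))
    }
  }
  grid <- design$grid
  nvox <- prod(grid)
  vol <- array(0, c(grid, nrow(x)))
  for (m in seq_len(nrow(x))) vol[idx + (m - 1) * nvox] <- s[m, ]
  list(signals = vol, truth = truth, mask = mask, scheme = design$scheme, group = group)
}

#' Generate a reproducible synthetic cohort
#'
#' Simulates every subject of both groups with per-subject seeds derived
#' from the design seed, returning the signal volumes together with the
#' ground-truth tensor fields for parameter-recovery scoring.
#'
#' @param design A [cohort_design()].
#' @return A list of class `"cohort"` with `subjects` (each a
#'   [simulate_subject()] bundle), `labels` (factor control/patient),
#'   `mask`, `scheme`, `design`, `subject_seeds`.
#' @export
generate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  groups <- rep(c("control", "patient"), design$n_per_group)
  seeds <- (design$seed + 7919L * seq_along(groups)) %% 2147483647L
  subjects <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    subjects[[i]] <- simulate_subject(design, groups[i], seeds[i])
  }
  names(subjects) <- sprintf("%s_%02d", groups, stats::ave(seq_along(groups), groups, FUN = seq_along))
  structure(
    list(
      subjects = subjects, labels = factor(groups, c("control", "patient")),
      mask = make_roi_mask(design), scheme = design$scheme, design = design,
      subject_seeds = seeds
    ),
    class = "cohort"
  )
}
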