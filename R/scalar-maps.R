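#' Mean diffusivity
#'
#' Trace of the diffusion tensor divided by 3, equal to the mean of its
#' eigenvalues.
#'
#' @param d A `diffusion_tensor` or length-6 canonical component vector.
#' @return Mean diffusivity (mm^2/s).
#' @export
mean_diffusivity <- function(d) {
  d <- as.numeric(d)
  stopifnot(length(d) == 6)
  mean(d[1:3])
}

#' Fractional anisotropy
#'
#' Standard eigenvalue definition:
#' FA = sqrt(3/2) * ||lambda - mean(lambda)|| / ||lambda||, ranging from 0
#' (isotropic) to 1 (diffusion confined to one axis).
#'
#' @param d A `diffusion_tensor` or length-6 canonical component vector.
#' @return Dimensionless FA in \[0, 1\] for positive-semidefinite tensors.
#' @export
fractional_anisotropy <- function(d) {
  d <- as.numeric(d)
  stopifnot(length(d) == 6)
  lam <- eigen(dt_matrix(d), symmetric = TRUE, only.values = TRUE)$values
  nrm <- sqrt(sum(lam^2))
  if (nrm == 0) stop("FA is undefined for the zero tensor")
  sqrt(1.5) * sqrt(sum((lam - mean(lam))^2)) / nrm
}

#' Mean kurtosis by spherical averaging
#'
#' Averages the directional kurtosis K(n) over a deterministic,
#' approximately uniform full-sphere spiral ([sphere_directions()]). K(n)
#' is even in n, so the full-sphere average equals the average over the
#' antipodally symmetrized set; the spiral is used directly because its
#' point distribution converges faster than hemisphere-pair constructions
#' at the same direction count. This directional average is the common
#' numerical surrogate for the closed-form mean kurtosis.
#'
#' @param pair A [tensor_pair()].
#' @param n_directions Number of quadrature directions (even, >= 60;
#'   default 256).
#' @param tol Degeneracy tolerance on |D(n)| forwarded to the directional
#'   kurtosis.
#' @return Dimensionless mean kurtosis.
#' @export
mean_kurtosis <- function(pair, n_directions = 256, tol = 1e-12) {
  stopifnot(inherits(pair, "tensor_pair"))
  if (n_directions < 60) stop("n_directions must be >= 60")
  dirs <- sphere_directions(n_directions)
  d <- as.numeric(pair$d)
  w <- as.numeric(pair$w)
  dbar <- mean(d[1:3])
  dn <- drop(.dt_monomials(dirs) %*% d)
  if (any(abs(dn) < tol)) stop("degenerate voxel: D(n) vanishes along a quadrature direction")
  wq <- drop(.kt_monomials(dirs) %*% w)
  mean(dbar^2 / dn^2 * wq)
}

# Vectorized scalar maps over component matrices (components x voxels).
# Returns a numeric vector per voxel; degenerate voxels yield NA.
.md_many <- function(dmat) colMeans(dmat[1:3, , drop = FALSE])

.fa_many <- function(dmat) {
  apply(dmat, 2, function(d) {
    if (all(d == 0)) return(NA_real_)
    fractional_anisotropy(d)
  })
}

.mk_many <- function(dmat, wmat, n_directions = 256, tol = 1e-12) {
  dirs <- sphere_directions(n_directions)
  a2 <- .dt_monomials(dirs)
  a4 <- .kt_monomials(dirs)
  dn <- a2 %*% dmat          # directions x voxels
  wq <- a4 %*% wmat
  dbar <- colMeans(dmat[1:3, , drop = FALSE])
  bad <- apply(abs(dn) < tol, 2, any)
  k <- sweep(wq / dn^2, 2, dbar^2, "*")
  out <- colMeans(k)
  out[bad] <- NA_real_
  out
}

#' Scalar biomarker maps from a fitted tensor volume
#'
#' Derives single-volume maps of mean diffusivity (MD), fractional
#' anisotropy (FA) and mean kurtosis (MK) from a [fit_volume()] result.
#' Out-of-mask voxels stay exactly zero; degenerate in-mask voxels
#' (flagged during fitting) propagate as NA.
#'
#' @param fit A `"tensor_fit"` object.
#' @param which Character vector among `"md"`, `"fa"`, `"mk"`.
#' @param n_directions Quadrature directions for MK.
#' @return Named list of 3-D arrays on the fit grid.
#' @export
scalar_maps <- function(fit, which = c("md", "fa", "mk"), n_directions = 256) {
  stopifnot(inherits(fit, "tensor_fit"))
  which <- match.arg(which, c("md", "fa", "mk"), several.ok = TRUE)
  idx <- fit$voxel_index
  grid <- fit$dim
  nvox <- prod(grid)
  dmat <- sapply(1:6, function(k) fit$d[idx + (k - 1) * nvox])
  dmat <- matrix(t(dmat), nrow = 6)
  wmat <- sapply(1:15, function(k) fit$w[idx + (k - 1) * nvox])
  wmat <- matrix(t(wmat), nrow = 15)
  degenerate <- bitwAnd(fit$flags[idx], 2L) > 0
  out <- list()
  for (nm in which) {
    vals <- switch(nm,
      md = .md_many(dmat),
      fa = .fa_many(dmat),
      mk = .mk_many(dmat, wmat, n_directions)
    )
    if (nm == "mk") vals[degenerate] <- NA_real_
    m <- array(0, grid)
    m[idx] <- vals
    out[[nm]] <- m
  }
  out
}
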