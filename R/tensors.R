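#' @keywords internal
"_PACKAGE"

# Canonical component orderings shared by every module. Feature matrices,
# NIfTI tensor maps and the design matrix all use these orders; changing them
# breaks feature reproducibility across runs.
.dt_names <- c("D11", "D22", "D33", "D12", "D13", "D23")
.dt_index <- matrix(c(1, 1, 2, 2, 3, 3, 1, 2, 1, 3, 2, 3), ncol = 2, byrow = TRUE)
.dt_mult <- c(1, 1, 1, 2, 2, 2)

.kt_names <- c(
  "W1111", "W2222", "W3333",
  "W1112", "W1113", "W1222", "W2223", "W1333", "W2333",
  "W1122", "W1133", "W2233",
  "W1123", "W1223", "W1233"
)
.kt_index <- matrix(c(
  1, 1, 1, 1,
  2, 2, 2, 2,
  3, 3, 3, 3,
  1, 1, 1, 2,
  1, 1, 1, 3,
  1, 2, 2, 2,
  2, 2, 2, 3,
  1, 3, 3, 3,
  2, 3, 3, 3,
  1, 1, 2, 2,
  1, 1, 3, 3,
  2, 2, 3, 3,
  1, 1, 2, 3,
  1, 2, 2, 3,
  1, 2, 3, 3
), ncol = 4, byrow = TRUE)
# multiplicity of each index multiset under the 4! permutations
.kt_mult <- c(1, 1, 1, 4, 4, 4, 4, 4, 4, 6, 6, 6, 12, 12, 12)

#' Number of independent components of a fully symmetric tensor
#'
#' A fully symmetric tensor of a given order in `dimension` spatial
#' dimensions has one independent component per index multiset, i.e.
#' `choose(dimension + order - 1, order)`. For the diffusion tensor
#' (order 2, dimension 3) this gives 6; for the kurtosis tensor (order 4)
#' it gives 15, so the diffusion-weighted signal model carries 21
#' independent tensor components plus the unweighted signal.
#'
#' @param order Tensor order (number of indices), a positive integer.
#' @param dimension Spatial dimension, a positive integer.
#' @return Integer count of symmetry-distinct components.
#' @examples
#' count_independent_components(2, 3) # 6
#' count_independent_components(4, 3) # 15
#' @export
count_independent_components <- function(order, dimension) {
  stopifnot(length(order) == 1, length(dimension) == 1)
  if (order < 1 || order != round(order)) stop("'order' must be a positive integer")
  if (dimension < 1 || dimension != round(dimension)) stop("'dimension' must be a positive integer")
  as.integer(choose(dimension + order - 1, order))
}

#' Construct a diffusion tensor from its six independent components
#'
#' Components are stored in the package's canonical order
#' (D11, D22, D33, D12, D13, D23), in mm^2/s.
#'
#' @param x Numeric vector of length 6, or a symmetric 3x3 matrix.
#' @return A named numeric vector of class `"diffusion_tensor"`.
#' @export
diffusion_tensor <- function(x) {
  if (is.matrix(x)) {
    stopifnot(all(dim(x) == c(3, 3)))
    if (max(abs(x - t(x))) > 1e-12 * max(1, max(abs(x)))) {
      stop("matrix form of a diffusion tensor must be symmetric")
    }
    x <- c(x[1, 1], x[2, 2], x[3, 3], x[1, 2], x[1, 3], x[2, 3])
  }
  stopifnot(is.numeric(x), length(x) == 6)
  structure(stats::setNames(as.numeric(x), .dt_names), class = "diffusion_tensor")
}

#' Expand a 6-component diffusion tensor to its symmetric 3x3 matrix
#' @param d Numeric vector of 6 canonical components.
#' @return A symmetric 3x3 matrix.
#' @export
dt_matrix <- function(d) {
  d <- as.numeric(d)
  stopifnot(length(d) == 6)
  m <- matrix(0, 3, 3)
  m[cbind(.dt_index[, 1], .dt_index[, 2])] <- d
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

#' Construct a kurtosis tensor from its fifteen independent components
#'
#' Canonical order: W1111, W2222, W3333, W1112, W1113, W1222, W2223, W1333,
#' W2333, W1122, W1133, W2233, W1123, W1223, W1233 (dimensionless).
#'
#' @param x Numeric vector of length 15, or a fully symmetric 3x3x3x3 array.
#' @return A named numeric vector of class `"kurtosis_tensor"`.
#' @export
kurtosis_tensor <- function(x) {
  if (is.array(x) && length(dim(x)) == 4) {
    stopifnot(all(dim(x) == 3))
    x <- x[.kt_index]
  }
  stopifnot(is.numeric(x), length(x) == 15)
  structure(stats::setNames(as.numeric(x), .kt_names), class = "kurtosis_tensor")
}

#' Expand a 15-component kurtosis tensor to the full 3x3x3x3 array
#'
#' The result is invariant under all 24 index permutations.
#'
#' @param w Numeric vector of 15 canonical components.
#' @return A 3x3x3x3 numeric array.
#' @export
kt_array <- function(w) {
  w <- as.numeric(w)
  stopifnot(length(w) == 15)
  a <- array(0, c(3, 3, 3, 3))
  perms <- .perm4()
  for (k in seq_len(15)) {
    idx <- .kt_index[k, ]
    for (p in seq_len(nrow(perms))) {
      a[idx[perms[p, 1]], idx[perms[p, 2]], idx[perms[p, 3]], idx[perms[p, 4]]] <- w[k]
    }
  }
  a
}

.perm4 <- function() {
  # all 24 permutations of 4 indices, enumerated once
  out <- matrix(0L, 24, 4)
  r <- 1L
  for (i in 1:4) for (j in 1:4) for (k in 1:4) for (l in 1:4) {
    if (length(unique(c(i, j, k, l))) == 4L) {
      out[r, ] <- c(i, j, k, l)
      r <- r + 1L
    }
  }
  out
}

#' Isotropic kurtosis tensor with constant directional kurtosis
#'
#' Builds W_ijkl = (K/3) (d_ij d_kl + d_ik d_jl + d_il d_jk), the fully
#' symmetric isotropic tensor whose directional kurtosis equals `k` along
#' every direction when the diffusion tensor is isotropic.
#'
#' @param k Directional kurtosis level (dimensionless scalar).
#' @return A `kurtosis_tensor` (15 canonical components).
#' @export
isotropic_kurtosis_tensor <- function(k) {
  stopifnot(is.numeric(k), length(k) == 1)
  w <- numeric(15)
  w[1:3] <- k          # Wiiii = 3*(K/3)
  w[10:12] <- k / 3    # Wiijj = K/3
  kurtosis_tensor(w)
}

#' Bundle a diffusion tensor, kurtosis tensor and unweighted signal
#'
#' @param d A `diffusion_tensor` or length-6 numeric vector.
#' @param w A `kurtosis_tensor` or length-15 numeric vector.
#' @param s0 Unweighted signal S0 (> 0, arbitrary intensity units).
#' @param flags Character vector of fit-quality flags (e.g. `"clipped"`,
#'   `"degenerate"`).
#' @return A list of class `"tensor_pair"`.
#' @export
tensor_pair <- function(d, w, s0 = 1, flags = character()) {
  d <- diffusion_tensor(d)
  w <- kurtosis_tensor(w)
  stopifnot(is.numeric(s0), length(s0) == 1)
  if (!(s0 > 0)) stop("s0 must be positive")
  structure(list(d = d, w = w, s0 = s0, flags = flags), class = "tensor_pair")
}

# Monomial matrices mapping canonical component vectors to directional
# quadratic/quartic forms: rows are directions, columns components, with the
# index-multiset multiplicities folded in so that e.g.
# (quad %*% d)[m] = sum_ij n_i n_j D_ij for direction m.
.dt_monomials <- function(dirs) {
  dirs <- .as_dir_matrix(dirs)
  m <- matrix(0, nrow(dirs), 6)
  for (k in 1:6) {
    m[, k] <- .dt_mult[k] * dirs[, .dt_index[k, 1]] * dirs[, .dt_index[k, 2]]
  }
  m
}

.kt_monomials <- function(dirs) {
  dirs <- .as_dir_matrix(dirs)
  m <- matrix(0, nrow(dirs), 15)
  for (k in 1:15) {
    m[, k] <- .kt_mult[k] * dirs[, .kt_index[k, 1]] * dirs[, .kt_index[k, 2]] *
      dirs[, .kt_index[k, 3]] * dirs[, .kt_index[k, 4]]
  }
  m
}

.as_dir_matrix <- function(dirs) {
  if (is.null(dim(dirs))) dirs <- matrix(dirs, nrow = 1)
  stopifnot(ncol(dirs) == 3)
  dirs
}

#' Apparent diffusivity along a direction
#'
#' Evaluates the signed quadratic form D(n) = sum_ij n_i n_j D_ij. For a
#' physical (positive-semidefinite) tensor this is non-negative; the sign is
#' preserved rather than taking an absolute value so that fit pathologies
#' remain visible.
#'
#' @param d A `diffusion_tensor` or length-6 numeric vector.
#' @param direction Unit 3-vector.
#' @return Diffusivity in mm^2/s.
#' @export
directional_diffusivity <- function(d, direction) {
  direction <- as.numeric(direction)
  stopifnot(length(direction) == 3)
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("direction must be a nonzero vector")
  if (abs(nrm - 1) > 1e-6) stop("direction must be a unit vector")
  drop(.dt_monomials(direction) %*% as.numeric(d))
}

#' Directional kurtosis along a direction
#'
#' Evaluates K(n) = (Dbar^2 / D(n)^2) sum_ijkl n_i n_j n_k n_l W_ijkl,
#' where Dbar is the mean diffusivity of the paired diffusion tensor.
#'
#' @param pair A `tensor_pair`.
#' @param direction Unit 3-vector.
#' @param tol Directions with |D(n)| below `tol` (mm^2/s) are rejected as
#'   degenerate.
#' @return Dimensionless kurtosis.
#' @export
directional_kurtosis <- function(pair, direction, tol = 1e-12) {
  stopifnot(inherits(pair, "tensor_pair"))
  dn <- directional_diffusivity(pair$d, direction)
  if (abs(dn) < tol) stop("degenerate direction: D(n) is numerically zero")
  dbar <- mean(as.numeric(pair$d)[1:3])
  wq <- drop(.kt_monomials(direction) %*% as.numeric(pair$w))
  dbar^2 / dn^2 * wq
}

#' Predicted log-signal of the diffusion-kurtosis model
#'
#' Evaluates, for every measurement of a gradient scheme,
#' ln S(b, n) = ln S0 - b sum_ij n_i n_j D_ij
#'            + (b^2 Dbar^2 / 6) sum_ijkl n_i n_j n_k n_l W_ijkl,
#' the fourth-order cumulant expansion of the diffusion-weighted signal.
#'
#' @param pair A `tensor_pair`.
#' @param scheme A [gradient_scheme()].
#' @return Numeric vector of log-signal values, one per measurement.
#' @export
predict_log_signal <- function(pair, scheme) {
  stopifnot(inherits(pair, "tensor_pair"), inherits(scheme, "gradient_scheme"))
  d <- as.numeric(pair$d)
  w <- as.numeric(pair$w)
  dbar <- mean(d[1:3])
  b <- scheme$bvalues
  quad <- drop(.dt_monomials(scheme$directions) %*% d)
  quart <- drop(.kt_monomials(scheme$directions) %*% w)
  log(pair$s0) - b * quad + (b^2 * dbar^2 / 6) * quart
}
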