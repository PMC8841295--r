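# Shared fixtures: small deterministic schemes and random-but-seeded tensors.

# compact two-shell scheme (2 b0 + 2 x 16 directions) -- enough rank for the
# 22-parameter model but ~3x fewer measurements than the clinical protocol
small_scheme <- function(n_dirs = 24) {
  default_scheme(bvalues = c(1000, 2000), n_dirs = n_dirs, n_b0 = 2)
}

# random symmetric positive-definite diffusion tensor with brain-scale
# diffusivities (~1e-3 mm^2/s)
random_spd_tensor <- function(md = 1e-3, spread = 0.3) {
  m <- matrix(rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  lam <- md * (1 + spread * runif(3, -1, 1))
  diffusion_tensor(q %*% diag(lam) %*% t(q))
}

# random valid tensor pair: SPD diffusion plus a mildly anisotropic
# kurtosis tensor around a physiological mean level
random_tensor_pair <- function(md = 1e-3, k = 0.8, w_jitter = 0.1, s0 = 1000) {
  d <- random_spd_tensor(md)
  w <- as.numeric(isotropic_kurtosis_tensor(k)) + w_jitter * k * rnorm(15)
  tensor_pair(d, w, s0 = s0)
}

# tiny cohort design used by pipeline-level unit tests
tiny_design <- function(seed = 1, n = c(4, 4), snr = 50) {
  cohort_design(
    n_per_group = n, grid = c(9, 9, 9), roi_semiaxes = c(3, 2.5, 2),
    scheme = small_scheme(), noise_snr = snr, seed = seed
  )
}

# brute-force directional kurtosis via full tensor expansion: contracts the
# 3x3x3x3 array directly, independent of the package's monomial tables
brute_force_k <- function(pair, dirs) {
  dm <- dt_matrix(as.numeric(pair$d))
  wfull <- kt_array(as.numeric(pair$w))
  dbar <- mean(as.numeric(pair$d)[1:3])
  w99 <- matrix(wfull, 9, 9)
  nn <- dirs[, rep(1:3, each = 3)] * dirs[, rep(1:3, times = 3)]
  quart <- rowSums((nn %*% w99) * nn)
  dn <- rowSums((dirs %*% dm) * dirs)
  dbar^2 / dn^2 * quart
}
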