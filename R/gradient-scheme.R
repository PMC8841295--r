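#' Acquisition geometry for multi-shell diffusion MRI
#'
#' A gradient scheme pairs each measurement with a diffusion weighting
#' (b-value, s/mm^2) and a unit gradient direction. Directions on b = 0
#' measurements are arbitrary and conventionally zero. Shells are the sets
#' of measurements sharing one b-value.
#'
#' @param bvalues Numeric vector of b-values (s/mm^2), all >= 0.
#' @param directions Numeric matrix of gradient directions, either
#'   measurements x 3 or the FSL-style 3 x measurements layout.
#' @return A list of class `"gradient_scheme"` with elements `bvalues`,
#'   `directions` (measurements x 3), and `shell_ids` (integer shell index,
#'   0 for b = 0).
#' @export
gradient_scheme <- function(bvalues, directions) {
  bvalues <- as.numeric(bvalues)
  if (any(!is.finite(bvalues)) || any(bvalues < 0)) {
    stop("all b-values must be finite and non-negative")
  }
  if (is.null(dim(directions))) directions <- matrix(directions, ncol = 3, byrow = TRUE)
  directions <- as.matrix(directions)
  if (nrow(directions) == 3 && ncol(directions) != 3) directions <- t(directions)
  if (ncol(directions) != 3 || nrow(directions) != length(bvalues)) {
    stop("directions must supply one 3-vector per b-value")
  }
  dimnames(directions) <- NULL
  nrm <- sqrt(rowSums(directions^2))
  bad <- bvalues > 0 & abs(nrm - 1) > 1e-6
  if (any(bad)) {
    stop(sprintf(
      "invalid scheme: %d measurement(s) with b > 0 have non-unit directions",
      sum(bad)
    ))
  }
  if (!any(bvalues == 0)) {
    stop("scheme needs at least one b = 0 measurement for absolute-signal fitting")
  }
  nz <- sort(unique(bvalues[bvalues > 0]))
  shell_ids <- integer(length(bvalues))
  if (length(nz)) shell_ids[bvalues > 0] <- match(bvalues[bvalues > 0], nz)
  structure(
    list(bvalues = bvalues, directions = directions, shell_ids = shell_ids),
    class = "gradient_scheme"
  )
}

#' @export
print.gradient_scheme <- function(x, ...) {
  tab <- table(x$bvalues)
  cat("gradient_scheme:", length(x$bvalues), "measurements\n")
  for (b in names(tab)) cat(sprintf("  b = %s s/mm^2: %d\n", b, tab[[b]]))
  invisible(x)
}

#' Deterministic approximately uniform unit directions
#'
#' Generalized spiral (golden-angle / Fibonacci) points on the unit sphere;
#' deterministic for a given `n`. Used both for synthetic acquisition
#' direction tables and as a quadrature grid.
#'
#' @param n Number of directions.
#' @return An `n` x 3 matrix of unit vectors.
#' @export
sphere_directions <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  phi <- golden * (seq_len(n) - 1)
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Antipodally symmetric direction set
#'
#' Half the points are spiral-distributed over the upper hemisphere and the
#' other half are their antipodes, so every direction appears with its
#' negative. Useful as an independent quadrature construction when
#' cross-checking spherical averages of even functions.
#'
#' @param n Total number of directions (must be even).
#' @return An `n` x 3 matrix of unit vectors closed under negation.
#' @export
antipodal_directions <- function(n) {
  stopifnot(n >= 2, n %% 2 == 0)
  m <- n / 2
  i <- seq_len(m) - 0.5
  z <- i / m           # upper hemisphere only
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  phi <- golden * (seq_len(m) - 1)
  upper <- cbind(r * cos(phi), r * sin(phi), z)
  rbind(upper, -upper)
}

#' Default two-shell acquisition scheme
#'
#' Mirrors a standard clinical DKI protocol: `n_b0` unweighted measurements
#' followed by the same `n_dirs` directions acquired at each nonzero
#' b-value (default shells at 1000 and 2000 s/mm^2 with 50 directions each).
#'
#' @param bvalues Nonzero shell b-values (s/mm^2).
#' @param n_dirs Directions per shell.
#' @param n_b0 Number of b = 0 measurements.
#' @return A [gradient_scheme()].
#' @export
default_scheme <- function(bvalues = c(1000, 2000), n_dirs = 50, n_b0 = 2) {
  dirs <- sphere_directions(n_dirs)
  b <- c(rep(0, n_b0), rep(bvalues, each = n_dirs))
  g <- rbind(
    matrix(0, n_b0, 3),
    do.call(rbind, replicate(length(bvalues), dirs, simplify = FALSE))
  )
  gradient_scheme(b, g)
}

#' Read a gradient table in the FSL bval/bvec dialect
#'
#' `bval` holds one whitespace-delimited row of b-values; `bvec` holds three
#' rows with the x, y and z direction components.
#'
#' @param bval_path,bvec_path Paths to the two text files.
#' @return A [gradient_scheme()].
#' @export
read_bval_bvec <- function(bval_path, bvec_path) {
  if (!file.exists(bval_path)) stop("bval file not found: ", bval_path)
  if (!file.exists(bvec_path)) stop("bvec file not found: ", bvec_path)
  b <- scan(bval_path, what = numeric(), quiet = TRUE)
  v <- scan(bvec_path, what = numeric(), quiet = TRUE)
  if (length(v) != 3 * length(b)) {
    stop(sprintf(
      "malformed gradient table: %s has %d b-values but %s has %d components (expected %d)",
      bval_path, length(b), bvec_path, length(v), 3 * length(b)
    ))
  }
  dirs <- t(matrix(v, nrow = 3, byrow = TRUE))
  gradient_scheme(b, dirs)
}

#' Write a gradient scheme as FSL-style bval/bvec files
#'
#' @param scheme A [gradient_scheme()].
#' @param bval_path,bvec_path Output paths.
#' @return Invisibly, the scheme.
#' @export
write_bval_bvec <- function(scheme, bval_path, bvec_path) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  writeLines(paste(format(scheme$bvalues, trim = TRUE), collapse = " "), bval_path)
  rows <- apply(t(scheme$directions), 1, function(r) {
    paste(format(r, trim = TRUE, digits = 10), collapse = " ")
  })
  writeLines(rows, bvec_path)
  invisible(scheme)
}
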