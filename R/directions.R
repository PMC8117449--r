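# Deterministic unit-vector designs on the sphere.
#
# Kurtosis metrics are defined as averages of the apparent (directional)
# kurtosis over the sphere; we evaluate them on a fixed spherical Fibonacci
# design rather than with analytic closed forms, and validate the design
# against a Monte-Carlo oracle in the test suite.

#' Spherical Fibonacci point set
#'
#' Generates `n` near-uniform unit vectors on the sphere using the spherical
#' Fibonacci lattice. The set is deterministic: the same `n` always yields the
#' same matrix, which keeps every kurtosis metric reproducible bit-for-bit.
#'
#' @param n Number of points.
#' @return An `n x 3` matrix of unit row vectors.
#' @export
#' @examples
#' dirs <- fibonacci_sphere(64)
#' range(rowSums(dirs^2)) # all 1
fibonacci_sphere <- function(n) {
  stopifnot(is_scalar_number(n), n >= 1)
  n <- as.integer(n)
  i <- seq_len(n) - 0.5
  phi <- (1 + sqrt(5)) / 2
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  theta <- 2 * pi * i / phi
  cbind(x = r * cos(theta), y = r * sin(theta), z = z)
}

#' Spherical product quadrature
#'
#' Gauss-Legendre nodes in the polar direction crossed with an equispaced
#' (trapezoid) grid in azimuth. For smooth integrands on the sphere -- the
#' apparent-kurtosis function is a rational function of the direction --
#' this rule converges spectrally, so the sphere average of the directional
#' kurtosis is effectively exact (and therefore rotation invariant to
#' numerical precision).
#'
#' @param n_polar Gauss-Legendre order; azimuth uses `2 * n_polar` points.
#' @return List with `dirs` (N x 3 unit rows) and normalized weights `w`
#'   (summing to 1).
#' @export
sphere_quadrature <- function(n_polar = 32L) {
  gl <- pracma::gaussLegendre(n_polar, -1, 1)
  n_phi <- 2L * n_polar
  phi <- 2 * pi * (seq_len(n_phi) - 1L) / n_phi
  z <- rep(gl$x, each = n_phi)
  wz <- rep(gl$w, each = n_phi)
  ph <- rep(phi, n_polar)
  r <- sqrt(pmax(0, 1 - z^2))
  list(
    dirs = cbind(r * cos(ph), r * sin(ph), z),
    w = wz / (2 * n_phi)
  )
}

# Fixed quadrature used for mean-kurtosis evaluation, with its quadratic and
# quartic design matrices precomputed (validated against a Monte-Carlo
# oracle in the test suite).
dki_mk_design <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      q <- sphere_quadrature(32L)
      cache <<- list(
        dirs = q$dirs, w = q$w,
        Q = quadratic_design(q$dirs), P = quartic_design(q$dirs)
      )
    }
    cache
  }
})

#' Unit directions perpendicular to a given axis
#'
#' Returns `n` directions equally spaced in angle in the plane orthogonal to
#' `axis`; used to average the apparent kurtosis radially.
#'
#' @param axis Length-3 vector (need not be unit).
#' @param n Number of in-plane directions.
#' @return An `n x 3` matrix of unit row vectors, each orthogonal to `axis`.
#' @export
perpendicular_directions <- function(axis, n = 64L) {
  stopifnot(length(axis) == 3L, sum(axis^2) > 0)
  a <- axis / sqrt(sum(axis^2))
  # pick a helper vector not parallel to the axis
  h <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- h - sum(h * a) * a
  u <- u / sqrt(sum(u^2))
  v <- c(
    a[2] * u[3] - a[3] * u[2],
    a[3] * u[1] - a[1] * u[3],
    a[1] * u[2] - a[2] * u[1]
  )
  ang <- 2 * pi * (seq_len(n) - 1L) / n
  cos(ang) %o% u + sin(ang) %o% v
}

#' Deterministic multi-shell acquisition table
#'
#' Builds the diffusion acquisition used throughout the package: one b = 0
#' measurement plus `n_dirs` gradient directions repeated on each nonzero
#' shell. Directions come from the spherical Fibonacci set restricted to a
#' hemisphere (antipodal directions are redundant for diffusion).
#'
#' @param bvals_shells Nonzero shell b-values in s/mm^2.
#' @param n_dirs Directions per shell.
#' @param n_b0 Number of b = 0 measurements.
#' @return List with `bvals` (length m vector, s/mm^2) and `bvecs`
#'   (`m x 3` unit rows; zero rows for b = 0).
#' @export
default_acquisition <- function(bvals_shells = c(1000, 2500), n_dirs = 30L,
                                n_b0 = 1L) {
  dirs <- fibonacci_sphere(2L * n_dirs)
  dirs <- dirs[dirs[, 3] >= 0, , drop = FALSE]
  dirs <- dirs[seq_len(n_dirs), , drop = FALSE]
  bvals <- c(rep(0, n_b0), rep(bvals_shells, each = n_dirs))
  bvecs <- rbind(
    matrix(0, n_b0, 3L),
    do.call(rbind, replicate(length(bvals_shells), dirs, simplify = FALSE))
  )
  list(bvals = bvals, bvecs = unname(bvecs))
}
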