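# Diffusion tensor (rank 2) and kurtosis tensor (rank 4) machinery.
#
# Conventions used throughout:
#   * b-values are handled internally in ms/um^2 (so b = 1000 s/mm^2 -> 1.0)
#     and diffusivities in um^2/ms; the unit conversion happens once, at the
#     API boundary (see build_design_matrix / read_dwi).
#   * D is a symmetric 3x3 tensor, stored compactly as the length-6 vector
#     (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz).
#   * W is the fully symmetric rank-4 kurtosis tensor, stored as its 15
#     unique elements in the fixed order given by `kt_elements()`.
#
# The signal model for direction n (unit) and b in ms/um^2 is
#   ln S(b, n) = ln S0 - b * D(n) + (b^2 / 6) * MD^2 * W(n)
# with D(n) = n' D n and W(n) = sum_ijkl n_i n_j n_k n_l W_ijkl, and the
# apparent (directional) kurtosis K(n) = MD^2 * W(n) / D(n)^2.

# unique element order for the compact D vector
DT_ELEMENTS <- c("xx", "yy", "zz", "xy", "xz", "yz")

#' Unique kurtosis-tensor elements and their multiplicities
#'
#' @return A data frame with columns `i, j, k, l` (1-based axis indices of a
#'   representative element), `name`, and `mult` (the number of index
#'   permutations the element stands for, used when contracting with
#'   direction monomials).
#' @export
kt_elements <- function() {
  idx <- rbind(
    c(1, 1, 1, 1), c(2, 2, 2, 2), c(3, 3, 3, 3),
    c(1, 1, 1, 2), c(1, 1, 1, 3), c(1, 2, 2, 2),
    c(2, 2, 2, 3), c(1, 3, 3, 3), c(2, 3, 3, 3),
    c(1, 1, 2, 2), c(1, 1, 3, 3), c(2, 2, 3, 3),
    c(1, 1, 2, 3), c(1, 2, 2, 3), c(1, 2, 3, 3)
  )
  mult <- apply(idx, 1L, function(r) {
    tab <- tabulate(r, 3L)
    factorial(4L) / prod(factorial(tab))
  })
  ax <- c("x", "y", "z")
  data.frame(
    i = idx[, 1], j = idx[, 2], k = idx[, 3], l = idx[, 4],
    name = apply(idx, 1L, function(r) paste0(ax[r], collapse = "")),
    mult = mult
  )
}

# design row-blocks -----------------------------------------------------

#' Quadratic direction monomials weighted for the compact D vector
#'
#' For unit directions `dirs` (n x 3), returns the n x 6 matrix `Q` such that
#' `Q %*% dvec = n' D n` per row.
#' @noRd
quadratic_design <- function(dirs) {
  dirs <- rbind(dirs)
  cbind(
    dirs[, 1]^2, dirs[, 2]^2, dirs[, 3]^2,
    2 * dirs[, 1] * dirs[, 2],
    2 * dirs[, 1] * dirs[, 3],
    2 * dirs[, 2] * dirs[, 3]
  )
}

#' Quartic direction monomials weighted for the compact W vector
#'
#' Returns the n x 15 matrix `P` such that `P %*% wvec = W(n)` per row.
#' @noRd
quartic_design <- function(dirs) {
  dirs <- rbind(dirs)
  kt <- kt_elements()
  out <- matrix(0, nrow(dirs), 15L)
  for (e in seq_len(15L)) {
    out[, e] <- kt$mult[e] *
      dirs[, kt$i[e]] * dirs[, kt$j[e]] * dirs[, kt$k[e]] * dirs[, kt$l[e]]
  }
  out
}

# compact <-> matrix representations ------------------------------------

#' @rdname compute_dt_metrics
#' @param dvec Length-6 compact diffusion tensor
#'   `(Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)`.
#' @export
dt_vec_to_mat <- function(dvec) {
  stopifnot(length(dvec) == 6L)
  matrix(c(
    dvec[1], dvec[4], dvec[5],
    dvec[4], dvec[2], dvec[6],
    dvec[5], dvec[6], dvec[3]
  ), 3L, 3L)
}

#' @rdname compute_dt_metrics
#' @param D Symmetric 3x3 diffusion tensor (um^2/ms).
#' @export
dt_mat_to_vec <- function(D) {
  stopifnot(is.matrix(D), all(dim(D) == 3L))
  if (max(abs(D - t(D))) > 1e-8 * max(1, max(abs(D)))) {
    abort_fetdki("diffusion tensor must be symmetric")
  }
  c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
}

#' Rotate a compact (D, W) tensor pair
#'
#' Applies the rotation `R` to both tensors; used by the rotation-invariance
#' tests and the anisotropic phantom.
#'
#' @param dvec,wvec Compact tensors (lengths 6 and 15).
#' @param R 3x3 rotation matrix.
#' @return List with rotated `dvec` and `wvec`.
#' @export
rotate_tensors <- function(dvec, wvec, R) {
  stopifnot(all(dim(R) == 3L))
  D <- R %*% dt_vec_to_mat(dvec) %*% t(R)
  kt <- kt_elements()
  # rebuild the full rank-4 tensor, rotate, and re-read unique elements
  Wfull <- array(0, c(3, 3, 3, 3))
  for (e in seq_len(15L)) {
    perms <- unique(perms4(c(kt$i[e], kt$j[e], kt$k[e], kt$l[e])))
    for (p in seq_len(nrow(perms))) {
      Wfull[perms[p, 1], perms[p, 2], perms[p, 3], perms[p, 4]] <- wvec[e]
    }
  }
  Wrot <- array(0, c(3, 3, 3, 3))
  for (a in 1:3) for (b in 1:3) for (cc in 1:3) for (d in 1:3) {
    s <- 0
    for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3) {
      s <- s + R[a, i] * R[b, j] * R[cc, k] * R[d, l] * Wfull[i, j, k, l]
    }
    Wrot[a, b, cc, d] <- s
  }
  wv <- numeric(15L)
  for (e in seq_len(15L)) {
    wv[e] <- Wrot[kt$i[e], kt$j[e], kt$k[e], kt$l[e]]
  }
  list(dvec = dt_mat_to_vec(D), wvec = wv)
}

# all permutations of a length-4 index vector
perms4 <- function(v) {
  p <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  p <- p[apply(p, 1, function(r) length(unique(r)) == 4L), ]
  m <- as.matrix(p)
  t(apply(m, 1L, function(r) v[r]))
}

# forward model ---------------------------------------------------------

#' Noise-free diffusion kurtosis signal
#'
#' Evaluates `S = S0 * exp(-b D(n) + b^2/6 * MD^2 * W(n))` for each
#' measurement.
#'
#' @param bvals b-values in s/mm^2.
#' @param bvecs Measurement x 3 matrix of unit directions (rows may be zero
#'   for b = 0).
#' @param S0 Non-diffusion-weighted signal.
#' @param dvec Compact diffusion tensor (um^2/ms).
#' @param wvec Compact kurtosis tensor (unitless). For an isotropic voxel
#'   with scalar kurtosis `K0`, use `isotropic_wvec(K0)`.
#' @return Numeric vector of signals.
#' @export
dki_signal <- function(bvals, bvecs, S0, dvec, wvec) {
  b <- bvals / 1000 # -> ms/um^2
  bvecs <- unname(rbind(bvecs))
  Dn <- drop(quadratic_design(bvecs) %*% dvec)
  Wn <- drop(quartic_design(bvecs) %*% wvec)
  md <- mean(dvec[1:3])
  S0 * exp(-b * Dn + (b^2 / 6) * md^2 * Wn)
}

#' Isotropic kurtosis tensor with scalar kurtosis K0
#'
#' Returns the compact W vector of the isotropic rank-4 tensor
#' `W_ijkl = (K0/3) (d_ij d_kl + d_ik d_jl + d_il d_jk)`, whose directional
#' contraction `W(n)` equals `K0` for every unit `n`. Combined with an
#' isotropic D this gives apparent kurtosis `K0` in all directions.
#'
#' @param K0 Scalar kurtosis.
#' @return Length-15 compact kurtosis tensor.
#' @export
isotropic_wvec <- function(K0) {
  kt <- kt_elements()
  vapply(seq_len(15L), function(e) {
    i <- kt$i[e]; j <- kt$j[e]; k <- kt$k[e]; l <- kt$l[e]
    d <- function(a, b) as.numeric(a == b)
    (K0 / 3) * (d(i, j) * d(k, l) + d(i, k) * d(j, l) + d(i, l) * d(j, k))
  }, numeric(1))
}

# tensor-derived metrics ------------------------------------------------

#' Diffusion-tensor metrics
#'
#' Computes mean, axial and radial diffusivity from the eigenvalues of the
#' diffusion tensor (sorted `lambda1 >= lambda2 >= lambda3`): `MD = mean`,
#' `AD = lambda1`, `RD = (lambda2 + lambda3)/2`.
#'
#' @return `compute_dt_metrics()` returns a list with `md`, `ad`, `rd`
#'   (um^2/ms), the sorted `eigenvalues` and `eigenvectors` (columns, matching
#'   the sorted order).
#' @export
#' @examples
#' compute_dt_metrics(diag(c(1.7, 0.4, 0.4)))
compute_dt_metrics <- function(D) {
  if (is.matrix(D)) {
    dvec <- dt_mat_to_vec(D) # validates symmetry
  } else {
    dvec <- D
  }
  e <- eigen(dt_vec_to_mat(dvec), symmetric = TRUE)
  lam <- e$values # eigen() returns decreasing order for symmetric input
  list(
    md = mean(lam), ad = lam[1], rd = (lam[2] + lam[3]) / 2,
    eigenvalues = lam, eigenvectors = e$vectors
  )
}

#' Apparent (directional) kurtosis
#'
#' `K(n) = MD^2 * W(n) / (n' D n)^2` for each row of `dirs`.
#'
#' @param dvec,wvec Compact tensors.
#' @param dirs n x 3 unit directions.
#' @param clip Optional length-2 range to which directional kurtosis is
#'   clipped (the package's post-hoc constraint projection); `NULL` for raw
#'   values.
#' @return Numeric vector of apparent kurtoses.
#' @export
apparent_kurtosis <- function(dvec, wvec, dirs, clip = NULL) {
  dirs <- rbind(dirs)
  Dn <- drop(quadratic_design(dirs) %*% dvec)
  if (any(Dn <= 0)) {
    abort_fetdki("apparent diffusivity non-positive along an evaluated direction")
  }
  Wn <- drop(quartic_design(dirs) %*% wvec)
  md <- mean(dvec[1:3])
  K <- md^2 * Wn / Dn^2
  if (!is.null(clip)) K <- pmin(pmax(K, clip[1]), clip[2])
  K
}

#' Kurtosis-tensor metrics
#'
#' Mean kurtosis (MK) is the spherical average of the apparent kurtosis,
#' evaluated on a fixed 2048-point Gauss-Legendre product quadrature (see
#' [sphere_quadrature()]); axial kurtosis (AK) is the apparent kurtosis
#' along the principal eigenvector of D; radial kurtosis (RK) is the average
#' over 64 equally spaced directions perpendicular to it.
#'
#' @param dvec Compact diffusion tensor (or symmetric 3x3 matrix).
#' @param wvec Compact kurtosis tensor.
#' @param clip Range to which directional kurtosis is clipped before
#'   averaging (default `c(0, 3)`, matching the histogram truncation
#'   downstream); `NULL` disables clipping.
#' @param n_radial Number of perpendicular directions for RK.
#' @return List with `mk`, `rk`, `ak` and the logical `clipped` (TRUE when
#'   any evaluated direction needed clipping).
#' @export
#' @examples
#' # isotropic voxel: MK = RK = AK = K0
#' compute_kt_metrics(c(1, 1, 1, 0, 0, 0), isotropic_wvec(0.6))
compute_kt_metrics <- function(dvec, wvec, clip = c(0, 3), n_radial = 64L) {
  if (is.matrix(dvec)) dvec <- dt_mat_to_vec(dvec)
  dt <- compute_dt_metrics(dvec)
  if (dt$eigenvalues[3] <= 0 || dt$md <= 0) {
    return(list(mk = NA_real_, rk = NA_real_, ak = NA_real_, clipped = NA))
  }
  des <- dki_mk_design()
  e1 <- dt$eigenvectors[, 1]
  dirs_rk <- perpendicular_directions(e1, n_radial)
  md <- dt$md
  Dn <- drop(des$Q %*% dvec)
  if (any(Dn <= 0)) {
    return(list(mk = NA_real_, rk = NA_real_, ak = NA_real_, clipped = NA))
  }
  k_mk <- md^2 * drop(des$P %*% wvec) / Dn^2
  k_rk <- apparent_kurtosis(dvec, wvec, dirs_rk)
  k_ak <- apparent_kurtosis(dvec, wvec, rbind(e1))
  clipped <- FALSE
  if (!is.null(clip)) {
    allk <- c(k_mk, k_rk, k_ak)
    clipped <- any(allk < clip[1] | allk > clip[2])
    k_mk <- pmin(pmax(k_mk, clip[1]), clip[2])
    k_rk <- pmin(pmax(k_rk, clip[1]), clip[2])
    k_ak <- pmin(pmax(k_ak, clip[1]), clip[2])
  }
  list(
    mk = sum(des$w * k_mk), rk = mean(k_rk), ak = mean(k_ak),
    clipped = clipped
  )
}
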