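# Voxelwise and volumewise diffusion kurtosis estimation.

#' Multi-shell diffusion dataset
#'
#' Bundles the 4D signal with its acquisition table and validates the
#' invariants the kurtosis model needs: unit gradient directions, at least
#' two nonzero shells and enough non-collinear directions for the
#' 21-parameter model + S0 (checked through the numerical rank of the design
#' matrix).
#'
#' @param signal 4D array `(x, y, z, measurement)`, arbitrary signal units.
#' @param bvals b-values in s/mm^2, one per measurement.
#' @param bvecs Measurement x 3 matrix (or 3 x measurement, auto-detected)
#'   of unit gradient directions; zero rows for b = 0.
#' @param voxel_size Voxel edge lengths in mm (length 1 or 3).
#' @param brain_mask Logical 3D array; default all-TRUE.
#' @return An object of class `fetdki_dwi`.
#' @export
dwi_dataset <- function(signal, bvals, bvecs, voxel_size = 2,
                        brain_mask = NULL) {
  stopifnot(length(dim(signal)) == 4L)
  m <- dim(signal)[4]
  bvecs <- as.matrix(bvecs)
  if (ncol(bvecs) != 3L && nrow(bvecs) == 3L) bvecs <- t(bvecs) # FSL 3-row
  if (nrow(bvecs) != m || length(bvals) != m) {
    abort_fetdki("signal has %d measurements but bvals/bvecs describe %d/%d",
                 m, length(bvals), nrow(bvecs))
  }
  if (is.null(brain_mask)) {
    brain_mask <- array(TRUE, dim(signal)[1:3])
  }
  stopifnot(identical(dim(brain_mask), dim(signal)[1:3]))
  # validates unit norms, shell count and direction sufficiency
  X <- build_design_matrix(bvals, bvecs)
  structure(
    list(
      signal = signal, bvals = as.numeric(bvals), bvecs = unname(bvecs),
      voxel_size = rep_len(voxel_size, 3L),
      brain_mask = brain_mask, design = X
    ),
    class = "fetdki_dwi"
  )
}

#' @export
print.fetdki_dwi <- function(x, ...) {
  d <- dim(x$signal)
  shells <- sort(unique(round(x$bvals)))
  cat(sprintf(
    "<fetdki_dwi> %dx%dx%d grid, %d measurements (b = %s s/mm^2), %d mask voxels\n",
    d[1], d[2], d[3], d[4], paste(shells, collapse = "/"),
    sum(x$brain_mask)
  ))
  invisible(x)
}

#' Fit the kurtosis model in a single voxel
#'
#' Fits `ln S = ln S0 - b D(n) + b^2/6 V(n)` (with `V = MD^2 W`). A
#' weighted linear fit on the log signal (weights `S^2`, the usual
#' variance-stabilizing choice) provides the initialization; `method =
#' "nlls"` then refines it by nonlinear least squares on the exponentiated
#' model (Levenberg-Marquardt, analytic Jacobian, relative tolerance 1e-8,
#' at most 100 iterations). The diffusion tensor is projected to the
#' positive-semidefinite cone by eigenvalue clipping; directional kurtosis
#' is clipped to [0, 3] when metrics are computed.
#'
#' @param signal_row Positive signal vector, one value per design row.
#' @param design Design matrix from [build_design_matrix()].
#' @param method `"nlls"` (default) or `"wls"` (initialization only).
#' @param sigma Known noise sigma of the (bias-corrected) signal. When
#'   supplied, the log-linearized WLS stage includes the second-order
#'   delta-method debiasing term `+ sigma^2 / (2 S^2)` on the log signal
#'   for measurements with local SNR >= 3 (below that the expansion is
#'   invalid and the term is dropped); this removes the log-noise asymmetry
#'   bias of the weighted linear estimator.
#' @return List of class `fetdki_voxel_fit`: `S0`, `dvec`, `D` (3x3), `wvec`
#'   (compact W = V / MD^2), `md`, `fit_residual` (root-mean-square relative
#'   residual), `converged`, `degenerate` (TRUE when MD ~ 0 so W is
#'   unidentifiable).
#' @export
fit_dki_voxel <- function(signal_row, design, method = c("nlls", "wls"),
                          sigma = NULL) {
  method <- match.arg(method)
  if (any(!is.finite(signal_row)) || any(signal_row <= 0)) {
    abort_fetdki("fit_dki_voxel requires finite positive signals")
  }
  if (length(signal_row) != nrow(design)) {
    abort_fetdki("signal length %d does not match design rows %d",
                 length(signal_row), nrow(design))
  }
  y <- log(signal_row)
  if (!is.null(sigma) && sigma > 0) {
    y <- y + ifelse(signal_row >= 3 * sigma,
                    sigma^2 / (2 * signal_row^2), 0)
  }
  w <- signal_row^2
  wls <- stats::lm.wfit(design, y, w)
  beta <- wls$coefficients
  converged <- TRUE
  if (method == "nlls") {
    fn <- function(par) signal_row - exp(drop(design %*% par))
    jac <- function(par) -exp(drop(design %*% par)) * design
    res <- tryCatch(
      minpack.lm::nls.lm(
        par = beta, fn = fn, jac = jac,
        control = minpack.lm::nls.lm.control(
          maxiter = 100L, ftol = 1e-8, ptol = 1e-8
        )
      ),
      error = function(e) NULL
    )
    if (is.null(res) || res$info %in% c(0L, 5L, 9L)) {
      converged <- FALSE # keep WLS estimate, flag the voxel
    } else {
      beta <- res$par
    }
  }
  S0 <- exp(beta[1])
  dvec <- beta[2:7]
  vvec <- beta[8:22]
  # PSD projection of D
  e <- eigen(dt_vec_to_mat(dvec), symmetric = TRUE)
  if (any(e$values < 0)) {
    lam <- pmax(e$values, 0)
    dvec <- dt_mat_to_vec(e$vectors %*% diag(lam) %*% t(e$vectors))
  }
  md <- mean(dvec[1:3])
  degenerate <- md < 1e-6
  wvec <- if (degenerate) rep(0, 15L) else vvec / md^2
  shat <- exp(drop(design %*% beta))
  structure(
    list(
      S0 = unname(S0), dvec = unname(dvec), D = dt_vec_to_mat(dvec),
      wvec = unname(wvec), md = md,
      fit_residual = sqrt(mean((signal_row - shat)^2)) / S0,
      converged = converged, degenerate = degenerate
    ),
    class = "fetdki_voxel_fit"
  )
}

#' Fit the kurtosis model over a volume
#'
#' Applies (optionally) Rician bias correction and then voxelwise fitting
#' inside the brain mask, producing the six metric maps MD/RD/AD (um^2/ms)
#' and MK/RK/AK (unitless).
#'
#' Measurements floored to zero by bias correction are dropped from the
#' affected voxel's fit; a voxel is excluded (and counted in the report)
#' only when more than `max_floored_frac` of its measurements are floored
#' or its optimizer fails, so low shell-SNR data do not silently select on
#' noise.
#'
#' @param dwi A [dwi_dataset()].
#' @param method Passed to [fit_dki_voxel()].
#' @param rician_correction Apply power-images bias correction first?
#' @param sigma Noise sigma; if `NULL` and correction is requested it is
#'   estimated from `background_mask`.
#' @param background_mask Logical 3D array of signal-free voxels used for
#'   sigma estimation (required when `sigma` is NULL and correction is on).
#' @param kurtosis_clip Directional-kurtosis clipping range (see
#'   [compute_kt_metrics()]).
#' @param max_floored_frac Maximum fraction of floored measurements a voxel
#'   may lose before it is excluded outright.
#' @return Object of class `fetdki_maps`: arrays `md`, `rd`, `ad`, `mk`,
#'   `rk`, `ak` (NA outside the converged mask), logical `mask`, and a
#'   `report` list (voxel counts, sigma used).
#' @export
fit_dki_volume <- function(dwi, method = c("nlls", "wls"),
                           rician_correction = TRUE, sigma = NULL,
                           background_mask = NULL, kurtosis_clip = c(0, 3),
                           max_floored_frac = 0.25) {
  stopifnot(inherits(dwi, "fetdki_dwi"))
  method <- match.arg(method)
  sig <- dwi$signal
  n_floored <- 0L
  if (rician_correction) {
    if (is.null(sigma)) {
      if (is.null(background_mask)) {
        abort_fetdki("supply sigma or background_mask for Rician correction")
      }
      bg4 <- array(background_mask, dim(sig)) # recycle mask over measurements
      sigma <- estimate_background_sigma(sig, bg4)
    }
    corr <- rician_bias_correct(sig, sigma)
    floored <- attr(corr, "floored")
    sig <- corr
  } else {
    sigma <- NA_real_
    floored <- array(FALSE, dim(sig))
  }
  dims <- dim(sig)[1:3]
  empty <- array(NA_real_, dims)
  maps <- list(md = empty, rd = empty, ad = empty,
               mk = empty, rk = empty, ak = empty)
  fitted_mask <- array(FALSE, dims)
  idx <- which(dwi$brain_mask)
  if (!length(idx)) {
    warn_fetdki("brain mask is empty; returning empty maps")
  }
  n_meas <- dim(sig)[4]
  n_vox <- prod(dims)
  sig_mat <- matrix(sig, nrow = n_vox, ncol = n_meas)
  floored_any <- matrix(floored, nrow = n_vox, ncol = n_meas)
  n_nonconv <- 0L; n_degen <- 0L; n_part <- 0L
  n_keep_min <- ceiling((1 - max_floored_frac) * n_meas)
  for (v in idx) {
    row <- sig_mat[v, ]
    ok <- !floored_any[v, ] & row > 0
    if (sum(ok) < max(n_keep_min, 23L)) {
      n_floored <- n_floored + 1L
      next
    }
    if (!all(ok)) n_part <- n_part + 1L
    fit <- tryCatch(
      fit_dki_voxel(row[ok], dwi$design[ok, , drop = FALSE],
                    method = method,
                    sigma = if (rician_correction) sigma else NULL),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$converged) {
      n_nonconv <- n_nonconv + 1L
      next
    }
    dtm <- compute_dt_metrics(fit$dvec)
    maps$md[v] <- dtm$md; maps$ad[v] <- dtm$ad; maps$rd[v] <- dtm$rd
    if (fit$degenerate) {
      n_degen <- n_degen + 1L
      maps$mk[v] <- NA_real_; maps$rk[v] <- NA_real_; maps$ak[v] <- NA_real_
    } else {
      ktm <- compute_kt_metrics(fit$dvec, fit$wvec, clip = kurtosis_clip)
      maps$mk[v] <- ktm$mk; maps$rk[v] <- ktm$rk; maps$ak[v] <- ktm$ak
    }
    fitted_mask[v] <- TRUE
  }
  structure(
    list(
      md = maps$md, rd = maps$rd, ad = maps$ad,
      mk = maps$mk, rk = maps$rk, ak = maps$ak,
      mask = fitted_mask, voxel_size = dwi$voxel_size,
      report = list(
        n_mask = length(idx), n_fitted = sum(fitted_mask),
        n_floored = n_floored, n_partial = n_part,
        n_nonconverged = n_nonconv,
        n_degenerate = n_degen, sigma = sigma, method = method,
        rician_correction = rician_correction
      )
    ),
    class = "fetdki_maps"
  )
}

#' @export
print.fetdki_maps <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "<fetdki_maps> %s grid; %d/%d voxels fitted (%d floored, %d non-converged, %d degenerate)\n",
    paste(dim(x$md), collapse = "x"),
    r$n_fitted, r$n_mask, r$n_floored, r$n_nonconverged, r$n_degenerate
  ))
  invisible(x)
}
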