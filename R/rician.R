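# Rician noise handling: background sigma estimation and power-images
# bias correction.

#' Estimate background noise sigma from magnitude data
#'
#' In signal-free background, magnitude-MRI voxels are Rayleigh distributed
#' with scale equal to the standard deviation `sigma` of the underlying
#' complex Gaussian noise. The maximum-likelihood Rayleigh estimate is
#' `sigma_hat = sqrt(mean(M^2) / 2)`.
#'
#' @param signal_volume Numeric array (any shape) of magnitude values.
#' @param background_mask Logical array of the same shape selecting
#'   signal-free voxels (must not intersect the brain).
#' @return Estimated sigma (signal units).
#' @export
estimate_background_sigma <- function(signal_volume, background_mask) {
  if (!any(background_mask)) abort_fetdki("background mask is empty")
  m <- signal_volume[background_mask]
  if (all(m == 0)) {
    abort_fetdki("background is identically zero; cannot estimate noise")
  }
  sigma <- sqrt(mean(m^2) / 2)
  if (var(m) < .Machine$double.eps * max(1, mean(m)^2)) {
    warn_fetdki("background variance is near zero; sigma estimate %.3g may be degenerate",
                sigma)
  }
  sigma
}

#' Power-images Rician bias correction
#'
#' Removes the positive noise bias of magnitude MRI via the power-images
#' estimator of the noise-free amplitude, `A_hat = sqrt(max(M^2 - 2 sigma^2,
#' 0))`. Voxels floored to zero are flagged so downstream fitting can exclude
#' them.
#'
#' @param signal Numeric vector/array of magnitudes.
#' @param sigma Noise standard deviation (>= 0).
#' @return Corrected signal with attribute `floored` (logical, same shape)
#'   marking voxels where `M^2 < 2 sigma^2`.
#' @export
#' @examples
#' rician_bias_correct(3, 1) # sqrt(7)
rician_bias_correct <- function(signal, sigma) {
  if (!is_scalar_number(sigma) || sigma < 0) {
    abort_fetdki("sigma must be a single non-negative number")
  }
  p <- signal^2 - 2 * sigma^2
  floored <- p < 0
  out <- sqrt(pmax(p, 0))
  attributes(out) <- attributes(signal)
  attr(out, "floored") <- floored
  out
}
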