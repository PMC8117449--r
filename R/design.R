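# Linearized DKI design matrix.

#' DKI design matrix
#'
#' Builds the measurement x 22 matrix `X` mapping the parameter vector
#' `theta = (ln S0, D_xx..D_yz, V_1..V_15)` to the log-signal,
#' `ln S = X theta`, where `V = MD^2 * W` is the standard reparameterization
#' in which the quartic term carries its own coefficients (so the model is
#' linear in `theta`). b-values are converted internally to ms/um^2, so the
#' fitted D is in um^2/ms and V is unitless.
#'
#' @param bvals b-values in s/mm^2, one per measurement.
#' @param bvecs Measurement x 3 matrix of gradient directions (unit rows;
#'   zero rows allowed only for b = 0).
#' @param check_rank If TRUE (default), error when the design has numerical
#'   rank < 22 (too few non-collinear directions/shells for the 21-parameter
#'   model + S0).
#' @return The design matrix with column names
#'   `c("lnS0", "D.xx", ..., "V.xxxx", ...)` and attribute `b_ms`.
#' @export
#' @examples
#' acq <- default_acquisition()
#' X <- build_design_matrix(acq$bvals, acq$bvecs)
#' qr(X)$rank # 22
build_design_matrix <- function(bvals, bvecs, check_rank = TRUE) {
  bvecs <- rbind(bvecs)
  if (length(bvals) != nrow(bvecs)) {
    abort_fetdki("bvals (%d) and bvecs rows (%d) disagree",
                 length(bvals), nrow(bvecs))
  }
  nrm <- sqrt(rowSums(bvecs^2))
  bad <- which(bvals > 0 & abs(nrm - 1) > 1e-3)
  if (length(bad)) {
    abort_fetdki("non-unit gradient direction(s) at measurement(s) %s",
                 paste(head(bad, 5L), collapse = ", "))
  }
  b <- bvals / 1000 # ms/um^2
  Q <- quadratic_design(bvecs)
  P <- quartic_design(bvecs)
  X <- cbind(1, -b * Q, (b^2 / 6) * P)
  colnames(X) <- c(
    "lnS0", paste0("D.", DT_ELEMENTS), paste0("V.", kt_elements()$name)
  )
  if (check_rank) {
    r <- qr(X)$rank
    if (r < 22L) {
      abort_fetdki(paste0(
        "design matrix rank %d < 22: the acquisition cannot identify the ",
        "kurtosis model (need >= 2 nonzero shells and >= 15 non-collinear ",
        "directions plus b = 0)"), r)
    }
  }
  attr(X, "b_ms") <- b
  X
}
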