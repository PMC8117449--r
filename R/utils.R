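# internal helpers shared across modules

#' Stop with a formatted message
#' @noRd
abort_fetdki <- function(...) stop(sprintf(...), call. = FALSE)

#' Warn with a formatted message
#' @noRd
warn_fetdki <- function(...) warning(sprintf(...), call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Run an expression under a local RNG seed, leaving the global RNG untouched
#' when `seed` is NULL.
#' @noRd
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is_scalar_number(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Voxel-center coordinates (mm) for a grid, 0-based indices times voxel size.
#' @noRd
voxel_grid_mm <- function(dim3, voxel_size) {
  voxel_size <- rep_len(voxel_size, 3L)
  list(
    x = (seq_len(dim3[1]) - 1L) * voxel_size[1],
    y = (seq_len(dim3[2]) - 1L) * voxel_size[2],
    z = (seq_len(dim3[3]) - 1L) * voxel_size[3]
  )
}

#' Squared distance (mm^2) of every voxel center from a center given in voxel
#' coordinates (0-based).
#' @noRd
dist2_from_center <- function(dim3, voxel_size, center_vox) {
  voxel_size <- rep_len(voxel_size, 3L)
  dx <- ((seq_len(dim3[1]) - 1L) - center_vox[1]) * voxel_size[1]
  dy <- ((seq_len(dim3[2]) - 1L) - center_vox[2]) * voxel_size[2]
  dz <- ((seq_len(dim3[3]) - 1L) - center_vox[3]) * voxel_size[3]
  d2 <- outer(outer(dx^2, dy^2, `+`), dz^2, `+`)
  d2
}
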