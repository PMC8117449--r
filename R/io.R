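# File interfaces: NIfTI volumes, FSL-style bval/bvec tables, frame-timing
# JSON sidecars, cohort CSV.

# drop RNifti header attributes, leaving a plain numeric array
as_plain_array <- function(im) {
  arr <- as.array(im)
  attributes(arr) <- list(dim = dim(arr))
  arr
}

as_nifti_vol <- function(arr, voxel_size) {
  im <- RNifti::asNifti(arr)
  nd <- length(dim(arr))
  RNifti::pixdim(im) <- c(rep_len(voxel_size, 3L), rep(1, nd - 3L))
  im
}

#' Write a diffusion dataset to NIfTI + bval/bvec
#'
#' @param dwi A [dwi_dataset()].
#' @param prefix Path prefix; writes `<prefix>.nii.gz`, `<prefix>.bval`,
#'   `<prefix>.bvec` (FSL dialect: one whitespace-separated row of b-values,
#'   three rows of direction components) and `<prefix>_mask.nii.gz`.
#' @return Invisibly, the paths written.
#' @export
write_dwi <- function(dwi, prefix) {
  stopifnot(inherits(dwi, "fetdki_dwi"))
  paths <- c(
    nii = paste0(prefix, ".nii.gz"),
    bval = paste0(prefix, ".bval"),
    bvec = paste0(prefix, ".bvec"),
    mask = paste0(prefix, "_mask.nii.gz")
  )
  RNifti::writeNifti(as_nifti_vol(dwi$signal, dwi$voxel_size), paths["nii"])
  writeLines(paste(format(dwi$bvals, scientific = FALSE), collapse = " "),
             paths["bval"])
  writeLines(apply(t(dwi$bvecs), 1L, paste, collapse = " "), paths["bvec"])
  RNifti::writeNifti(as_nifti_vol(dwi$brain_mask * 1L, dwi$voxel_size),
                     paths["mask"])
  invisible(paths)
}

read_numeric_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  if (length(unique(lengths(rows))) != 1L) {
    abort_fetdki("%s: ragged rows", path)
  }
  do.call(rbind, rows)
}

#' Read a diffusion dataset from NIfTI + bval/bvec
#'
#' Accepts both FSL bvec dialects (3 rows x m columns, or m rows x 3
#' columns) and normalizes to the internal measurement-by-3 layout.
#'
#' @param nii_path 4D NIfTI path.
#' @param bval_path,bvec_path Acquisition table paths.
#' @param mask_path Optional brain-mask NIfTI.
#' @param voxel_size Override voxel size; default read from the NIfTI
#'   header.
#' @return A [dwi_dataset()].
#' @export
read_dwi <- function(nii_path, bval_path, bvec_path, mask_path = NULL,
                     voxel_size = NULL) {
  im <- RNifti::readNifti(nii_path)
  arr <- as_plain_array(im)
  if (length(dim(arr)) != 4L) {
    abort_fetdki("%s: expected a 4D volume, got %dD", nii_path,
                 length(dim(arr)))
  }
  m <- dim(arr)[4]
  bvals <- drop(read_numeric_table(bval_path))
  if (is.matrix(bvals)) bvals <- as.numeric(t(bvals))
  bvecs <- read_numeric_table(bvec_path)
  if (nrow(bvecs) == 3L && ncol(bvecs) != 3L) bvecs <- t(bvecs)
  if (length(bvals) != m || nrow(bvecs) != m) {
    abort_fetdki(
      "%s: %d volumes but %d b-values (%s) / %d directions (%s)",
      nii_path, m, length(bvals), bval_path, nrow(bvecs), bvec_path)
  }
  if (is.null(voxel_size)) {
    voxel_size <- RNifti::pixdim(im)[1:3]
  }
  mask <- if (!is.null(mask_path)) {
    as_plain_array(RNifti::readNifti(mask_path)) > 0
  } else NULL
  dwi_dataset(arr, bvals, bvecs, voxel_size, mask)
}

#' Write a dynamic PET study to NIfTI + frame-timing JSON
#'
#' @param pet A [pet_study()].
#' @param prefix Writes `<prefix>.nii.gz` and `<prefix>_frames.json`
#'   (array of `{start_min, end_min}` objects).
#' @return Invisibly, the paths written.
#' @export
write_pet <- function(pet, prefix) {
  stopifnot(inherits(pet, "fetdki_pet"))
  paths <- c(nii = paste0(prefix, ".nii.gz"),
             timing = paste0(prefix, "_frames.json"))
  RNifti::writeNifti(as_nifti_vol(pet$frames, pet$voxel_size), paths["nii"])
  jsonlite::write_json(
    data.frame(start_min = pet$frame_start, end_min = pet$frame_end),
    paths["timing"], digits = NA
  )
  invisible(paths)
}

#' Read a dynamic PET study from NIfTI + frame-timing JSON
#'
#' @param nii_path 4D NIfTI path.
#' @param timing_path JSON sidecar with `start_min`/`end_min` per frame.
#' @param voxel_size Override; default from the header.
#' @return A [pet_study()].
#' @export
read_pet <- function(nii_path, timing_path, voxel_size = NULL) {
  im <- RNifti::readNifti(nii_path)
  arr <- as_plain_array(im)
  timing <- jsonlite::fromJSON(timing_path)
  if (is.null(voxel_size)) voxel_size <- RNifti::pixdim(im)[1:3]
  pet_study(arr, timing$start_min, timing$end_min, voxel_size)
}

#' Write metric maps to one NIfTI per metric plus a JSON fit report
#'
#' @param maps A `fetdki_maps` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_maps <- function(maps, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  metrics <- c("md", "rd", "ad", "mk", "rk", "ak")
  paths <- character(0)
  for (m in metrics) {
    p <- file.path(dir, paste0(m, ".nii.gz"))
    RNifti::writeNifti(as_nifti_vol(maps[[m]], maps$voxel_size), p)
    paths[m] <- p
  }
  p <- file.path(dir, "mask.nii.gz")
  RNifti::writeNifti(as_nifti_vol(maps$mask * 1L, maps$voxel_size), p)
  paths["mask"] <- p
  rp <- file.path(dir, "fit_report.json")
  jsonlite::write_json(maps$report, rp, auto_unbox = TRUE, digits = NA)
  paths["report"] <- rp
  invisible(paths)
}

#' Read metric maps written by [write_maps()]
#' @param dir Directory containing `md.nii.gz` ... and `fit_report.json`.
#' @return A `fetdki_maps` object.
#' @export
read_maps <- function(dir) {
  metrics <- c("md", "rd", "ad", "mk", "rk", "ak")
  out <- list()
  vs <- NULL
  for (m in metrics) {
    im <- RNifti::readNifti(file.path(dir, paste0(m, ".nii.gz")))
    out[[m]] <- as_plain_array(im)
    vs <- RNifti::pixdim(im)[1:3]
  }
  out$mask <- as_plain_array(
    RNifti::readNifti(file.path(dir, "mask.nii.gz"))) > 0
  out$voxel_size <- vs
  rp <- file.path(dir, "fit_report.json")
  out$report <- if (file.exists(rp)) jsonlite::fromJSON(rp) else NULL
  structure(out, class = "fetdki_maps")
}

#' Write / read a cohort feature table
#'
#' CSV with header `patient_id,group,<feature...>`.
#' @param cohort Tibble.
#' @param path CSV path.
#' @return `read_cohort()` returns a tibble; `write_cohort()` its path,
#'   invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
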