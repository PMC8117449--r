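# Static and dynamic FET PET analytics: summed images, tumor-to-brain
# ratios, PET-guided lesion segmentation, and time-activity-curve metrics.

#' Default 50-minute dynamic frame schedule
#'
#' 16 frames: 5 x 1 min, 5 x 3 min, 6 x 5 min.
#' @return Tibble with `start_min`, `end_min`, `mid_min`.
#' @export
default_frame_schedule <- function() {
  dur <- c(rep(1, 5), rep(3, 5), rep(5, 6))
  end <- cumsum(dur)
  tibble(start_min = end - dur, end_min = end, mid_min = end - dur / 2)
}

#' Dynamic PET study
#'
#' @param frames 4D array `(x, y, z, frame)` in SUV (or any activity unit;
#'   TBR quantities are scale invariant).
#' @param frame_start,frame_end Frame start/end times in minutes
#'   post-injection; must be contiguous, non-overlapping and span 0-50 min.
#' @param voxel_size Voxel edge lengths in mm (length 1 or 3).
#' @return Object of class `fetdki_pet`.
#' @export
pet_study <- function(frames, frame_start, frame_end, voxel_size = 2) {
  stopifnot(length(dim(frames)) == 4L)
  nf <- dim(frames)[4]
  if (length(frame_start) != nf || length(frame_end) != nf) {
    abort_fetdki("frame timing length does not match %d frames", nf)
  }
  if (any(frame_end <= frame_start)) abort_fetdki("non-positive frame durations")
  if (any(abs(frame_start[-1] - frame_end[-nf]) > 1e-9)) {
    abort_fetdki("frames must be contiguous and non-overlapping")
  }
  if (abs(frame_start[1]) > 1e-9 || abs(frame_end[nf] - 50) > 1e-9) {
    abort_fetdki("frame schedule must span 0-50 min (got %.3g-%.3g)",
                 frame_start[1], frame_end[nf])
  }
  structure(
    list(frames = frames, frame_start = as.numeric(frame_start),
         frame_end = as.numeric(frame_end),
         frame_mid = (as.numeric(frame_start) + as.numeric(frame_end)) / 2,
         voxel_size = rep_len(voxel_size, 3L)),
    class = "fetdki_pet"
  )
}

#' @export
print.fetdki_pet <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<fetdki_pet> %dx%dx%d grid, %d frames spanning %g-%g min\n",
              d[1], d[2], d[3], d[4], x$frame_start[1], max(x$frame_end)))
  invisible(x)
}

#' Time-weighted summed image over an uptake window
#'
#' Duration-weighted mean of all frames overlapping the window; frames
#' partially inside contribute proportionally to their overlap.
#'
#' @param pet A [pet_study()].
#' @param window Length-2 minutes vector, default the standard 20-40 min
#'   uptake window.
#' @return 3D volume.
#' @export
sum_frames <- function(pet, window = c(20, 40)) {
  stopifnot(inherits(pet, "fetdki_pet"), length(window) == 2L,
            window[1] < window[2])
  if (window[1] < min(pet$frame_start) - 1e-9 ||
      window[2] > max(pet$frame_end) + 1e-9) {
    abort_fetdki("window [%g, %g] outside acquisition [%g, %g]",
                 window[1], window[2], min(pet$frame_start),
                 max(pet$frame_end))
  }
  ov <- pmax(0, pmin(pet$frame_end, window[2]) -
               pmax(pet$frame_start, window[1]))
  w <- ov / sum(ov)
  dims <- dim(pet$frames)[1:3]
  out <- array(0, dims)
  for (f in which(w > 0)) out <- out + w[f] * pet$frames[, , , f]
  out
}

#' Mean SUV of a healthy-brain reference region
#'
#' @param summed 3D summed image.
#' @param reference_mask Logical 3D array (nonempty).
#' @return Scalar background SUV.
#' @export
compute_background <- function(summed, reference_mask) {
  if (!any(reference_mask)) abort_fetdki("reference mask is empty")
  mean(summed[reference_mask])
}

# connectivity ----------------------------------------------------------

# seeded flood fill over a logical array; `neighbors` is an offset matrix
flood_fill <- function(mask, seed_idx, neighbors) {
  dims <- dim(mask)
  out <- array(FALSE, dims)
  if (!mask[matrix(seed_idx, 1L)]) return(out)
  queue <- matrix(seed_idx, 1L)
  out[matrix(seed_idx, 1L)] <- TRUE
  nd <- length(dims)
  while (nrow(queue)) {
    cur <- queue[nrow(queue), , drop = FALSE]
    queue <- queue[-nrow(queue), , drop = FALSE]
    cand <- sweep(neighbors, 2L, cur[1, ], `+`)
    ok <- rep(TRUE, nrow(cand))
    for (d in seq_len(nd)) {
      ok <- ok & cand[, d] >= 1L & cand[, d] <= dims[d]
    }
    cand <- cand[ok, , drop = FALSE]
    if (!nrow(cand)) next
    keep <- mask[cand] & !out[cand]
    if (any(keep)) {
      nxt <- cand[keep, , drop = FALSE]
      out[nxt] <- TRUE
      queue <- rbind(queue, nxt)
    }
  }
  out
}

neighbors_26 <- function() {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  unname(g[rowSums(abs(g)) > 0, , drop = FALSE])
}

neighbors_8 <- function() {
  g <- as.matrix(expand.grid(-1:1, -1:1))
  unname(g[rowSums(abs(g)) > 0, , drop = FALSE])
}

#' PET-guided 3D lesion segmentation
#'
#' Returns the 26-connected component of `{tbr_map >= threshold}` containing
#' the seed voxel: the semi-automatic TBR-threshold lesion definition.
#'
#' @param tbr_map 3D tumor-to-brain-ratio map.
#' @param threshold TBR threshold (default 1.6).
#' @param seed_point Integer voxel index (1-based, length 3) with
#'   `tbr >= threshold`.
#' @return Logical 3D mask.
#' @export
segment_roi3d <- function(tbr_map, threshold = 1.6, seed_point) {
  stopifnot(length(dim(tbr_map)) == 3L, length(seed_point) == 3L)
  seed_point <- as.integer(seed_point)
  supra <- tbr_map >= threshold
  if (!supra[matrix(seed_point, 1L)]) {
    near <- which(supra, arr.ind = TRUE)
    hint <- if (nrow(near)) {
      d2 <- colSums((t(near) - seed_point)^2)
      nearest <- near[order(d2)[seq_len(min(3L, nrow(near)))], , drop = FALSE]
      paste(apply(nearest, 1L, paste, collapse = ","), collapse = "; ")
    } else "none in volume"
    abort_fetdki(
      "seed voxel (%s) has TBR %.3g < threshold %.3g; nearest supra-threshold voxels: %s",
      paste(seed_point, collapse = ","), tbr_map[matrix(seed_point, 1L)],
      threshold, hint)
  }
  flood_fill(supra, seed_point, neighbors_26())
}

#' Mean TBR by 2D auto-contouring
#'
#' Mean TBR over the 8-connected supra-threshold region in the axial slice
#' containing the global TBR maximum (or a caller-chosen slice), the 2D
#' auto-contour definition of mean lesion uptake.
#'
#' @param tbr_map 3D TBR map.
#' @param threshold TBR threshold (default 1.6).
#' @param slice Axial (third-axis) slice index; default the slice of the
#'   global maximum.
#' @return Scalar `tbr_mean`, with attributes `slice` and `n_voxels`.
#' @export
tbr_mean_autocontour <- function(tbr_map, threshold = 1.6, slice = NULL) {
  stopifnot(length(dim(tbr_map)) == 3L)
  if (is.null(slice)) {
    slice <- which(tbr_map == max(tbr_map), arr.ind = TRUE)[1L, 3L]
  }
  sl <- tbr_map[, , slice]
  supra <- sl >= threshold
  if (!any(supra)) {
    abort_fetdki("no supra-threshold voxels in slice %d", slice)
  }
  seed2d <- which(sl == max(sl), arr.ind = TRUE)[1L, ]
  region <- flood_fill(supra, as.integer(seed2d), neighbors_8())
  out <- mean(sl[region])
  attr(out, "slice") <- as.integer(slice)
  attr(out, "n_voxels") <- sum(region)
  out
}

# in-plane circular ROI membership (voxel-center inclusion)
circle_mask_2d <- function(dims2, center, radius_mm, voxel_size2) {
  dx <- (seq_len(dims2[1]) - center[1]) * voxel_size2[1]
  dy <- (seq_len(dims2[2]) - center[2]) * voxel_size2[2]
  outer(dx^2, dy^2, `+`) <= radius_mm^2
}

#' Maximum TBR from a circular ROI at the uptake maximum
#'
#' Places a 2D circular ROI of the given diameter on the axial slice of the
#' global uptake maximum (optionally restricted to a lesion mask), centered
#' on the maximum voxel, and divides the circle's summary SUV by the
#' background SUV. The summary statistic defaults to the circle mean (the
#' reading under which the circle's size matters); `stat = "max"` gives the
#' single-voxel maximum instead.
#'
#' @param summed 3D summed SUV image.
#' @param background_suv Mean SUV of healthy brain (> 0).
#' @param diameter_mm Circle diameter (default 16 mm = 1.6 cm).
#' @param voxel_size Voxel size in mm.
#' @param lesion_mask Optional logical 3D mask restricting the search for
#'   the maximum.
#' @param stat `"mean"` (default) or `"max"`.
#' @return Scalar `tbr_max` with attributes `center` (voxel index) and
#'   `n_voxels`.
#' @export
tbr_max_circle <- function(summed, background_suv, diameter_mm = 16,
                           voxel_size = 2, lesion_mask = NULL,
                           stat = c("mean", "max")) {
  stat <- match.arg(stat)
  stopifnot(length(dim(summed)) == 3L)
  if (!is_scalar_number(background_suv) || background_suv <= 0) {
    abort_fetdki("background SUV must be a positive number")
  }
  voxel_size <- rep_len(voxel_size, 3L)
  search <- summed
  if (!is.null(lesion_mask)) search[!lesion_mask] <- -Inf
  cand <- which(search == max(search), arr.ind = TRUE)
  if (nrow(cand) > 1L) {
    # plateau of maximal uptake: anchor on the voxel nearest its centroid
    cen <- colMeans(cand)
    ctr <- cand[which.min(colSums((t(cand) - cen)^2)), ]
  } else {
    ctr <- cand[1L, ]
  }
  r <- diameter_mm / 2
  circ <- circle_mask_2d(dim(summed)[1:2], ctr[1:2], r, voxel_size[1:2])
  # warn when the circle extends past the image edge (it is silently clipped)
  nx <- dim(summed)[1]; ny <- dim(summed)[2]
  need <- ceiling(r / voxel_size[1:2])
  if (ctr[1] - need[1] < 1 || ctr[1] + need[1] > nx ||
      ctr[2] - need[2] < 1 || ctr[2] + need[2] > ny) {
    warn_fetdki("circular ROI clipped at the image boundary")
  }
  vals <- summed[, , ctr[3]][circ]
  out <- switch(stat, mean = mean(vals), max = max(vals)) / background_suv
  attr(out, "center") <- as.integer(ctr)
  attr(out, "n_voxels") <- sum(circ)
  out
}

#' Lesion time-activity curve from a spherical VOI
#'
#' Per-frame mean SUV over voxels whose centers fall inside a 2 ml sphere
#' (diameter 1.6 cm) centered on the given voxel (normally the maximal
#' uptake voxel of the summed image).
#'
#' @param pet A [pet_study()].
#' @param center Voxel index (1-based, length 3) of the sphere center.
#' @param diameter_mm Sphere diameter (default 16 mm).
#' @return Tibble with `frame`, `start_min`, `end_min`, `mid_min`, `suv`;
#'   attribute `n_voxels`.
#' @export
extract_tac <- function(pet, center, diameter_mm = 16) {
  stopifnot(inherits(pet, "fetdki_pet"), length(center) == 3L)
  dims <- dim(pet$frames)[1:3]
  d2 <- dist2_from_center(dims, pet$voxel_size, as.numeric(center) - 1)
  inside <- d2 <= (diameter_mm / 2)^2
  n <- sum(inside)
  if (n == 0L) abort_fetdki("spherical VOI contains no voxel centers")
  suv <- vapply(seq_along(pet$frame_mid),
                function(f) mean(pet$frames[, , , f][inside]), numeric(1))
  out <- tibble(
    frame = seq_along(suv), start_min = pet$frame_start,
    end_min = pet$frame_end, mid_min = pet$frame_mid, suv = suv
  )
  attr(out, "n_voxels") <- n
  out
}

#' Time to peak of a time-activity curve
#'
#' Mid-time of the first frame attaining the curve maximum (ties resolve to
#' the earliest frame).
#'
#' @param tac Tibble with `mid_min` and `suv` (as from [extract_tac()]).
#' @return Minutes.
#' @export
ttp <- function(tac) {
  stopifnot(nrow(tac) >= 1L, all(c("mid_min", "suv") %in% names(tac)))
  tac$mid_min[which.max(tac$suv)]
}

#' Late-phase slope of a time-activity curve
#'
#' Ordinary least-squares slope of SUV against frame mid-time over the
#' 20-50 min late phase, expressed in SUV per hour.
#'
#' @param tac Tibble with `mid_min` and `suv`.
#' @param window Late-phase window in minutes.
#' @return SUV/h.
#' @export
late_slope <- function(tac, window = c(20, 50)) {
  late <- tac[tac$mid_min >= window[1] & tac$mid_min <= window[2], ]
  if (nrow(late) < 2L) {
    abort_fetdki("need >= 2 frames with mid-times in [%g, %g] min",
                 window[1], window[2])
  }
  unname(coef(lm(suv ~ mid_min, data = late))[2]) * 60
}

#' All PET-derived parameters for one study
#'
#' Runs the full static + dynamic PET analysis: 20-40 min summed image,
#' background SUV, TBR map, 3D lesion ROI at the TBR threshold, 2D
#' auto-contour TBRmean, circular-ROI TBRmax, spherical-VOI TAC, TTP and
#' late slope.
#'
#' @param pet A [pet_study()].
#' @param reference_mask Logical 3D mask of healthy brain.
#' @param seed_point Voxel index seeding the 3D segmentation; default the
#'   global maximum of the TBR map.
#' @param threshold TBR threshold for segmentation/auto-contour.
#' @param tbrmax_stat Summary statistic inside the TBRmax circle.
#' @return Object of class `fetdki_pet_derived`: list with `summed_20_40`,
#'   `background_suv`, `tbr_map`, `roi3d`, `tbr_mean`, `tbr_max`, `tac`,
#'   `ttp`, `slope` and a one-row tibble `parameters`.
#' @export
pet_derived <- function(pet, reference_mask, seed_point = NULL,
                        threshold = 1.6, tbrmax_stat = "mean") {
  summed <- sum_frames(pet)
  bg <- compute_background(summed, reference_mask)
  if (bg <= 0) abort_fetdki("non-positive background SUV")
  tbr <- summed / bg
  if (is.null(seed_point)) {
    seed_point <- which(tbr == max(tbr), arr.ind = TRUE)[1L, ]
  }
  roi3d <- segment_roi3d(tbr, threshold, seed_point)
  tbr_mean <- tbr_mean_autocontour(tbr, threshold)
  tbr_max <- tbr_max_circle(summed, bg, voxel_size = pet$voxel_size,
                            lesion_mask = roi3d, stat = tbrmax_stat)
  ctr <- attr(tbr_max, "center")
  tac <- extract_tac(pet, ctr)
  structure(
    list(
      summed_20_40 = summed, background_suv = bg, tbr_map = tbr,
      roi3d = roi3d, tbr_mean = as.numeric(tbr_mean),
      tbr_max = as.numeric(tbr_max), tac = tac,
      ttp = ttp(tac), slope = late_slope(tac),
      parameters = tibble(
        TBR_mean = as.numeric(tbr_mean), TBR_max = as.numeric(tbr_max),
        TTP = ttp(tac), Slope = late_slope(tac),
        background_suv = bg, roi3d_voxels = sum(roi3d)
      )
    ),
    class = "fetdki_pet_derived"
  )
}

#' @export
print.fetdki_pet_derived <- function(x, ...) {
  cat(sprintf(
    "<fetdki_pet_derived> TBRmean %.2f, TBRmax %.2f, TTP %.1f min, slope %.2f SUV/h, ROI %d voxels\n",
    x$tbr_mean, x$tbr_max, x$ttp, x$slope, sum(x$roi3d)))
  invisible(x)
}
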