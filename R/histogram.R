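# Histogram-centile feature extraction over the PET-defined 3D ROI:
# truncation, volume-normalized relative-frequency histograms with
# moving-average smoothing, and the 18 DT/KT summary variables.

#' Histogram analysis specification
#'
#' Truncation ranges, smoothing windows and derived bin widths for the
#' diffusivity ("dt") and kurtosis ("kt") map families. Values outside
#' 0.5-3.5 um^2/ms (DT) and 0.4-1.2 (KT) are discarded as noise; smoothing
#' uses a moving average spanning 0.14 um^2/ms (DT) and 0.04 (KT). The bin
#' width defaults to window/7 so the moving average spans exactly 7 bins.
#'
#' @param dt_range,kt_range Closed truncation intervals.
#' @param dt_smooth_window,kt_smooth_window Moving-average window widths in
#'   map units.
#' @param smooth_bins Odd number of bins the smoothing window spans
#'   (bin width = window / smooth_bins).
#' @param centiles_dt,centiles_kt Centiles extracted per family (%).
#' @return Object of class `fetdki_histogram_spec`.
#' @export
histogram_spec <- function(dt_range = c(0.5, 3.5), kt_range = c(0.4, 1.2),
                           dt_smooth_window = 0.14, kt_smooth_window = 0.04,
                           smooth_bins = 7L,
                           centiles_dt = c(5, 10), centiles_kt = c(90, 95)) {
  stopifnot(dt_range[1] < dt_range[2], kt_range[1] < kt_range[2],
            dt_smooth_window > 0, kt_smooth_window > 0,
            smooth_bins >= 1L, smooth_bins %% 2L == 1L)
  structure(
    list(
      dt_range = dt_range, kt_range = kt_range,
      dt_smooth_window = dt_smooth_window,
      kt_smooth_window = kt_smooth_window,
      smooth_bins = as.integer(smooth_bins),
      bin_width_dt = dt_smooth_window / smooth_bins,
      bin_width_kt = kt_smooth_window / smooth_bins,
      centiles_dt = centiles_dt, centiles_kt = centiles_kt
    ),
    class = "fetdki_histogram_spec"
  )
}

family_range <- function(spec, family) {
  switch(family, dt = spec$dt_range, kt = spec$kt_range,
         abort_fetdki("unknown family '%s'", family))
}

#' Truncate map values to the family's plausible range
#'
#' Keeps values inside the closed interval and reports how many were
#' discarded.
#'
#' @param values Numeric vector (NAs are dropped and counted separately).
#' @param range Length-2 closed interval.
#' @return Numeric vector of kept values with attributes `n_discarded` and
#'   `n_missing`. Errors if nothing survives.
#' @export
truncate_values <- function(values, range) {
  stopifnot(length(range) == 2L, range[1] <= range[2])
  n_missing <- sum(!is.finite(values))
  v <- values[is.finite(values)]
  keep <- v >= range[1] & v <= range[2]
  out <- v[keep]
  if (!length(out)) {
    abort_fetdki("all %d values fall outside [%g, %g]; empty feature set",
                 length(values), range[1], range[2])
  }
  attr(out, "n_discarded") <- sum(!keep)
  attr(out, "n_missing") <- n_missing
  out
}

#' Volume-normalized relative-frequency histogram
#'
#' Bins truncated values on a fixed grid spanning the truncation range,
#' normalizes counts by the total in-range voxel count (so relative
#' frequencies sum to 1 for any ROI volume), and applies centered
#' moving-average smoothing over `smooth_bins` bins (partial windows at the
#' edges), renormalizing so the smoothed frequencies also sum to 1.
#'
#' @param values Truncated values (see [truncate_values()]).
#' @param spec A [histogram_spec()].
#' @param family `"dt"` or `"kt"`.
#' @return Object of class `fetdki_histogram`: tibble-backed list with
#'   `bin_edges`, `mid`, `rel_freq`, `smoothed`.
#' @export
build_histogram <- function(values, spec = histogram_spec(),
                            family = c("dt", "kt")) {
  family <- match.arg(family)
  if (!length(values)) abort_fetdki("no values to histogram")
  rng <- family_range(spec, family)
  bw <- switch(family, dt = spec$bin_width_dt, kt = spec$bin_width_kt)
  n_bins <- max(1L, round(diff(rng) / bw))
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  # closed upper boundary: top values land in the last bin
  bin <- pmin(findInterval(values, edges, rightmost.closed = TRUE), n_bins)
  counts <- tabulate(bin, n_bins)
  rel <- counts / sum(counts)
  half <- (spec$smooth_bins - 1L) %/% 2L
  sm <- vapply(seq_len(n_bins), function(i) {
    lo <- max(1L, i - half); hi <- min(n_bins, i + half)
    mean(rel[lo:hi])
  }, numeric(1))
  sm <- sm / sum(sm)
  structure(
    list(bin_edges = edges, mid = (edges[-1] + edges[-length(edges)]) / 2,
         rel_freq = rel, smoothed = sm, family = family, n = length(values)),
    class = "fetdki_histogram"
  )
}

#' Histogram mean and centiles of truncated voxel values
#'
#' The mean is the arithmetic mean of the truncated voxel values; centiles
#' are linear-interpolation quantiles between closest ranks (inclusive;
#' R's default type-7 convention), computed on the raw truncated values
#' rather than the smoothed histogram so they do not depend on bin width.
#'
#' @param values Truncated values.
#' @param spec A [histogram_spec()].
#' @param family `"dt"` or `"kt"` (selects which centiles to report).
#' @return Named numeric vector: `mean` plus `C<p>` entries.
#' @export
summarize_histogram <- function(values, spec = histogram_spec(),
                                family = c("dt", "kt")) {
  family <- match.arg(family)
  if (!length(values)) abort_fetdki("no values to summarize")
  cents <- switch(family, dt = spec$centiles_dt, kt = spec$centiles_kt)
  q <- quantile(values, cents / 100, type = 7, names = FALSE)
  setNames(c(mean(values), q), c("mean", paste0("C", cents)))
}

#' Extract the 18 DT/KT histogram variables from metric maps in an ROI
#'
#' Applies truncation and summarization per metric map (MD/RD/AD with the
#' diffusivity range and low centiles; MK/RK/AK with the kurtosis range and
#' high centiles) over the PET-defined 3D ROI.
#'
#' @param maps A `fetdki_maps` object (or any list with arrays `md`, `rd`,
#'   `ad`, `mk`, `rk`, `ak` and `voxel_size`).
#' @param roi3d Logical 3D mask on the same grid.
#' @param spec A [histogram_spec()].
#' @param keep_histograms Also return the smoothed histograms per metric?
#' @return One-row tibble with the 18 feature columns (`MD_mean` ...
#'   `AK_C95`), `roi_volume_ml`, and per-metric used-voxel counts
#'   (`n_used_MD` ...). Metrics whose in-range voxel set is empty yield NA
#'   features and a warning. With `keep_histograms = TRUE` the tibble gains
#'   a list-column `histograms`.
#' @export
extract_features <- function(maps, roi3d, spec = histogram_spec(),
                             keep_histograms = FALSE) {
  stopifnot(is.logical(roi3d))
  if (!any(roi3d)) abort_fetdki("3D ROI is empty")
  if (!identical(dim(roi3d), dim(maps$md))) {
    abort_fetdki("ROI grid %s does not match map grid %s",
                 paste(dim(roi3d), collapse = "x"),
                 paste(dim(maps$md), collapse = "x"))
  }
  metrics <- c(MD = "md", RD = "rd", AD = "ad",
               MK = "mk", RK = "rk", AK = "ak")
  fams <- c(MD = "dt", RD = "dt", AD = "dt",
            MK = "kt", RK = "kt", AK = "kt")
  feats <- list()
  counts <- list()
  hists <- list()
  for (m in names(metrics)) {
    vals <- maps[[metrics[[m]]]][roi3d]
    res <- tryCatch(
      truncate_values(vals, family_range(spec, fams[[m]])),
      error = function(e) NULL
    )
    if (is.null(res)) {
      warn_fetdki("metric %s: no in-range voxels in ROI; features set NA", m)
      cents <- switch(fams[[m]], dt = spec$centiles_dt, kt = spec$centiles_kt)
      s <- setNames(rep(NA_real_, 1 + length(cents)),
                    c("mean", paste0("C", cents)))
      counts[[paste0("n_used_", m)]] <- 0L
    } else {
      s <- summarize_histogram(res, spec, fams[[m]])
      counts[[paste0("n_used_", m)]] <- length(res)
      if (keep_histograms) hists[[m]] <- build_histogram(res, spec, fams[[m]])
    }
    names(s) <- paste0(m, "_", names(s))
    feats[[m]] <- s
  }
  voxel_ml <- prod(rep_len(maps$voxel_size %||% 2, 3L)) / 1000
  out <- dplyr::bind_cols(
    as_tibble(as.list(unlist(unname(feats)))),
    tibble(roi_volume_ml = sum(roi3d) * voxel_ml),
    as_tibble(counts)
  )
  if (keep_histograms) out$histograms <- list(hists)
  out
}
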