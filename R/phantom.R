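# Digital phantoms: a spherical lesion inside an ellipsoidal "brain" of
# anisotropic white matter, with signal-free air outside. The DWI phantom
# generates signal from the kurtosis forward model with Rician noise; the
# PET phantom generates a 16-frame dynamic study whose lesion
# time-activity curve is calibrated to a target time-to-peak, late-phase
# slope, and 20-40 min tumor-to-brain ratio.

#' Phantom configuration
#'
#' Defines one virtual patient. Lesion targets not supplied explicitly are
#' drawn (under `seed`) from the group-calibrated marginal distributions of
#' [calibration_targets()] (MD mean, MK mean, TBRmax); the TAC shape defaults to
#' the group-median time-to-peak and late slope.
#'
#' @param group `"TPR"` or `"TRC"`.
#' @param grid_shape Voxels per axis (default 48 x 48 x 32).
#' @param voxel_size mm, isotropic scalar or length 3 (default 2).
#' @param lesion_center Voxel coordinates (1-based, possibly fractional);
#'   default slightly off-center so the contralateral side is clean.
#' @param lesion_radius_mm Lesion sphere radius (default 8 mm).
#' @param wm_tensor_eigenvalues White-matter diffusion eigenvalues in
#'   um^2/ms (default 1.7, 0.4, 0.4, principal axis along x).
#' @param wm_kurtosis White-matter mean kurtosis target (default 0.9).
#' @param lesion_md_target,lesion_mk_target Lesion ground-truth MD
#'   (um^2/ms) and MK; `NULL` draws from the group distribution.
#' @param pet_background_suv Healthy-brain SUV (default 1.0).
#' @param lesion_tbr_target 20-40 min lesion/background ratio; `NULL` draws
#'   from the group TBRmax distribution.
#' @param tac_shape List with `ttp_minutes` (must equal a frame mid-time)
#'   and `late_slope_suv_per_h`; `NULL` uses group medians.
#' @param s0 Non-diffusion-weighted tissue signal (arbitrary units).
#' @param noise_sigma DWI Rician noise sigma (signal units; default `s0/25`,
#'   i.e. SNR 25 at b = 0).
#' @param pet_noise_sigma Gaussian SUV noise per PET frame (default 0.02).
#' @param seed Integer; fixes both the target draws and the noise.
#' @return Object of class `fetdki_phantom_config`.
#' @export
phantom_config <- function(group = c("TPR", "TRC"),
                           grid_shape = c(48L, 48L, 32L),
                           voxel_size = 2,
                           lesion_center = NULL,
                           lesion_radius_mm = 8,
                           wm_tensor_eigenvalues = c(1.7, 0.4, 0.4),
                           wm_kurtosis = 0.9,
                           lesion_md_target = NULL,
                           lesion_mk_target = NULL,
                           pet_background_suv = 1.0,
                           lesion_tbr_target = NULL,
                           tac_shape = NULL,
                           s0 = 500,
                           noise_sigma = s0 / 25,
                           pet_noise_sigma = 0.02,
                           seed = NULL) {
  group <- match.arg(group)
  grid_shape <- as.integer(rep_len(grid_shape, 3L))
  voxel_size <- rep_len(voxel_size, 3L)
  if (is.null(lesion_center)) {
    lesion_center <- c(grid_shape[1] * 0.68, grid_shape[2] / 2 + 0.5,
                       grid_shape[3] / 2 + 0.5)
  }
  targets <- calibration_targets()
  # draws are clamped to the model-valid range (the skewed families match
  # the quartiles exactly but can have heavy tails beyond them)
  draw_target <- function(feature, lo, hi) {
    t <- targets[targets$feature == feature & targets$group == group, ]
    fam <- fit_quantile_family(t$median, min(t$q1, t$q3), max(t$q1, t$q3))
    min(max(fam$qfun(runif(1)), lo), hi)
  }
  drawn <- with_local_seed(seed, {
    list(
      md = lesion_md_target %||% draw_target("MD_mean", 0.6, 3.4),
      mk = lesion_mk_target %||% draw_target("MK_mean", 0.15, 2.5),
      tbr = lesion_tbr_target %||% draw_target("TBR_max", 1.8, 6)
    )
  })
  if (is.null(tac_shape)) {
    med <- function(f) targets$median[targets$feature == f &
                                        targets$group == group]
    tac_shape <- list(ttp_minutes = med("TTP"),
                      late_slope_suv_per_h = med("Slope"))
  }
  cfg <- structure(
    list(group = group, grid_shape = grid_shape, voxel_size = voxel_size,
         lesion_center = lesion_center, lesion_radius_mm = lesion_radius_mm,
         wm_tensor_eigenvalues = wm_tensor_eigenvalues,
         wm_kurtosis = wm_kurtosis,
         lesion_md_target = drawn$md, lesion_mk_target = drawn$mk,
         pet_background_suv = pet_background_suv,
         lesion_tbr_target = drawn$tbr, tac_shape = tac_shape,
         s0 = s0, noise_sigma = noise_sigma,
         pet_noise_sigma = pet_noise_sigma, seed = seed),
    class = "fetdki_phantom_config"
  )
  validate_phantom_config(cfg)
}

validate_phantom_config <- function(cfg) {
  ext <- (cfg$grid_shape - 1) * cfg$voxel_size
  lo <- (cfg$lesion_center - 1) * cfg$voxel_size - cfg$lesion_radius_mm
  hi <- (cfg$lesion_center - 1) * cfg$voxel_size + cfg$lesion_radius_mm
  if (any(lo < 0) || any(hi > ext)) {
    abort_fetdki("lesion sphere extends outside the grid")
  }
  dvals <- c(cfg$lesion_md_target, cfg$wm_tensor_eigenvalues)
  if (any(dvals <= 0) || any(dvals > 3.5)) {
    abort_fetdki("diffusivities must lie in (0, 3.5] um^2/ms")
  }
  kvals <- c(cfg$lesion_mk_target, cfg$wm_kurtosis)
  if (any(kvals <= 0) || any(kvals >= 3)) {
    abort_fetdki("kurtosis targets must lie in (0, 3)")
  }
  if (cfg$noise_sigma < 0 || cfg$pet_noise_sigma < 0) {
    abort_fetdki("noise sigmas must be >= 0")
  }
  cfg
}

# voxel-class masks shared by the DWI and PET phantoms
phantom_masks <- function(cfg) {
  dims <- cfg$grid_shape
  ctr <- (dims + 1) / 2
  semi <- (dims - 1) * cfg$voxel_size * 0.45
  dx <- ((seq_len(dims[1]) - ctr[1]) * cfg$voxel_size[1] / semi[1])^2
  dy <- ((seq_len(dims[2]) - ctr[2]) * cfg$voxel_size[2] / semi[2])^2
  dz <- ((seq_len(dims[3]) - ctr[3]) * cfg$voxel_size[3] / semi[3])^2
  brain <- outer(outer(dx, dy, `+`), dz, `+`) <= 1
  d2 <- dist2_from_center(dims, cfg$voxel_size, cfg$lesion_center - 1)
  lesion <- d2 <= cfg$lesion_radius_mm^2 & brain
  # healthy reference: brain tissue well away from the lesion (contralateral)
  reference <- brain & d2 > (cfg$lesion_radius_mm + 4 * max(cfg$voxel_size))^2
  list(brain = brain, lesion = lesion, background = !brain,
       reference = reference, lesion_d2 = d2)
}

# Mild center-bright radial uptake profile over the lesion, normalized to
# mean 1 so TBR calibration is unaffected. Keeps the uptake maximum at the
# lesion center (as in real lesions), which anchors the circular ROI and
# the spherical VOI there.
lesion_profile <- function(masks, cfg, alpha = 0.05) {
  u <- 1 - masks$lesion_d2[masks$lesion] / cfg$lesion_radius_mm^2
  1 + alpha * (u - mean(u))
}

#' Simulate a multi-shell DWI phantom
#'
#' Generates the diffusion signal of every voxel from the kurtosis forward
#' model (white matter: anisotropic tensor with the configured eigenvalues
#' and a kurtosis tensor scaled so its spherical-mean kurtosis equals
#' `wm_kurtosis`; lesion: isotropic with the configured MD/MK targets), then
#' applies Rician noise. Ground-truth metric maps are returned alongside the
#' noisy data so parameter recovery can be measured exactly.
#'
#' @param config A [phantom_config()].
#' @param acquisition List with `bvals` (s/mm^2) and `bvecs`, as from
#'   [default_acquisition()] (b = 0, 1000, 2500 s/mm^2, 30 directions).
#' @return List of class `fetdki_dwi_phantom`: `dwi` (a [dwi_dataset()]
#'   whose mask is the brain), `truth` (list of md/rd/ad/mk/rk/ak arrays,
#'   NA outside the brain), `masks` (brain/lesion/background/reference) and
#'   `config`.
#' @export
simulate_dwi_phantom <- function(config, acquisition = default_acquisition()) {
  stopifnot(inherits(config, "fetdki_phantom_config"))
  bvals <- acquisition$bvals
  bvecs <- acquisition$bvecs
  if (any(bvals > 2500)) {
    warn_fetdki("b-values above 2500 s/mm^2 exceed the kurtosis model's validated range")
  }
  masks <- phantom_masks(config)
  dims <- config$grid_shape

  # white matter tensors: principal axis along x
  ev <- config$wm_tensor_eigenvalues
  dvec_wm <- c(ev[1], ev[2], ev[3], 0, 0, 0)
  md_wm <- mean(ev)
  des <- dki_mk_design()
  # isotropic W scaled so the spherical-mean kurtosis hits wm_kurtosis
  mk_per_unit <- sum(des$w * (md_wm^2 / drop(des$Q %*% dvec_wm)^2))
  wvec_wm <- isotropic_wvec(config$wm_kurtosis / mk_per_unit)
  # lesion: isotropic
  dvec_le <- c(rep(config$lesion_md_target, 3L), 0, 0, 0)
  wvec_le <- isotropic_wvec(config$lesion_mk_target)

  sig_wm <- dki_signal(bvals, bvecs, config$s0, dvec_wm, wvec_wm)
  sig_le <- dki_signal(bvals, bvecs, config$s0, dvec_le, wvec_le)

  n_meas <- length(bvals)
  n_vox <- prod(dims)
  sig <- matrix(0, n_vox, n_meas)
  wm_idx <- which(masks$brain & !masks$lesion)
  le_idx <- which(masks$lesion)
  sig[wm_idx, ] <- matrix(sig_wm, length(wm_idx), n_meas, byrow = TRUE)
  sig[le_idx, ] <- matrix(sig_le, length(le_idx), n_meas, byrow = TRUE)

  if (config$noise_sigma > 0) {
    sig <- with_local_seed(config$seed, {
      re <- sig + rnorm(length(sig), 0, config$noise_sigma)
      im <- matrix(rnorm(length(sig), 0, config$noise_sigma), nrow(sig))
      sqrt(re^2 + im^2)
    })
  }
  signal <- array(sig, c(dims, n_meas))

  # ground-truth maps
  truth_tpl <- array(NA_real_, dims)
  truth <- list(md = truth_tpl, rd = truth_tpl, ad = truth_tpl,
                mk = truth_tpl, rk = truth_tpl, ak = truth_tpl)
  dt_wm <- compute_dt_metrics(dvec_wm)
  kt_wm <- compute_kt_metrics(dvec_wm, wvec_wm)
  fill <- function(map, idx, v) { map[idx] <- v; map }
  truth$md <- fill(fill(truth$md, wm_idx, dt_wm$md), le_idx, config$lesion_md_target)
  truth$ad <- fill(fill(truth$ad, wm_idx, dt_wm$ad), le_idx, config$lesion_md_target)
  truth$rd <- fill(fill(truth$rd, wm_idx, dt_wm$rd), le_idx, config$lesion_md_target)
  truth$mk <- fill(fill(truth$mk, wm_idx, kt_wm$mk), le_idx, config$lesion_mk_target)
  truth$rk <- fill(fill(truth$rk, wm_idx, kt_wm$rk), le_idx, config$lesion_mk_target)
  truth$ak <- fill(fill(truth$ak, wm_idx, kt_wm$ak), le_idx, config$lesion_mk_target)

  dwi <- dwi_dataset(signal, bvals, bvecs, config$voxel_size,
                     brain_mask = masks$brain)
  structure(
    list(dwi = dwi, truth = truth, masks = masks, config = config),
    class = "fetdki_dwi_phantom"
  )
}

# lesion TAC values at the frame mid-times, calibrated so that
#   * argmax is exactly the frame whose mid-time equals ttp_minutes,
#   * the OLS slope over late-phase mid-times equals the target,
#   * the duration-weighted 20-40 min mean equals tbr * background.
# The peak is imposed as a perturbation of the late-phase line that is
# orthogonal to the intercept, slope and 20-40 min mean functionals.
lesion_tac_values <- function(mids, ttp_min, slope_suv_h, tbr, bg) {
  s <- slope_suv_h / 60
  in2040 <- mids >= 20 & mids <= 40
  a <- tbr * bg - s * mean(mids[in2040])
  late <- mids >= 20
  v <- numeric(length(mids))
  v[late] <- a + s * mids[late]
  # smooth uptake ramp before the late phase
  v[!late] <- (a + s * 20) * (mids[!late] / 20) * exp(1 - mids[!late] / 20)
  j <- which(abs(mids - ttp_min) < 1e-9)
  if (!length(j)) {
    abort_fetdki("ttp_minutes (%.4g) must equal a frame mid-time (%s)",
                 ttp_min, paste(mids, collapse = ", "))
  }
  margin <- 0.02 * max(tbr * bg, 1)
  if (!late[j]) {
    # early peak: does not touch the late phase or the 20-40 min mean
    v[j] <- max(v) + 5 * margin
    return(v)
  }
  li <- which(late)
  A <- rbind(1, mids[li], as.numeric(in2040[li]))
  u <- as.numeric(li == j) # unit vector at the peak frame, late subspace
  proj <- t(A) %*% solve(A %*% t(A), A %*% u)
  e <- u - drop(proj)
  if (abs(e[which(li == j)]) < 1e-9) {
    abort_fetdki("cannot place a peak at %.4g min under the calibration constraints",
                 ttp_min)
  }
  e <- e / e[which(li == j)]
  # choose the bump size so the peak frame strictly dominates all others
  full_e <- numeric(length(mids))
  full_e[li] <- e
  gain <- 1 - full_e      # d(v_j - v_i)/d(delta) for i != j
  need <- (v - v[j] + margin) / gain
  need[j] <- 0
  need[gain <= 0] <- NA   # cannot dominate these via delta; check after
  delta <- max(c(need, 5 * margin), na.rm = TRUE)
  v2 <- v + delta * full_e
  if (any(v2[-j] >= v2[j])) {
    abort_fetdki("peak placement failed for ttp %.4g min", ttp_min)
  }
  v2
}

#' Simulate a dynamic PET phantom
#'
#' Builds a 16-frame dynamic study (5 x 1, 5 x 3, 6 x 5 min): the lesion
#' follows a calibrated time-activity curve (see Details), healthy brain is
#' flat at `pet_background_suv`, air is zero, and independent Gaussian noise
#' of sd `pet_noise_sigma` is added per voxel and frame.
#'
#' @details The lesion curve is built so that three contracts hold exactly
#' in the noiseless case: the frame of maximum uptake is the one whose
#' mid-time equals `tac_shape$ttp_minutes`; the least-squares slope over the
#' late-phase (20-50 min) frame mid-times equals
#' `tac_shape$late_slope_suv_per_h`; and the duration-weighted 20-40 min
#' mean equals `lesion_tbr_target * pet_background_suv`. When the slope is
#' positive and the target peak is not the last frame, these constraints
#' conflict for any monotone late phase, so the peak is imposed as a bump at
#' the target frame orthogonal to the slope and mean functionals.
#'
#' @param config A [phantom_config()].
#' @param frame_schedule Tibble with `start_min`/`end_min`; must span
#'   0-50 min (default [default_frame_schedule()]).
#' @return List of class `fetdki_pet_phantom`: `pet` (a [pet_study()]),
#'   `masks`, `true_tac` (noise-free lesion TAC values at frame mid-times)
#'   and `config`.
#' @export
simulate_pet_phantom <- function(config,
                                 frame_schedule = default_frame_schedule()) {
  stopifnot(inherits(config, "fetdki_phantom_config"))
  fs <- frame_schedule
  if (abs(fs$start_min[1]) > 1e-9 ||
      abs(fs$end_min[nrow(fs)] - 50) > 1e-9) {
    abort_fetdki("frame schedule must total 0-50 min")
  }
  mids <- (fs$start_min + fs$end_min) / 2
  tac <- lesion_tac_values(
    mids, config$tac_shape$ttp_minutes,
    config$tac_shape$late_slope_suv_per_h,
    config$lesion_tbr_target, config$pet_background_suv
  )
  masks <- phantom_masks(config)
  prof <- lesion_profile(masks, config)
  dims <- config$grid_shape
  nf <- length(mids)
  frames <- array(0, c(dims, nf))
  for (f in seq_len(nf)) {
    vol <- array(0, dims)
    vol[masks$brain] <- config$pet_background_suv
    vol[masks$lesion] <- tac[f] * prof
    frames[, , , f] <- vol
  }
  if (config$pet_noise_sigma > 0) {
    frames <- with_local_seed(
      if (is.null(config$seed)) NULL else config$seed + 1L,
      frames + rnorm(length(frames), 0, config$pet_noise_sigma)
    )
  }
  pet <- pet_study(frames, fs$start_min, fs$end_min, config$voxel_size)
  structure(
    list(pet = pet, masks = masks, true_tac = tac, config = config),
    class = "fetdki_pet_phantom"
  )
}
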