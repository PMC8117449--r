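# Rician handling and voxel/volume kurtosis fitting.

test_that("power-images correction follows its closed form", {
  expect_equal(as.numeric(rician_bias_correct(3, 1)), sqrt(7))
  x <- c(1, 5, 10)
  expect_equal(as.numeric(rician_bias_correct(x, 0)), x)
  floored <- rician_bias_correct(1, 2)
  expect_equal(as.numeric(floored), 0)
  expect_true(attr(floored, "floored"))
  expect_error(rician_bias_correct(1, -1), "non-negative")
})

test_that("background sigma is recovered from Rayleigh magnitudes within 2%", {
  set.seed(7)
  n <- 1e5
  m <- sqrt(rnorm(n, 0, 5)^2 + rnorm(n, 0, 5)^2)
  est <- estimate_background_sigma(m, rep(TRUE, n))
  expect_lt(abs(est - 5) / 5, 0.02)

  expect_error(estimate_background_sigma(rep(0, 10), rep(TRUE, 10)),
               "identically zero")
  expect_error(estimate_background_sigma(m, rep(FALSE, n)), "empty")
  expect_warning(estimate_background_sigma(rep(2, 50), rep(TRUE, 50)),
                 "variance")
})

test_that("noiseless voxel fits recover the generating tensors", {
  acq <- test_acquisition()
  X <- build_design_matrix(acq$bvals, acq$bvecs)

  s_iso <- dki_signal(acq$bvals, acq$bvecs, 100, c(1, 1, 1, 0, 0, 0),
                      isotropic_wvec(0.6))
  f <- fit_dki_voxel(s_iso, X)
  expect_equal(compute_dt_metrics(f$dvec)$md, 1, tolerance = 1e-6)
  expect_equal(compute_kt_metrics(f$dvec, f$wvec)$mk, 0.6, tolerance = 1e-6)

  s_ani <- dki_signal(acq$bvals, acq$bvecs, 100,
                      c(1.7, 0.4, 0.4, 0, 0, 0), isotropic_wvec(0.5))
  fa <- fit_dki_voxel(s_ani, X)
  dm <- compute_dt_metrics(fa$dvec)
  expect_equal(dm$ad, 1.7, tolerance = 1e-6)
  expect_equal(dm$rd, 0.4, tolerance = 1e-6)

  # pure S0: zero-diffusivity limit is flagged degenerate
  fd <- fit_dki_voxel(rep(100, length(acq$bvals)), X)
  expect_true(fd$degenerate)
  expect_lt(compute_dt_metrics(fd$dvec)$md, 1e-5)

  expect_error(fit_dki_voxel(c(-1, s_iso[-1]), X), "positive")
})

test_that("noiseless phantom maps equal ground truth within 1e-4", {
  ph <- simulate_dwi_phantom(small_phantom_config(
    lesion_md_target = 1.32, lesion_mk_target = 0.61,
    lesion_tbr_target = 3.3))
  dwi <- ph$dwi
  # fit the lesion plus a band of white matter
  fitmask <- ph$masks$lesion
  wm <- which(ph$masks$brain & !ph$masks$lesion)[1:60]
  fitmask[wm] <- TRUE
  dwi$brain_mask <- fitmask
  maps <- fit_dki_volume(dwi, rician_correction = FALSE)
  for (m in c("md", "rd", "ad", "mk", "rk", "ak")) {
    expect_lt(max(abs(maps[[m]][fitmask] - ph$truth[[m]][fitmask])), 1e-4)
  }
  expect_equal(maps$report$n_fitted, sum(fitmask))
})

test_that("empty mask yields empty maps with a warning", {
  ph <- simulate_dwi_phantom(small_phantom_config())
  dwi <- ph$dwi
  dwi$brain_mask <- array(FALSE, dim(dwi$signal)[1:3])
  expect_warning(maps <- fit_dki_volume(dwi, rician_correction = FALSE),
                 "empty")
  expect_equal(maps$report$n_fitted, 0L)
  expect_true(all(is.na(maps$md)))
})

test_that("Gaussian-diffusion data yield near-zero MK at high SNR", {
  acq <- test_acquisition()
  X <- build_design_matrix(acq$bvals, acq$bvecs)
  s0 <- 100
  clean <- dki_signal(acq$bvals, acq$bvecs, s0,
                      c(1.0, 0.8, 0.6, 0, 0, 0), rep(0, 15))
  sim_mk <- function(n, sigma, method) {
    replicate(n, {
      noisy <- sqrt((clean + rnorm(length(clean), 0, sigma))^2 +
                      rnorm(length(clean), 0, sigma)^2)
      corr <- pmax(rician_bias_correct(noisy, sigma), 1e-6)
      f <- fit_dki_voxel(corr, X, method = method, sigma = sigma)
      compute_kt_metrics(f$dvec, f$wvec, clip = c(-3, 3))$mk
    })
  }
  # log-domain WLS at SNR 50
  set.seed(12)
  expect_lt(abs(mean(sim_mk(1500, s0 / 50, "wls"))), 0.02)
  # magnitude-domain NLLS at SNR 100
  expect_lt(abs(mean(sim_mk(300, s0 / 100, "nlls"))), 0.02)
})

test_that("eigenvalue ordering forces AD >= MD >= RD on noisy fits", {
  acq <- test_acquisition()
  X <- build_design_matrix(acq$bvals, acq$bvecs)
  clean <- dki_signal(acq$bvals, acq$bvecs, 100,
                      c(1.5, 0.6, 0.5, 0.05, 0, 0), isotropic_wvec(0.7))
  set.seed(13)
  for (i in 1:10) {
    noisy <- sqrt((clean + rnorm(length(clean), 0, 4))^2 +
                    rnorm(length(clean), 0, 4)^2)
    f <- fit_dki_voxel(noisy, X)
    dm <- compute_dt_metrics(f$dvec)
    expect_gte(dm$ad, dm$md)
    expect_gte(dm$md, dm$rd)
  }
})

test_that("bias-corrected fits land closer to the true MK than uncorrected", {
  acq <- test_acquisition()
  X <- build_design_matrix(acq$bvals, acq$bvecs)
  s0 <- 100; sigma <- 3; mk_true <- 0.61
  clean <- dki_signal(acq$bvals, acq$bvecs, s0,
                      c(1.32, 1.32, 1.32, 0, 0, 0), isotropic_wvec(mk_true))
  set.seed(14)
  mk <- replicate(300, {
    noisy <- sqrt((clean + rnorm(length(clean), 0, sigma))^2 +
                    rnorm(length(clean), 0, sigma)^2)
    f_raw <- fit_dki_voxel(noisy, X, method = "wls")
    f_cor <- fit_dki_voxel(pmax(rician_bias_correct(noisy, sigma), 1e-6), X,
                           method = "wls", sigma = sigma)
    c(raw = compute_kt_metrics(f_raw$dvec, f_raw$wvec)$mk,
      cor = compute_kt_metrics(f_cor$dvec, f_cor$wvec)$mk)
  })
  # paired comparison: corrected fits are less biased and less wrong overall
  expect_lt(abs(mean(mk["cor", ]) - mk_true), abs(mean(mk["raw", ]) - mk_true))
  expect_lt(mean(abs(mk["cor", ] - mk_true)), mean(abs(mk["raw", ] - mk_true)))
})

test_that("SNR-25 phantom keeps lesion-median MK bias below 5%", {
  cfg <- small_phantom_config(noise_sigma = 20, seed = 99,
                              lesion_md_target = 1.32,
                              lesion_mk_target = 0.61,
                              lesion_tbr_target = 3.3)
  ph <- simulate_dwi_phantom(cfg)
  dwi <- ph$dwi
  dwi$brain_mask <- ph$masks$lesion
  maps <- fit_dki_volume(dwi, method = "wls",
                         background_mask = ph$masks$background)
  expect_equal(maps$report$n_fitted, sum(ph$masks$lesion))
  med_mk <- median(maps$mk[ph$masks$lesion], na.rm = TRUE)
  expect_lt(abs(med_mk - 0.61) / 0.61, 0.05)
})
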