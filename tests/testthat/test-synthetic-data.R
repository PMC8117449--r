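# Phantom and cohort simulators.

test_that("phantom configuration enforces its invariants", {
  expect_error(
    phantom_config(grid_shape = c(10, 10, 8), lesion_center = c(9, 5, 4),
                   lesion_radius_mm = 8, seed = 1),
    "outside the grid")
  expect_error(small_phantom_config(lesion_md_target = 4.0), "3.5")
  expect_error(small_phantom_config(lesion_mk_target = 3.2), "kurtosis")
  expect_error(small_phantom_config(noise_sigma = -1), "sigma")
})

test_that("drawn lesion targets follow the group calibration distributions", {
  draws <- vapply(1:200, function(s) {
    small_phantom_config(group = "TPR", seed = s)$lesion_mk_target
  }, numeric(1))
  # TPR MK mean target: median 0.61, quartiles 0.57/0.69
  expect_lt(abs(median(draws) - 0.61), 0.03)
  expect_lt(abs(quantile(draws, 0.25, names = FALSE) - 0.57), 0.04)
  # clamped into the model-valid kurtosis range
  expect_true(all(draws >= 0.15 & draws <= 2.5))
})

test_that("identical seed and config give bit-identical phantoms", {
  cfg <- small_phantom_config(noise_sigma = 15, pet_noise_sigma = 0.02,
                              seed = 7)
  a <- simulate_dwi_phantom(cfg); b <- simulate_dwi_phantom(cfg)
  expect_identical(a$dwi$signal, b$dwi$signal)
  pa <- simulate_pet_phantom(cfg); pb <- simulate_pet_phantom(cfg)
  expect_identical(pa$pet$frames, pb$pet$frames)
})

test_that("noiseless phantom signals follow the forward model exactly", {
  cfg <- small_phantom_config(lesion_md_target = 1.0,
                              lesion_mk_target = 0.6)
  ph <- simulate_dwi_phantom(cfg)
  acq <- test_acquisition()
  v <- which(ph$masks$lesion)[1]
  sig <- matrix(ph$dwi$signal, prod(cfg$grid_shape), length(acq$bvals))[v, ]
  expect_equal(sig[1], cfg$s0) # b = 0 identity
  expected <- dki_signal(acq$bvals, acq$bvecs, cfg$s0,
                         c(1, 1, 1, 0, 0, 0), isotropic_wvec(0.6))
  expect_equal(sig, expected, tolerance = 1e-12)
  # b = 1000 along any direction for the isotropic lesion: S0 * exp(-0.9)
  expect_equal(unname(sig[2]), cfg$s0 * exp(-1 + 0.1), tolerance = 1e-12)
})

test_that("phantom ground-truth maps carry the configured lesion targets", {
  cfg <- small_phantom_config(lesion_md_target = 1.32,
                              lesion_mk_target = 0.61)
  ph <- simulate_dwi_phantom(cfg)
  expect_true(all(ph$truth$mk[ph$masks$lesion] == 0.61))
  expect_true(all(ph$truth$md[ph$masks$lesion] == 1.32))
  wm <- ph$masks$brain & !ph$masks$lesion
  expect_equal(unique(ph$truth$ad[wm]), 1.7)
  expect_equal(unique(ph$truth$rd[wm]), 0.4)
  # white-matter MK calibrated to the configured spherical-mean kurtosis
  expect_equal(unique(ph$truth$mk[wm]), 0.9, tolerance = 1e-9)
})

test_that("PET phantom honors its TBR, TTP and slope calibration", {
  cfg <- small_phantom_config(lesion_tbr_target = 2.0,
                              tac_shape = list(ttp_minutes = 27.5,
                                               late_slope_suv_per_h = 0.25))
  pp <- simulate_pet_phantom(cfg)
  summed <- sum_frames(pp$pet)
  # summed lesion/background ratio hits the target (profile mean is 1)
  expect_equal(mean(summed[pp$masks$lesion]) /
                 mean(summed[pp$masks$reference]), 2.0, tolerance = 1e-9)
  # true TAC: peak frame and late-phase OLS slope are exact
  mids <- pp$pet$frame_mid
  expect_equal(mids[which.max(pp$true_tac)], 27.5)
  late <- mids >= 20
  fit <- lm(pp$true_tac[late] ~ mids[late])
  expect_equal(unname(coef(fit)[2]) * 60, 0.25, tolerance = 1e-9)

  # extracted (sphere-averaged) slope on the noiseless default-size phantom
  cfg2 <- phantom_config("TPR", lesion_tbr_target = 3.3,
                         noise_sigma = 0, pet_noise_sigma = 0, seed = 2)
  pp2 <- simulate_pet_phantom(cfg2)
  der <- pet_derived(pp2$pet, pp2$masks$reference)
  expect_equal(der$ttp, 27.5)
  expect_lt(abs(der$slope - 0.25), 0.05)
})

test_that("invalid frame schedules are rejected", {
  cfg <- small_phantom_config()
  short <- default_frame_schedule()[1:10, ]
  expect_error(simulate_pet_phantom(cfg, short), "50 min")
  expect_error(
    phantom_config(tac_shape = list(ttp_minutes = 26,
                                    late_slope_suv_per_h = 0.2),
                   seed = 1) |> simulate_pet_phantom(),
    "mid-time")
})

test_that("cohort simulation is deterministic and respects group sizes", {
  cfg <- cohort_sim_config(seed = 5)
  a <- simulate_feature_cohort(cfg)
  b <- simulate_feature_cohort(cfg)
  expect_identical(a, b)
  expect_equal(sum(a$group == "TRC"), 11L)
  expect_equal(sum(a$group == "TPR"), 21L)
  expect_true(all(feature_schema() %in% names(a)))

  only_tpr <- simulate_feature_cohort(cohort_sim_config(n_trc = 0, seed = 5))
  expect_true(all(only_tpr$group == "TPR"))
})

test_that("infeasible targets are rejected with the feature named", {
  bad <- calibration_targets()
  bad$median[bad$feature == "MK_C90" & bad$group == "TPR"] <- 99
  expect_error(cohort_sim_config(feature_targets = bad), "MK_C90")
})

test_that("per-patient centile ordering holds in simulated cohorts", {
  ch <- simulate_feature_cohort(cohort_sim_config(n_trc = 200, n_tpr = 200,
                                                  seed = 8))
  for (m in c("MD", "RD", "AD")) {
    expect_true(all(ch[[paste0(m, "_C5")]] <= ch[[paste0(m, "_C10")]]))
    expect_true(all(ch[[paste0(m, "_C10")]] <= ch[[paste0(m, "_mean")]]))
  }
  for (m in c("MK", "RK", "AK")) {
    expect_true(all(ch[[paste0(m, "_mean")]] <= ch[[paste0(m, "_C90")]]))
    expect_true(all(ch[[paste0(m, "_C90")]] <= ch[[paste0(m, "_C95")]]))
  }
})

test_that("TPR MK C90 median matches its calibration target at large n", {
  ch <- simulate_feature_cohort(cohort_sim_config(n_trc = 0, n_tpr = 10000,
                                                  seed = 13))
  expect_lt(abs(median(ch$MK_C90) - 0.78), 0.02)
})

test_that("an identity copula leaves different metrics uncorrelated", {
  R <- diag(22)
  dimnames(R) <- list(feature_schema(), feature_schema())
  ch <- simulate_feature_cohort(
    cohort_sim_config(n_trc = 0, n_tpr = 8000, correlation_spec = R,
                      seed = 3))
  # rank correlation: the copula's dependence measure, stable under the
  # heavy-tailed marginals
  cmat <- cor(as.matrix(ch[, feature_schema()]), method = "spearman")
  metric_of <- sub("_(mean|C\\d+)$", "", feature_schema())
  cross <- abs(cmat[outer(metric_of, metric_of, `!=`)])
  expect_lt(max(cross), 0.05)
})

test_that("quantile families reproduce their defining quartiles", {
  fam <- fit_quantile_family(0.78, 0.70, 0.83) # left-skewed
  expect_equal(fam$qfun(c(0.25, 0.5, 0.75)), c(0.70, 0.78, 0.83),
               tolerance = 1e-12)
  fam2 <- fit_quantile_family(1.32, 1.24, 1.55) # right-skewed
  expect_equal(fam2$qfun(c(0.25, 0.5, 0.75)), c(1.24, 1.32, 1.55),
               tolerance = 1e-12)
  fam3 <- fit_quantile_family(0.42, 0.32, 0.65, family = "normal")
  expect_equal(fam3$qfun(0.5), 0.42)
  expect_error(fit_quantile_family(0.5, 0.6, 0.7), "outside")
})
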