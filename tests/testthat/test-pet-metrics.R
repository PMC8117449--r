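# PET analytics: summed images, TBR quantities, segmentation, TAC metrics.

make_pet <- function(fill = 1) {
  fs <- default_frame_schedule()
  frames <- array(fill, c(8, 8, 6, nrow(fs)))
  pet_study(frames, fs$start_min, fs$end_min, voxel_size = 2)
}

test_that("summed image is the duration-weighted mean over the window", {
  pet <- make_pet(3)
  expect_true(all(sum_frames(pet) == 3))

  # two equal frames valued 1 and 3 -> 2
  fr <- array(0, c(2, 2, 2, 2))
  fr[, , , 1] <- 1; fr[, , , 2] <- 3
  # overlap weighting: 15-25 min value 1, 25-40 min value 2, window 20-40
  mk2 <- function(s, e, v) {
    f <- array(0, c(1, 1, 1, length(s)))
    f[1, 1, 1, ] <- v
    structure(list(frames = f, frame_start = s, frame_end = e,
                   frame_mid = (s + e) / 2, voxel_size = rep(2, 3)),
              class = "fetdki_pet")
  }
  p1 <- mk2(c(20, 30), c(30, 40), c(1, 3))
  expect_equal(as.numeric(sum_frames(p1)), 2)
  p2 <- mk2(c(15, 25), c(25, 40), c(1, 2))
  expect_equal(as.numeric(sum_frames(p2)), (5 * 1 + 15 * 2) / 20)
  expect_error(sum_frames(p2, window = c(10, 60)), "outside")
})

test_that("background SUV is the reference-region mean", {
  vol <- array(5, c(4, 4, 4))
  expect_equal(compute_background(vol, array(TRUE, dim(vol))), 5)
  vol[1, 1, 1] <- 1; vol[2, 1, 1] <- 3
  m <- array(FALSE, dim(vol)); m[1:2, 1, 1] <- TRUE
  expect_equal(compute_background(vol, m), 2)
  expect_error(compute_background(vol, array(FALSE, dim(vol))), "empty")

  set.seed(2)
  big <- array(1 + rnorm(40^3, 0, 0.01), c(40, 40, 40))
  expect_lt(abs(compute_background(big, array(TRUE, dim(big))) - 1), 0.005)
})

test_that("3D segmentation returns the seeded connected component", {
  cfg <- small_phantom_config(lesion_tbr_target = 2.0)
  pp <- simulate_pet_phantom(cfg)
  summed <- sum_frames(pp$pet)
  tbr <- summed / compute_background(summed, pp$masks$reference)
  seed_vox <- round(cfg$lesion_center)
  roi <- segment_roi3d(tbr, 1.6, seed_vox)
  expect_identical(roi, pp$masks$lesion)

  expect_error(segment_roi3d(array(1, c(5, 5, 5)), 1.6, c(3, 3, 3)),
               "threshold")

  # two disjoint blobs: only the seeded one comes back
  two <- array(0, c(10, 10, 3))
  two[2:3, 2:3, 2] <- 2; two[8:9, 8:9, 2] <- 2
  roi2 <- segment_roi3d(two, 1.6, c(2, 2, 2))
  expect_true(all(which(roi2, arr.ind = TRUE)[, 1] <= 3))
  expect_equal(sum(roi2), 4L)
})

test_that("2D auto-contour mean TBR matches direct enumeration", {
  m <- array(1, c(9, 9, 3))
  m[4:6, 4:6, 2] <- 2
  expect_equal(as.numeric(tbr_mean_autocontour(m)), 2)

  m2 <- array(1, c(9, 9, 3))
  m2[4, 4, 2] <- 1.6; m2[4, 5, 2] <- 2.0; m2[4, 6, 2] <- 2.4
  expect_equal(as.numeric(tbr_mean_autocontour(m2)), 2)

  # radial gradient: compare against brute-force mean over the 2D region
  cfg <- small_phantom_config(lesion_tbr_target = 2.5)
  pp <- simulate_pet_phantom(cfg)
  summed <- sum_frames(pp$pet)
  bg <- compute_background(summed, pp$masks$reference)
  tbr <- summed / bg
  got <- tbr_mean_autocontour(tbr)
  sl <- attr(got, "slice")
  expect_equal(as.numeric(got), mean(tbr[, , sl][tbr[, , sl] >= 1.6]))
})

test_that("circular-ROI TBRmax behaves like its voxel enumeration", {
  # uniform hot disk larger than the circle: ratio is exact
  vol <- array(1.5, c(21, 21, 3))
  d2 <- dist2_from_center <- outer((1:21 - 11)^2, (1:21 - 11)^2, `+`) * 4
  disk <- d2 <= 14^2
  sl <- vol[, , 2]; sl[disk] <- 3; vol[, , 2] <- sl
  expect_equal(as.numeric(tbr_max_circle(vol, 1.5, voxel_size = 2)), 2)

  # single hot voxel: circle mean is attenuated and equals brute force
  vol2 <- array(1, c(21, 21, 3))
  vol2[11, 11, 2] <- 5
  got <- tbr_max_circle(vol2, 1, voxel_size = 2)
  circ <- d2 <= 8^2
  expect_equal(as.numeric(got), mean(vol2[, , 2][circ]))
  expect_lt(as.numeric(got), 5)
  expect_equal(attr(got, "n_voxels"), sum(circ))

  expect_error(tbr_max_circle(vol2, 0), "positive")
  expect_warning(tbr_max_circle(array(c(9, rep(1, 63)), c(4, 4, 4)), 1,
                                voxel_size = 2), "clipped")
})

test_that("spherical VOI TAC extraction counts voxels by center inclusion", {
  pet <- make_pet(2)
  tac <- extract_tac(pet, c(4, 4, 3))
  expect_true(all(tac$suv == 2))
  expect_equal(nrow(tac), 16L)

  # 2 mm voxels, 16 mm sphere: 257 lattice points within radius 4 voxels
  big <- pet_study(array(1, c(20, 20, 20, 16)),
                   default_frame_schedule()$start_min,
                   default_frame_schedule()$end_min, voxel_size = 2)
  tac2 <- extract_tac(big, c(10, 10, 10))
  expect_equal(attr(tac2, "n_voxels"), 257L)

  expect_error(extract_tac(pet, c(4.5, 4, 3), diameter_mm = 0.5), "no voxel")
})

test_that("TTP takes the mid-time of the first maximal frame", {
  fs <- default_frame_schedule()
  tac <- tibble::tibble(mid_min = fs$mid_min, suv = seq_len(16))
  expect_equal(ttp(tac), 47.5)
  tac2 <- tac; tac2$suv <- c(1:11, 20, 11:8) # peak in the 25-30 min frame
  expect_equal(ttp(tac2), 27.5)
  tac3 <- tac; tac3$suv <- rep(1, 16) # full tie -> earliest frame
  expect_equal(ttp(tac3), 0.5)
})

test_that("late slope is the OLS slope of the 20-50 min segment in SUV/h", {
  fs <- default_frame_schedule()
  tac <- tibble::tibble(mid_min = fs$mid_min,
                        suv = 1 + 0.01 * fs$mid_min) # 0.1 SUV / 10 min
  expect_equal(late_slope(tac), 0.6, tolerance = 1e-12)
  flat <- tibble::tibble(mid_min = fs$mid_min, suv = rep(2, 16))
  expect_equal(late_slope(flat), 0, tolerance = 1e-12)
  expect_error(late_slope(tac[1:10, ]), ">= 2 frames")

  set.seed(31)
  est <- replicate(50, {
    noisy <- tibble::tibble(
      mid_min = fs$mid_min,
      suv = 1 + (0.25 / 60) * fs$mid_min + rnorm(16, 0, 0.01))
    late_slope(noisy)
  })
  expect_lt(abs(est[1] - 0.25), 0.05) # single seeded estimate
  expect_lt(abs(mean(est) - 0.25), 0.01) # unbiased across replicates
})

test_that("TBR quantities are scale invariant; slope scales linearly", {
  cfg <- small_phantom_config(noise_sigma = 0, pet_noise_sigma = 0.01,
                              seed = 17)
  pp <- simulate_pet_phantom(cfg)
  der1 <- pet_derived(pp$pet, pp$masks$reference)
  pet_k <- pp$pet
  pet_k$frames <- pet_k$frames * 3.7
  der2 <- pet_derived(pet_k, pp$masks$reference)
  expect_equal(der2$tbr_mean, der1$tbr_mean, tolerance = 1e-12)
  expect_equal(der2$tbr_max, der1$tbr_max, tolerance = 1e-12)
  expect_identical(der2$roi3d, der1$roi3d)
  expect_equal(der2$ttp, der1$ttp)
  expect_equal(der2$slope, 3.7 * der1$slope, tolerance = 1e-9)
})
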