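# Shared fixtures: small phantoms and acquisitions that keep the suite fast.

# compact two-shell acquisition reused across fitting tests
test_acquisition <- function() default_acquisition()

# small phantom: 20x20x14 grid, 5 mm lesion, noise-free unless overridden
small_phantom_config <- function(group = "TPR", noise_sigma = 0,
                                 pet_noise_sigma = 0, seed = 42L, ...) {
  phantom_config(
    group = group, grid_shape = c(20L, 20L, 14L),
    lesion_center = c(13, 10.5, 7.5), lesion_radius_mm = 5,
    noise_sigma = noise_sigma, pet_noise_sigma = pet_noise_sigma,
    seed = seed, ...
  )
}

# a generic valid anisotropic tensor pair for metric tests
example_tensor_pair <- function() {
  list(dvec = c(1.7, 0.4, 0.4, 0, 0, 0), wvec = isotropic_wvec(0.5))
}

random_rotation <- function() {
  qr.Q(qr(matrix(rnorm(9), 3L)))
}

# fresh temporary directory, removed when the calling test finishes
withr_local_tempdir <- function(env = parent.frame()) {
  d <- tempfile("fetdki")
  dir.create(d)
  withr::defer(unlink(d, recursive = TRUE), envir = env)
  d
}

# brute-force pairwise AUC: mean over all (pos, neg) pairs with ties at 1/2
brute_force_auc <- function(pos, neg) {
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}
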