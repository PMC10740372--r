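test_that("median spacing uses the per-axis lower median", {
  mk <- function(sp) image_volume(array(0, c(2, 2, 2)), spacing = sp)
  vols <- list(mk(c(1, 1, 2)), mk(c(1, 1, 2)), mk(c(0.5, 0.5, 1)))
  expect_equal(compute_median_spacing(vols), c(1, 1, 2))
  expect_equal(compute_median_spacing(list(mk(c(0.8, 1, 1.2)))), c(0.8, 1, 1.2))
  expect_equal(compute_median_spacing(list(mk(c(1, 1, 1)), mk(c(2, 2, 2)))),
               c(1, 1, 1))
  expect_error(compute_median_spacing(list()), class = "cs_argument_error")
})

test_that("resampling halves shape at doubled spacing and is identity at own spacing", {
  vol <- random_volume(c(16, 16, 16), seed = 2)
  same <- resample(vol, c(1, 1, 1))
  expect_identical(dim(same$data), dim(vol$data))
  expect_lt(max(abs(same$data - vol$data)), 1e-5)

  half <- resample(vol, c(2, 2, 2))
  expect_identical(dim(half$data), c(8L, 8L, 8L))
  expect_equal(half$spacing, c(2, 2, 2))

  msk <- random_mask(c(16, 16, 16), seed = 3)
  half_m <- resample(msk, c(2, 2, 2), mode = "mask")
  expect_true(all(half_m$data %in% c(0L, 1L)))
  expect_error(resample(vol, c(0, 1, 1)), class = "cs_argument_error")
})

test_that("upsampling then downsampling approximately restores a smooth volume", {
  ph <- generate_phantom(tiny_spec(), seed = 8)
  vol <- ph$volume
  fine <- resample(vol, c(0.5, 0.5, 0.5))
  back <- resample(fine, c(1, 1, 1))
  expect_identical(dim(back$data), dim(vol$data))
  expect_lt(mean(abs(back$data - vol$data)), 2 * phantom_spec()$noise_sd)
})

test_that("z-score normalization has unit moments and affine invariance", {
  vol <- random_volume(c(16, 16, 16), seed = 5)
  z <- zscore_normalize(vol)
  expect_lt(abs(mean(z$data)), 1e-5)
  expect_lt(abs(stats::sd(as.vector(z$data)) - 1), 1e-5)

  aff <- image_volume(3.2 * vol$data + 17, spacing = vol$spacing)
  z2 <- zscore_normalize(aff)
  expect_equal(z2$data, z$data, tolerance = 1e-10)

  flat <- image_volume(array(4, c(4, 4, 4)))
  expect_error(zscore_normalize(flat), class = "cs_normalization_error")
})

test_that("augmentation with zero probabilities is the identity and is deterministic", {
  ph <- generate_phantom(tiny_spec(), seed = 12)
  off <- augment_params(apply_probs = c(rotation = 0, scale = 0, elastic = 0,
                                        gamma = 0, inversion = 0))
  out <- augment(ph$volume, ph$lesion_mask, off, seed = 1)
  expect_identical(out$volume$data, ph$volume$data)
  expect_identical(out$masks$data, ph$lesion_mask$data)

  on <- augment_params()
  a <- augment(ph$volume, ph$lesion_mask, on, seed = 42)
  b <- augment(ph$volume, ph$lesion_mask, on, seed = 42)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$masks$data, b$masks$data)
  c <- augment(ph$volume, ph$lesion_mask, on, seed = 43)
  expect_false(identical(c$volume$data, a$volume$data))
})

test_that("pure rotation approximately conserves mask volume", {
  ph <- generate_phantom(tiny_spec(), seed = 9)
  rot_only <- augment_params(rotation_range = 90,
                             apply_probs = c(rotation = 1, scale = 0,
                                             elastic = 0, gamma = 0, inversion = 0))
  before <- sum(ph$gland_mask$data)
  out <- augment(ph$volume, ph$gland_mask, rot_only, seed = 3)
  after <- sum(out$masks$data)
  expect_lt(abs(after - before) / before, 0.05)
})

test_that("spatial augmentation preserves the lesion-within-gland pairing", {
  ph <- generate_phantom(tiny_spec(), seed = 14)
  params <- augment_params(apply_probs = c(rotation = 1, scale = 1, elastic = 1,
                                           gamma = 0, inversion = 1))
  for (s in c(1, 7, 23)) {
    out <- augment(ph$volume, list(gland = ph$gland_mask, lesion = ph$lesion_mask),
                   params, seed = s)
    expect_true(all(out$masks$gland$data[out$masks$lesion$data > 0] > 0))
  }
})

test_that("augment rejects misaligned inputs", {
  vol <- random_volume(c(8, 8, 8))
  bad <- random_mask(c(6, 6, 6))
  expect_error(augment(vol, bad, augment_params(), 1), class = "cs_alignment_error")
})
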