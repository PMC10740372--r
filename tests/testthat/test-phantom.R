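test_that("phantom generation is deterministic and satisfies mask invariants", {
  spec <- tiny_spec()
  a <- generate_phantom(spec, seed = 5, center = 1L)
  b <- generate_phantom(spec, seed = 5, center = 1L)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$lesion_mask$data, b$lesion_mask$data)

  for (s in c(2, 9, 31)) {
    ph <- generate_phantom(spec, seed = s)
    # lesion inside gland, heart disjoint from gland
    expect_true(all(ph$gland_mask$data[ph$lesion_mask$data > 0] > 0))
    expect_equal(sum(ph$heart_mask$data > 0 & ph$gland_mask$data > 0), 0)
    expect_gt(sum(ph$lesion_mask$data), 0)
    expect_gt(sum(ph$heart_mask$data), 0)
  }
})

test_that("single-lesion spec yields exactly one lesion component", {
  ph <- generate_phantom(tiny_spec(), seed = 17)
  lab <- cascadeseg:::label_components(ph$lesion_mask$data > 0)
  expect_equal(length(unique(lab[lab > 0])), 1L)
})

test_that("gland ground truth is one connected component (midline overlap)", {
  for (s in 1:3) {
    ph <- generate_phantom(phantom_spec(), seed = s)
    lab <- cascadeseg:::label_components(ph$gland_mask$data > 0)
    expect_equal(length(unique(lab[lab > 0])), 1L)
  }
})

test_that("lesion and heart intensities are confusable (within one tissue SD)", {
  spec <- phantom_spec()
  # spec-level invariant
  expect_lt(abs(spec$intensity_means[["lesion"]] - spec$intensity_means[["heart"]]),
            spec$intensity_sd)
  # realized phantoms: mean voxel intensities of the two tissues stay within
  # one tissue SD of each other
  diffs <- vapply(11:15, function(s) {
    ph <- generate_phantom(spec, seed = s)
    les <- mean(ph$volume$data[ph$lesion_mask$data > 0])
    hrt <- mean(ph$volume$data[ph$heart_mask$data > 0])
    abs(les - hrt) / spec$intensity_sd
  }, numeric(1))
  expect_lt(mean(diffs), 1)
})

test_that("cohort generation writes files, links them, and is deterministic", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(4, tiny_spec(), seed = 21, out_dir = dir)
  expect_equal(nrow(co), 4L)
  expect_true(all(file.exists(co$image_path)))
  expect_true(all(file.exists(co$lesion_mask_path)))
  back <- load_cohort(file.path(dir, "cohort.csv"))
  expect_equal(back$pcr_label, co$pcr_label)

  dir2 <- withr::local_tempdir()
  co2 <- generate_cohort(4, tiny_spec(), seed = 21, out_dir = dir2)
  expect_equal(co2$ki67, co$ki67)
  expect_equal(co2$pcr_label, co$pcr_label)
  expect_error(generate_cohort(0, tiny_spec()), class = "cs_argument_error")
})

test_that("null outcome model gives prevalence near one half", {
  dir <- withr::local_tempdir()
  null_model <- outcome_model(intercept = 0, coef_her2 = 0, coef_er = 0,
                              coef_pr = 0, coef_ki67 = 0, coef_lesion_volume = 0)
  co <- generate_cohort(50, tiny_spec(), outcome = null_model, seed = 33,
                        out_dir = dir)
  # binomial 99% bounds for n = 50, p = 0.5
  expect_gte(sum(co$pcr_label), qbinom(0.005, 50, 0.5))
  expect_lte(sum(co$pcr_label), qbinom(0.995, 50, 0.5))
})

test_that("a strong negative ki67 coefficient induces negative correlation", {
  dir <- withr::local_tempdir()
  m <- outcome_model(intercept = 1, coef_her2 = 0, coef_er = 0, coef_pr = 0,
                     coef_ki67 = -4, coef_lesion_volume = 0)
  co <- generate_cohort(300, tiny_spec(c(24, 24, 24)), outcome = m, seed = 7,
                        out_dir = dir)
  expect_lt(cor(co$ki67, co$pcr_label), 0)
})

test_that("mean predicted probability matches empirical prevalence", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(300, tiny_spec(c(24, 24, 24)), seed = 13, out_dir = dir)
  p_bar <- mean(co$p_pcr_true)
  se <- sqrt(p_bar * (1 - p_bar) / nrow(co))
  expect_lt(abs(mean(co$pcr_label) - p_bar), 3 * se)
})

test_that("center_mix = 0 puts every sample in the first center", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(6, tiny_spec(), center_mix = 0, seed = 2, out_dir = dir)
  expect_true(all(co$center_id == "C1"))
})

test_that("the two centers differ by KS distance > 0.2 in gland intensities", {
  spec <- phantom_spec()
  ks <- c()
  for (s in 1:3) {
    a <- generate_phantom(spec, seed = s, center = 1L)
    b <- generate_phantom(spec, seed = s + 100, center = 2L)
    ks <- c(ks, ks_distance(a$volume$data[a$gland_mask$data > 0],
                            b$volume$data[b$gland_mask$data > 0]))
  }
  expect_gt(mean(ks), 0.2)
})
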