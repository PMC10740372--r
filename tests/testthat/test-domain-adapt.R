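test_that("histograms count quantized levels and conserve voxel totals", {
  v <- image_volume(array(c(rep(0, 4), rep(255, 4)), c(2, 2, 2)))
  h <- compute_histogram(v, 256L)
  expect_equal(h$counts[1], 4)
  expect_equal(h$counts[256], 4)
  expect_equal(sum(h$counts), 8)

  r <- random_volume(c(9, 9, 9), seed = 5)
  hr <- compute_histogram(r, 64L)
  expect_equal(sum(hr$counts), prod(dim(r$data)))

  flat <- image_volume(array(7, c(3, 3, 3)))
  hf <- compute_histogram(flat, 256L)
  expect_equal(hf$counts[1], 27)
  expect_equal(sum(hf$counts[-1]), 0)
})

test_that("equalization map matches the cumulative-sum formula", {
  h <- structure(list(counts = rep(1, 4), L = 4L, total = 4, range = c(0, 3)),
                 class = "gray_histogram")
  expect_equal(equalization_map(h)$s, c(0.75, 1.5, 2.25, 3))

  h0 <- structure(list(counts = c(100, rep(0, 255)), L = 256L, total = 100,
                       range = c(0, 1)), class = "gray_histogram")
  expect_equal(equalization_map(h0)$s[1], 255)

  # oracle equivalence on random histograms: s_k = (L-1)/total * sum_{j<=k} n_j
  for (seed in 1:20) {
    set.seed(seed)
    L <- sample(4:64, 1)
    counts <- rpois(L, lambda = runif(1, 0.5, 20))
    if (sum(counts) == 0) counts[1] <- 1
    h <- structure(list(counts = counts, L = L, total = sum(counts),
                        range = c(0, 100)), class = "gray_histogram")
    s <- equalization_map(h)$s
    brute <- vapply(seq_len(L), function(k) {
      acc <- 0
      for (j in seq_len(k)) acc <- acc + counts[j]
      (L - 1) / sum(counts) * acc
    }, numeric(1))
    expect_equal(s, brute, tolerance = 1e-12)
    expect_true(all(diff(s) >= 0))
    expect_equal(s[L], L - 1, tolerance = 1e-6)
  }
})

test_that("matching a volume to its own histogram is near-idempotent", {
  ph <- generate_phantom(tiny_spec(), seed = 3)
  L <- 256L
  h <- compute_histogram(ph$volume, L)
  matched <- match_histogram(ph$volume, h)
  bin_width <- diff(h$range) / L
  expect_lte(max(abs(matched$data - ph$volume$data)), bin_width + 1e-9)
})

test_that("matching preserves geometry and monotone intensity order", {
  a <- generate_phantom(tiny_spec(), seed = 4, center = 1L)
  b <- generate_phantom(tiny_spec(), seed = 5, center = 2L)
  ref <- compute_histogram(b$volume)
  m <- match_histogram(a$volume, ref)
  expect_identical(dim(m$data), dim(a$volume$data))
  expect_equal(m$spacing, a$volume$spacing)
  set.seed(1)
  i <- sample(length(m$data), 4000, replace = TRUE)
  j <- sample(length(m$data), 4000, replace = TRUE)
  le <- a$volume$data[i] <= a$volume$data[j]
  expect_true(all(m$data[i][le] <= m$data[j][le] + 1e-9))
})

test_that("matched output follows the reference CDF (one-sample KS < 0.05)", {
  src <- generate_phantom(phantom_spec(), seed = 6, center = 1L)
  ref_ph <- generate_phantom(phantom_spec(), seed = 7, center = 2L)
  ref <- compute_histogram(ref_ph$volume)
  m <- match_histogram(src$volume, ref)
  ref_cdf <- cumsum(ref$counts) / ref$total
  centers <- cascadeseg:::level_centers(ref)
  emp <- vapply(centers, function(cc) mean(m$data <= cc + 1e-9), numeric(1))
  expect_lt(max(abs(emp - ref_cdf)), 0.05)
})

test_that("L mismatch is rejected", {
  v <- random_volume(seed = 8)
  h <- compute_histogram(v, 64L)
  expect_error(match_histogram(v, h, L = 128L), class = "cs_argument_error")
})

test_that("histogram JSON round-trips", {
  dir <- withr::local_tempdir()
  h <- compute_histogram(random_volume(seed = 9), 32L)
  f <- file.path(dir, "h.json")
  save_histogram(h, f)
  back <- load_histogram(f)
  expect_equal(back$counts, h$counts)
  expect_equal(back$L, h$L)
  expect_equal(back$range, h$range, tolerance = 1e-12)
})

test_that("cohort matching doubles the set, is seeded, and leaves masks alone", {
  dir <- withr::local_tempdir()
  train <- generate_cohort(3, tiny_spec(), center_mix = 0, seed = 10,
                           out_dir = file.path(dir, "train"))
  test <- generate_cohort(2, tiny_spec(), center_mix = 1, seed = 11,
                          out_dir = file.path(dir, "test"))
  hists <- lapply(test$image_path, function(p) compute_histogram(load_volume(p)))
  aug <- augment_cohort_by_matching(train, hists, out_dir = file.path(dir, "hm"),
                                    seed = 5)
  expect_equal(nrow(aug), 2 * nrow(train))
  expect_equal(sum(grepl("_hm$", aug$patient_id)), nrow(train))
  # masks untouched: matched rows reference the same mask files
  expect_identical(aug$lesion_mask_path[4:6], train$lesion_mask_path)

  aug2 <- augment_cohort_by_matching(train, hists, out_dir = file.path(dir, "hm2"),
                                     seed = 5)
  expect_identical(attr(aug, "histogram_picks"), attr(aug2, "histogram_picks"))
  expect_error(augment_cohort_by_matching(train, list()), class = "cs_argument_error")
})

test_that("matching reduces the cross-center KS distance of gland intensities", {
  spec <- phantom_spec()
  n_per <- 6
  ks_raw <- c(); ks_matched <- c()
  for (i in seq_len(n_per)) {
    a <- generate_phantom(spec, seed = 100 + i, center = 1L)
    b <- generate_phantom(spec, seed = 200 + i, center = 2L)
    ref <- compute_histogram(b$volume)
    m <- match_histogram(a$volume, ref)
    gl <- a$gland_mask$data > 0
    bg <- b$gland_mask$data > 0
    ks_raw <- c(ks_raw, ks_distance(a$volume$data[gl], b$volume$data[bg]))
    ks_matched <- c(ks_matched, ks_distance(m$data[gl], b$volume$data[bg]))
  }
  expect_lt(mean(ks_matched), mean(ks_raw))
  expect_lt(mean(ks_matched) / mean(ks_raw), 0.5)
})
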