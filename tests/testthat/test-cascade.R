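test_that("patch grids tile with half-patch stride and end alignment", {
  g <- make_patch_grid(c(128, 128, 128), 64L)
  expect_equal(sort(unique(g$origins[, 1])), c(0, 32, 64))
  g1 <- make_patch_grid(c(64, 64, 64), 64L)
  expect_equal(nrow(g1$origins), 1L)
  expect_equal(unname(g1$origins[1, ]), c(0, 0, 0))
  g2 <- make_patch_grid(c(100, 64, 64), 64L)
  expect_equal(sort(unique(g2$origins[, 1])), c(0, 32, 36))
  expect_error(make_patch_grid(c(32, 32, 32), 64L), class = "cs_argument_error")
})

test_that("every voxel is covered by at least one patch (coverage oracle)", {
  set.seed(13)
  for (i in 1:100) {
    shape <- sample(16:80, 3, replace = TRUE)
    patch <- 2L * sample(4:(min(shape) %/% 2L), 1)
    g <- make_patch_grid(shape, patch)
    covered <- array(FALSE, shape)
    for (r in seq_len(nrow(g$origins))) {
      o <- g$origins[r, ]
      covered[(o[1] + 1):(o[1] + patch), (o[2] + 1):(o[2] + patch),
              (o[3] + 1):(o[3] + patch)] <- TRUE
    }
    expect_true(all(covered))
    # consecutive origins along each axis differ by the stride
    for (a in 1:3) {
      ax <- sort(unique(g$origins[, a]))
      if (length(ax) > 2) expect_true(all(diff(ax)[1:(length(ax) - 2)] == patch / 2))
    }
  }
})

test_that("the Gaussian weight map peaks centrally, is symmetric, and floors", {
  w <- gaussian_weight_map(32L, 1 / 8)
  expect_equal(which.max(w), which(w == max(w))[1])
  ctr <- c(16, 16, 16)
  expect_gte(w[ctr[1], ctr[2], ctr[3]], max(w) - 1e-12)
  expect_equal(w, w[32:1, , ])
  expect_equal(w, w[, , 32:1])
  expect_true(all(w > 0))
  expect_lt(w[1, 1, 1] / max(w), 0.01)
})

test_that("fusing a constant-output model returns that constant everywhere", {
  cfg <- segnet_config(depth = 2L, base_channels = 2L, patch_size = 8L)
  m <- build_segnet(cfg, seed = 2)
  # force a constant head: zero weights, fixed bias -> constant class probs
  m$head$params$W[] <- 0
  m$head$params$b <- c(1.3, 0.2)
  p_const <- cascadeseg:::row_softmax(matrix(c(1.3, 0.2), 1))
  vol <- random_volume(c(20, 12, 16), seed = 4)
  g <- make_patch_grid(dim(vol$data), 8L)
  probs <- sliding_window_predict(m, vol, g)
  expect_equal(max(abs(probs[, , , 1] - p_const[1])), 0, tolerance = 1e-10)
  expect_equal(max(abs(probs[, , , 2] - p_const[2])), 0, tolerance = 1e-10)
  # probabilities sum to one per voxel
  expect_equal(range(probs[, , , 1] + probs[, , , 2]), c(1, 1), tolerance = 1e-5)
})

test_that("single-patch fusion equals the bare model output", {
  cfg <- segnet_config(depth = 2L, base_channels = 2L, patch_size = 8L)
  m <- build_segnet(cfg, seed = 6)
  vol <- random_volume(c(8, 8, 8), seed = 7)
  g <- make_patch_grid(c(8, 8, 8), 8L)
  fused <- sliding_window_predict(m, vol, g)
  direct <- cascadeseg:::segnet_forward(m, vol$data)$probs
  expect_equal(matrix(fused, ncol = 2), direct, tolerance = 1e-10)
})

test_that("fused probabilities are convex combinations of patch outputs", {
  cfg <- segnet_config(depth = 2L, base_channels = 2L, patch_size = 8L)
  m <- build_segnet(cfg, seed = 8)
  vol <- random_volume(c(12, 12, 12), seed = 9)
  g <- make_patch_grid(dim(vol$data), 8L)
  fused <- sliding_window_predict(m, vol, g)
  # per-voxel min/max over contributing patches bounds the fused value
  p <- 8L
  lo <- array(Inf, dim(vol$data)); hi <- array(-Inf, dim(vol$data))
  for (r in seq_len(nrow(g$origins))) {
    o <- g$origins[r, ]
    patch <- vol$data[(o[1] + 1):(o[1] + p), (o[2] + 1):(o[2] + p), (o[3] + 1):(o[3] + p)]
    pr <- array(cascadeseg:::segnet_forward(m, patch)$probs[, 1], c(p, p, p))
    ix <- (o[1] + 1):(o[1] + p); iy <- (o[2] + 1):(o[2] + p); iz <- (o[3] + 1):(o[3] + p)
    lo[ix, iy, iz] <- pmin(lo[ix, iy, iz], pr)
    hi[ix, iy, iz] <- pmax(hi[ix, iy, iz], pr)
  }
  expect_true(all(fused[, , , 1] >= lo - 1e-9))
  expect_true(all(fused[, , , 1] <= hi + 1e-9))
})

test_that("largest_component keeps exactly the biggest blob deterministically", {
  m <- array(0L, c(12, 12, 12))
  m[2:3, 2:6, 2] <- 1L           # 10 voxels
  m[9:10, 9, 9] <- 1L            # 2 voxels (moved apart from the big blob)
  m[6, 11, 11] <- 1L             # 1 voxel
  msk <- label_mask(m)
  keep <- largest_component(msk)
  expect_equal(sum(keep$data), 10L)
  expect_true(all(keep$data[2:3, 2:6, 2] == 1L))

  single <- largest_component(label_mask(array(as.integer(
    cascadeseg:::in_ellipsoid(cascadeseg:::coord_grid(c(10, 10, 10)),
                              c(5, 5, 5), c(3, 3, 3))), c(10, 10, 10))))
  expect_equal(sum(single$data > 0), sum(single$data))

  # equal-size tie: exactly one survives, and reruns agree
  tie <- array(0L, c(10, 10, 10))
  tie[2:3, 2, 2] <- 1L
  tie[8:9, 8, 8] <- 1L
  r1 <- largest_component(label_mask(tie))
  r2 <- largest_component(label_mask(tie))
  expect_equal(sum(r1$data), 2L)
  expect_identical(r1$data, r2$data)

  empty <- label_mask(array(0L, c(4, 4, 4)))
  expect_warning(out <- largest_component(empty))
  expect_true(isTRUE(attr(out, "empty")))
  expect_equal(sum(out$data), 0L)
})

test_that("post-processing never increases the foreground", {
  for (s in 1:5) {
    m <- random_mask(c(8, 8, 8), p = 0.25, seed = 300 + s)
    suppressWarnings(keep <- largest_component(m))
    expect_lte(sum(keep$data), sum(m$data))
    expect_true(all(m$data[keep$data > 0] > 0))
  }
})

test_that("crop_to_mask returns the right box and offset round-trips", {
  vol <- random_volume(c(10, 10, 10), seed = 11)
  full <- label_mask(array(1L, c(10, 10, 10)))
  cr <- crop_to_mask(vol, full, margin_mm = 0)
  expect_identical(cr$volume$data, vol$data)
  expect_equal(cr$offset, c(0L, 0L, 0L))

  single <- array(0L, c(10, 10, 10)); single[6, 6, 6] <- 1L
  cr2 <- crop_to_mask(vol, label_mask(single), margin_mm = 0)
  expect_identical(dim(cr2$volume$data), c(1L, 1L, 1L))
  expect_equal(cr2$offset, c(5L, 5L, 5L))
  expect_equal(cr2$volume$data[1, 1, 1], vol$data[6, 6, 6])

  # back-mapping reproduces the original intensities
  blob <- array(0L, c(10, 10, 10)); blob[3:6, 4:7, 2:5] <- 1L
  cr3 <- crop_to_mask(vol, label_mask(blob), margin_mm = 1)
  o <- cr3$offset; d <- dim(cr3$volume$data)
  expect_identical(vol$data[(o[1] + 1):(o[1] + d[1]), (o[2] + 1):(o[2] + d[2]),
                            (o[3] + 1):(o[3] + d[3])], cr3$volume$data)
  expect_error(crop_to_mask(vol, label_mask(array(0L, c(10, 10, 10)))),
               class = "cs_crop_error")
})

test_that("spherical dilation matches the discrete ball and is monotone", {
  m <- array(0L, c(15, 15, 15)); m[8, 8, 8] <- 1L
  msk <- label_mask(m)
  expect_identical(dilate_lesion(msk, 0)$data, msk$data)
  d5 <- dilate_lesion(msk, 5)
  # brute-force discrete ball voxel count
  offs <- expand.grid(-5:5, -5:5, -5:5)
  ball <- sum(rowSums(offs^2) <= 25)
  expect_equal(sum(d5$data), ball)
  for (r in c(1, 2, 3)) {
    big <- random_mask(c(12, 12, 12), p = 0.1, seed = r)
    dd <- dilate_lesion(big, r)
    expect_true(all(dd$data[big$data > 0] > 0))
    expect_gte(sum(dd$data), sum(big$data))
  }
  expect_error(dilate_lesion(msk, -1), class = "cs_argument_error")
})
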