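test_that("fusion config ties FC widths to image channels and validates", {
  cfg <- fusion_config(image_channels = c(4, 4, 8, 8, 8), input_cube = 16L)
  expect_equal(cfg$fc_widths, cfg$image_channels)
  expect_error(fusion_config(image_channels = c(4, 4), input_cube = 16L),
               class = "cs_config_error")
  expect_error(fusion_config(input_cube = 20L), class = "cs_config_error")
})

test_that("forward pass yields two probabilities summing to one, deterministically", {
  cfg <- fusion_config(image_channels = c(2, 2, 4, 4, 4), input_cube = 16L,
                       dropout = 0)
  m <- build_fusion_net(cfg, seed = 4)
  x <- array(rnorm(16^3), c(16, 16, 16))
  mk <- c(1, 0, 1, 0.3)
  fw <- cascadeseg:::fusion_forward(m, x, mk)
  expect_equal(dim(fw$probs), c(1L, 2L))
  expect_equal(sum(fw$probs), 1, tolerance = 1e-9)
  expect_true(all(fw$probs >= 0))
  fw2 <- cascadeseg:::fusion_forward(m, x, mk)
  expect_identical(fw$probs, fw2$probs)
  m2 <- build_fusion_net(cfg, seed = 4)
  expect_identical(cascadeseg:::fusion_forward(m2, x, mk)$probs, fw$probs)
})

test_that("all-ones gates reduce the network to the ungated image branch", {
  cfg <- fusion_config(image_channels = c(2, 2, 4, 4, 4), input_cube = 16L,
                       dropout = 0)
  m <- build_fusion_net(cfg, seed = 6)
  x <- array(rnorm(16^3), c(16, 16, 16))
  a <- cascadeseg:::fusion_forward(m, x, c(1, 0, 1, 0.2), force_gates = 1)$logits
  b <- cascadeseg:::fusion_forward(m, x, c(0, 1, 0, 0.9), force_gates = 1)$logits
  expect_identical(a, b)  # markers cannot influence a fully forced network
})

test_that("all-zero stage-1 gates make the logits image-blind", {
  cfg <- fusion_config(image_channels = c(2, 2, 4, 4, 4), input_cube = 16L,
                       dropout = 0)
  m <- build_fusion_net(cfg, seed = 7)
  mk <- c(1, 1, 0, 0.5)
  zero1 <- list(0, NULL, NULL, NULL, NULL)
  a <- cascadeseg:::fusion_forward(m, array(rnorm(16^3), c(16, 16, 16)), mk,
                                   force_gates = zero1)$logits
  b <- cascadeseg:::fusion_forward(m, array(rnorm(16^3), c(16, 16, 16)), mk,
                                   force_gates = zero1)$logits
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("crop_resample_lesion returns a z-scored cube and identity resample", {
  ph <- generate_phantom(tiny_spec(), seed = 5)
  crop <- crop_resample_lesion(ph$volume, ph$lesion_mask, cube = 16L)
  expect_identical(dim(crop$data), c(16L, 16L, 16L))
  expect_lt(abs(mean(crop$data)), 1e-9)
  expect_lt(abs(stats::sd(as.vector(crop$data)) - 1), 1e-9)

  # mask spanning exactly cube^3 voxels: resampling is the identity (up to
  # the z-score affine)
  vol <- random_volume(c(24, 24, 24), seed = 9)
  m <- array(0L, c(24, 24, 24)); m[5:12, 7:14, 3:10] <- 1L
  crop8 <- crop_resample_lesion(vol, label_mask(m), cube = 8L)
  ref <- vol$data[5:12, 7:14, 3:10]
  ref <- (ref - mean(ref)) / stats::sd(as.vector(ref))
  expect_equal(crop8$data, ref, tolerance = 1e-10)

  expect_error(crop_resample_lesion(vol, label_mask(array(0L, c(24, 24, 24)))),
               class = "cs_crop_error")
})

test_that("predict_pcr enforces the crop shape and the 0.5 threshold", {
  cfg <- fusion_config(image_channels = c(2, 2, 4, 4, 4), input_cube = 16L,
                       dropout = 0)
  m <- build_fusion_net(cfg, seed = 8)
  crop <- array(rnorm(16^3), c(16, 16, 16))
  out <- predict_pcr(m, crop, c(1, 0, 0, 0.4), "P1")
  expect_true(out$p_pcr >= 0 && out$p_pcr <= 1)
  expect_equal(out$predicted_label, as.integer(out$p_pcr >= 0.5))
  out2 <- predict_pcr(m, crop, c(1, 0, 0, 0.4), "P1")
  expect_identical(out$p_pcr, out2$p_pcr)
  expect_error(predict_pcr(m, array(0, c(8, 8, 8)), c(1, 0, 0, 0.4)),
               class = "cs_argument_error")
})

test_that("fusion training decreases the loss, is seeded, and rejects one-class labels", {
  set.seed(31)
  n <- 24; cube <- 16L
  crops <- array(rnorm(cube^3 * n), c(cube, cube, cube, n))
  markers <- cbind(rbinom(n, 1, 0.5), rbinom(n, 1, 0.5), rbinom(n, 1, 0.5),
                   runif(n))
  labels <- as.integer(markers[, 1] == 1)  # depends only on her2
  cfg <- fusion_config(image_channels = c(2, 2, 4, 4, 4), input_cube = cube,
                       dropout = 0)
  m <- train_fusion(build_fusion_net(cfg, 2), crops, markers, labels,
                    epochs = 10L, batch_size = 8L, seed = 2)
  cv <- attr(m, "curve")
  expect_lt(cv$loss[10], cv$loss[1])

  m2 <- train_fusion(build_fusion_net(cfg, 2), crops, markers, labels,
                     epochs = 10L, batch_size = 8L, seed = 2)
  expect_equal(tail(attr(m2, "curve")$loss, 1), tail(cv$loss, 1),
               tolerance = 1e-12)

  expect_error(train_fusion(build_fusion_net(cfg, 2), crops, markers,
                            rep(1L, n), epochs = 2L),
               class = "cs_training_error")
})

test_that("marker-only signal is recovered when images are pure noise", {
  # labels depend only on the markers (a strong, clean logistic link); the
  # fused model must recover the signal through the gating pathway
  set.seed(77)
  n_tr <- 200; n_te <- 100; cube <- 16L
  n <- n_tr + n_te
  mk_all <- cbind(rbinom(n, 1, 0.5), rbinom(n, 1, 0.5), rbinom(n, 1, 0.5),
                  runif(n))
  p <- plogis(4 * mk_all[, 1] + 2 * mk_all[, 2] - 5 * mk_all[, 4] + 0.2)
  y <- rbinom(n, 1, p)
  crops <- array(rnorm(cube^3 * n), c(cube, cube, cube, n))
  cfg <- fusion_config(image_channels = c(8, 8, 8, 8, 8), input_cube = cube,
                       dropout = 0.3)
  m <- train_fusion(build_fusion_net(cfg, 3), crops[, , , 1:n_tr],
                    mk_all[1:n_tr, ], y[1:n_tr], epochs = 150L,
                    batch_size = 8L, seed = 3)
  te_idx <- (n_tr + 1):n
  pred <- predict_pcr_cohort(m, list(crops = crops[, , , te_idx],
                                     markers = mk_all[te_idx, ],
                                     labels = y[te_idx],
                                     ids = as.character(te_idx)))
  expect_gt(auc(y[te_idx], pred$p_pcr), 0.75)
})

test_that("the dilation ablation harness produces the full report shape", {
  dir <- withr::local_tempdir()
  tr <- generate_cohort(10, tiny_spec(), seed = 41, out_dir = file.path(dir, "tr"))
  te <- generate_cohort(8, tiny_spec(), seed = 42, out_dir = file.path(dir, "te"))
  cfg <- fusion_config(image_channels = c(2, 2, 4, 4, 4), input_cube = 16L)
  rep <- dilation_ablation(tr, te, radii = c(0, 5, 10, 15), cube = 16L,
                           config = cfg, epochs = 2L, batch_size = 5L, seed = 1)
  expect_s3_class(rep, "cs_ablation_report")
  expect_equal(rep$radius, c(0, 5, 10, 15))
  expect_true(all(rep$accuracy >= 0 & rep$accuracy <= 1))
  expect_true(all(rep$auc >= 0 & rep$auc <= 1))
})
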