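test_that("segnet forward produces per-voxel softmax of the right shape", {
  cfg <- segnet_config(depth = 2L, base_channels = 4L, patch_size = 8L,
                       num_classes = 3L)
  m <- build_segnet(cfg, seed = 1)
  x <- array(rnorm(8^3), c(8, 8, 8))
  fw <- cascadeseg:::segnet_forward(m, x)
  expect_equal(dim(fw$probs), c(512L, 3L))
  expect_equal(rowSums(fw$probs), rep(1, 512), tolerance = 1e-5)
  expect_true(all(fw$probs >= 0 & fw$probs <= 1))
})

test_that("weight initialization and forward are deterministic given the seed", {
  cfg <- segnet_config(depth = 2L, base_channels = 4L, patch_size = 8L)
  m1 <- build_segnet(cfg, seed = 9)
  m2 <- build_segnet(cfg, seed = 9)
  expect_identical(m1$head$params$W, m2$head$params$W)
  expect_identical(m1$enc[[1]]$b1$conv$params$W, m2$enc[[1]]$b1$conv$params$W)
  x <- array(rnorm(8^3), c(8, 8, 8))
  expect_identical(cascadeseg:::segnet_forward(m1, x)$probs,
                   cascadeseg:::segnet_forward(m2, x)$probs)
  m3 <- build_segnet(cfg, seed = 10)
  expect_false(identical(m1$head$params$W, m3$head$params$W))
})

test_that("config validation rejects indivisible patch sizes", {
  expect_error(segnet_config(depth = 4L, patch_size = 20L),
               class = "cs_config_error")
  expect_s3_class(segnet_config(depth = 3L, patch_size = 20L), "segnet_config")
})

test_that("backprop matches finite differences through a linear head loss", {
  cfg <- segnet_config(depth = 2L, base_channels = 2L, patch_size = 8L)
  m <- build_segnet(cfg, seed = 3)
  layers <- cascadeseg:::segnet_layers(m)
  set.seed(21)
  x <- array(rnorm(8^3), c(8, 8, 8))
  R <- matrix(rnorm(512 * 2), 512, 2)
  lf <- function() sum(cascadeseg:::segnet_forward(m, x)$logits * R)
  cascadeseg:::zero_grads(layers)
  cascadeseg:::segnet_forward(m, x, training = TRUE)
  cascadeseg:::segnet_backward(m, R)
  eps <- 1e-5
  checked <- 0
  for (l in layers) {
    for (nm in names(l$grads)) {
      k <- sample(length(l$params[[nm]]), 1)
      w0 <- l$params[[nm]][k]
      l$params[[nm]][k] <- w0 + eps; lp <- lf()
      l$params[[nm]][k] <- w0 - eps; lm <- lf()
      l$params[[nm]][k] <- w0
      num <- (lp - lm) / (2 * eps)
      ana <- l$grads[[nm]][k]
      expect_equal(ana, num, tolerance = 1e-3)
      checked <- checked + 1
    }
  }
  expect_gt(checked, 10)
})

test_that("a short training run reduces the loss on tiny phantoms", {
  spec <- tiny_spec(c(24, 24, 24))
  ds <- lapply(1:4, function(i) {
    ph <- generate_phantom(spec, seed = 40 + i)
    list(img = zscore_normalize(ph$volume)$data, lab = ph$lesion_mask$data)
  })
  cfg <- segnet_config(depth = 2L, base_channels = 4L, patch_size = 16L)
  sched <- train_schedule(max_epochs = 8L)
  m <- train_segmenter(build_segnet(cfg, 5), ds, sched, seed = 5,
                       batches_per_epoch = 6L, batch_size = 2L)
  cv <- attr(m, "curve")
  expect_equal(nrow(cv), 8L)
  expect_lt(cv$loss[8], cv$loss[1])
  expect_true(all(cv$lr == 3e-4))  # too few epochs for any decay

  # determinism of the full training loop
  m2 <- train_segmenter(build_segnet(cfg, 5), ds, sched, seed = 5,
                        batches_per_epoch = 6L, batch_size = 2L)
  expect_equal(attr(m2, "curve")$loss, cv$loss, tolerance = 1e-12)
})

test_that("train_segmenter rejects empty datasets and inverted schedules", {
  cfg <- segnet_config(depth = 2L, base_channels = 2L, patch_size = 8L)
  m <- build_segnet(cfg, 1)
  expect_error(train_segmenter(m, list(), train_schedule()),
               class = "cs_argument_error")
  bad <- train_schedule()
  bad$lr_floor <- 1    # beyond what the constructor allows
  ds <- list(list(img = array(rnorm(512), c(8, 8, 8)),
                  lab = array(0L, c(8, 8, 8))))
  expect_error(train_segmenter(m, ds, bad), class = "cs_argument_error")
})
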