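# Multi-modal pCR prediction: a 5-stage 3D convolutional image branch whose
# feature maps are multiplicatively gated, stage by stage, by the outputs of
# a 5-layer fully connected branch fed the molecular markers
# (HER2, ER, PR, Ki-67).
#
# Gating semantics: after image stage s produces features with C_s channels,
# every channel c is multiplied by the c-th output of the s-th FC layer
# (broadcast over space); the FC widths are therefore tied to the stage
# channel counts.  With all gates forced to one the network reduces exactly
# to the ungated image branch; with stage-1 gates forced to zero the logits
# are independent of image content.

#' Fusion network configuration
#'
#' @param image_channels Integer vector of length 5: channels per image
#'   stage.  The FC widths of the marker branch are tied to these.
#' @param input_cube Edge length of the cubic lesion crop the network
#'   consumes.  The reference protocol uses 128; the desk-scale default is
#'   32.  Must be divisible by 16 (four 2x downsamplings).
#' @param num_stages Number of stages (fixed at 5).
#' @param markers Number of tabular inputs (4: HER2, ER, PR, Ki-67).
#' @param dropout Dropout rate on the pooled image features during
#'   training (regularizes the small-cohort image branch).
#' @return An object of class `fusion_config`.
#' @export
fusion_config <- function(image_channels = c(8, 16, 16, 32, 32),
                          input_cube = 32L, num_stages = 5L, markers = 4L,
                          dropout = 0.3) {
  assert_that(length(image_channels) == num_stages,
              "`image_channels` must have one entry per stage", "cs_config_error")
  assert_that(input_cube %% 2^(num_stages - 1) == 0,
              "`input_cube` must be divisible by 2^(num_stages-1)", "cs_config_error")
  assert_that(dropout >= 0 && dropout < 1, "`dropout` must lie in [0, 1)")
  structure(list(image_channels = as.integer(image_channels),
                 fc_widths = as.integer(image_channels),
                 input_cube = as.integer(input_cube),
                 num_stages = as.integer(num_stages),
                 markers = as.integer(markers),
                 dropout = dropout),
            class = "fusion_config")
}

#' Build the multi-modal fusion network
#'
#' Image branch: a convolutional stem then four residual stages with 2x
#' downsampling (a 3D residual backbone in the ResNet mold); marker branch:
#' five FC+ReLU layers whose outputs gate the image features after each
#' stage; head: global average pooling and a linear layer to 2-class
#' softmax.
#'
#' @param config A [fusion_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `fusion_net`.
#' @export
build_fusion_net <- function(config = fusion_config(), seed = 1L) {
  assert_that(inherits(config, "fusion_config"), "`config` must be a fusion_config")
  with_preserved_rng(seed, {
    ch <- config$image_channels
    S <- config$num_stages
    # ResNet-style stride-2 stem; later stages stop downsampling once the
    # spatial extent reaches one voxel
    stem <- list(conv = ly_conv(1L, ch[1], stride = 2L), norm = ly_inorm(ch[1]),
                 act = ly_lrelu())
    stem$conv$is_first <- TRUE
    down <- vector("list", S - 1)
    res <- vector("list", S - 1)
    dims_s <- max(config$input_cube %/% 2L, 1L)
    for (s in 2:S) {
      if (dims_s > 1L) {
        down[[s - 1]] <- ly_conv(ch[s - 1], ch[s], kernel = 2L, stride = 2L, pad = 0L)
        dims_s <- dims_s %/% 2L
      } else {
        down[[s - 1]] <- ly_conv(ch[s - 1], ch[s], kernel = 1L, stride = 1L, pad = 0L)
      }
      res[[s - 1]] <- list(conv1 = ly_conv(ch[s], ch[s]), norm1 = ly_inorm(ch[s]),
                           act1 = ly_lrelu(), conv2 = ly_conv(ch[s], ch[s]),
                           norm2 = ly_inorm(ch[s]), act_out = ly_lrelu())
    }
    fc <- vector("list", S)
    fc_act <- vector("list", S)
    for (s in seq_len(S)) {
      fc[[s]] <- ly_linear(if (s == 1) config$markers else ch[s - 1], ch[s])
      # start gates near the multiplicative identity: a ReLU gate that opens
      # at zero would annihilate the image features and kill all gradients
      fc[[s]]$params$b[] <- 1
      # leaky activation: a hard-ReLU gate that dies during training severs
      # the marker pathway permanently
      fc_act[[s]] <- ly_lrelu()
    }
    head <- ly_linear(ch[S], 2L)
    # small head init keeps initial logits near zero (loss ~ log 2); the
    # feature magnitudes grow through the residual stages and a He-scaled
    # head would start deep in softmax saturation
    head$params$W <- head$params$W * 0.01
    structure(list(config = config, stem = stem, down = down, res = res,
                   fc = fc, fc_act = fc_act, head = head, seed = seed,
                   cache = new.env(parent = emptyenv())),
              class = "fusion_net")
  })
}

fusion_layers <- function(model) {
  out <- list(model$stem$conv, model$stem$norm, model$stem$act)
  for (r in model$res) out <- c(out, list(r$conv1, r$norm1, r$act1, r$conv2, r$norm2, r$act_out))
  c(out, model$down, model$fc, model$fc_act, list(model$head))
}

#' @export
print.fusion_net <- function(x, ...) {
  cat(sprintf("<fusion_net> %d stages, channels %s, cube %d^3, %s parameters\n",
              x$config$num_stages, paste(x$config$image_channels, collapse = "/"),
              x$config$input_cube,
              format(n_params(fusion_layers(x)), big.mark = ",")))
  invisible(x)
}

apply_gate <- function(t, g) {
  nvox <- prod(t$dims)
  grp <- rep(seq_len(t$B), each = nvox)
  list(X = t$X * g[grp, , drop = FALSE], dims = t$dims, B = t$B, grp = grp)
}

resolve_gate <- function(force_gates, s, g, B) {
  f <- if (is.list(force_gates)) force_gates[[s]] else force_gates
  if (is.null(f)) return(g)
  matrix(f, B, ncol(g), byrow = length(f) == ncol(g))
}

# x: array (cube,cube,cube) or (...,B); markers: B x 4 matrix.
# force_gates: NULL, a scalar/vector recycled at every stage, or a list of
# per-stage overrides (NULL entries keep the learned gate).
fusion_forward <- function(model, x, markers, training = FALSE,
                           force_gates = NULL) {
  d <- dim(x)
  if (length(d) == 3L) { B <- 1L; dims <- d } else { B <- d[4]; dims <- d[1:3] }
  if (is.null(dim(markers))) markers <- matrix(markers, nrow = B, byrow = TRUE)
  S <- model$config$num_stages
  cc <- if (training) list() else NULL

  # marker branch: gates g_1..g_S
  g <- vector("list", S)
  m <- markers
  for (s in seq_len(S)) {
    m <- layer_forward(model$fc[[s]], m, training)
    m <- layer_forward(model$fc_act[[s]], m, training)
    g[[s]] <- resolve_gate(force_gates, s, m, B)
    m <- g[[s]]   # a forced gate also feeds the next FC layer
  }

  # image branch with per-stage gating
  t <- list(X = matrix(as.vector(x), ncol = 1L), dims = dims, B = B)
  t <- block_forward(model$stem, t, training)
  if (training) cc$pre_gate <- list(t$X)
  t <- apply_gate(t, g[[1]])
  for (s in 2:S) {
    t <- layer_forward(model$down[[s - 1]], t, training)
    r <- model$res[[s - 1]]
    t_in <- t
    u <- layer_forward(r$conv1, t, training)
    u <- layer_forward(r$norm1, u, training)
    u <- layer_forward(r$act1, u, training)
    u <- layer_forward(r$conv2, u, training)
    u <- layer_forward(r$norm2, u, training)
    t <- list(X = u$X + t_in$X, dims = u$dims, B = u$B)
    t <- layer_forward(r$act_out, t, training)
    if (training) cc$pre_gate[[s]] <- t$X
    t <- apply_gate(t, g[[s]])
  }

  nvox <- prod(t$dims)
  grp <- rep(seq_len(B), each = nvox)
  pooled <- rowsum(t$X, grp) / nvox
  drop_mask <- NULL
  if (training && model$config$dropout > 0) {
    # inverted dropout on the pooled features
    keep <- 1 - model$config$dropout
    drop_mask <- matrix(stats::rbinom(length(pooled), 1, keep) / keep,
                        nrow(pooled), ncol(pooled))
    pooled <- pooled * drop_mask
  }
  logits <- layer_forward(model$head, pooled, training)
  probs <- row_softmax(logits)
  if (training) {
    cc$gates <- g
    cc$dims_last <- t$dims
    cc$force_gates <- force_gates
    cc$drop_mask <- drop_mask
    model$cache$fw <- cc
  }
  list(probs = probs, logits = logits, B = B)
}

fusion_backward <- function(model, g_logits) {
  cc <- model$cache$fw
  S <- model$config$num_stages
  g_pool <- layer_backward(model$head, g_logits)
  if (!is.null(cc$drop_mask)) g_pool <- g_pool * cc$drop_mask
  nvox <- prod(cc$dims_last)
  B <- nrow(g_pool)
  grp <- rep(seq_len(B), each = nvox)
  gt <- g_pool[grp, , drop = FALSE] / nvox

  g_gate <- vector("list", S)   # gradients w.r.t. the gate vectors
  for (s in S:2) {
    pre <- cc$pre_gate[[s]]
    g_gate[[s]] <- rowsum(gt * pre, rep(seq_len(B), each = nrow(pre) / B))
    gt <- gt * cc$gates[[s]][rep(seq_len(B), each = nrow(pre) / B), , drop = FALSE]
    r <- model$res[[s - 1]]
    gt <- layer_backward(r$act_out, gt)
    gu <- layer_backward(r$norm2, gt)
    gu <- layer_backward(r$conv2, gu)
    gu <- layer_backward(r$act1, gu)
    gu <- layer_backward(r$norm1, gu)
    gu <- layer_backward(r$conv1, gu)
    gt <- gt + gu                  # residual skip
    gt <- layer_backward(model$down[[s - 1]], gt)
  }
  pre <- cc$pre_gate[[1]]
  g_gate[[1]] <- rowsum(gt * pre, rep(seq_len(B), each = nrow(pre) / B))
  gt <- gt * cc$gates[[1]][rep(seq_len(B), each = nrow(pre) / B), , drop = FALSE]
  gt <- layer_backward(model$stem$act, gt)
  gt <- layer_backward(model$stem$norm, gt)
  invisible(layer_backward(model$stem$conv, gt))

  # marker branch: gate s feeds both the image gating and FC layer s+1
  gm <- NULL
  for (s in S:1) {
    forced <- if (is.list(cc$force_gates)) !is.null(cc$force_gates[[s]]) else !is.null(cc$force_gates)
    gtot <- g_gate[[s]]
    if (!is.null(gm)) gtot <- gtot + gm
    if (forced) gtot <- gtot * 0   # a forced gate blocks the gradient
    gtot <- layer_backward(model$fc_act[[s]], gtot)
    gm <- layer_backward(model$fc[[s]], gtot)
  }
  model$cache$fw <- NULL
  invisible(NULL)
}

#' Crop the lesion region and resample it to a fixed cube
#'
#' Bounding-box crop of the (possibly dilated) lesion mask, trilinearly
#' resampled to `cube^3` voxels and z-score normalized.  With
#' `mask_background = TRUE`, voxels outside the mask are zeroed after
#' normalization (a hard-masked lesion-only input).
#'
#' @param vol An [image_volume()].
#' @param lesion_mask A nonempty aligned binary [label_mask()].
#' @param cube Output edge length in voxels.
#' @param mask_background Zero out non-lesion voxels (default `FALSE`:
#'   plain box crop).
#' @return An [image_volume()] of shape `cube^3` with unit spacing.
#' @export
crop_resample_lesion <- function(vol, lesion_mask, cube = 32L,
                                 mask_background = FALSE) {
  if (!any(lesion_mask$data > 0)) stop_cs("lesion mask is empty", "cs_crop_error")
  bb <- mask_bbox(lesion_mask$data > 0)
  take <- function(a) a[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3], drop = FALSE]
  box <- take(vol$data)
  bd <- dim(box)
  coords <- coord_grid(c(cube, cube, cube))
  for (a in 1:3) {
    coords[, a] <- if (cube > 1) coords[, a] * (bd[a] - 1) / (cube - 1) else (bd[a] - 1) / 2
  }
  out <- array(sample_trilinear(box, coords), dim = c(cube, cube, cube))
  s <- stats::sd(as.vector(out))
  if (!is.finite(s) || s == 0) stop_cs("degenerate lesion crop (zero variance)", "cs_crop_error")
  out <- (out - mean(out)) / s
  if (mask_background) {
    mbox <- take(lesion_mask$data)
    m <- array(sample_nearest(mbox, coords), dim = c(cube, cube, cube))
    out <- out * (m > 0)
  }
  image_volume(out, spacing = c(1, 1, 1))
}

#' Prepare fusion-model inputs from a cohort table
#'
#' Loads each patient's image and lesion mask, optionally dilates the mask
#' with a spherical kernel, and produces the fixed-size z-scored lesion
#' crops plus the encoded marker matrix and labels.
#'
#' @param cohort Cohort tibble (see [load_cohort()]).
#' @param cube Crop edge length.
#' @param dilate_radius Spherical dilation radius in voxels (0 = none).
#' @param mask_background Passed to [crop_resample_lesion()].
#' @return A list with `crops` (4D array `(cube,cube,cube,n)`), `markers`
#'   (`n x 4`), `labels`, `ids`.
#' @export
prepare_fusion_inputs <- function(cohort, cube = 32L, dilate_radius = 0L,
                                  mask_background = FALSE) {
  n <- nrow(cohort)
  crops <- array(0, c(cube, cube, cube, n))
  markers <- matrix(0, n, 4)
  for (i in seq_len(n)) {
    vol <- load_volume(cohort$image_path[i])
    msk <- load_volume(cohort$lesion_mask_path[i], mask = TRUE)
    if (dilate_radius > 0) msk <- dilate_lesion(msk, dilate_radius)
    crops[, , , i] <- crop_resample_lesion(vol, msk, cube, mask_background)$data
    markers[i, ] <- encode_markers(cohort[i, ])
  }
  list(crops = crops, markers = markers,
       labels = as.integer(cohort$pcr_label), ids = cohort$patient_id)
}

#' Train the fusion network
#'
#' Cross-entropy training with Adam (initial learning rate `1e-4` per the
#' reference protocol).  Set `image_only = TRUE` to feed the marker branch
#' a constant vector, yielding the image-only baseline with identical
#' architecture.
#'
#' @param model A [build_fusion_net()] model.
#' @param crops 4D array of lesion crops `(cube,cube,cube,n)`.
#' @param markers `n x 4` marker matrix.
#' @param labels Integer 0/1 pCR labels (both classes must be present).
#' @param epochs Training epochs (reference 200; scale down for desk use).
#' @param lr Learning rate (default `1e-4`).
#' @param batch_size Minibatch size.
#' @param seed Integer seed (shuffling is deterministic given it).
#' @param image_only Replace markers by constants.
#' @param flip_augment Randomly flip crops along each axis during training
#'   (default `TRUE`); at cohort sizes of a few hundred this curbs
#'   memorization of individual crops.
#' @param verbose Print per-epoch loss.
#' @return The model with the training curve attached as attribute
#'   `"curve"`.
#' @export
train_fusion <- function(model, crops, markers, labels, epochs = 200L,
                         lr = 1e-4, batch_size = 16L, seed = 1L,
                         image_only = FALSE, flip_augment = TRUE,
                         verbose = FALSE) {
  n <- dim(crops)[4]
  assert_that(length(labels) == n && nrow(markers) == n,
              "crops, markers and labels must agree in length")
  if (length(unique(labels)) < 2) {
    stop_cs("cohort labels are single-class; cannot train", "cs_training_error")
  }
  if (image_only) markers <- matrix(0.5, n, ncol(markers))
  layers <- fusion_layers(model)
  curve <- numeric(epochs)
  with_preserved_rng(seed, {
    step_t <- 0L
    for (epoch in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      nb <- 0L
      for (start in seq.int(1L, n, by = batch_size)) {
        rows <- ord[start:min(start + batch_size - 1L, n)]
        B <- length(rows)
        x <- crops[, , , rows, drop = FALSE]
        if (flip_augment) {
          cube <- dim(x)[1]
          for (bi in seq_len(B)) {
            fl <- stats::runif(3) < 0.5
            idx <- lapply(1:3, function(a) if (fl[a]) cube:1 else 1:cube)
            x[, , , bi] <- x[idx[[1]], idx[[2]], idx[[3]], bi]
          }
        }
        v <- one_hot(labels[rows], 2L)
        zero_grads(layers)
        fw <- fusion_forward(model, x, markers[rows, , drop = FALSE], training = TRUE)
        loss <- -sum(v * log(pmax(fw$probs, 1e-7))) / B
        fusion_backward(model, (fw$probs - v) / B)
        step_t <- step_t + 1L
        adam_step(layers, lr, step_t)
        ep_loss <- ep_loss + loss
        nb <- nb + 1L
      }
      curve[epoch] <- ep_loss / nb
      if (verbose) message(sprintf("epoch %3d  loss %.4f", epoch, curve[epoch]))
    }
  })
  attr(model, "curve") <- structure(
    tibble::tibble(epoch = seq_len(epochs), loss = curve, lr = lr, decayed = FALSE),
    class = c("cs_training_curve", class(tibble::tibble())))
  model
}

#' Predict pCR probability for one patient
#'
#' @param model A trained [build_fusion_net()].
#' @param crop Lesion crop from [crop_resample_lesion()] (an
#'   [image_volume()] or bare array of the configured cube size).
#' @param markers Length-4 marker vector from [encode_markers()].
#' @param patient_id Optional identifier carried into the result.
#' @return A one-row tibble with `patient_id`, `p_pcr`, `predicted_label`
#'   (1 iff `p_pcr >= 0.5`).
#' @export
predict_pcr <- function(model, crop, markers, patient_id = NA_character_) {
  x <- if (inherits(crop, "image_volume")) crop$data else crop
  cube <- model$config$input_cube
  if (!identical(as.integer(dim(x)), rep(cube, 3L))) {
    stop_cs(sprintf("crop must be %d^3, got %s", cube,
                    paste(dim(x), collapse = "x")), "cs_argument_error")
  }
  fw <- fusion_forward(model, x, matrix(markers, 1L), training = FALSE)
  p <- fw$probs[1, 2]
  tibble::tibble(patient_id = patient_id, p_pcr = p,
                 predicted_label = as.integer(p >= 0.5))
}

#' Predict pCR for a prepared input set
#'
#' @param model A trained [build_fusion_net()].
#' @param inputs A [prepare_fusion_inputs()] list.
#' @param image_only Feed the marker branch constants (must match how the
#'   model was trained).
#' @param batch_size Samples per forward pass.
#' @return A tibble with `patient_id`, `p_pcr`, `predicted_label`.
#' @export
predict_pcr_cohort <- function(model, inputs, image_only = FALSE,
                               batch_size = 16L) {
  n <- dim(inputs$crops)[4]
  markers <- if (image_only) matrix(0.5, n, ncol(inputs$markers)) else inputs$markers
  p <- numeric(n)
  for (start in seq.int(1L, n, by = batch_size)) {
    rows <- start:min(start + batch_size - 1L, n)
    fw <- fusion_forward(model, inputs$crops[, , , rows, drop = FALSE],
                         markers[rows, , drop = FALSE], training = FALSE)
    p[rows] <- fw$probs[, 2]
  }
  tibble::tibble(patient_id = inputs$ids, p_pcr = p,
                 predicted_label = as.integer(p >= 0.5))
}

#' Lesion-periphery dilation ablation
#'
#' Re-runs pCR training and evaluation with the segmented lesion expanded by
#' spherical kernels of the given radii (0 = the undilated lesion), mirroring
#' the periphery-expansion experiment design.
#'
#' @param train_cohort,test_cohort Cohort tibbles with image and lesion-mask
#'   paths.
#' @param radii Dilation radii in voxels.
#' @param cube Crop edge length.
#' @param config A [fusion_config()].
#' @param epochs,lr,batch_size,seed Training settings.
#' @param mask_background Passed to [crop_resample_lesion()].
#' @return A tibble (class `cs_ablation_report`) with one row per radius:
#'   `radius`, `accuracy`, `auc`.
#' @export
dilation_ablation <- function(train_cohort, test_cohort, radii = c(0, 5, 10, 15),
                              cube = 16L, config = fusion_config(input_cube = cube),
                              epochs = 20L, lr = 1e-4, batch_size = 16L,
                              seed = 1L, mask_background = TRUE) {
  rows <- vector("list", length(radii))
  seeds <- split_seed(seed, length(radii))
  for (i in seq_along(radii)) {
    r <- radii[i]
    tr <- prepare_fusion_inputs(train_cohort, cube, dilate_radius = r,
                                mask_background = mask_background)
    te <- prepare_fusion_inputs(test_cohort, cube, dilate_radius = r,
                                mask_background = mask_background)
    net <- build_fusion_net(config, seed = seeds[i])
    net <- train_fusion(net, tr$crops, tr$markers, tr$labels, epochs = epochs,
                        lr = lr, batch_size = batch_size, seed = seeds[i])
    pred <- predict_pcr_cohort(net, te)
    rows[[i]] <- tibble::tibble(radius = r,
                                accuracy = accuracy(te$labels, pred$predicted_label),
                                auc = auc(te$labels, pred$p_pcr))
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cs_ablation_report", class(out))
  out
}
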