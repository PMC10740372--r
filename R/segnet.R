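# Configurable 3D encoder-decoder segmentation network.
#
# Topology per resolution level l (channels c_l = base_channels * 2^(l-1)):
#   encoder: [conv3 -> instance norm -> leaky ReLU] x2, strided 2x2x2 conv
#            between levels;
#   decoder: trilinear x2 upsample, concatenate the skip, then
#            [conv3 -> IN -> lReLU] x2;
#   head:    1x1x1 conv to K classes, per-voxel softmax.
# The patch size must be divisible by 2^(depth-1) so shapes halve and double
# exactly.

#' Segmentation network configuration
#'
#' @param depth Number of resolution levels (default 4).
#' @param base_channels Channels at the first level; doubled per level
#'   (default 16).
#' @param patch_size Cubic patch edge in voxels; must be divisible by
#'   `2^(depth-1)`.
#' @param num_classes Number of output classes `K` (default 2:
#'   background/foreground).
#' @param in_channels Number of input image channels (default 1).
#' @param norm Feature normalization inside conv blocks: `"instance"` or
#'   `"none"`.  Instance norm discards each patch's absolute intensity
#'   level; at small patch sizes (16^3), where a patch may contain a single
#'   tissue, that absolute level is exactly what separates a lesion from
#'   bright parenchyma, so `"none"` is the default.
#' @return An object of class `segnet_config`.
#' @export
segnet_config <- function(depth = 4L, base_channels = 16L, patch_size = 32L,
                          num_classes = 2L, in_channels = 1L,
                          norm = c("none", "instance")) {
  assert_that(is_count(depth) && depth >= 2, "`depth` must be an integer >= 2")
  if (patch_size %% 2^(depth - 1) != 0) {
    stop_cs(sprintf("patch_size %d is not divisible by 2^(depth-1) = %d",
                    patch_size, 2^(depth - 1)), "cs_config_error")
  }
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 patch_size = as.integer(patch_size),
                 num_classes = as.integer(num_classes),
                 in_channels = as.integer(in_channels),
                 norm = match.arg(norm)),
            class = "segnet_config")
}

conv_block <- function(cin, cout, norm = "instance") {
  if (norm == "instance") {
    list(conv = ly_conv(cin, cout), norm = ly_inorm(cout), act = ly_lrelu())
  } else {
    list(conv = ly_conv(cin, cout), act = ly_lrelu())
  }
}

#' Build a 3D encoder-decoder segmentation network
#'
#' Parameter initialization (He-scaled Gaussian) is deterministic given
#' `seed`.
#'
#' @param config A [segnet_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `segnet`.
#' @export
build_segnet <- function(config, seed = 1L) {
  assert_that(inherits(config, "segnet_config"), "`config` must be a segnet_config")
  with_preserved_rng(seed, {
    D <- config$depth
    ch <- config$base_channels * 2^(seq_len(D) - 1)
    enc <- vector("list", D)
    down <- vector("list", D - 1)
    for (l in seq_len(D)) {
      cin <- if (l == 1) config$in_channels else ch[l]
      enc[[l]] <- list(b1 = conv_block(cin, ch[l], config$norm),
                       b2 = conv_block(ch[l], ch[l], config$norm))
      if (l == 1) enc[[l]]$b1$conv$is_first <- TRUE
      if (l < D) down[[l]] <- ly_conv(ch[l], ch[l + 1], kernel = 2L, stride = 2L, pad = 0L)
    }
    up <- vector("list", D - 1)
    dec <- vector("list", D - 1)
    for (l in seq_len(D - 1)) {
      up[[l]] <- ly_upsample()
      dec[[l]] <- list(b1 = conv_block(ch[l + 1] + ch[l], ch[l], config$norm),
                       b2 = conv_block(ch[l], ch[l], config$norm))
    }
    head <- ly_linear(ch[1], config$num_classes)
    structure(list(config = config, enc = enc, down = down, up = up, dec = dec,
                   head = head, seed = seed),
              class = "segnet")
  })
}

segnet_layers <- function(model) {
  out <- list()
  grab_block <- function(b) {
    if (is.null(b$norm)) list(b$conv, b$act) else list(b$conv, b$norm, b$act)
  }
  for (e in model$enc) out <- c(out, grab_block(e$b1), grab_block(e$b2))
  out <- c(out, model$down)
  for (d in model$dec) out <- c(out, grab_block(d$b1), grab_block(d$b2))
  out <- c(out, model$up, list(model$head))
  out
}

#' @export
print.segnet <- function(x, ...) {
  cat(sprintf("<segnet> depth %d, base %d, patch %d^3, %d classes, %s parameters\n",
              x$config$depth, x$config$base_channels, x$config$patch_size,
              x$config$num_classes,
              format(n_params(segnet_layers(x)), big.mark = ",")))
  invisible(x)
}

block_forward <- function(b, x, training) {
  x <- layer_forward(b$conv, x, training)
  if (!is.null(b$norm)) x <- layer_forward(b$norm, x, training)
  layer_forward(b$act, x, training)
}

block_backward <- function(b, g) {
  g <- layer_backward(b$act, g)
  if (!is.null(b$norm)) g <- layer_backward(b$norm, g)
  layer_backward(b$conv, g)
}

# x: array (p,p,p) or (p,p,p,B).  Returns list(probs = (B*nvox) x K, logits,
# dims, B); skip activations are cached on the model layers for backward.
segnet_forward <- function(model, x, training = FALSE) {
  d <- dim(x)
  if (length(d) == 3L) { B <- 1L; dims <- d } else { B <- d[4]; dims <- d[1:3] }
  t <- list(X = matrix(as.vector(x), ncol = model$config$in_channels),
            dims = dims, B = B)
  D <- model$config$depth
  skips <- vector("list", D)
  for (l in seq_len(D)) {
    t <- block_forward(model$enc[[l]]$b1, t, training)
    t <- block_forward(model$enc[[l]]$b2, t, training)
    skips[[l]] <- t
    if (l < D) t <- layer_forward(model$down[[l]], t, training)
  }
  for (l in rev(seq_len(D - 1))) {
    t <- layer_forward(model$up[[l]], t, training)
    t <- list(X = cbind(t$X, skips[[l]]$X), dims = t$dims, B = t$B)
    t <- block_forward(model$dec[[l]]$b1, t, training)
    t <- block_forward(model$dec[[l]]$b2, t, training)
  }
  logits <- layer_forward(model$head, t$X, training)
  list(probs = row_softmax(logits), logits = logits, dims = t$dims, B = B)
}

# g_logits: gradient w.r.t. the head logits, (B*nvox) x K
segnet_backward <- function(model, g_logits) {
  D <- model$config$depth
  ch <- model$config$base_channels * 2^(seq_len(D) - 1)
  g <- layer_backward(model$head, g_logits)
  g_skip <- vector("list", D)
  for (l in seq_len(D - 1)) {
    g <- block_backward(model$dec[[l]]$b2, g)
    g <- block_backward(model$dec[[l]]$b1, g)
    up_ch <- ch[l + 1]
    g_skip[[l]] <- g[, (up_ch + 1):(up_ch + ch[l]), drop = FALSE]
    g <- layer_backward(model$up[[l]], g[, seq_len(up_ch), drop = FALSE])
  }
  for (l in rev(seq_len(D))) {
    if (l < D) g <- layer_backward(model$down[[l]], g) + g_skip[[l]]
    g <- block_backward(model$enc[[l]]$b2, g)
    g <- block_backward(model$enc[[l]]$b1, g)
  }
  invisible(NULL)
}
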