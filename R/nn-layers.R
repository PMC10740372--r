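# Minimal 3D neural-network layer kit: im2col convolutions backed by BLAS
# matrix multiplication, instance normalization, leaky ReLU, trilinear x2
# upsampling, and fully connected layers, each with a hand-written backward
# pass, plus an Adam optimizer.
#
# Feature maps are stored as (B * nvox) x C matrices: rows are voxels in R's
# column-major order, sample-major across the batch; columns are channels.
# Spatial shape travels alongside as `dims` and batch size as `B`.  All
# gather/scatter index tables are precomputed and cached per (dims, B).

new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$params <- list()
  e$grads <- list()
  e$adam <- list()
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  class(e) <- c(paste0("ly_", type), "cs_layer")
  e
}

he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, 0, sqrt(2 / fan_in)), nrow, ncol)
}

ly_conv <- function(cin, cout, kernel = 3L, stride = 1L,
                    pad = (kernel - 1L) %/% 2L) {
  K <- kernel^3
  l <- new_layer("conv", cin = cin, cout = cout, kernel = as.integer(kernel),
                 stride = as.integer(stride), pad = as.integer(pad),
                 idx_cache = list())
  l$params$W <- he_init(K * cin, cout, K * cin)
  l$params$b <- numeric(cout)
  l
}

ly_inorm <- function(c, eps = 1e-5) {
  l <- new_layer("inorm", c = c, eps = eps)
  l$params$gamma <- rep(1, c)
  l$params$beta <- rep(0, c)
  l
}

ly_lrelu <- function(slope = 0.01) new_layer("lrelu", slope = slope)

ly_upsample <- function() new_layer("upsample", idx_cache = list())

ly_linear <- function(cin, cout) {
  l <- new_layer("linear", cin = cin, cout = cout)
  l$params$W <- he_init(cin, cout, cin)
  l$params$b <- numeric(cout)
  l
}

ly_relu <- function() new_layer("relu")

# ---- index tables ----------------------------------------------------------

# Gather table for im2col: a (B*nvox_out) x kernel^3 matrix of row indices
# into the zero-augmented input matrix; out-of-grid taps point at the pad row.
conv_index_table <- function(dims, B, kernel, stride, pad) {
  od <- (dims + 2L * pad - kernel) %/% stride + 1L
  nvox_in <- prod(dims)
  nvox_out <- prod(od)
  K <- kernel^3
  ax <- lapply(1:3, function(a) {
    outer((seq_len(od[a]) - 1L) * stride - pad, 0:(kernel - 1L), "+")
  })
  M <- matrix(NA_integer_, nvox_out, K)
  col <- 0L
  for (c3 in seq_len(kernel)) for (c2 in seq_len(kernel)) for (c1 in seq_len(kernel)) {
    col <- col + 1L
    a1 <- rep.int(ax[[1]][, c1], od[2] * od[3])
    a2 <- rep.int(rep(ax[[2]][, c2], each = od[1]), od[3])
    a3 <- rep(ax[[3]][, c3], each = od[1] * od[2])
    valid <- a1 >= 0L & a1 < dims[1] & a2 >= 0L & a2 < dims[2] & a3 >= 0L & a3 < dims[3]
    lin <- 1L + a1 + a2 * dims[1] + a3 * dims[1] * dims[2]
    lin[!valid] <- NA_integer_
    M[, col] <- lin
  }
  pad_row <- B * nvox_in + 1L
  Mb <- matrix(pad_row, B * nvox_out, K)
  nas <- is.na(M)
  for (b in seq_len(B)) {
    block <- M + (b - 1L) * nvox_in
    block[nas] <- pad_row
    Mb[((b - 1L) * nvox_out + 1L):(b * nvox_out), ] <- block
  }
  list(Mb = Mb, Mb_vec = as.vector(Mb), out_dims = od, nvox_in = nvox_in,
       nvox_out = nvox_out, K = K)
}

# Gather/weight tables for trilinear x2 upsampling: 8 corner indices and
# weights per output voxel (replicate padding at the boundary).
upsample_index_table <- function(dims, B) {
  od <- 2L * dims
  ax <- lapply(1:3, function(a) {
    xin <- (seq_len(od[a]) - 1) / 2 - 0.25
    f <- pmin(pmax(floor(xin), 0), dims[a] - 1)
    w <- pmin(pmax(xin - f, 0), 1)
    cbind(f = f, c = pmin(f + 1, dims[a] - 1), w = w)
  })
  nvox_out <- prod(od)
  nvox_in <- prod(dims)
  e1 <- rep.int(seq_len(od[1]), od[2] * od[3])
  e2 <- rep.int(rep(seq_len(od[2]), each = od[1]), od[3])
  e3 <- rep(seq_len(od[3]), each = od[1] * od[2])
  idx8 <- matrix(0L, nvox_out, 8L)
  w8 <- matrix(0, nvox_out, 8L)
  col <- 0L
  for (c3 in 0:1) for (c2 in 0:1) for (c1 in 0:1) {
    col <- col + 1L
    i1 <- ax[[1]][e1, if (c1 == 1) "c" else "f"]
    i2 <- ax[[2]][e2, if (c2 == 1) "c" else "f"]
    i3 <- ax[[3]][e3, if (c3 == 1) "c" else "f"]
    w1 <- ax[[1]][e1, "w"]; w2 <- ax[[2]][e2, "w"]; w3 <- ax[[3]][e3, "w"]
    idx8[, col] <- 1L + i1 + i2 * dims[1] + i3 * dims[1] * dims[2]
    w8[, col] <- (if (c1 == 1) w1 else 1 - w1) *
                 (if (c2 == 1) w2 else 1 - w2) *
                 (if (c3 == 1) w3 else 1 - w3)
  }
  Mb <- matrix(0L, B * nvox_out, 8L)
  for (b in seq_len(B)) {
    Mb[((b - 1L) * nvox_out + 1L):(b * nvox_out), ] <- idx8 + (b - 1L) * nvox_in
  }
  wb <- w8[rep(seq_len(nvox_out), B), , drop = FALSE]
  list(Mb = Mb, wb = wb, out_dims = od, nvox_in = nvox_in, nvox_out = nvox_out)
}

# scatter-add rows of `g` grouped by `group` into a matrix with `n` rows
scatter_rowsum <- function(g, group, n) {
  agg <- rowsum(g, group)
  out <- matrix(0, n, ncol(g))
  out[as.integer(rownames(agg)), ] <- agg
  out
}

# Gradient of a convolution w.r.t. its input.  Two fast paths avoid the
# generic scatter-add: same-pad stride-1 convolutions backpropagate as a
# convolution of the output gradient with the index-reversed kernel (a pure
# gather + matmul), and kernel==stride, pad==0 convolutions touch every
# input voxel exactly once, so the scatter is a plain permutation.
conv_input_grad <- function(l, gy, cc) {
  tab <- cc$tab
  K <- tab$K
  if (l$stride == 1L && l$kernel %% 2L == 1L &&
      l$pad == (l$kernel - 1L) %/% 2L) {
    # transposed conv: gX[v, cin] = sum_{kk,cout} gY[v + off_rev(kk), cout]
    # * W[(cin-1)K + kk, cout]; reuse the same index table on the gradient
    G2 <- rbind(gy, 0)[tab$Mb_vec, , drop = FALSE]
    dim(G2) <- c(nrow(tab$Mb), K * l$cout)
    W2 <- matrix(0, K * l$cout, l$cin)
    kk <- seq_len(K)
    for (ci in seq_len(l$cin)) {
      # reversed kernel index: tap kk of the forward maps to K+1-kk here
      W2[, ci] <- as.vector(l$params$W[(ci - 1L) * K + (K + 1L - kk), ,
                                       drop = FALSE])
    }
    G2 %*% W2
  } else if (l$stride == l$kernel && l$pad == 0L) {
    gG <- gy %*% t(l$params$W)
    dim(gG) <- c(nrow(tab$Mb) * K, l$cin)
    gX <- matrix(0, cc$B * tab$nvox_in + 1L, l$cin)
    gX[tab$Mb_vec, ] <- gG
    gX[-nrow(gX), , drop = FALSE]
  } else {
    gG <- gy %*% t(l$params$W)
    dim(gG) <- c(nrow(tab$Mb) * K, l$cin)
    gX <- scatter_rowsum(gG, tab$Mb_vec, cc$B * tab$nvox_in + 1L)
    gX[-nrow(gX), , drop = FALSE]
  }
}

# ---- forward / backward ----------------------------------------------------

# x: list(X = (B*nvox) x C matrix, dims = int[3], B = int)
layer_forward <- function(l, x, training = TRUE) {
  switch(l$type,
    conv = {
      key <- paste(c(x$dims, x$B), collapse = "_")
      tab <- l$idx_cache[[key]]
      if (is.null(tab)) {
        tab <- conv_index_table(x$dims, x$B, l$kernel, l$stride, l$pad)
        l$idx_cache[[key]] <- tab
      }
      X_aug <- rbind(x$X, 0)
      G <- X_aug[tab$Mb_vec, , drop = FALSE]
      dim(G) <- c(nrow(tab$Mb), tab$K * l$cin)
      Y <- G %*% l$params$W
      Y <- Y + rep(l$params$b, each = nrow(Y))
      if (training) { l$cache <- list(G = G, tab = tab, B = x$B) } else l$cache <- NULL
      list(X = Y, dims = tab$out_dims, B = x$B)
    },
    inorm = {
      nvox <- prod(x$dims)
      grp <- rep(seq_len(x$B), each = nvox)
      mu <- rowsum(x$X, grp) / nvox
      xc <- x$X - mu[grp, , drop = FALSE]
      v <- rowsum(xc * xc, grp) / nvox
      istd <- 1 / sqrt(v + l$eps)
      xhat <- xc * istd[grp, , drop = FALSE]
      Y <- xhat * rep(l$params$gamma, each = nrow(xhat)) +
        rep(l$params$beta, each = nrow(xhat))
      if (training) l$cache <- list(xhat = xhat, istd = istd, grp = grp, nvox = nvox) else l$cache <- NULL
      list(X = Y, dims = x$dims, B = x$B)
    },
    lrelu = {
      bare <- !is.list(x)            # FC branches pass plain matrices
      Y <- if (bare) x else x$X
      neg <- Y < 0
      Y[neg] <- Y[neg] * l$slope
      if (training) l$cache <- list(neg = neg) else l$cache <- NULL
      if (bare) Y else list(X = Y, dims = x$dims, B = x$B)
    },
    upsample = {
      key <- paste(c(x$dims, x$B), collapse = "_")
      tab <- l$idx_cache[[key]]
      if (is.null(tab)) {
        tab <- upsample_index_table(x$dims, x$B)
        l$idx_cache[[key]] <- tab
      }
      Y <- matrix(0, nrow(tab$Mb), ncol(x$X))
      for (j in 1:8) {
        Y <- Y + x$X[tab$Mb[, j], , drop = FALSE] * tab$wb[, j]
      }
      if (training) l$cache <- list(tab = tab, B = x$B) else l$cache <- NULL
      list(X = Y, dims = tab$out_dims, B = x$B)
    },
    linear = {
      Y <- x %*% l$params$W
      Y <- Y + rep(l$params$b, each = nrow(Y))
      if (training) l$cache <- list(X = x) else l$cache <- NULL
      Y
    },
    relu = {
      neg <- x < 0
      Y <- x
      Y[neg] <- 0
      if (training) l$cache <- list(neg = neg) else l$cache <- NULL
      Y
    },
    stop_cs(paste("unknown layer type", l$type), "cs_internal_error")
  )
}

# gy: gradient w.r.t. the layer output, same layout as the output
layer_backward <- function(l, gy) {
  switch(l$type,
    conv = {
      cc <- l$cache
      l$grads$W <- acc_grad(l$grads$W, crossprod(cc$G, gy))
      l$grads$b <- acc_grad(l$grads$b, colSums(gy))
      # the first layer of a network has no upstream to propagate to
      gX <- if (isTRUE(l$is_first)) NULL else conv_input_grad(l, gy, cc)
      l$cache <- NULL
      gX
    },
    inorm = {
      cc <- l$cache
      n <- cc$nvox
      gxhat <- gy * rep(l$params$gamma, each = nrow(gy))
      l$grads$gamma <- acc_grad(l$grads$gamma, colSums(gy * cc$xhat))
      l$grads$beta <- acc_grad(l$grads$beta, colSums(gy))
      sum_g <- rowsum(gxhat, cc$grp)
      sum_gx <- rowsum(gxhat * cc$xhat, cc$grp)
      gx <- (gxhat - (sum_g[cc$grp, , drop = FALSE] +
                        cc$xhat * sum_gx[cc$grp, , drop = FALSE]) / n) *
        cc$istd[cc$grp, , drop = FALSE]
      l$cache <- NULL
      gx
    },
    lrelu = {
      g <- gy
      g[l$cache$neg] <- g[l$cache$neg] * l$slope
      l$cache <- NULL
      g
    },
    upsample = {
      cc <- l$cache
      tab <- cc$tab
      gX <- matrix(0, cc$B * tab$nvox_in, ncol(gy))
      for (j in 1:8) {
        gX <- gX + scatter_rowsum(gy * tab$wb[, j], tab$Mb[, j], cc$B * tab$nvox_in)
      }
      l$cache <- NULL
      gX
    },
    linear = {
      cc <- l$cache
      l$grads$W <- acc_grad(l$grads$W, crossprod(cc$X, gy))
      l$grads$b <- acc_grad(l$grads$b, colSums(gy))
      l$cache <- NULL
      gy %*% t(l$params$W)
    },
    relu = {
      g <- gy
      g[l$cache$neg] <- 0
      l$cache <- NULL
      g
    }
  )
}

acc_grad <- function(old, g) if (is.null(old)) g else old + g

zero_grads <- function(layers) {
  for (l in layers) l$grads <- list()
  invisible(NULL)
}

# One Adam update over all parameterized layers; `t` is the step counter.
adam_step <- function(layers, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in layers) {
    for (nm in names(l$grads)) {
      g <- l$grads[[nm]]
      st <- l$adam[[nm]]
      if (is.null(st)) st <- list(m = g * 0, v = g * 0)
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      l$adam[[nm]] <- st
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      l$params[[nm]] <- l$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  invisible(NULL)
}

n_params <- function(layers) {
  sum(vapply(layers, function(l) sum(vapply(l$params, length, integer(1))), numeric(1)))
}

row_softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}
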