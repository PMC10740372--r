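# Sliding-window inference with center-weighted patch fusion, and the
# two-step gland -> lesion cascade.
#
# Volumes are tiled with stride patch_size/2 (consecutive patches overlap by
# half a patch); the last patch along each axis is end-aligned with the
# volume boundary so coverage is complete.  Per-voxel probabilities from
# overlapping patches are fused as a weighted average under a separable
# Gaussian weight map that peaks at the patch center, down-weighting the
# less reliable patch edges.

#' Build the patch grid covering a volume
#'
#' Patch origins (0-based) lie at multiples of `patch_size/2`, plus one
#' end-aligned origin per axis when the last regular patch does not reach
#' the boundary.
#'
#' @param vol_shape Integer length-3 volume shape.
#' @param patch_size Even patch edge length, at most `min(vol_shape)`.
#' @return An object of class `patch_grid`: a list with `patch_size`,
#'   `stride`, and `origins` (a matrix of 0-based corner indices, one row
#'   per patch).
#' @export
make_patch_grid <- function(vol_shape, patch_size) {
  vol_shape <- as.integer(vol_shape)
  assert_that(patch_size %% 2 == 0, "`patch_size` must be even")
  if (any(patch_size > vol_shape)) {
    stop_cs(sprintf("patch (%d) larger than volume (%s)", patch_size,
                    paste(vol_shape, collapse = "x")), "cs_argument_error")
  }
  stride <- patch_size %/% 2L
  axis_origins <- lapply(vol_shape, function(n) {
    o <- seq.int(0L, n - patch_size, by = stride)
    if (max(o) < n - patch_size) o <- c(o, n - patch_size)
    o
  })
  origins <- as.matrix(expand.grid(axis_origins))
  dimnames(origins) <- NULL
  structure(list(patch_size = as.integer(patch_size), stride = stride,
                 vol_shape = vol_shape, origins = origins),
            class = "patch_grid")
}

#' Gaussian center-weight map for patch fusion
#'
#' A separable Gaussian centered on the patch, SD = `sigma_fraction *
#' patch_size` per axis, floored at `1e-3` of its maximum so every voxel
#' keeps positive weight.
#'
#' @param patch_size Patch edge length.
#' @param sigma_fraction Gaussian SD as a fraction of the patch size
#'   (default 1/8).
#' @return A `patch_size^3` array of positive weights, maximal at the
#'   center.
#' @export
gaussian_weight_map <- function(patch_size, sigma_fraction = 1 / 8) {
  assert_that(sigma_fraction > 0, "`sigma_fraction` must be positive")
  ctr <- (patch_size - 1) / 2
  g1 <- exp(-0.5 * ((seq_len(patch_size) - 1 - ctr) / (sigma_fraction * patch_size))^2)
  w <- outer(outer(g1, g1), g1)
  pmax(w, 1e-3 * max(w))
}

#' Sliding-window prediction over a patch grid
#'
#' Each voxel's class probabilities are the weight-map-weighted average of
#' the predictions of every patch covering it, renormalized to sum to one.
#'
#' @param model A trained [build_segnet()] model.
#' @param vol An [image_volume()] (already preprocessed).
#' @param grid A [make_patch_grid()] for `dim(vol$data)`.
#' @param weights A [gaussian_weight_map()] of the model's patch size.
#' @param batch_size Patches predicted per forward pass.
#' @return A 4D array `(shape, K)` of fused per-voxel class probabilities.
#' @export
sliding_window_predict <- function(model, vol, grid, weights = NULL,
                                   batch_size = 4L) {
  d <- dim(vol$data)
  if (!identical(as.integer(d), grid$vol_shape)) {
    stop_cs("grid was built for a different volume shape", "cs_argument_error")
  }
  p <- grid$patch_size
  K <- model$config$num_classes
  if (is.null(weights)) weights <- gaussian_weight_map(p)
  wvec <- as.vector(weights)
  num <- array(0, c(d, K))
  den <- array(0, d)
  n_patch <- nrow(grid$origins)
  for (start in seq.int(1L, n_patch, by = batch_size)) {
    rows <- start:min(start + batch_size - 1L, n_patch)
    B <- length(rows)
    x <- array(0, c(p, p, p, B))
    for (bi in seq_len(B)) {
      o <- grid$origins[rows[bi], ]
      x[, , , bi] <- vol$data[(o[1] + 1):(o[1] + p),
                              (o[2] + 1):(o[2] + p),
                              (o[3] + 1):(o[3] + p)]
    }
    fw <- segnet_forward(model, x, training = FALSE)
    nvox <- p^3
    for (bi in seq_len(B)) {
      o <- grid$origins[rows[bi], ]
      pr <- fw$probs[((bi - 1) * nvox + 1):(bi * nvox), , drop = FALSE]
      ix <- (o[1] + 1):(o[1] + p); iy <- (o[2] + 1):(o[2] + p); iz <- (o[3] + 1):(o[3] + p)
      for (k in seq_len(K)) {
        num[ix, iy, iz, k] <- num[ix, iy, iz, k] + array(pr[, k] * wvec, c(p, p, p))
      }
      den[ix, iy, iz] <- den[ix, iy, iz] + weights
    }
  }
  sweep_den <- array(rep(den, K), c(d, K))
  num / sweep_den
}

# argmax over the class axis of a (shape, K) probability array; ties go to
# the lower class index.
prob_argmax <- function(probs) {
  d <- dim(probs)
  K <- d[length(d)]
  m <- matrix(probs, ncol = K)
  array(max.col(m, ties.method = "first") - 1L, d[-length(d)])
}

#' Crop a volume to the bounding box of a mask
#'
#' Axis-aligned bounding box of the mask foreground, expanded by
#' `margin_mm` (converted to voxels per axis) and clipped to the volume.
#' The crop is a box crop: voxels inside the box but outside the mask are
#' retained.
#'
#' @param vol An [image_volume()].
#' @param mask A nonempty aligned [label_mask()].
#' @param margin_mm Margin around the bounding box, in mm.
#' @return A list with `volume` (the crop) and `offset` (0-based corner of
#'   the crop in the input grid, for coordinate back-mapping).
#' @export
crop_to_mask <- function(vol, mask, margin_mm = 0) {
  if (!any(mask$data > 0)) stop_cs("mask is empty; cannot crop", "cs_crop_error")
  d <- dim(vol$data)
  bb <- mask_bbox(mask$data > 0)
  mg <- as.integer(ceiling(margin_mm / vol$spacing))
  lo <- pmax(bb$lo - mg, 1L)
  hi <- pmin(bb$hi + mg, d)
  crop <- vol$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  list(volume = image_volume(crop, spacing = vol$spacing, origin = vol$origin),
       offset = lo - 1L)
}

# Pad an array up to at least `target` per axis (replicating edge values for
# images, zeros for masks); returns the padded array and the pre-pad shape.
pad_to <- function(arr, target, fill = NULL) {
  d <- dim(arr)
  newd <- pmax(d, target)
  if (all(newd == d)) return(list(arr = arr, orig = d))
  out <- array(if (is.null(fill)) 0 else fill, newd)
  out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- arr
  if (is.null(fill)) {
    # replicate edges so the network does not see an artificial boundary
    if (newd[1] > d[1]) out[(d[1] + 1):newd[1], , ] <- out[rep(d[1], newd[1] - d[1]), , ]
    if (newd[2] > d[2]) out[, (d[2] + 1):newd[2], ] <- out[, rep(d[2], newd[2] - d[2]), ]
    if (newd[3] > d[3]) out[, , (d[3] + 1):newd[3]] <- out[, , rep(d[3], newd[3] - d[3])]
  }
  list(arr = out, orig = d)
}

predict_binary_mask <- function(model, vol, sigma_fraction, batch_size = 4L) {
  p <- model$config$patch_size
  padded <- pad_to(vol$data, c(p, p, p))
  pv <- image_volume(padded$arr, spacing = vol$spacing)
  grid <- make_patch_grid(dim(pv$data), p)
  probs <- sliding_window_predict(model, pv, grid,
                                  gaussian_weight_map(p, sigma_fraction),
                                  batch_size)
  lab <- prob_argmax(probs)
  lab <- lab[seq_len(padded$orig[1]), seq_len(padded$orig[2]),
             seq_len(padded$orig[3]), drop = FALSE]
  label_mask(array(as.integer(lab > 0), dim = padded$orig), spacing = vol$spacing)
}

#' Two-step cascade inference: gland first, then lesion within the gland
#'
#' Pipeline: resample to the training spacing and z-score; sliding-window
#' gland prediction; argmax and largest connected component; crop the
#' (unnormalized) resampled volume to the gland bounding box with margin;
#' z-score the crop only (no further resampling); sliding-window lesion
#' prediction inside the crop; argmax and largest component; map the lesion
#' mask back to the original grid.  Segmenting the gland first removes
#' high-intensity confounders outside the breast -- chiefly the heart, whose
#' intensity is close to lesion intensity.
#'
#' @param vol The input [image_volume()].
#' @param gland_model,lesion_model Trained [build_segnet()] models.
#' @param target_spacing Spacing (mm) the models were trained at.
#' @param margin_mm Margin around the gland bounding box (default 5 mm).
#' @param sigma_fraction Fusion weight-map SD as a fraction of patch size.
#' @param batch_size Patches per forward pass.
#' @return The lesion [label_mask()] in the original volume geometry, with
#'   the gland mask (model grid) attached as attribute `"gland_mask"`.
#' @export
run_two_step <- function(vol, gland_model, lesion_model,
                         target_spacing = vol$spacing, margin_mm = 5,
                         sigma_fraction = 1 / 8, batch_size = 4L) {
  same_grid <- all(abs(target_spacing - vol$spacing) < 1e-8)
  work <- if (same_grid) vol else resample(vol, target_spacing, mode = "image")

  gland <- predict_binary_mask(gland_model, zscore_normalize(work),
                               sigma_fraction, batch_size)
  if (!any(gland$data > 0)) {
    stop_cs("cascade failed at stage 'gland': empty gland mask", "cs_cascade_error")
  }
  gland <- largest_component(gland)

  crop <- crop_to_mask(work, gland, margin_mm)
  lesion_crop <- predict_binary_mask(lesion_model, zscore_normalize(crop$volume),
                                     sigma_fraction, batch_size)
  if (any(lesion_crop$data > 0)) lesion_crop <- largest_component(lesion_crop)

  full <- array(0L, dim(work$data))
  cd <- dim(lesion_crop$data)
  o <- crop$offset
  full[(o[1] + 1):(o[1] + cd[1]), (o[2] + 1):(o[2] + cd[2]),
       (o[3] + 1):(o[3] + cd[3])] <- lesion_crop$data
  out <- label_mask(full, spacing = work$spacing, origin = vol$origin)

  if (!same_grid) {
    out <- resample(out, vol$spacing, mode = "mask")
    # guard against rounding: force the original shape
    d0 <- dim(vol$data)
    if (!identical(dim(out$data), d0)) {
      fixed <- array(0L, d0)
      dd <- pmin(dim(out$data), d0)
      fixed[seq_len(dd[1]), seq_len(dd[2]), seq_len(dd[3])] <-
        out$data[seq_len(dd[1]), seq_len(dd[2]), seq_len(dd[3])]
      out <- label_mask(fixed, spacing = vol$spacing, origin = vol$origin)
    }
  }
  attr(out, "gland_mask") <- gland
  out
}
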