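# Training-time augmentation: random rotation, scaling, elastic deformation,
# gamma correction and inversion (spatial flips by default).
#
# Spatial transforms are composed into a single displacement of the sampling
# grid and applied identically to the image (trilinear) and masks (nearest
# neighbor), so mask pairings (lesion inside gland) are preserved.  Order is
# fixed for reproducibility: rotation -> scaling -> elastic, then the
# intensity transforms gamma -> inversion.

#' Augmentation parameters
#'
#' @param rotation_range Max absolute rotation per axis, degrees.
#' @param scale_range Multiplicative scale bounds (isotropic).
#' @param elastic_alpha Elastic displacement SD at control points, mm.
#' @param elastic_sigma Control-point spacing of the coarse deformation
#'   grid, mm (larger = smoother deformation).
#' @param gamma_range Gamma-exponent bounds; gamma is applied to min-max
#'   rescaled intensities and mapped back, so it is well defined for
#'   arbitrary intensity ranges.
#' @param inversion_mode `"flip"` (spatial axis flips, the default) or
#'   `"intensity"` (negate around the intensity midpoint).
#' @param apply_probs Named per-transform application probabilities
#'   (`rotation`, `scale`, `elastic`, `gamma`, `inversion`).
#' @return An object of class `augment_params`.
#' @export
augment_params <- function(rotation_range = 15,
                           scale_range = c(0.9, 1.1),
                           elastic_alpha = 2,
                           elastic_sigma = 16,
                           gamma_range = c(0.7, 1.5),
                           inversion_mode = c("flip", "intensity"),
                           apply_probs = c(rotation = 0.5, scale = 0.5,
                                           elastic = 0.5, gamma = 0.5,
                                           inversion = 0.5)) {
  assert_that(all(scale_range > 0) && all(gamma_range > 0),
              "scale and gamma bounds must be positive")
  assert_that(all(apply_probs >= 0 & apply_probs <= 1),
              "probabilities must lie in [0,1]")
  structure(list(rotation_range = rotation_range, scale_range = scale_range,
                 elastic_alpha = elastic_alpha, elastic_sigma = elastic_sigma,
                 gamma_range = gamma_range,
                 inversion_mode = match.arg(inversion_mode),
                 apply_probs = apply_probs),
            class = "augment_params")
}

rotation_matrix <- function(angles_deg) {
  a <- angles_deg * pi / 180
  rx <- matrix(c(1, 0, 0, 0, cos(a[1]), sin(a[1]), 0, -sin(a[1]), cos(a[1])), 3, 3)
  ry <- matrix(c(cos(a[2]), 0, -sin(a[2]), 0, 1, 0, sin(a[2]), 0, cos(a[2])), 3, 3)
  rz <- matrix(c(cos(a[3]), sin(a[3]), 0, -sin(a[3]), cos(a[3]), 0, 0, 0, 1), 3, 3)
  rz %*% ry %*% rx
}

#' Apply the same random augmentation to a volume and its masks
#'
#' @param vol An [image_volume()].
#' @param masks A single [label_mask()] or a named list of them, aligned
#'   with `vol`.
#' @param params An [augment_params()].
#' @param seed Integer seed; the same `(input, params, seed)` always yields
#'   identical output.
#' @return A list `(volume, masks)` with the transformed image and mask(s).
#' @export
augment <- function(vol, masks, params = augment_params(), seed = 1L) {
  single <- inherits(masks, "label_mask")
  mask_list <- if (single) list(mask = masks) else masks
  for (m in mask_list) {
    if (!validate_alignment(vol, m)) {
      stop_cs("volume and masks are not aligned", "cs_alignment_error")
    }
  }
  shape <- dim(vol$data)
  sp <- vol$spacing

  out <- with_preserved_rng(seed, {
    p <- params$apply_probs
    do_rot <- stats::runif(1) < p[["rotation"]]
    do_scale <- stats::runif(1) < p[["scale"]]
    do_elastic <- stats::runif(1) < p[["elastic"]]
    do_gamma <- stats::runif(1) < p[["gamma"]]
    do_inv <- stats::runif(1) < p[["inversion"]]

    angles <- stats::runif(3, -params$rotation_range, params$rotation_range)
    scale <- stats::runif(1, params$scale_range[1], params$scale_range[2])
    flip_axes <- stats::runif(3) < 0.5
    gamma <- stats::runif(1, params$gamma_range[1], params$gamma_range[2])

    spatial <- do_rot || do_scale || do_elastic
    img <- vol$data
    msk <- lapply(mask_list, function(m) m$data)

    if (spatial) {
      # build sampling positions in physical mm about the volume center
      coords_mm <- phantom_coords(shape, sp)
      center <- (shape - 1) * sp / 2
      pos <- sweep(coords_mm, 2, center)
      A <- diag(3)
      if (do_rot) A <- A %*% rotation_matrix(angles)
      if (do_scale) A <- A / scale   # sampling grid shrinks when object grows
      pos <- pos %*% t(A)
      if (do_elastic) {
        # coarse random displacement field, trilinearly upsampled
        nc <- pmax(2L, as.integer(ceiling(shape * sp / params$elastic_sigma)))
        up <- coord_grid(shape)
        for (a in 1:3) up[, a] <- up[, a] / (shape[a] - 1) * (nc[a] - 1)
        for (a in 1:3) {
          ctrl <- array(stats::rnorm(prod(nc), 0, params$elastic_alpha), dim = nc)
          pos[, a] <- pos[, a] + sample_trilinear(ctrl, up)
        }
      }
      pos <- sweep(pos, 2, center, FUN = "+")
      for (a in 1:3) pos[, a] <- pos[, a] / sp[a]   # back to voxel coords
      img <- array(sample_trilinear(vol$data, pos), dim = shape)
      msk <- lapply(msk, function(m) array(as.integer(sample_nearest(m, pos)), dim = shape))
    }

    if (do_gamma) {
      rng <- range(img)
      if (diff(rng) > 0) {
        img <- ((img - rng[1]) / diff(rng))^gamma * diff(rng) + rng[1]
      }
    }
    if (do_inv) {
      if (params$inversion_mode == "flip") {
        idx <- lapply(1:3, function(a) if (flip_axes[a]) rev(seq_len(shape[a])) else seq_len(shape[a]))
        img <- img[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
        msk <- lapply(msk, function(m) m[idx[[1]], idx[[2]], idx[[3]], drop = FALSE])
      } else {
        img <- max(img) + min(img) - img
      }
    }
    list(img = img, msk = msk)
  })

  new_masks <- lapply(out$msk, function(m) label_mask(m, spacing = sp, origin = vol$origin))
  list(
    volume = image_volume(out$img, spacing = sp, origin = vol$origin),
    masks = if (single) new_masks[[1]] else new_masks
  )
}
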