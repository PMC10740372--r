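# Grid sampling and spacing-aware resampling.
#
# All geometry is physical: a voxel with 0-based index i sits at i * spacing
# mm along its axis.  Sampling positions are expressed as continuous 0-based
# voxel coordinates of the source grid; out-of-grid positions are clamped to
# the boundary (replicate padding).

# coords: n x 3 matrix of continuous 0-based voxel coordinates.
sample_trilinear <- function(arr, coords) {
  d <- dim(arr)
  out <- numeric(nrow(coords))
  f <- matrix(0, nrow(coords), 3)
  w <- matrix(0, nrow(coords), 3)
  for (a in 1:3) {
    x <- pmin(pmax(coords[, a], 0), d[a] - 1)
    f0 <- pmin(floor(x), d[a] - 1)
    f[, a] <- f0
    w[, a] <- x - f0
  }
  # 8-corner accumulation; corner offsets in {0,1}^3 clamped to the grid
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    i <- pmin(f[, 1] + cx, d[1] - 1)
    j <- pmin(f[, 2] + cy, d[2] - 1)
    k <- pmin(f[, 3] + cz, d[3] - 1)
    wt <- (if (cx == 1) w[, 1] else 1 - w[, 1]) *
          (if (cy == 1) w[, 2] else 1 - w[, 2]) *
          (if (cz == 1) w[, 3] else 1 - w[, 3])
    idx <- 1 + i + j * d[1] + k * d[1] * d[2]
    out <- out + wt * arr[idx]
  }
  out
}

sample_nearest <- function(arr, coords) {
  d <- dim(arr)
  i <- pmin(pmax(round(coords[, 1]), 0), d[1] - 1)
  j <- pmin(pmax(round(coords[, 2]), 0), d[2] - 1)
  k <- pmin(pmax(round(coords[, 3]), 0), d[3] - 1)
  arr[1 + i + j * d[1] + k * d[1] * d[2]]
}

# 0-based voxel coordinate grid for a given shape, as an n x 3 matrix
# ordered column-major (first axis fastest), matching R array layout.
coord_grid <- function(shape) {
  cbind(
    rep.int(seq_len(shape[1]) - 1, shape[2] * shape[3]),
    rep.int(rep(seq_len(shape[2]) - 1, each = shape[1]), shape[3]),
    rep(seq_len(shape[3]) - 1, each = shape[1] * shape[2])
  )
}

#' Per-axis median voxel spacing of a set of volumes
#'
#' Training data from multiple scanners varies in spatial resolution, so all
#' volumes are resampled to the per-axis median spacing of the dataset
#' before training.  For an even number of volumes the lower median is used,
#' so the result is always a spacing that occurs in the data.
#'
#' @param volumes A list of [image_volume()] objects.
#' @return Numeric length-3 spacing (mm per axis).
#' @export
compute_median_spacing <- function(volumes) {
  assert_that(is.list(volumes) && length(volumes) >= 1,
              "`volumes` must be a non-empty list of image volumes")
  sp <- vapply(volumes, function(v) v$spacing, numeric(3))
  lower_median <- function(x) sort(x)[ceiling(length(x) / 2)]
  apply(sp, 1, lower_median)
}

#' Resample a volume or mask to a target voxel spacing
#'
#' The output shape is `round(shape * spacing / target_spacing)` (at least 1
#' voxel per axis).  Images are interpolated trilinearly, masks by nearest
#' neighbor so label values are preserved exactly.
#'
#' @param vol An [image_volume()] or [label_mask()].
#' @param target_spacing Numeric length-3 (or scalar) target spacing in mm.
#' @param mode `"image"` (trilinear) or `"mask"` (nearest neighbor);
#'   defaults to `"mask"` for `label_mask` input and `"image"` otherwise.
#' @return The resampled volume/mask with `spacing = target_spacing`.
#' @export
resample <- function(vol, target_spacing,
                     mode = if (inherits(vol, "label_mask")) "mask" else "image") {
  target_spacing <- rep_len(as.numeric(target_spacing), 3)
  assert_that(all(is.finite(target_spacing)) && all(target_spacing > 0),
              "`target_spacing` must be positive")
  mode <- match.arg(mode, c("image", "mask"))
  d <- dim(vol$data)
  new_shape <- pmax(1L, as.integer(round(d * vol$spacing / target_spacing)))
  # target voxel j sits at j * target mm -> source coordinate j * target / spacing
  coords <- coord_grid(new_shape)
  for (a in 1:3) coords[, a] <- coords[, a] * target_spacing[a] / vol$spacing[a]
  vals <- if (mode == "image") sample_trilinear(vol$data, coords) else sample_nearest(vol$data, coords)
  data <- array(vals, dim = new_shape)
  if (mode == "mask") {
    label_mask(data, spacing = target_spacing, origin = vol$origin)
  } else {
    image_volume(data, spacing = target_spacing, origin = vol$origin)
  }
}

#' Z-score normalize a volume
#'
#' Normalization is done independently per patient volume: the output has
#' mean 0 and standard deviation 1 over all voxels of that single volume.
#'
#' @param vol An [image_volume()].
#' @return The normalized [image_volume()].
#' @export
zscore_normalize <- function(vol) {
  x <- vol$data
  assert_that(length(x) > 1, "volume must have more than one voxel")
  s <- stats::sd(as.vector(x))
  if (!is.finite(s) || s == 0) {
    stop_cs("cannot z-score a constant volume (zero variance)", "cs_normalization_error")
  }
  image_volume(array((x - mean(x)) / s, dim = dim(x)),
               spacing = vol$spacing, origin = vol$origin)
}
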