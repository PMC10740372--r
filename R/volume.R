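# ImageVolume / LabelMask containers and NIfTI round-trip I/O.

#' Construct a 3D image volume
#'
#' An `image_volume` is a 3D scalar intensity grid together with its voxel
#' spacing (mm per axis) and physical origin.  Voxel indices are 0-based in
#' all geometric computations; the center of voxel `(0,0,0)` sits at
#' `origin` in physical space and voxel `i` along an axis sits at
#' `origin + i * spacing`.
#'
#' @param data Numeric 3D array of intensities.
#' @param spacing Numeric length-3, voxel size in mm per axis; all > 0.
#' @param origin Numeric length-3 physical position of the first voxel
#'   center, in mm.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  assert_that(is.array(data) && length(dim(data)) == 3L,
              "`data` must be a 3D array", "cs_shape_error")
  assert_that(all(dim(data) >= 1L), "all axes must have length >= 1", "cs_shape_error")
  spacing <- as.numeric(spacing)
  assert_that(length(spacing) == 3L && all(is.finite(spacing)) && all(spacing > 0),
              "`spacing` must be 3 positive numbers")
  structure(
    list(data = data, spacing = spacing, origin = as.numeric(origin)),
    class = "image_volume"
  )
}

#' Construct a 3D label mask
#'
#' A `label_mask` is an integer-valued 3D grid aligned voxel-for-voxel with
#' an [image_volume()]; 0 is background.
#'
#' @param data Integer-valued 3D array of nonnegative class labels.
#' @inheritParams image_volume
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  assert_that(is.array(data) && length(dim(data)) == 3L,
              "`data` must be a 3D array", "cs_shape_error")
  vals <- as.vector(data)
  assert_that(all(vals >= 0) && all(vals == round(vals)),
              "mask values must be nonnegative integers", "cs_validation_error")
  storage.mode(data) <- "integer"
  out <- image_volume(data, spacing, origin)
  class(out) <- c("label_mask", class(out))
  out
}

#' @export
print.image_volume <- function(x, ...) {
  kind <- if (inherits(x, "label_mask")) "label_mask" else "image_volume"
  cat(sprintf("<%s> %s voxels, spacing %s mm\n", kind,
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x")))
  if (inherits(x, "label_mask")) {
    tab <- table(x$data)
    cat("  labels:", paste(sprintf("%s (n=%s)", names(tab), as.vector(tab)),
                           collapse = ", "), "\n")
  } else {
    cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  }
  invisible(x)
}

#' Load a volume or mask from a NIfTI file
#'
#' @param path Path to a `.nii` / `.nii.gz` file containing a 3D image.
#' @param mask If `TRUE` return a [label_mask()] (values must be nonnegative
#'   integers), otherwise an [image_volume()].
#' @return An `image_volume` or `label_mask` with spacing taken from the
#'   NIfTI header; intensity values are not modified.
#' @export
load_volume <- function(path, mask = FALSE) {
  assert_that(is.character(path) && length(path) == 1L, "`path` must be a single string")
  if (!file.exists(path)) {
    stop_cs(sprintf("file does not exist: %s", path), "cs_io_error")
  }
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) {
    stop_cs(sprintf("expected a 3D image, got %d axes in %s", length(d), path),
            "cs_shape_error")
  }
  spacing <- abs(RNifti::pixdim(img))[1:3]
  data <- array(as.vector(img), dim = d)
  if (mask) label_mask(data, spacing = spacing) else image_volume(data, spacing = spacing)
}

#' Save a volume or mask to a NIfTI file
#'
#' Masks (and any volume whose `data` is integer) are written as unsigned
#' 8-bit NIfTI when their values fit in 0..255, preserving integer type on
#' reload; floating-point data is written in double precision so round-trips
#' are lossless.
#'
#' @param vol An [image_volume()] or [label_mask()].
#' @param path Output file path (`.nii` or `.nii.gz`); parent directory must
#'   exist and be writable.
#' @return Invisibly, `path`.
#' @export
save_volume <- function(vol, path) {
  assert_that(inherits(vol, "image_volume"), "`vol` must be an image_volume or label_mask")
  dir <- dirname(path)
  if (!dir.exists(dir) || file.access(dir, 2L) != 0L) {
    stop_cs(sprintf("directory not writable: %s", dir), "cs_io_error")
  }
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  datatype <- if (is.integer(vol$data)) {
    if (max(vol$data) <= 255L) "uint8" else "int32"
  } else {
    "double"
  }
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Check that a volume and a mask share the same geometry
#'
#' @param vol An [image_volume()].
#' @param mask A [label_mask()] (or second volume).
#' @param tol Relative spacing tolerance (default `1e-4`).
#' @return `TRUE` iff shapes are equal and spacings agree within `tol`
#'   relative tolerance; `FALSE` otherwise (never errors on mismatch).
#' @export
validate_alignment <- function(vol, mask, tol = 1e-4) {
  if (!identical(dim(vol$data), dim(mask$data))) return(FALSE)
  rel <- abs(vol$spacing - mask$spacing) / pmax(abs(vol$spacing), .Machine$double.eps)
  all(rel <= tol)
}
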