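# Gray-level histograms, the cumulative equalization map, histogram matching
# between volumes, and training-cohort augmentation with test-center
# histograms.
#
# The equalized level of gray level k is
#     s_k = (L - 1) / M * sum_{j <= k} n_j,
# with M the total voxel count (the 2D "width x height" generalized to 3D)
# and n_j the count of voxels at level j.  Matching composes the source's
# equalization map with the inverse of the reference's: source level k maps
# to the reference level whose equalized value is nearest to s_k (ties to
# the lower level).

#' Compute the gray-level histogram of a volume
#'
#' Intensities are linearly quantized from the volume's own `[min, max]`
#' range into `L` levels (MRI intensities are not calibrated across
#' scanners, so quantization is per-volume).  A constant volume puts all
#' mass in level 0.
#'
#' The histogram also records the intensity range it was computed over, so
#' a matched volume can be expressed on the reference's intensity scale.
#'
#' @param vol An [image_volume()].
#' @param L Number of gray levels (>= 2), default 256.
#' @return An object of class `gray_histogram` with fields `counts`
#'   (length `L`, levels `0..L-1`), `L`, `total`, and `range`.
#' @export
compute_histogram <- function(vol, L = 256L) {
  assert_that(is_count(L) && L >= 2, "`L` must be an integer >= 2")
  x <- as.vector(vol$data)
  rng <- range(x)
  lev <- quantize_levels(x, rng, L)
  counts <- tabulate(lev + 1L, nbins = L)
  structure(list(counts = counts, L = as.integer(L), total = length(x), range = rng),
            class = "gray_histogram")
}

# map intensities to integer levels 0..L-1 over the range rng
quantize_levels <- function(x, rng, L) {
  if (diff(rng) == 0) return(rep(0L, length(x)))
  pmin(as.integer(floor((x - rng[1]) / diff(rng) * L)), L - 1L)
}

level_centers <- function(hist) {
  if (diff(hist$range) == 0) return(rep(hist$range[1], hist$L))
  hist$range[1] + (seq_len(hist$L) - 0.5) / hist$L * diff(hist$range)
}

#' Cumulative equalization map of a histogram
#'
#' @param hist A [compute_histogram()] result with `total > 0`.
#' @return An object of class `equalization_map` with field `s`, the
#'   monotone nondecreasing equalized level for each gray level `0..L-1`;
#'   `s[L-1] = L-1` exactly.
#' @export
equalization_map <- function(hist) {
  assert_that(inherits(hist, "gray_histogram"), "`hist` must be a gray_histogram")
  if (hist$total <= 0) stop_cs("histogram is empty", "cs_argument_error")
  s <- (hist$L - 1) / hist$total * cumsum(hist$counts)
  structure(list(s = s, L = hist$L), class = "equalization_map")
}

#' Match a volume's gray-level distribution to a reference histogram
#'
#' Standard equalize-invert composition: each source level maps to the
#' reference level whose equalized value is nearest (ties resolved to the
#' lower level); the output voxel takes the center intensity of its
#' reference level, so the matched volume lives on the reference's
#' intensity scale.  Geometry (shape, spacing) is unchanged and the mapping
#' is monotone, so intensity order is preserved.
#'
#' @param source An [image_volume()].
#' @param reference A `gray_histogram` (the target distribution).
#' @param L Number of gray levels used to quantize the source; must equal
#'   the reference's `L`.
#' @return The matched [image_volume()].
#' @export
match_histogram <- function(source, reference, L = reference$L) {
  assert_that(inherits(reference, "gray_histogram"), "`reference` must be a gray_histogram")
  if (L != reference$L) {
    stop_cs(sprintf("L mismatch: source quantization %d vs reference %d", L, reference$L),
            "cs_argument_error")
  }
  src_hist <- compute_histogram(source, L)
  s_src <- equalization_map(src_hist)$s
  s_ref <- equalization_map(reference)$s
  # nearest reference level per source level; which.min takes the first
  # (lowest) index on ties
  j <- vapply(s_src, function(v) which.min(abs(s_ref - v)), integer(1))
  ref_centers <- level_centers(reference)
  lev <- quantize_levels(as.vector(source$data), src_hist$range, L)
  out <- ref_centers[j[lev + 1L]]
  image_volume(array(out, dim = dim(source$data)),
               spacing = source$spacing, origin = source$origin)
}

#' Serialize / deserialize a gray-level histogram as JSON
#'
#' Histograms carry no patient-identifying information, so they can be
#' shared across centers where raw images cannot.
#'
#' @param hist A `gray_histogram`.
#' @param path JSON file path.
#' @return `save_histogram` returns `path` invisibly; `load_histogram`
#'   returns the `gray_histogram`.
#' @export
save_histogram <- function(hist, path) {
  jsonlite::write_json(unclass(hist), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_histogram
#' @export
load_histogram <- function(path) {
  if (!file.exists(path)) stop_cs(sprintf("file does not exist: %s", path), "cs_io_error")
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(counts = as.numeric(x$counts), L = as.integer(x$L),
                 total = as.numeric(x$total), range = as.numeric(x$range)),
            class = "gray_histogram")
}

#' Augment a training cohort by histogram matching against test centers
#'
#' For each training sample, emits the original plus one copy matched
#' against a uniformly random histogram from the test-center pool (one copy
#' per sample, doubling the set).  Mask paths are reused unchanged: matching
#' never alters geometry.  Deterministic given `seed`.
#'
#' @param train Training cohort tibble (see [load_cohort()]).
#' @param test_histograms Non-empty list of `gray_histogram` objects from
#'   the test center(s).
#' @param out_dir Directory for the matched image files.
#' @param seed Integer seed controlling the histogram assignments.
#' @return A cohort tibble with `2 * nrow(train)` rows; matched copies get
#'   patient ids suffixed `"_hm"`.
#' @export
augment_cohort_by_matching <- function(train, test_histograms,
                                       out_dir = tempfile("hm_"), seed = 1L) {
  assert_that(length(test_histograms) >= 1, "need at least one test histogram")
  validate_cohort(train)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  picks <- with_preserved_rng(seed, sample.int(length(test_histograms),
                                               nrow(train), replace = TRUE))
  matched <- train
  for (i in seq_len(nrow(train))) {
    vol <- load_volume(train$image_path[i])
    mv <- match_histogram(vol, test_histograms[[picks[i]]])
    new_path <- file.path(out_dir, paste0(train$patient_id[i], "_hm_img.nii.gz"))
    save_volume(mv, new_path)
    matched$image_path[i] <- new_path
    matched$patient_id[i] <- paste0(train$patient_id[i], "_hm")
  }
  out <- dplyr::bind_rows(train, matched)
  attr(out, "histogram_picks") <- picks
  out
}
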