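# Binary 3D morphology: connected components by iterative label propagation,
# exact Euclidean distance transform by separable min-plus passes, and
# spherical ("circular" in 3D) dilation.

shift_array <- function(a, off, fill) {
  d <- dim(a)
  src <- vector("list", 3)
  dst <- vector("list", 3)
  for (ax in 1:3) {
    o <- off[ax]
    if (o >= 0) {
      src[[ax]] <- seq_len(d[ax] - o)
      dst[[ax]] <- seq_len(d[ax] - o) + o
    } else {
      src[[ax]] <- seq_len(d[ax] + o) - o
      dst[[ax]] <- seq_len(d[ax] + o)
    }
    if (length(src[[ax]]) == 0) return(array(fill, d))
  }
  out <- array(fill, d)
  out[dst[[1]], dst[[2]], dst[[3]]] <-
    a[src[[1]], src[[2]], src[[3]], drop = FALSE]
  out
}

neighbor_offsets <- function(connectivity = 26L) {
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6L) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  if (connectivity == 18L) offs <- offs[rowSums(abs(offs)) <= 2, , drop = FALSE]
  offs
}

# Connected-component labels of a binary array: each foreground voxel gets
# the smallest linear index in its component (iterated min-propagation).
label_components <- function(bin, connectivity = 26L) {
  d <- dim(bin)
  fg <- bin > 0
  lab <- array(Inf, d)
  lab[fg] <- which(fg)
  offs <- neighbor_offsets(connectivity)
  repeat {
    new <- lab
    for (r in seq_len(nrow(offs))) {
      new <- pmin(new, shift_array(lab, offs[r, ], Inf))
    }
    new[!fg] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  lab[!fg] <- 0
  lab
}

#' Keep only the largest connected component of a binary mask
#'
#' Components use 26-connectivity by default.  Ties between equally sized
#' components are broken deterministically in favor of the component
#' containing the lowest linear voxel index.  An empty mask is returned
#' unchanged with attribute `"empty" = TRUE` and a warning.
#'
#' @param mask A binary [label_mask()].
#' @param connectivity 6, 18 or 26 (default 26).
#' @return A [label_mask()] containing only the largest component.
#' @export
largest_component <- function(mask, connectivity = 26L) {
  bin <- mask$data > 0
  if (!any(bin)) {
    rlang::warn("largest_component: mask is empty")
    out <- label_mask(array(0L, dim(mask$data)), spacing = mask$spacing,
                      origin = mask$origin)
    attr(out, "empty") <- TRUE
    return(out)
  }
  lab <- label_components(bin, connectivity)
  ids <- lab[lab > 0]
  tab <- table(ids)
  sizes <- as.vector(tab)
  # max size; ties -> smallest component id = lowest linear index
  best <- as.numeric(names(tab)[sizes == max(sizes)])[1]
  keep <- array(as.integer(lab == best), dim(mask$data))
  label_mask(keep, spacing = mask$spacing, origin = mask$origin)
}

# Exact squared Euclidean distance transform (to the nearest foreground
# voxel), separable min-plus per axis; spacing-aware.  O(n^2) per line but
# fully vectorized across lines.
distance_transform_sq <- function(fg, spacing = c(1, 1, 1)) {
  d <- dim(fg)
  D <- array(ifelse(fg, 0, Inf), d)
  for (ax in 1:3) {
    n <- d[ax]
    if (n == 1) next
    perm <- c(ax, setdiff(1:3, ax))
    Dm <- matrix(aperm(D, perm), nrow = n)
    off2 <- outer(seq_len(n), seq_len(n),
                  function(i, k) ((i - k) * spacing[ax])^2)
    res <- matrix(Inf, nrow(Dm), ncol(Dm))
    for (i in seq_len(n)) {
      cand <- Dm + off2[, i]
      res[i, ] <- do.call(pmin, lapply(seq_len(n), function(k) cand[k, ]))
    }
    D <- aperm(array(res, d[perm]), order(perm))
  }
  D
}

#' Dilate a binary mask with a spherical structuring element
#'
#' Morphological dilation by the discrete ball of the given radius (in
#' voxels): a voxel is foreground in the output iff its Euclidean distance
#' to the input foreground is at most `radius_vox`.  Radius 0 is the
#' identity.  Implemented with an exact distance transform, computed on the
#' padded bounding box of the foreground for speed.
#'
#' @param mask A binary [label_mask()].
#' @param radius_vox Nonnegative integer radius in voxels.
#' @return The dilated [label_mask()].
#' @export
dilate_lesion <- function(mask, radius_vox) {
  assert_that(is.numeric(radius_vox) && length(radius_vox) == 1 && radius_vox >= 0,
              "`radius_vox` must be a nonnegative number")
  if (radius_vox == 0 || !any(mask$data > 0)) return(mask)
  d <- dim(mask$data)
  bb <- mask_bbox(mask$data > 0)
  r <- as.integer(ceiling(radius_vox))
  lo <- pmax(bb$lo - r, 1L)
  hi <- pmin(bb$hi + r, d)
  sub <- mask$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE] > 0
  D2 <- distance_transform_sq(sub)
  out <- array(0L, d)
  out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- as.integer(D2 <= radius_vox^2)
  label_mask(out, spacing = mask$spacing, origin = mask$origin)
}

mask_bbox <- function(bin) {
  stopifnot(any(bin))
  d <- dim(bin)
  ix <- which(bin) - 1L
  c1 <- ix %% d[1]
  c2 <- (ix %/% d[1]) %% d[2]
  c3 <- ix %/% (d[1] * d[2])
  list(lo = c(min(c1), min(c2), min(c3)) + 1L,
       hi = c(max(c1), max(c2), max(c3)) + 1L)
}
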