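# Segmentation overlap/surface metrics and classification metrics.

check_mask_pair <- function(a, b) {
  if (!validate_alignment(a, b)) {
    stop_cs("masks are not aligned (shape/spacing mismatch)", "cs_alignment_error")
  }
}

#' Dice coefficient between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param a,b Aligned binary [label_mask()] objects.
#' @return Scalar in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  check_mask_pair(a, b)
  A <- a$data > 0; B <- b$data > 0
  if (!any(A) && !any(B)) return(1)
  2 * sum(A & B) / (sum(A) + sum(B))
}

#' Intersection over union (Jaccard) between two binary masks
#'
#' `|A n B| / |A u B|`; defined as 1 when both masks are empty.
#'
#' @inheritParams dice_coefficient
#' @return Scalar in `[0, 1]`.
#' @export
iou <- function(a, b) {
  check_mask_pair(a, b)
  A <- a$data > 0; B <- b$data > 0
  if (!any(A) && !any(B)) return(1)
  sum(A & B) / sum(A | B)
}

# surface voxels: foreground with at least one 6-neighbor outside the mask
surface_voxels <- function(bin, spacing) {
  inner <- bin
  for (ax in 1:3) {
    for (dir in c(-1L, 1L)) {
      off <- integer(3); off[ax] <- dir
      inner <- inner & shift_array(bin, off, FALSE)
    }
  }
  surf <- bin & !inner
  d <- dim(bin)
  ix <- which(surf) - 1L
  cbind((ix %% d[1]) * spacing[1],
        ((ix %/% d[1]) %% d[2]) * spacing[2],
        (ix %/% (d[1] * d[2])) * spacing[3])
}

min_dists <- function(from, to) {
  # chunked pairwise distances; sizes here are surface sets, a few thousand
  out <- numeric(nrow(from))
  chunk <- 2000L
  for (start in seq.int(1L, nrow(from), by = chunk)) {
    rows <- start:min(start + chunk - 1L, nrow(from))
    d2 <- outer(rowSums(from[rows, , drop = FALSE]^2), rowSums(to^2), "+") -
      2 * from[rows, , drop = FALSE] %*% t(to)
    out[rows] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' 95th-percentile Hausdorff distance between two masks
#'
#' The 95th percentile of the pooled symmetric surface-distance set
#' (distances from each surface voxel of A to the nearest surface voxel of
#' B, and vice versa), in mm.  Surface voxels are defined by 6-connectivity
#' erosion difference.
#'
#' @inheritParams dice_coefficient
#' @param percentile Percentile of the pooled distance set (default 95).
#' @return Distance in mm.
#' @export
hd95 <- function(a, b, percentile = 95) {
  check_mask_pair(a, b)
  A <- a$data > 0; B <- b$data > 0
  if (!any(A) || !any(B)) stop_cs("hd95 requires two nonempty masks", "cs_metric_error")
  sa <- surface_voxels(A, a$spacing)
  sb <- surface_voxels(B, b$spacing)
  d <- c(min_dists(sa, sb), min_dists(sb, sa))
  as.numeric(stats::quantile(d, percentile / 100, type = 7))
}

#' Classification accuracy
#'
#' @param labels True 0/1 labels.
#' @param predictions Predicted 0/1 labels.
#' @return Fraction of correct predictions.
#' @export
accuracy <- function(labels, predictions) {
  assert_that(length(labels) == length(predictions), "length mismatch")
  mean(labels == predictions)
}

#' Area under the ROC curve (rank-based)
#'
#' Mann-Whitney form: the probability that a random positive scores above a
#' random negative, ties counted 1/2.
#'
#' @param labels True 0/1 labels (both classes must be present).
#' @param scores Real-valued scores (higher = more positive).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(labels, scores) {
  assert_that(length(labels) == length(scores), "length mismatch")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop_cs("AUC needs both classes present", "cs_metric_error")
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

#' Evaluate predicted masks against ground truth
#'
#' @param pred,truth Lists of aligned binary [label_mask()] pairs (same
#'   length and order).
#' @param ids Optional identifiers.
#' @return A tibble with `id`, `dice`, `iou`, `hd95` (NA when either mask
#'   is empty).
#' @export
evaluate_masks <- function(pred, truth, ids = seq_along(pred)) {
  assert_that(length(pred) == length(truth), "pred/truth length mismatch")
  rows <- lapply(seq_along(pred), function(i) {
    h <- if (any(pred[[i]]$data > 0) && any(truth[[i]]$data > 0)) {
      hd95(pred[[i]], truth[[i]])
    } else {
      NA_real_
    }
    tibble::tibble(id = ids[i],
                   dice = dice_coefficient(pred[[i]], truth[[i]]),
                   iou = iou(pred[[i]], truth[[i]]),
                   hd95 = h)
  })
  dplyr::bind_rows(rows)
}
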