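# Compound segmentation loss: L_total = L_dice + L_ce.
#
#   L_ce   = -(1/N) sum_i sum_k v_ik log u_ik
#   L_dice = -(2/K) sum_k (sum_i u_ik v_ik + eps) /
#                         (sum_i u_ik + sum_i v_ik + eps)
#
# u are predicted per-voxel class probabilities, v the ground-truth one-hot
# code, K the number of classes (background included -- the sum over k runs
# over all classes), N the voxel count.  The soft Dice term is smoothed with
# eps in numerator and denominator so classes absent from both prediction
# and truth contribute ~eps/eps-scaled terms instead of 0/0.

as_prob_matrix <- function(u) {
  if (is.matrix(u)) return(u)
  d <- dim(u)
  matrix(u, nrow = prod(d[-length(d)]), ncol = d[length(d)])
}

#' One-hot encode a label mask
#'
#' @param labels Integer vector/array of class labels in `0..K-1`.
#' @param K Number of classes.
#' @return An `N x K` 0/1 matrix with exactly one 1 per row.
#' @export
one_hot <- function(labels, K) {
  lab <- as.integer(as.vector(labels))
  assert_that(all(lab >= 0 & lab < K), "labels must lie in 0..K-1")
  v <- matrix(0, length(lab), K)
  v[cbind(seq_along(lab), lab + 1L)] <- 1
  v
}

check_uv <- function(u, v) {
  assert_that(identical(dim(u), dim(v)),
              "prediction and truth shapes differ", "cs_argument_error")
}

#' Cross-entropy loss
#'
#' Mean over voxels of `-sum_k v_ik log(u_ik)`; probabilities are clipped to
#' `[eps, 1]` before the log.
#'
#' @param u Predicted probabilities, an `N x K` matrix (or array with class
#'   as last axis).
#' @param v One-hot ground truth of the same shape.
#' @param eps Clipping floor for the log (default `1e-7`).
#' @return Nonnegative scalar.
#' @export
ce_loss <- function(u, v, eps = 1e-7) {
  u <- as_prob_matrix(u); v <- as_prob_matrix(v)
  check_uv(u, v)
  -sum(v * log(pmax(u, eps))) / nrow(u)
}

#' Soft Dice loss
#'
#' `-(2/K) sum_k (sum_i u_ik v_ik + eps) / (sum_i u_ik + sum_i v_ik + eps)`,
#' summed over all `K` classes including background; lies in `[-1, 0]`.
#'
#' @inheritParams ce_loss
#' @param eps Additive smoothing for absent classes (default `1e-5`).
#' @return Scalar in `[-1, 0]`.
#' @export
dice_loss <- function(u, v, eps = 1e-5) {
  u <- as_prob_matrix(u); v <- as_prob_matrix(v)
  check_uv(u, v)
  K <- ncol(u)
  num <- colSums(u * v) + eps
  den <- colSums(u) + colSums(v) + eps
  -(2 / K) * sum(num / den)
}

#' Total segmentation loss
#'
#' The exact sum `dice_loss(u, v) + ce_loss(u, v)`.
#'
#' @inheritParams ce_loss
#' @return Scalar.
#' @export
total_loss <- function(u, v) {
  dice_loss(u, v) + ce_loss(u, v)
}

# Gradient of L_total with respect to the softmax logits z (u = softmax(z)).
# dCE/dz = (u - v)/N;  for Dice, dL/du_ik = -(2/K) (v_ik D_k - N_k) / D_k^2
# is pushed through the softmax Jacobian.
total_loss_logit_grad <- function(u, v, eps_dice = 1e-5) {
  N <- nrow(u)
  K <- ncol(u)
  g_ce <- (u - v) / N
  num <- colSums(u * v) + eps_dice
  den <- colSums(u) + colSums(v) + eps_dice
  g_u <- -(2 / K) * (sweep(v, 2, den, "*") - rep(num, each = N)) /
    rep(den^2, each = N)
  dot <- rowSums(g_u * u)
  g_dice <- u * (g_u - dot)
  g_ce + g_dice
}
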