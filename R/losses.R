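# Training objective: hybrid Dice + binary cross-entropy on the region
# map, BCE on the boundary map, and a gradient-aligned term that matches
# the Sobel gradient magnitude of the predicted region map to that of the
# ground truth. All three terms vanish at a perfect binary prediction (up
# to the BCE clamping epsilon).

#' Loss weights
#'
#' @param alpha Weight of the region (Dice + BCE) term.
#' @param beta Weight of the boundary BCE term.
#' @param gamma Weight of the gradient-aligned term. Values outside the
#'   recommended `[0.1, 0.5]` band trigger a warning (not an error).
#' @param dice_mix Dice fraction inside the hybrid region term, in
#'   `[0, 1]`.
#' @param eps Dice smoothing constant (stabilizes empty-mask batches).
#' @return A `loss_weights` list.
#' @export
loss_weights <- function(alpha = 0.6, beta = 0.2, gamma = 0.2,
                         dice_mix = 0.5, eps = 1) {
  if (alpha < 0 || beta < 0 || gamma < 0)
    stop("loss_weights: weights must be >= 0")
  if (alpha + beta + gamma == 0)
    stop("loss_weights: at least one weight must be positive")
  if (dice_mix < 0 || dice_mix > 1)
    stop("loss_weights: dice_mix must be in [0, 1]")
  if (gamma != 0 && (gamma < 0.1 || gamma > 0.5))
    warning("loss_weights: gamma outside the recommended [0.1, 0.5] band")
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 dice_mix = dice_mix, eps = eps),
            class = "loss_weights")
}

.check_shapes <- function(a, b, what) {
  da <- dim(a); db <- dim(b)
  if (is.null(da)) da <- length(a)
  if (is.null(db)) db <- length(b)
  if (!identical(as.integer(da), as.integer(db)))
    stop(what, ": shape mismatch (", paste(da, collapse = "x"), " vs ",
         paste(db, collapse = "x"), ")")
}

# node-level terms (used by both the public scalar API and training)

.dice_bce_node <- function(p, y, dice_mix, eps) {
  dice <- op_soft_dice(p, y, eps)
  bce <- op_bce_mean(p, y)
  op_wsum(list(op_add_const(op_scale(dice, -1), 1), bce),
          c(dice_mix, 1 - dice_mix))
}

.glga_node <- function(p, y_true) {
  kx <- array(sobel_kx(), c(3, 3, 1, 1))
  ky <- array(sobel_ky(), c(3, 3, 1, 1))
  gx <- op_conv2d(p, kx, NULL, pad = 1L, replicate = TRUE)
  gy <- op_conv2d(p, ky, NULL, pad = 1L, replicate = TRUE)
  mag <- op_hypot_eps(gx, gy)
  yt <- as4d(node_value(y_true))
  tgx <- cpp_conv2d_forward(yt, kx, NULL, 1L, 1L, 1L, 1L)
  tgy <- cpp_conv2d_forward(yt, ky, NULL, 1L, 1L, 1L, 1L)
  tmag <- sqrt(tgx^2 + tgy^2 + 1e-12)
  op_mae_const(mag, tmag)
}

#' Hybrid Dice + BCE segmentation loss
#'
#' `dice_mix * (1 - softDice) + (1 - dice_mix) * BCE`, with
#' `softDice = (2*sum(p*y) + eps) / (sum(p) + sum(y) + eps)` and BCE
#' probabilities clamped to `[1e-7, 1 - 1e-7]`.
#'
#' @param y_pred Probability array in `[0, 1]`.
#' @param y_true Binary array of the same shape.
#' @param dice_mix,eps See [loss_weights()].
#' @return Nonnegative scalar.
#' @export
dice_bce_loss <- function(y_pred, y_true, dice_mix = 0.5, eps = 1) {
  .check_shapes(y_pred, y_true, "dice_bce_loss")
  node_value(.dice_bce_node(ad_const(as4d(y_pred)), as4d(y_true),
                            dice_mix, eps))
}

#' Mean binary cross-entropy for the boundary head
#'
#' @param y_edge_pred Probability array.
#' @param edge_true Binary array of the same shape.
#' @return Nonnegative scalar.
#' @export
edge_bce <- function(y_edge_pred, edge_true) {
  .check_shapes(y_edge_pred, edge_true, "edge_bce")
  node_value(op_bce_mean(ad_const(as4d(y_edge_pred)), as4d(edge_true)))
}

#' Gradient-aligned boundary loss
#'
#' Sobel gradients (replicate padding) of the predicted and true region
#' maps are reduced to magnitude fields; the loss is the mean absolute
#' difference of the two fields. Differentiable in the prediction (the
#' magnitude square root is stabilized with a tiny epsilon).
#'
#' @param y_pred Probability array (may be soft).
#' @param y_true Binary array of the same shape.
#' @return Nonnegative scalar.
#' @export
gradient_aligned_loss <- function(y_pred, y_true) {
  .check_shapes(y_pred, y_true, "gradient_aligned_loss")
  node_value(.glga_node(ad_const(as4d(y_pred)), as4d(y_true)))
}

#' Full training objective
#'
#' `alpha * L_seg + beta * L_edge + gamma * L_glga` on the bundle's region
#' and boundary maps.
#'
#' @param pred A `prediction_bundle` (or list with `y_seg`, `y_edge`).
#' @param region_true,edge_true Binary ground-truth arrays.
#' @param w A [loss_weights()].
#' @return A `loss_breakdown`: `l_seg`, `l_edge`, `l_glga`, `l_total`.
#' @export
total_loss <- function(pred, region_true, edge_true, w = loss_weights()) {
  l_seg <- dice_bce_loss(pred$y_seg, region_true, w$dice_mix, w$eps)
  l_edge <- edge_bce(pred$y_edge, edge_true)
  l_glga <- gradient_aligned_loss(pred$y_seg, region_true)
  structure(list(l_seg = l_seg, l_edge = l_edge, l_glga = l_glga,
                 l_total = w$alpha * l_seg + w$beta * l_edge +
                   w$gamma * l_glga),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("loss: total %.5f (seg %.5f, edge %.5f, glga %.5f)\n",
              x$l_total, x$l_seg, x$l_edge, x$l_glga))
  invisible(x)
}

# node-level total loss for training; returns nodes and numeric breakdown
.total_loss_node <- function(y_seg, y_edge, region_true, edge_true, w) {
  rt <- as4d(region_true)
  et <- as4d(edge_true)
  l_seg <- .dice_bce_node(y_seg, rt, w$dice_mix, w$eps)
  l_edge <- op_bce_mean(y_edge, et)
  l_glga <- .glga_node(y_seg, rt)
  total <- op_wsum(list(l_seg, l_edge, l_glga), c(w$alpha, w$beta, w$gamma))
  list(node = total,
       breakdown = c(l_seg = node_value(l_seg), l_edge = node_value(l_edge),
                     l_glga = node_value(l_glga), l_total = node_value(total)))
}
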