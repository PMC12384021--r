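# Region- and boundary-level evaluation: Dice, IoU, pixel precision and
# recall, boundary F1 with a pixel tolerance, and the exact symmetric
# Hausdorff distance between boundary pixel sets.

#' Metrics configuration
#'
#' @param threshold Binarization cutoff for probability maps, in (0, 1).
#' @param bf1_tolerance Boundary-F1 matching tolerance delta in pixels.
#' @param hd_empty_policy Value reported (and flagged) for the Hausdorff
#'   distance when a boundary set is empty: `"diagonal"` uses the image
#'   diagonal; a number is used as-is.
#' @return A `metrics_config` list.
#' @export
metrics_config <- function(threshold = 0.5, bf1_tolerance = 2,
                           hd_empty_policy = "diagonal") {
  if (threshold <= 0 || threshold >= 1)
    stop("metrics_config: threshold must be in (0, 1)")
  if (bf1_tolerance < 0)
    stop("metrics_config: bf1_tolerance must be >= 0")
  structure(list(threshold = threshold, bf1_tolerance = bf1_tolerance,
                 hd_empty_policy = hd_empty_policy),
            class = "metrics_config")
}

#' Pixel confusion counts
#'
#' @param pred_bin,true_bin Binary arrays of identical shape.
#' @return Named list `TP`, `FP`, `FN`, `TN`.
#' @export
confusion_counts <- function(pred_bin, true_bin) {
  .check_shapes(pred_bin, true_bin, "confusion_counts")
  p <- pred_bin > 0
  t <- true_bin > 0
  list(TP = sum(p & t), FP = sum(p & !t), FN = sum(!p & t),
       TN = sum(!p & !t))
}

flagged <- function(value, flag) {
  attr(value, "flag") <- flag
  value
}

#' Dice similarity coefficient from confusion counts
#'
#' `2TP / (2TP + FP + FN)`. When both masks are empty the convention is
#' 1.0 with a `"degenerate"` flag attribute.
#'
#' @param counts From [confusion_counts()].
#' @export
dice <- function(counts) {
  den <- 2 * counts$TP + counts$FP + counts$FN
  if (den == 0) return(flagged(1.0, "degenerate"))
  2 * counts$TP / den
}

#' Intersection over union (Jaccard) from confusion counts
#' @inheritParams dice
#' @export
iou <- function(counts) {
  den <- counts$TP + counts$FP + counts$FN
  if (den == 0) return(flagged(1.0, "degenerate"))
  counts$TP / den
}

#' Pixel precision and recall from confusion counts
#'
#' Empty denominators follow the Dice convention: 1 (flagged) if the
#' counterpart mask is also empty, else 0 (flagged).
#'
#' @inheritParams dice
#' @return Named vector `precision`, `recall` (flag attribute when
#'   degenerate).
#' @export
precision_recall <- function(counts) {
  prec <- if (counts$TP + counts$FP == 0) {
    if (counts$FN == 0) flagged(1.0, "degenerate") else flagged(0.0, "degenerate")
  } else counts$TP / (counts$TP + counts$FP)
  rec <- if (counts$TP + counts$FN == 0) {
    if (counts$FP == 0) flagged(1.0, "degenerate") else flagged(0.0, "degenerate")
  } else counts$TP / (counts$TP + counts$FN)
  c(precision = as.numeric(prec), recall = as.numeric(rec))
}

#' Boundary pixels of a binary mask
#'
#' Inner boundary under 4-connectivity: foreground pixels with at least
#' one 4-neighbor that is background or outside the frame. A subset of the
#' mask by construction.
#'
#' @param mask_bin Binary matrix.
#' @return Two-column matrix of (row, col) coordinates (possibly 0 rows).
#' @export
extract_boundary <- function(mask_bin) {
  m <- mask_bin > 0
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- m
  core <- pad[2:(h + 1), 2:(w + 1)]
  nb <- pad[1:h, 2:(w + 1)] & pad[3:(h + 2), 2:(w + 1)] &
    pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)]
  b <- core & !nb
  out <- which(b, arr.ind = TRUE)
  colnames(out) <- c("row", "col")
  out
}

#' Symmetric Hausdorff distance between boundary sets
#'
#' Maximum over both directed max-min Euclidean distances. If either set
#' is empty the policy value is returned with a flag.
#'
#' @param p_boundary,g_boundary Coordinate matrices from
#'   [extract_boundary()].
#' @param cfg A [metrics_config()].
#' @param diag Image diagonal used when `hd_empty_policy = "diagonal"`
#'   (defaults to `Inf` if unknown).
#' @return Distance in pixels (flag attribute when degenerate).
#' @export
hausdorff <- function(p_boundary, g_boundary, cfg = metrics_config(),
                      diag = Inf) {
  np <- nrow(p_boundary); ng <- nrow(g_boundary)
  if (np == 0 || ng == 0) {
    v <- if (identical(cfg$hd_empty_policy, "diagonal")) diag
         else as.numeric(cfg$hd_empty_policy)
    return(flagged(v, "empty-boundary"))
  }
  d1 <- max(cpp_min_dists(p_boundary + 0, g_boundary + 0))
  d2 <- max(cpp_min_dists(g_boundary + 0, p_boundary + 0))
  max(d1, d2)
}

#' Boundary F1 score with pixel tolerance
#'
#' Boundary precision is the fraction of predicted boundary pixels within
#' Euclidean distance `delta` of any true boundary pixel; recall is the
#' symmetric fraction; BF1 their harmonic mean (0 when both are 0). Both
#' sets empty gives 1 (flagged); exactly one empty gives 0 (flagged).
#'
#' @param p_boundary,g_boundary Coordinate matrices.
#' @param delta Tolerance in pixels (>= 0).
#' @export
boundary_f1 <- function(p_boundary, g_boundary, delta = 2) {
  if (delta < 0) stop("boundary_f1: delta must be >= 0")
  np <- nrow(p_boundary); ng <- nrow(g_boundary)
  if (np == 0 && ng == 0) return(flagged(1.0, "degenerate"))
  if (np == 0 || ng == 0) return(flagged(0.0, "degenerate"))
  tol <- delta + 1e-9
  prec <- mean(cpp_min_dists(p_boundary + 0, g_boundary + 0) <= tol)
  rec <- mean(cpp_min_dists(g_boundary + 0, p_boundary + 0) <= tol)
  if (prec + rec == 0) return(0)
  2 * prec * rec / (prec + rec)
}

#' Evaluate one prediction against ground truth
#'
#' Binarizes the probability map at `cfg$threshold` and computes all
#' region and boundary metrics.
#'
#' @param pred_prob Probability matrix (or already-binary mask).
#' @param true_mask Binary matrix.
#' @param cfg A [metrics_config()].
#' @return A `metrics_report`: `dice`, `iou`, `bf1`, `precision`,
#'   `recall`, `hausdorff`, `flags`.
#' @export
evaluate <- function(pred_prob, true_mask, cfg = metrics_config()) {
  .check_shapes(pred_prob, true_mask, "evaluate")
  pb <- (pred_prob > cfg$threshold) * 1L
  tb <- (true_mask > 0) * 1L
  cc <- confusion_counts(pb, tb)
  dv <- dice(cc)
  iv <- iou(cc)
  pr <- precision_recall(cc)
  bp <- extract_boundary(pb)
  bg <- extract_boundary(tb)
  diag <- sqrt(nrow(pb)^2 + ncol(pb)^2)
  hd <- hausdorff(bp, bg, cfg, diag = diag)
  bf <- boundary_f1(bp, bg, cfg$bf1_tolerance)
  flags <- character(0)
  if (!is.null(attr(dv, "flag"))) flags <- c(flags, "region-degenerate")
  if (!is.null(attr(hd, "flag"))) flags <- c(flags, "empty-boundary")
  if (!is.null(attr(bf, "flag"))) flags <- c(flags, "bf1-degenerate")
  structure(list(dice = as.numeric(dv), iou = as.numeric(iv),
                 bf1 = as.numeric(bf),
                 precision = unname(pr["precision"]),
                 recall = unname(pr["recall"]),
                 hausdorff = as.numeric(hd), flags = flags),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "dice %.4f | iou %.4f | bf1 %.4f | prec %.4f | rec %.4f | hd %.2f%s\n",
    x$dice, x$iou, x$bf1, x$precision, x$recall, x$hausdorff,
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
    else ""))
  invisible(x)
}

#' Aggregate metric reports
#'
#' @param reports Non-empty list of `metrics_report` objects.
#' @param exclude_degenerate Drop flagged images from the per-metric
#'   means/sds (the counts are still reported)?
#' @return Data frame with one row per metric (`mean`, `sd`, `n`), plus
#'   attributes `n_flagged` and `hd_valid_fraction` (share of reports
#'   whose Hausdorff distance came from two non-empty boundaries).
#' @export
aggregate_reports <- function(reports, exclude_degenerate = FALSE) {
  if (length(reports) == 0) stop("aggregate_reports: empty report list")
  keep <- if (exclude_degenerate)
    vapply(reports, function(r) length(r$flags) == 0, logical(1))
  else rep(TRUE, length(reports))
  if (!any(keep)) keep <- rep(TRUE, length(reports))
  metrics <- c("dice", "iou", "bf1", "precision", "recall", "hausdorff")
  rows <- lapply(metrics, function(m) {
    v <- vapply(reports[keep], function(r) r[[m]], numeric(1))
    data.frame(metric = m, mean = mean(v),
               sd = if (length(v) > 1) sd(v) else 0, n = length(v))
  })
  out <- do.call(rbind, rows)
  attr(out, "n_flagged") <-
    sum(vapply(reports, function(r) length(r$flags) > 0, logical(1)))
  attr(out, "hd_valid_fraction") <-
    mean(vapply(reports, function(r) !"empty-boundary" %in% r$flags,
                logical(1)))
  out
}
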