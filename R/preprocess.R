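# Preprocessing: Reinhard stain standardization, grayscale conversion,
# bicubic resizing, intensity standardization, morphological mask cleaning
# and edge-target derivation.
#
# Pipeline order for RGB input: Reinhard -> grayscale -> resize -> [0,1]
# scaling -> zero-mean/unit-variance. Reinhard needs color, grayscale
# conversion precedes resizing to cut cost, and masks are resized with
# nearest-neighbor so they stay strictly binary.

#' Preprocessing configuration
#'
#' @param target_size Output square side in pixels (>= 32; 256 matches the
#'   evaluation resolution used for the published metrics).
#' @param reference_lab_stats Optional list `(mean, sd)` of per-channel LAB
#'   statistics for Reinhard standardization; if `NULL`, callers typically
#'   compute it from the first training image via [lab_stats()].
#' @param grayscale Convert to single channel (luminosity weights
#'   0.299/0.587/0.114)?
#' @param use_reinhard Apply Reinhard standardization to RGB input? Ignored
#'   for grayscale input.
#' @param min_object_px Smallest connected component (8-connectivity)
#'   retained by [clean_mask()].
#' @param opening_radius Disk radius (px) of the morphological opening in
#'   [clean_mask()]; 0 skips the opening.
#' @param edge_thickness Boundary-band width in pixels for [edge_target()].
#' @return A `preproc_config` list.
#' @export
preproc_config <- function(target_size = 256L,
                           reference_lab_stats = NULL,
                           grayscale = TRUE,
                           use_reinhard = TRUE,
                           min_object_px = 10L,
                           opening_radius = 1L,
                           edge_thickness = 1L) {
  cfg <- list(target_size = as.integer(target_size),
              reference_lab_stats = reference_lab_stats,
              grayscale = isTRUE(grayscale),
              use_reinhard = isTRUE(use_reinhard),
              min_object_px = as.integer(min_object_px),
              opening_radius = as.integer(opening_radius),
              edge_thickness = as.integer(edge_thickness))
  if (cfg$target_size < 32L) stop("preproc_config: target_size must be >= 32")
  if (cfg$min_object_px < 0L) stop("preproc_config: min_object_px must be >= 0")
  if (cfg$edge_thickness < 1L) stop("preproc_config: edge_thickness must be >= 1")
  class(cfg) <- "preproc_config"
  cfg
}

#' Per-channel LAB statistics of an RGB image
#'
#' @param image RGB array `(H, W, 3)` with values in `[0, 1]`.
#' @return List with `mean` and `sd` (sample sd), each length 3 (L, a, b).
#' @export
lab_stats <- function(image) {
  lab <- rgb_to_lab(image)
  list(mean = colMeans(lab), sd = apply(lab, 2L, sd))
}

rgb_to_lab <- function(image) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L)
    stop("expected an RGB array (H, W, 3)")
  m <- matrix(image, ncol = 3L)
  grDevices::convertColor(m, from = "sRGB", to = "Lab")
}

lab_to_rgb <- function(lab, h, w) {
  m <- grDevices::convertColor(lab, from = "Lab", to = "sRGB")
  m <- pmin(pmax(m, 0), 1)
  array(m, c(h, w, 3L))
}

#' Reinhard color standardization
#'
#' Matches the per-channel mean and spread of the image in LAB space to a
#' reference: each channel is rescaled as
#' `(x - mean_src) * sd_ref / sd_src + mean_ref` and converted back to RGB.
#' A source channel with zero spread is shifted only.
#'
#' @param image RGB array `(H, W, 3)` in `[0, 1]`.
#' @param ref List `(mean, sd)` of reference LAB statistics (all sds > 0),
#'   e.g. from [lab_stats()].
#' @return RGB array in `[0, 1]` of the same shape.
#' @export
reinhard_normalize <- function(image, ref) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L)
    stop("reinhard_normalize: input must have 3 channels")
  if (any(ref$sd <= 0))
    stop("reinhard_normalize: reference sds must be > 0")
  lab <- rgb_to_lab(image)
  mu <- colMeans(lab)
  sg <- apply(lab, 2L, sd)
  for (c in 1:3) {
    if (sg[c] > 0) {
      lab[, c] <- (lab[, c] - mu[c]) * (ref$sd[c] / sg[c]) + ref$mean[c]
    } else {
      lab[, c] <- lab[, c] - mu[c] + ref$mean[c]
    }
  }
  lab_to_rgb(lab, d[1], d[2])
}

#' Convert RGB to grayscale with luminosity weights
#'
#' @param image `(H, W, 3)` array; single-channel input is passed through.
#' @return Matrix `(H, W)`.
#' @export
to_grayscale <- function(image) {
  d <- dim(image)
  if (length(d) == 2L) return(image)
  if (length(d) == 3L && d[3] == 1L) return(image[, , 1])
  if (length(d) == 3L && d[3] == 3L)
    return(0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3])
  stop("to_grayscale: expected 1 or 3 channels")
}

#' Zero-mean, unit-variance standardization
#'
#' Population moments are used. A constant image cannot be scaled to unit
#' variance; it maps to all zeros with a warning.
#'
#' @param image Numeric array of any shape with at least one element.
#' @return Array of the same shape with mean 0 and sd 1.
#' @export
standardize <- function(image) {
  if (length(image) == 0L) stop("standardize: empty image")
  m <- mean(image)
  s <- sqrt(mean((image - m)^2))
  if (s == 0) {
    warning("standardize: constant image mapped to zeros")
    return(image * 0)
  }
  (image - m) / s
}

#' Bicubic image resize
#'
#' Catmull-Rom bicubic kernel (a = -0.5) with half-pixel alignment and
#' edge clamping.
#'
#' @param image Matrix `(H, W)` or array `(H, W, C)`.
#' @param target_size Output square side (>= 1).
#' @return Resized array of the input's dimensionality.
#' @export
resize_bicubic <- function(image, target_size) {
  if (target_size < 1) stop("resize_bicubic: target_size must be >= 1")
  d <- dim(image)
  was2d <- length(d) == 2L
  if (was2d) dim(image) <- c(d, 1L)
  out <- cpp_resize_bicubic(image, as.integer(target_size),
                            as.integer(target_size))
  if (was2d) out <- out[, , 1]
  out
}

#' Nearest-neighbor mask resize
#'
#' Masks are resized with nearest-neighbor (bicubic would create
#' non-binary values) and re-binarized.
#'
#' @param mask Binary matrix.
#' @param target_size Output square side.
#' @return Binary 0/1 matrix `target_size x target_size`.
#' @export
resize_mask <- function(mask, target_size) {
  if (target_size < 1) stop("resize_mask: target_size must be >= 1")
  h <- nrow(mask); w <- ncol(mask)
  t <- as.integer(target_size)
  if (h == t && w == t) return((mask > 0.5) * 1L)
  map_r <- matrix((seq_len(t) - 0.5) * h / t - 0.5, t, t) # 0-based rows
  map_c <- matrix((seq_len(t) - 0.5) * w / t - 0.5, t, t, byrow = TRUE)
  m <- mask + 0
  dim(m) <- c(h, w, 1L)
  out <- cpp_warp(m, map_r, map_c, 0L)[, , 1]
  (out > 0.5) * 1L
}

# --- binary morphology ------------------------------------------------------
# Shift-accumulate morphology on 0/1 matrices with an explicit convention:
# pixels outside the frame are background. That convention is what makes a
# full-frame mask produce an edge band at the image border.

disk_se <- function(r) {
  if (r < 1) return(matrix(1L, 1L, 1L))
  g <- -r:r
  se <- outer(g, g, function(y, x) (y * y + x * x) <= (r + 0.5)^2)
  se * 1L
}

box_se <- function() matrix(1L, 3L, 3L)

shift_mat <- function(m, dy, dx, fill = 0L) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  ys <- max(1, 1 + dy):min(h, h + dy)
  xs <- max(1, 1 + dx):min(w, w + dx)
  if (length(ys) > 0 && length(xs) > 0)
    out[ys, xs] <- m[ys - dy, xs - dx]
  out
}

bin_dilate <- function(mask, se) {
  r <- (nrow(se) - 1L) %/% 2L
  cidx <- which(se > 0, arr.ind = TRUE)
  out <- matrix(0L, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(cidx)))
    out <- pmax(out, shift_mat(mask, cidx[i, 1] - r - 1L, cidx[i, 2] - r - 1L))
  out
}

bin_erode <- function(mask, se) {
  r <- (nrow(se) - 1L) %/% 2L
  cidx <- which(se > 0, arr.ind = TRUE)
  out <- matrix(1L, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(cidx)))
    out <- pmin(out, shift_mat(mask, cidx[i, 1] - r - 1L, cidx[i, 2] - r - 1L,
                               fill = 0L))
  out
}

bin_open <- function(mask, se) bin_dilate(bin_erode(mask, se), se)

#' Morphological mask cleaning
#'
#' Opens the mask with a disk structuring element of radius
#' `cfg$opening_radius` (offsets with `dy^2 + dx^2 <= (r + 0.5)^2`, so the
#' radius-1 disk is the full 3x3 neighborhood), then
#' removes 8-connected components smaller than `cfg$min_object_px`.
#' The output is always a pixel subset of the opened mask.
#'
#' @param mask Binary matrix.
#' @param cfg A [preproc_config()].
#' @return Cleaned binary 0/1 matrix.
#' @export
clean_mask <- function(mask, cfg = preproc_config()) {
  m <- (mask > 0) * 1L
  if (cfg$opening_radius >= 1L)
    m <- bin_open(m, disk_se(cfg$opening_radius))
  if (cfg$min_object_px > 0L) {
    lab <- cpp_label8(matrix(as.integer(m), nrow(m), ncol(m)))
    if (max(lab) > 0L) {
      sizes <- tabulate(lab[lab > 0L])
      small <- which(sizes < cfg$min_object_px)
      if (length(small) > 0) m[lab %in% small] <- 0L
    }
  }
  m
}

#' Boundary supervision target from a region mask
#'
#' Binarized morphological gradient: dilation minus erosion with a 3x3
#' square element applied `thickness` times. Pixels outside the frame count
#' as background, so a mask touching the border produces an edge band
#' there.
#'
#' @param region_mask Binary matrix.
#' @param thickness Band width in pixels (>= 1).
#' @return Binary 0/1 matrix marking the boundary band.
#' @export
edge_target <- function(region_mask, thickness = 1L) {
  if (thickness < 1L) stop("edge_target: thickness must be >= 1")
  m <- (region_mask > 0) * 1L
  dil <- m; ero <- m
  se <- box_se()
  for (i in seq_len(thickness)) {
    dil <- bin_dilate(dil, se)
    ero <- bin_erode(ero, se)
  }
  ((dil - ero) > 0L) * 1L
}

#' Full image/mask preprocessing for one sample
#'
#' Applies the pipeline (Reinhard if RGB and configured, grayscale, bicubic
#' resize, standardization) to the image and (nearest resize, cleaning,
#' edge derivation) to the mask.
#'
#' @param image Image array in `[0, 1]`.
#' @param region_mask Binary matrix matching the image.
#' @param cfg A [preproc_config()].
#' @return List `x` (standardized `(S, S, 1)` input), `region` and `edge`
#'   (binary `S x S` matrices).
#' @export
preprocess_sample <- function(image, region_mask, cfg = preproc_config()) {
  d <- dim(image)
  if (length(d) == 3L && d[3] == 3L && cfg$use_reinhard &&
      !is.null(cfg$reference_lab_stats))
    image <- reinhard_normalize(image, cfg$reference_lab_stats)
  if (cfg$grayscale) image <- to_grayscale(image)
  img <- resize_bicubic(image, cfg$target_size)
  img <- pmin(pmax(img, 0), 1)
  x <- standardize(img)
  region <- resize_mask(region_mask, cfg$target_size)
  region <- clean_mask(region, cfg)
  edge <- edge_target(region, cfg$edge_thickness)
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  list(x = x, region = region, edge = edge)
}
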