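# On-the-fly training augmentation: flips, bounded rotations, elastic
# deformation and contrast modulation. One spatial transform is composed
# and applied identically to the image and both masks (masks via
# nearest-neighbor, re-binarized); contrast touches the image only.

#' Augmentation configuration
#'
#' @param p_flip_h,p_flip_v,p_rotate,p_elastic,p_contrast Independent
#'   trigger probabilities in `[0, 1]`.
#' @param rotate_max_deg Rotation bound in degrees; the angle is drawn
#'   uniformly from `[-rotate_max_deg, rotate_max_deg]`.
#' @param elastic_alpha Displacement-field magnitude in pixels.
#' @param elastic_sigma Displacement-field smoothness (Gaussian sd, px;
#'   must be > 0). Mild defaults keep nuclear shapes biologically
#'   plausible.
#' @param contrast_range Multiplicative contrast-factor bounds around the
#'   image mean.
#' @return An `augment_config` list.
#' @export
augment_config <- function(p_flip_h = 0.5, p_flip_v = 0.5, p_rotate = 0.5,
                           p_elastic = 0.3, p_contrast = 0.3,
                           rotate_max_deg = 30, elastic_alpha = 20,
                           elastic_sigma = 4, contrast_range = c(0.8, 1.2)) {
  cfg <- list(p_flip_h = p_flip_h, p_flip_v = p_flip_v, p_rotate = p_rotate,
              p_elastic = p_elastic, p_contrast = p_contrast,
              rotate_max_deg = rotate_max_deg, elastic_alpha = elastic_alpha,
              elastic_sigma = elastic_sigma,
              contrast_range = as.numeric(contrast_range))
  ps <- c(cfg$p_flip_h, cfg$p_flip_v, cfg$p_rotate, cfg$p_elastic,
          cfg$p_contrast)
  if (any(ps < 0 | ps > 1))
    stop("augment_config: probabilities must be in [0, 1]")
  if (cfg$elastic_sigma <= 0)
    stop("augment_config: elastic_sigma must be > 0")
  class(cfg) <- "augment_config"
  cfg
}

# smoothed random displacement field, sd-normalized then scaled by alpha
elastic_field <- function(h, w, alpha, sigma, rng) {
  f <- function() {
    z <- matrix(rng$unif(h * w, -1, 1), h, w)
    k <- max(3L, 2L * ceiling(3 * sigma) + 1L)
    g <- dnorm(seq(-(k %/% 2), k %/% 2), sd = sigma)
    g <- g / sum(g)
    kern <- array(outer(g, g), c(k, k, 1L, 1L))
    dim(z) <- c(h, w, 1L, 1L)
    s <- cpp_conv2d_forward(z, kern, NULL, 1L, 1L, k %/% 2L, 1L)
    s <- matrix(s, h, w)
    mx <- max(abs(s))
    if (mx > 0) s / mx * alpha else s
  }
  list(dy = f(), dx = f())
}

#' Apply one augmentation draw to an image/mask/edge triple
#'
#' Each transform triggers independently with its configured probability
#' from the supplied RNG stream. The composed coordinate map is applied
#' once: bilinear for the image, nearest-neighbor (then re-binarized) for
#' both masks, with replicate borders.
#'
#' @param image Matrix or `(H, W, C)` array.
#' @param region_mask,edge_mask Binary matrices of the same spatial size.
#' @param cfg An [augment_config()].
#' @param rng An RNG stream from `make_rng()` (or an integer seed).
#' @return List `(image, region_mask, edge_mask)`.
#' @export
augment <- function(image, region_mask, edge_mask, cfg = augment_config(),
                    rng) {
  if (is.numeric(rng)) rng <- make_rng(as.integer(rng))
  d <- dim(image)
  h <- d[1]; w <- d[2]
  if (!all(dim(region_mask) == c(h, w)) || !all(dim(edge_mask) == c(h, w)))
    stop("augment: arrays must share spatial size")
  do_fh <- rng$unif() < cfg$p_flip_h
  do_fv <- rng$unif() < cfg$p_flip_v
  do_rot <- rng$unif() < cfg$p_rotate
  ang <- if (do_rot) rng$unif(1, -cfg$rotate_max_deg, cfg$rotate_max_deg) else 0
  do_el <- rng$unif() < cfg$p_elastic
  field <- if (do_el)
    elastic_field(h, w, cfg$elastic_alpha, cfg$elastic_sigma, rng) else NULL
  do_ct <- rng$unif() < cfg$p_contrast
  ctf <- if (do_ct) rng$unif(1, cfg$contrast_range[1], cfg$contrast_range[2]) else 1

  identity_transform <- !do_fh && !do_fv && !do_rot && !do_el
  if (!identity_transform) {
    # build the source-coordinate map (0-based) by composing, in sampling
    # order: elastic displacement, inverse rotation, flips
    rr <- matrix(seq_len(h) - 1, h, w)
    cc <- matrix(seq_len(w) - 1, h, w, byrow = TRUE)
    if (do_el) {
      rr <- rr + field$dy
      cc <- cc + field$dx
    }
    if (do_rot) {
      th <- ang * pi / 180
      cy <- (h - 1) / 2; cx <- (w - 1) / 2
      dy <- rr - cy; dx <- cc - cx
      rr <- cy + dy * cos(th) - dx * sin(th)
      cc <- cx + dy * sin(th) + dx * cos(th)
    }
    if (do_fh) cc <- (w - 1) - cc
    if (do_fv) rr <- (h - 1) - rr
    img3 <- if (length(d) == 2L) array(image, c(h, w, 1L)) else image
    image <- cpp_warp(img3, rr, cc, 1L)
    if (length(d) == 2L) image <- image[, , 1]
    region_mask <- (cpp_warp(array(region_mask + 0, c(h, w, 1L)),
                             rr, cc, 0L)[, , 1] > 0.5) * 1L
    edge_mask <- (cpp_warp(array(edge_mask + 0, c(h, w, 1L)),
                           rr, cc, 0L)[, , 1] > 0.5) * 1L
  } else {
    region_mask <- (region_mask > 0.5) * 1L
    edge_mask <- (edge_mask > 0.5) * 1L
  }
  if (do_ct) {
    m <- mean(image)
    image <- (image - m) * ctf + m
  }
  list(image = image, region_mask = region_mask, edge_mask = edge_mask)
}
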