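# Synthetic H&E-like nuclei fields with exact ground truth.
#
# A scene is a set of rotated, mildly lobulated ellipses ("nuclei") on a
# low-frequency textured background. Nuclei are darker than the background,
# as hematoxylin-stained chromatin is in an H&E field. Overlap between
# nuclei is placed deliberately so the fraction of nuclei touching another
# nucleus tracks a target, emulating the dense, overlapping fields seen in
# breast-cancer micrographs.

#' Scene specification for the synthetic nuclei generator
#'
#' @param image_size Square image side in pixels (>= 32).
#' @param nucleus_count_mean Poisson mean of the nucleus count; draws of 0
#'   are redrawn so every image contains at least one nucleus.
#' @param axis_range Length-2 range of semi-major axis lengths in pixels;
#'   minimum >= 2 and maximum < `image_size / 4`.
#' @param eccentricity_range Range of the minor/major axis ratio in (0, 1].
#' @param overlap_fraction Target fraction of nuclei whose outline
#'   intersects another nucleus, in `[0, 1]`.
#' @param intensity_contrast Mean foreground/background intensity gap in
#'   (0, 1]; nuclei are darker than the background.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise.
#' @param stain_jitter Half-width of the per-image multiplicative intensity
#'   jitter band (a factor drawn uniformly from `1 +/- stain_jitter`).
#' @param color If `TRUE`, a 3-channel H&E-like rendering is produced by
#'   mixing two synthetic stain fields; otherwise a single channel.
#' @return A validated `scene_spec` object (a list).
#' @export
scene_spec <- function(image_size = 64L,
                       nucleus_count_mean = 8,
                       axis_range = c(3, 8),
                       eccentricity_range = c(0.45, 0.95),
                       overlap_fraction = 0.3,
                       intensity_contrast = 0.35,
                       noise_sd = 0.05,
                       stain_jitter = 0.15,
                       color = FALSE) {
  spec <- list(image_size = as.integer(image_size),
               nucleus_count_mean = nucleus_count_mean,
               axis_range = as.numeric(axis_range),
               eccentricity_range = as.numeric(eccentricity_range),
               overlap_fraction = overlap_fraction,
               intensity_contrast = intensity_contrast,
               noise_sd = noise_sd,
               stain_jitter = stain_jitter,
               color = isTRUE(color))
  class(spec) <- "scene_spec"
  validate_scene_spec(spec)
  spec
}

validate_scene_spec <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  if (spec$image_size < 32L)
    stop("scene_spec: image_size must be >= 32")
  if (length(spec$axis_range) != 2L || spec$axis_range[1] < 2 ||
      spec$axis_range[2] < spec$axis_range[1])
    stop("scene_spec: axis_range must be (min, max) with min >= 2 px")
  if (spec$axis_range[2] >= spec$image_size / 4)
    stop("scene_spec: max semi-axis must be < image_size / 4")
  if (spec$nucleus_count_mean <= 0)
    stop("scene_spec: nucleus_count_mean must be positive")
  if (any(spec$eccentricity_range <= 0) || any(spec$eccentricity_range > 1) ||
      spec$eccentricity_range[2] < spec$eccentricity_range[1])
    stop("scene_spec: eccentricity_range must be an increasing range in (0, 1]")
  if (spec$overlap_fraction < 0 || spec$overlap_fraction > 1)
    stop("scene_spec: overlap_fraction must be in [0, 1]")
  if (spec$intensity_contrast <= 0 || spec$intensity_contrast > 1)
    stop("scene_spec: intensity_contrast must be in (0, 1]")
  if (spec$noise_sd < 0)
    stop("scene_spec: noise_sd must be >= 0")
  if (spec$stain_jitter < 0 || spec$stain_jitter >= 1)
    stop("scene_spec: stain_jitter must be in [0, 1)")
  invisible(spec)
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf(
    "scene_spec: %dx%d px, E[nuclei] = %.3g, semi-axes [%.3g, %.3g] px,\n",
    x$image_size, x$image_size, x$nucleus_count_mean,
    x$axis_range[1], x$axis_range[2]))
  cat(sprintf(
    "  overlap target %.3g, contrast %.3g, noise sd %.3g, %s\n",
    x$overlap_fraction, x$intensity_contrast, x$noise_sd,
    if (x$color) "H&E color" else "grayscale"))
  invisible(x)
}

# radial boundary of a lobulated ellipse in its own frame: the plain ellipse
# radius modulated by a low-order harmonic (keeps the shape star-convex, so
# every nucleus is a connected pixel set)
ellipse_radius <- function(phi, a, b, amp, phase) {
  r0 <- a * b / sqrt((b * cos(phi))^2 + (a * sin(phi))^2)
  r0 * (1 + amp * sin(2 * phi + phase))
}

# raster of one nucleus as a logical matrix over the full frame
rasterize_nucleus <- function(nuc, size) {
  pad <- ceiling(nuc$a * (1 + nuc$amp)) + 1
  r0 <- max(1, floor(nuc$cy - pad)); r1 <- min(size, ceiling(nuc$cy + pad))
  c0 <- max(1, floor(nuc$cx - pad)); c1 <- min(size, ceiling(nuc$cx + pad))
  out <- matrix(FALSE, size, size)
  if (r0 > r1 || c0 > c1) return(out)
  ys <- r0:r1; xs <- c0:c1
  dy <- outer(ys - nuc$cy, rep(1, length(xs)))
  dx <- outer(rep(1, length(ys)), xs - nuc$cx)
  u <- dx * cos(nuc$theta) + dy * sin(nuc$theta)
  v <- -dx * sin(nuc$theta) + dy * cos(nuc$theta)
  rho <- sqrt(u * u + v * v)
  phi <- atan2(v, u)
  inside <- rho <= ellipse_radius(phi, nuc$a, nuc$b, nuc$amp, nuc$phase)
  out[ys, xs] <- inside
  out
}

# low-frequency Gaussian random field, unit sd, via separable smoothing
smooth_field <- function(size, sigma) {
  z <- matrix(rnorm(size * size), size, size)
  k <- max(3L, 2L * ceiling(3 * sigma) + 1L)
  g <- dnorm(seq(-(k %/% 2), k %/% 2), sd = sigma)
  g <- g / sum(g)
  kern <- array(outer(g, g), c(k, k, 1L, 1L))
  dim(z) <- c(size, size, 1L, 1L)
  f <- cpp_conv2d_forward(z, kern, NULL, 1L, 1L, k %/% 2L, 1L)
  f <- matrix(f, size, size)
  s <- sd(as.vector(f))
  if (s > 0) f <- f / s
  f - mean(f)
}

#' Generate one synthetic nuclei image with exact ground truth
#'
#' A pure function of `(spec, seed)`: the same pair always yields a
#' bit-identical sample. Nuclei are drawn in z-order; on contested pixels a
#' later nucleus overwrites earlier labels, so `instance_labels` stays
#' single-valued. Labels left without pixels after overlap resolution are
#' dropped and the remaining labels renumbered `1..K`.
#'
#' @param spec A [scene_spec()].
#' @param seed Integer seed for this sample.
#' @return A `synthetic_sample`: list with `image` (array in `[0, 1]`,
#'   `(H, W)` or `(H, W, 3)`), `region_mask` (0/1 matrix), `instance_labels`
#'   (integer matrix, 0 = background), `nuclei` (placement provenance:
#'   centers, semi-axes, orientation, lobe amplitude/phase), `k_drawn` (the
#'   truncated-Poisson draw before overlap resolution), and `seed`.
#' @export
generate_sample <- function(spec, seed) {
  validate_scene_spec(spec)
  with_seed(as.integer(seed), function() .generate_sample_impl(spec, seed))
}

.generate_sample_impl <- function(spec, seed) {
  size <- spec$image_size
  k <- 0L
  repeat {
    k <- rpois(1L, spec$nucleus_count_mean)
    if (k >= 1L) break
  }
  n_ov <- round(spec$overlap_fraction * k)
  # overlap plan: n_ov nuclei live in touching pairs (anchor + attached);
  # odd counts put one extra attachment on the last anchor
  n_pairs <- n_ov %/% 2L
  n_extra <- n_ov %% 2L
  roles <- rep("free", k)
  if (n_ov > 0) {
    roles[seq_len(n_pairs)] <- "anchor"
    if (n_pairs + n_extra >= 1)
      roles[n_pairs + seq_len(n_pairs + n_extra)] <- "attach"
  }
  nuclei <- vector("list", k)
  placed <- list()
  anchors <- c()
  for (i in seq_len(k)) {
    a <- runif(1, spec$axis_range[1], spec$axis_range[2])
    ecc <- runif(1, spec$eccentricity_range[1], spec$eccentricity_range[2])
    b <- max(1.5, a * ecc)
    theta <- runif(1, 0, pi)
    amp <- runif(1, 0.02, 0.08)
    phase <- runif(1, 0, 2 * pi)
    role <- roles[i]
    if (role == "attach" && length(anchors) > 0) {
      j <- anchors[1 + (i %% length(anchors))]
      other <- nuclei[[j]]
      # inscribed disks (radius b*(1-amp)) forced to overlap => outlines do
      dmax <- max(1, other$b * (1 - other$amp) + b * (1 - amp) - 1.5)
      d <- runif(1, 0.3 * dmax, dmax)
      ang <- runif(1, 0, 2 * pi)
      cy <- min(max(other$cy + d * sin(ang), 1 + b), size - b)
      cx <- min(max(other$cx + d * cos(ang), 1 + b), size - b)
    } else {
      # rejection sampling away from everything already placed
      best <- NULL
      for (try in seq_len(60L)) {
        cy <- runif(1, 1 + a, size - a)
        cx <- runif(1, 1 + a, size - a)
        sep <- TRUE
        if (length(placed) > 0) {
          for (p in placed) {
            lim <- a * (1 + amp) + p$a * (1 + p$amp) + 1
            if ((cy - p$cy)^2 + (cx - p$cx)^2 < lim^2) { sep <- FALSE; break }
          }
        }
        if (is.null(best)) best <- c(cy, cx)
        if (sep) { best <- c(cy, cx); break }
      }
      cy <- best[1]; cx <- best[2]
    }
    nuc <- list(cy = cy, cx = cx, a = a, b = b, theta = theta,
                amp = amp, phase = phase)
    nuclei[[i]] <- nuc
    placed[[length(placed) + 1L]] <- nuc
    if (role == "anchor") anchors <- c(anchors, i)
  }
  labels <- matrix(0L, size, size)
  fg_levels <- numeric(k)
  bg_level <- 0.78
  fg_base <- bg_level - spec$intensity_contrast
  for (i in seq_len(k)) {
    m <- rasterize_nucleus(nuclei[[i]], size)
    labels[m] <- i
    fg_levels[i] <- fg_base + runif(1, -0.06, 0.06)
  }
  # drop labels fully overwritten by later nuclei; renumber the rest
  kept <- sort(unique(labels[labels > 0L]))
  relab <- integer(k)
  relab[kept] <- seq_along(kept)
  labels[labels > 0L] <- relab[labels[labels > 0L]]
  nuclei <- nuclei[kept]
  fg_levels <- fg_levels[kept]

  texture <- smooth_field(size, sigma = size / 16)
  img <- bg_level + 0.05 * texture
  if (length(kept) > 0) {
    for (i in seq_along(kept)) {
      m <- labels == i
      img[m] <- fg_levels[i] + 0.04 * texture[m]
    }
  }
  jit <- 1 + runif(1, -spec$stain_jitter, spec$stain_jitter)
  img <- img * jit
  if (spec$noise_sd > 0)
    img <- img + matrix(rnorm(size * size, sd = spec$noise_sd), size, size)
  img <- pmin(pmax(img, 0), 1)
  if (spec$color) {
    # mix two synthetic stain endpoints; darker pixels lean hematoxylin
    t <- pmin(pmax((bg_level - img) / spec$intensity_contrast, 0), 1)
    col_nuc <- c(0.36, 0.22, 0.55)
    col_bg <- c(0.91, 0.74, 0.86)
    rgb <- array(0, c(size, size, 3L))
    for (c in 1:3)
      rgb[, , c] <- pmin(pmax(col_bg[c] + (col_nuc[c] - col_bg[c]) * t +
                                0.15 * (img - bg_level), 0), 1)
    img <- rgb
  }
  structure(list(image = img,
                 region_mask = (labels > 0L) * 1L,
                 instance_labels = labels,
                 nuclei = nuclei,
                 k_drawn = k,
                 seed = as.integer(seed)),
            class = "synthetic_sample")
}

#' @export
print.synthetic_sample <- function(x, ...) {
  d <- dim(x$region_mask)
  cat(sprintf("synthetic_sample: %dx%d, %d nuclei, %.1f%% foreground, seed %d\n",
              d[1], d[2], max(x$instance_labels), 100 * mean(x$region_mask),
              x$seed))
  invisible(x)
}

#' Generate a reproducible collection of synthetic samples
#'
#' Sample `i` uses the child seed `child_seed(seed, i)`, so the collection
#' is reproducible as a whole and each element individually.
#'
#' @param spec A [scene_spec()].
#' @param n Number of samples (>= 1).
#' @param seed Integer master seed.
#' @return List of `synthetic_sample` objects.
#' @export
generate_dataset <- function(spec, n, seed) {
  if (n < 1) stop("generate_dataset: n must be >= 1")
  lapply(seq_len(n), function(i) generate_sample(spec, child_seed(seed, i)))
}

#' Write a dataset to disk as PNG pairs plus a manifest
#'
#' Images are 8-bit PNG (grayscale or RGB), masks are 0/255 PNG, and the
#' manifest is a TSV with columns `image_path`, `mask_path`, `seed`.
#'
#' @param samples List of `synthetic_sample` objects.
#' @param directory Output directory (created if missing).
#' @return Path of the written manifest, invisibly.
#' @export
write_dataset <- function(samples, directory) {
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory))
    stop("write_dataset: cannot create directory ", directory)
  rows <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    img_file <- sprintf("img_%04d.png", i)
    mask_file <- sprintf("mask_%04d.png", i)
    png::writePNG(s$image, file.path(directory, img_file))
    png::writePNG(s$region_mask + 0, file.path(directory, mask_file))
    rows[[i]] <- data.frame(image_path = img_file, mask_path = mask_file,
                            seed = s$seed)
  }
  manifest <- file.path(directory, "manifest.tsv")
  utils::write.table(do.call(rbind, rows), manifest, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param manifest Path to a `manifest.tsv`.
#' @return List of samples, each with `image`, `region_mask` and `seed`
#'   (instance labels are not serialized).
#' @export
read_dataset <- function(manifest) {
  if (!file.exists(manifest)) stop("read_dataset: no manifest at ", manifest)
  tab <- utils::read.table(manifest, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  base <- dirname(manifest)
  lapply(seq_len(nrow(tab)), function(i) {
    img <- png::readPNG(file.path(base, tab$image_path[i]))
    mask <- png::readPNG(file.path(base, tab$mask_path[i]))
    if (length(dim(mask)) == 3L) mask <- mask[, , 1]
    list(image = img, region_mask = (mask > 0.5) * 1L, seed = tab$seed[i])
  })
}
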