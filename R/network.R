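# Dual-stream segmentation network.
#
# Two encoder streams downsample in lockstep (stride-2 per level, so the
# per-level resolutions of the streams agree): a global-context stream of
# conv -> batch-norm -> deformable dilated conv -> GELU blocks with
# residual 1x1 projections, and a Sobel-enhanced local-detail stream of
# conv -> batch-norm -> GELU blocks. Per level, both streams are projected
# to a common width, concatenated, reweighted by a 7x7 spatial attention
# map built from channel-wise average/max descriptors, resampled to a base
# resolution and concatenated into a hypercolumn, which a depthwise
# separable 3x3 fusion block compresses. Two transposed-conv decoders
# (region and boundary) rebuild full-resolution maps with per-stage skip
# connections; at inference the boundary map multiplicatively refines the
# region map.

#' Network configuration
#'
#' @param levels Number of encoder/pyramid stages.
#' @param in_channels 1 (grayscale) or 3 (RGB).
#' @param global_channels,local_channels Per-level channel widths of the
#'   two encoder streams (`length(...) == levels`).
#' @param common_channels Common projection width C used before fusion.
#' @param hyper_channels Width D' of the fused hyperfeature map.
#' @param dilation_rates Per-level dilation of the global stream's
#'   deformable convolution.
#' @param use_deformable Use learned sampling offsets; `FALSE` falls back
#'   to a plain dilated convolution (identical at zero offsets).
#' @param lambda_refine Refinement weight in `[0, 1]` applied at inference.
#' @param attention_kernel Spatial attention kernel size (odd).
#' @param streams `"both"`, `"global"` or `"local"` (single-stream
#'   ablations).
#' @param use_hfem `FALSE` replaces attention fusion by simple additive
#'   fusion of the 1x1-matched streams.
#' @param use_boundary_decoder `FALSE` removes the boundary decoder (the
#'   edge map is zero and refinement is inert).
#' @return A `network_config` list.
#' @export
network_config <- function(levels = 4L,
                           in_channels = 1L,
                           global_channels = c(32L, 64L, 128L, 256L),
                           local_channels = c(16L, 32L, 64L, 128L),
                           common_channels = 64L,
                           hyper_channels = 128L,
                           dilation_rates = c(1L, 2L, 4L, 8L),
                           use_deformable = TRUE,
                           lambda_refine = 0.5,
                           attention_kernel = 7L,
                           streams = c("both", "global", "local"),
                           use_hfem = TRUE,
                           use_boundary_decoder = TRUE) {
  cfg <- list(levels = as.integer(levels),
              in_channels = as.integer(in_channels),
              global_channels = as.integer(global_channels),
              local_channels = as.integer(local_channels),
              common_channels = as.integer(common_channels),
              hyper_channels = as.integer(hyper_channels),
              dilation_rates = as.integer(dilation_rates),
              use_deformable = isTRUE(use_deformable),
              lambda_refine = lambda_refine,
              attention_kernel = as.integer(attention_kernel),
              streams = match.arg(streams),
              use_hfem = isTRUE(use_hfem),
              use_boundary_decoder = isTRUE(use_boundary_decoder))
  if (length(cfg$global_channels) != cfg$levels ||
      length(cfg$local_channels) != cfg$levels ||
      length(cfg$dilation_rates) != cfg$levels)
    stop("network_config: channel and dilation lists must have length `levels`")
  if (cfg$lambda_refine < 0 || cfg$lambda_refine > 1)
    stop("network_config: lambda_refine must be in [0, 1]")
  if (cfg$common_channels < 1L)
    stop("network_config: common_channels must be >= 1")
  if (cfg$attention_kernel %% 2L != 1L)
    stop("network_config: attention_kernel must be odd")
  if (!cfg$in_channels %in% c(1L, 3L))
    stop("network_config: in_channels must be 1 or 3")
  class(cfg) <- "network_config"
  cfg
}

#' Small configuration for CPU-scale experiments
#'
#' Three levels, eight base channels; the architecture is unchanged.
#' @param ... Overrides passed on to [network_config()].
#' @export
tiny_network_config <- function(...) {
  args <- list(levels = 3L, in_channels = 1L,
               global_channels = c(8L, 16L, 32L),
               local_channels = c(8L, 16L, 32L),
               common_channels = 16L, hyper_channels = 32L,
               dilation_rates = c(1L, 2L, 4L))
  over <- list(...)
  args[names(over)] <- over
  do.call(network_config, args)
}

has_global <- function(cfg) cfg$streams %in% c("both", "global")
has_local <- function(cfg) cfg$streams %in% c("both", "local")

# channel width of the per-level fused map entering the hypercolumn
fused_width <- function(cfg) {
  if (!cfg$use_hfem) return(cfg$common_channels)
  if (cfg$streams == "both") 2L * cfg$common_channels else cfg$common_channels
}

dec_channels <- function(cfg) {
  l <- cfg$levels
  c(rev(cfg$global_channels)[-1], cfg$global_channels[1])
}

he_init <- function(kh, kw, cin, cout) {
  array(rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
        c(kh, kw, cin, cout))
}

#' Build a model with freshly initialized weights
#'
#' Convolutions use He initialization, offset-predictor convolutions start
#' at zero (so a deformable convolution initially equals its dilated
#' counterpart), batch-norm starts at identity, and all biases start at 0.
#'
#' @param cfg A [network_config()].
#' @param seed Integer seed for weight initialization.
#' @return An `nf_model` (parameters, running statistics, config).
#' @export
build_model <- function(cfg = network_config(), seed = 42L) {
  params <- new.env(parent = emptyenv())
  with_seed(as.integer(seed), function() .init_params(cfg, params))
  m <- list(cfg = cfg, params = params,
            buffers = new.env(parent = emptyenv()), seed = as.integer(seed))
  class(m) <- "nf_model"
  m
}

.add_conv <- function(params, name, kh, kw, cin, cout, zero = FALSE) {
  w <- if (zero) array(0, c(kh, kw, cin, cout)) else he_init(kh, kw, cin, cout)
  params[[paste0(name, "_w")]] <- ad_param(w)
  params[[paste0(name, "_b")]] <- ad_param(rep(0, cout))
}

.add_bn <- function(params, name, c) {
  params[[paste0(name, "_g")]] <- ad_param(rep(1, c))
  params[[paste0(name, "_beta")]] <- ad_param(rep(0, c))
}

.init_params <- function(cfg, params) {
  l <- cfg$levels
  gc <- cfg$global_channels
  lc <- cfg$local_channels
  cc <- cfg$common_channels
  if (has_global(cfg)) {
    .add_conv(params, "g_stem", 3, 3, cfg$in_channels, gc[1])
    .add_bn(params, "g_stem_bn", gc[1])
    for (i in seq_len(l)) {
      cin <- if (i == 1) gc[1] else gc[i - 1]
      .add_conv(params, paste0("g_conv", i), 3, 3, cin, gc[i])
      .add_bn(params, paste0("g_bn", i), gc[i])
      if (cfg$use_deformable)
        .add_conv(params, paste0("g_off", i), 3, 3, gc[i], 18, zero = TRUE)
      .add_conv(params, paste0("g_dc", i), 3, 3, gc[i], gc[i])
      .add_conv(params, paste0("g_proj", i), 1, 1, cin, gc[i])
    }
  }
  if (has_local(cfg)) {
    .add_conv(params, "l_stem", 3, 3, cfg$in_channels + 1L, lc[1])
    .add_bn(params, "l_stem_bn", lc[1])
    for (i in seq_len(l)) {
      cin <- if (i == 1) lc[1] else lc[i - 1]
      .add_conv(params, paste0("l_conv", i), 3, 3, cin, lc[i])
      .add_bn(params, paste0("l_bn", i), lc[i])
    }
  }
  for (i in seq_len(l)) {
    if (has_global(cfg)) .add_conv(params, paste0("h_pg", i), 1, 1, gc[i], cc)
    if (has_local(cfg)) .add_conv(params, paste0("h_pl", i), 1, 1, lc[i], cc)
  }
  if (cfg$use_hfem) {
    k <- cfg$attention_kernel
    .add_conv(params, "h_att", k, k, 2, 1)
  }
  hw <- fused_width(cfg) * l
  params[["h_dw_w"]] <- ad_param(array(rnorm(9 * hw, sd = sqrt(2 / 9)),
                                       c(3, 3, hw)))
  params[["h_dw_b"]] <- ad_param(rep(0, hw))
  .add_conv(params, "h_pw", 1, 1, hw, cfg$hyper_channels)
  .add_bn(params, "h_bn", cfg$hyper_channels)

  dch <- dec_channels(cfg)
  enc_w <- (if (has_global(cfg)) gc else 0L) + (if (has_local(cfg)) lc else 0L)
  skip_src_seg <- c(rev(enc_w[seq_len(l - 1)]), enc_w[1])
  lcw <- if (has_local(cfg)) lc else gc
  skip_src_bnd <- c(rev(lcw[seq_len(l - 1)]), lcw[1])
  decoders <- c("s", if (cfg$use_boundary_decoder) "b")
  for (d in decoders) {
    src <- if (d == "s") skip_src_seg else skip_src_bnd
    for (j in seq_len(l)) {
      cin <- if (j == 1) cfg$hyper_channels else dch[j - 1] + dch[j - 1]
      .add_conv(params, paste0(d, "_t", j), 2, 2, cin, dch[j])
      .add_bn(params, paste0(d, "_bn", j), dch[j])
      .add_conv(params, paste0(d, "_sk", j), 1, 1, src[j], dch[j])
    }
    .add_conv(params, paste0(d, "_head"), 1, 1, dch[l] + dch[l], 1)
  }
  invisible(params)
}

#' @export
print.nf_model <- function(x, ...) {
  cat(sprintf(
    "nf_model: %d levels, streams=%s, %s, %d parameters (seed %d)\n",
    x$cfg$levels, x$cfg$streams,
    if (x$cfg$use_hfem) "attention fusion" else "additive fusion",
    parameter_count(x), x$seed))
  invisible(x)
}

#' Total number of trainable parameters
#' @param model An `nf_model`.
#' @export
parameter_count <- function(model) {
  sum(vapply(ls(model$params),
             function(nm) length(model$params[[nm]]$value), numeric(1)))
}

#' Sobel gradient enhancement of a single-channel image
#'
#' Computes horizontal and vertical Sobel responses with replicate
#' padding, their magnitude, and returns the image stacked with the
#' magnitude as a 2-channel array.
#'
#' @param image Matrix `(H, W)` (or `(H, W, 1)`).
#' @return Array `(H, W, 2)`: channel 1 the input, channel 2 the Sobel
#'   gradient magnitude.
#' @export
sobel_enhance <- function(image) {
  d <- dim(image)
  if (length(d) == 3L) {
    if (d[3] != 1L) stop("sobel_enhance: single-channel input required")
    image <- image[, , 1]
    d <- dim(image)
  }
  g <- sobel_magnitude(image)
  out <- array(0, c(d[1], d[2], 2L))
  out[, , 1] <- image
  out[, , 2] <- g
  out
}

sobel_kx <- function() matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
sobel_ky <- function() t(sobel_kx())

sobel_magnitude <- function(image) {
  x <- image
  dim(x) <- c(dim(image), 1L, 1L)
  kx <- array(sobel_kx(), c(3, 3, 1, 1))
  ky <- array(sobel_ky(), c(3, 3, 1, 1))
  gx <- cpp_conv2d_forward(x, kx, NULL, 1L, 1L, 1L, 1L)
  gy <- cpp_conv2d_forward(x, ky, NULL, 1L, 1L, 1L, 1L)
  matrix(sqrt(gx^2 + gy^2), nrow(image), ncol(image))
}

p_ <- function(model, name) {
  v <- model$params[[name]]
  if (is.null(v)) stop("missing parameter: ", name)
  v
}

conv_block <- function(model, x, name, stride = 1L, dil = 1L, pad = 1L) {
  op_conv2d(x, p_(model, paste0(name, "_w")), p_(model, paste0(name, "_b")),
            stride = stride, dil = dil, pad = pad)
}

bn_block <- function(model, x, name, training) {
  mom <- if (is.null(model$bn_momentum)) 0.1 else model$bn_momentum
  op_bn(x, p_(model, paste0(name, "_g")), p_(model, paste0(name, "_beta")),
        model$buffers, name, training, momentum = mom)
}

# encoder graph; x is a (H, W, C, N) node or array
.encode_graph <- function(model, x, training = FALSE) {
  cfg <- model$cfg
  x <- as_node(as4d(node_value(as_node(x))))
  d <- dim(x$value)
  if (d[1] %% (2^cfg$levels) != 0L || d[2] %% (2^cfg$levels) != 0L)
    stop(sprintf(
      "encode: spatial size (%d x %d) must be divisible by 2^levels = %d",
      d[1], d[2], 2^cfg$levels))
  out <- list(global = NULL, local = NULL, g_stem = NULL, l_stem = NULL)
  if (has_global(cfg)) {
    g <- op_gelu(bn_block(model,
                          conv_block(model, x, "g_stem"), "g_stem_bn",
                          training))
    out$g_stem <- g
    pyr <- vector("list", cfg$levels)
    for (i in seq_len(cfg$levels)) {
      dl <- cfg$dilation_rates[i]
      h <- conv_block(model, g, paste0("g_conv", i), stride = 2L)
      h <- bn_block(model, h, paste0("g_bn", i), training)
      if (cfg$use_deformable) {
        offs <- op_conv2d(h, p_(model, paste0("g_off", i, "_w")),
                          p_(model, paste0("g_off", i, "_b")),
                          stride = 1L, dil = 1L, pad = 1L)
        h <- op_dconv(h, offs, p_(model, paste0("g_dc", i, "_w")),
                      p_(model, paste0("g_dc", i, "_b")), dil = dl)
      } else {
        h <- op_conv2d(h, p_(model, paste0("g_dc", i, "_w")),
                       p_(model, paste0("g_dc", i, "_b")),
                       stride = 1L, dil = dl, pad = dl)
      }
      h <- op_gelu(h)
      res <- op_conv2d(g, p_(model, paste0("g_proj", i, "_w")),
                       p_(model, paste0("g_proj", i, "_b")),
                       stride = 2L, dil = 1L, pad = 0L)
      g <- op_add(h, res)
      pyr[[i]] <- g
    }
    out$global <- pyr
  }
  if (has_local(cfg)) {
    xv <- node_value(x)
    n <- dim(xv)[4]
    enh <- array(0, c(d[1], d[2], cfg$in_channels + 1L, n))
    for (b in seq_len(n)) {
      gray <- if (cfg$in_channels == 1L) xv[, , 1, b]
              else to_grayscale(xv[, , , b])
      enh[, , seq_len(cfg$in_channels), b] <- xv[, , , b]
      enh[, , cfg$in_channels + 1L, b] <- sobel_magnitude(gray)
    }
    lcl <- op_gelu(bn_block(model,
                            conv_block(model, ad_const(enh), "l_stem"),
                            "l_stem_bn", training))
    out$l_stem <- lcl
    pyr <- vector("list", cfg$levels)
    for (i in seq_len(cfg$levels)) {
      lcl <- conv_block(model, lcl, paste0("l_conv", i), stride = 2L)
      lcl <- op_gelu(bn_block(model, lcl, paste0("l_bn", i), training))
      pyr[[i]] <- lcl
    }
    out$local <- pyr
  }
  out
}

pyramid_of <- function(nodes, stream) {
  structure(list(levels = lapply(nodes, node_value), stream = stream),
            class = "feature_pyramid")
}

#' @export
print.feature_pyramid <- function(x, ...) {
  cat(sprintf("feature_pyramid (%s stream), %d levels:\n", x$stream,
              length(x$levels)))
  for (i in seq_along(x$levels)) {
    d <- dim(x$levels[[i]])
    cat(sprintf("  level %d: %d x %d x %d\n", i, d[1], d[2], d[3]))
  }
  invisible(x)
}

#' Run the dual-stream encoder
#'
#' @param model An `nf_model`.
#' @param image Input array `(H, W)`, `(H, W, C)` or `(H, W, C, N)` with
#'   spatial size divisible by `2^levels`.
#' @return List with `global` and `local` `feature_pyramid` objects (one
#'   may be `NULL` for single-stream variants).
#' @export
encode <- function(model, image) {
  enc <- .encode_graph(model, image, training = FALSE)
  list(global = if (!is.null(enc$global)) pyramid_of(enc$global, "global"),
       local = if (!is.null(enc$local)) pyramid_of(enc$local, "local"))
}

check_synchrony <- function(gl, lc) {
  for (i in seq_along(gl)) {
    dg <- dim(node_value(gl[[i]]))
    dl <- dim(node_value(lc[[i]]))
    if (dg[1] != dl[1] || dg[2] != dl[2])
      stop(sprintf(
        "hfem_fuse: pyramids out of sync at level %d (%dx%d vs %dx%d)",
        i, dg[1], dg[2], dl[1], dl[2]))
  }
}

.fuse_graph <- function(model, gl, lc, base_size, training = FALSE) {
  cfg <- model$cfg
  l <- cfg$levels
  att_w <- if (cfg$use_hfem) p_(model, "h_att_w")
  att_b <- if (cfg$use_hfem) p_(model, "h_att_b")
  apad <- (cfg$attention_kernel - 1L) %/% 2L
  maps <- vector("list", l)
  for (i in seq_len(l)) {
    pg <- if (has_global(cfg))
      op_conv2d(gl[[i]], p_(model, paste0("h_pg", i, "_w")),
                p_(model, paste0("h_pg", i, "_b")), pad = 0L)
    pl <- if (has_local(cfg))
      op_conv2d(lc[[i]], p_(model, paste0("h_pl", i, "_w")),
                p_(model, paste0("h_pl", i, "_b")), pad = 0L)
    if (cfg$use_hfem) {
      fcat <- if (!is.null(pg) && !is.null(pl)) op_concat_ch(list(pg, pl))
              else if (!is.null(pg)) pg else pl
      ss <- op_chan_summary(fcat)
      desc <- op_concat_ch(list(ss$avg, ss$max))
      att <- op_sigmoid(op_conv2d(desc, att_w, att_b, pad = apad))
      fat <- op_mul_bchan(fcat, att)
    } else {
      fat <- if (!is.null(pg) && !is.null(pl)) op_add(pg, pl)
             else if (!is.null(pg)) pg else pl
    }
    maps[[i]] <- op_resize_bilinear(fat, base_size[1], base_size[2])
  }
  h <- op_concat_ch(maps)
  h <- op_dwconv(h, p_(model, "h_dw_w"), p_(model, "h_dw_b"))
  h <- op_conv2d(h, p_(model, "h_pw_w"), p_(model, "h_pw_b"), pad = 0L)
  list(hyper = maps, fused = op_gelu(bn_block(model, h, "h_bn", training)))
}

#' Attention-guided hyperfeature fusion
#'
#' Projects each pyramid level of both streams to a common width,
#' concatenates them, applies a channel-summary spatial attention map,
#' resamples every attended level to `base_size`, concatenates the levels
#' into a hypercolumn and compresses it with a depthwise separable block.
#'
#' @param model An `nf_model`.
#' @param global,local `feature_pyramid` objects from [encode()] (matching
#'   the model's streams; pass `NULL` for an absent stream).
#' @param base_size Length-2 spatial size of the fused map; defaults to
#'   the coarsest pyramid level, where the decoders start.
#' @return The fused map as an `(H, W, D', N)` array.
#' @export
hfem_fuse <- function(model, global, local, base_size = NULL) {
  cfg <- model$cfg
  gl <- if (!is.null(global)) lapply(global$levels, function(v) ad_const(as4d(v)))
  lc <- if (!is.null(local)) lapply(local$levels, function(v) ad_const(as4d(v)))
  if (has_global(cfg) && is.null(gl)) stop("hfem_fuse: global pyramid required")
  if (has_local(cfg) && is.null(lc)) stop("hfem_fuse: local pyramid required")
  if (!is.null(gl) && !is.null(lc)) check_synchrony(gl, lc)
  one <- if (!is.null(gl)) gl else lc
  if (is.null(base_size)) {
    dl <- dim(node_value(one[[length(one)]]))
    base_size <- dl[1:2]
  }
  node_value(.fuse_graph(model, gl, lc, base_size)$fused)
}

.decoder_graph <- function(model, which, fused, skips, training) {
  cfg <- model$cfg
  l <- cfg$levels
  s <- fused
  for (j in seq_len(l)) {
    s <- op_convt2x2(s, p_(model, paste0(which, "_t", j, "_w")),
                     p_(model, paste0(which, "_t", j, "_b")))
    s <- op_gelu(bn_block(model, s, paste0(which, "_bn", j), training))
    sk <- skips[[j]]
    dsk <- dim(node_value(sk))
    dsv <- dim(node_value(s))
    if (dsk[1] != dsv[1] || dsk[2] != dsv[2])
      stop(sprintf(
        "decode: skip at stage %d is %dx%d but decoder map is %dx%d",
        j, dsk[1], dsk[2], dsv[1], dsv[2]))
    skp <- op_conv2d(sk, p_(model, paste0(which, "_sk", j, "_w")),
                     p_(model, paste0(which, "_sk", j, "_b")), pad = 0L)
    s <- op_concat_ch(list(s, skp))
  }
  op_conv2d(s, p_(model, paste0(which, "_head_w")),
            p_(model, paste0(which, "_head_b")), pad = 0L)
}

# assemble skip sources (finest-last decoder order) from encoder outputs
.skip_sources <- function(cfg, enc) {
  l <- cfg$levels
  seg <- vector("list", l)
  bnd <- vector("list", l)
  for (j in seq_len(l)) {
    if (j < l) {
      lev <- l - j
      parts <- list()
      if (!is.null(enc$global)) parts <- c(parts, list(enc$global[[lev]]))
      if (!is.null(enc$local)) parts <- c(parts, list(enc$local[[lev]]))
      seg[[j]] <- if (length(parts) > 1) op_concat_ch(parts) else parts[[1]]
      bnd[[j]] <- if (!is.null(enc$local)) enc$local[[lev]] else enc$global[[lev]]
    } else {
      parts <- list()
      if (!is.null(enc$g_stem)) parts <- c(parts, list(enc$g_stem))
      if (!is.null(enc$l_stem)) parts <- c(parts, list(enc$l_stem))
      seg[[j]] <- if (length(parts) > 1) op_concat_ch(parts) else parts[[1]]
      bnd[[j]] <- if (!is.null(enc$l_stem)) enc$l_stem else enc$g_stem
    }
  }
  list(seg = seg, bnd = bnd)
}

#' Run the region (segmentation) decoder
#'
#' @param model An `nf_model`.
#' @param fused Fused hyperfeature array from [hfem_fuse()].
#' @param skips List of `levels` skip arrays ordered coarse-to-fine
#'   (stage `j` expects spatial size `base * 2^j`).
#' @return Logits array (sigmoid is applied by [forward()]).
#' @export
decode_segmentation <- function(model, fused, skips) {
  node_value(.decoder_graph(model, "s", ad_const(as4d(fused)),
                            lapply(skips, function(v) ad_const(as4d(v))),
                            training = FALSE))
}

#' Run the boundary decoder
#' @inheritParams decode_segmentation
#' @export
decode_boundary <- function(model, fused, skips) {
  if (!model$cfg$use_boundary_decoder)
    stop("decode_boundary: this model has no boundary decoder")
  node_value(.decoder_graph(model, "b", ad_const(as4d(fused)),
                            lapply(skips, function(v) ad_const(as4d(v))),
                            training = FALSE))
}

#' Mutual boundary refinement of a region map
#'
#' `y_refined = clamp(y_seg * (1 + lambda * y_edge), 0, 1)`: pixels near a
#' predicted boundary are amplified, and clamping preserves the
#' probability interpretation.
#'
#' @param y_seg,y_edge Probability arrays of identical shape.
#' @param lambda Refinement weight in `[0, 1]`.
#' @return Refined probability array.
#' @export
refine <- function(y_seg, y_edge, lambda) {
  if (lambda < 0 || lambda > 1) stop("refine: lambda must be in [0, 1]")
  if (!identical(dim(y_seg), dim(y_edge)) &&
      !(is.null(dim(y_seg)) && is.null(dim(y_edge))))
    stop("refine: maps must share shape")
  pmin(pmax(y_seg * (1 + lambda * y_edge), 0), 1)
}

# full forward graph; returns nodes for training use
.forward_graph <- function(model, x, training = FALSE) {
  cfg <- model$cfg
  enc <- .encode_graph(model, x, training)
  one <- if (!is.null(enc$global)) enc$global else enc$local
  if (!is.null(enc$global) && !is.null(enc$local))
    check_synchrony(enc$global, enc$local)
  base <- dim(node_value(one[[cfg$levels]]))[1:2]
  fz <- .fuse_graph(model, enc$global, enc$local, base, training)
  skips <- .skip_sources(cfg, enc)
  seg_logits <- .decoder_graph(model, "s", fz$fused, skips$seg, training)
  y_seg <- op_sigmoid(seg_logits)
  if (cfg$use_boundary_decoder) {
    bnd_logits <- .decoder_graph(model, "b", fz$fused, skips$bnd, training)
    y_edge <- op_sigmoid(bnd_logits)
  } else {
    y_edge <- ad_const(array(0, dim(node_value(y_seg))))
  }
  list(y_seg = y_seg, y_edge = y_edge, enc = enc, fused = fz$fused)
}

#' Full forward pass
#'
#' Encoder, fusion, both decoders, sigmoid heads and refinement.
#'
#' @param model An `nf_model`.
#' @param image `(H, W)`, `(H, W, C)` or `(H, W, C, N)` array; spatial size
#'   divisible by `2^levels`.
#' @return A `prediction_bundle`: `y_seg`, `y_edge`, `y_refined`
#'   probability arrays (batch dimension dropped for single images).
#' @export
forward <- function(model, image) {
  had_batch <- length(dim(image)) == 4L
  g <- .forward_graph(model, image, training = FALSE)
  y_seg <- node_value(g$y_seg)
  y_edge <- node_value(g$y_edge)
  y_ref <- refine(y_seg, y_edge, model$cfg$lambda_refine)
  squeeze <- function(a) if (!had_batch) array(a, dim(a)[1:2]) else
    array(a, dim(a)[c(1, 2, 4)])
  structure(list(y_seg = squeeze(y_seg), y_edge = squeeze(y_edge),
                 y_refined = squeeze(y_ref)),
            class = "prediction_bundle")
}

#' @export
print.prediction_bundle <- function(x, ...) {
  d <- dim(x$y_seg)
  cat(sprintf(
    "prediction_bundle: %d x %d, seg [%.3f, %.3f], edge [%.3f, %.3f]\n",
    d[1], d[2], min(x$y_seg), max(x$y_seg), min(x$y_edge), max(x$y_edge)))
  invisible(x)
}
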