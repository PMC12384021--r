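# Differentiable operations on tape nodes. Values are (H, W, C, N) arrays;
# weight layout is (kh, kw, Cin, Cout) as in src/ops.cpp.

as4d <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected an array")
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 3L) dim(x) <- c(d, 1L)
  else if (length(d) != 4L) stop("expected a 2-4 dimensional array")
  x
}

op_conv2d <- function(x, w, b = NULL, stride = 1L, dil = 1L, pad = 0L,
                      replicate = FALSE) {
  x <- as_node(x); w <- as_node(w)
  b <- if (is.null(b)) NULL else as_node(b)
  xv <- x$value; wv <- w$value
  bv <- if (is.null(b)) NULL else b$value
  y <- cpp_conv2d_forward(xv, wv, bv, stride, dil, pad, as.integer(replicate))
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  ad_node(y, parents, function(g) {
    bk <- cpp_conv2d_backward(xv, wv, g, stride, dil, pad,
                              as.integer(replicate))
    if (is.null(b)) list(bk$gx, bk$gw) else list(bk$gx, bk$gw, bk$gb)
  })
}

op_convt2x2 <- function(x, w, b = NULL) {
  x <- as_node(x); w <- as_node(w)
  b <- if (is.null(b)) NULL else as_node(b)
  xv <- x$value; wv <- w$value
  y <- cpp_convt2x2_forward(xv, wv, if (is.null(b)) NULL else b$value)
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  ad_node(y, parents, function(g) {
    bk <- cpp_convt2x2_backward(xv, wv, g)
    if (is.null(b)) list(bk$gx, bk$gw) else list(bk$gx, bk$gw, bk$gb)
  })
}

op_dwconv <- function(x, w, b = NULL) {
  x <- as_node(x); w <- as_node(w)
  b <- if (is.null(b)) NULL else as_node(b)
  xv <- x$value; wv <- w$value
  y <- cpp_dwconv_forward(xv, wv, if (is.null(b)) NULL else b$value)
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  ad_node(y, parents, function(g) {
    bk <- cpp_dwconv_backward(xv, wv, g)
    if (is.null(b)) list(bk$gx, bk$gw) else list(bk$gx, bk$gw, bk$gb)
  })
}

op_dconv <- function(x, offs, w, b = NULL, dil = 1L) {
  x <- as_node(x); offs <- as_node(offs); w <- as_node(w)
  b <- if (is.null(b)) NULL else as_node(b)
  xv <- x$value; ov <- offs$value; wv <- w$value
  y <- cpp_dconv_forward(xv, ov, wv, if (is.null(b)) NULL else b$value, dil)
  parents <- if (is.null(b)) list(x, offs, w) else list(x, offs, w, b)
  ad_node(y, parents, function(g) {
    bk <- cpp_dconv_backward(xv, ov, wv, g, dil)
    if (is.null(b)) list(bk$gx, bk$go, bk$gw)
    else list(bk$gx, bk$go, bk$gw, bk$gb)
  })
}

# batch normalization over (H, W, N) per channel; buffers holds running
# moments keyed by `name` and is updated in place while training
op_bn <- function(x, gamma, beta, buffers, name, training,
                  momentum = 0.1, eps = 1e-5) {
  x <- as_node(x); gamma <- as_node(gamma); beta <- as_node(beta)
  xv <- x$value
  if (training) {
    st <- cpp_bn_stats(xv)
    mu <- st$mean
    va <- st$var
    rb <- buffers[[name]]
    if (is.null(rb)) rb <- list(mean = mu * 0, var = mu * 0 + 1)
    buffers[[name]] <- list(mean = (1 - momentum) * rb$mean + momentum * mu,
                            var = (1 - momentum) * rb$var + momentum * va)
  } else {
    rb <- buffers[[name]]
    if (is.null(rb)) {
      c_ <- dim(xv)[3]
      rb <- list(mean = rep(0, c_), var = rep(1, c_))
    }
    mu <- rb$mean
    va <- rb$var
  }
  istd <- 1 / sqrt(va + eps)
  y <- cpp_bn_apply(xv, gamma$value, beta$value, mu, istd)
  ad_node(y, list(x, gamma, beta), function(g) {
    bk <- cpp_bn_backward(xv, gamma$value, mu, istd, g, training)
    list(bk$gx, bk$ggamma, bk$gbeta)
  })
}

op_gelu <- function(x) {
  x <- as_node(x)
  xv <- x$value
  ad_node(cpp_gelu_forward(xv), list(x),
          function(g) list(cpp_gelu_backward(xv, g)))
}

op_sigmoid <- function(x) {
  x <- as_node(x)
  y <- 1 / (1 + exp(-x$value))
  ad_node(y, list(x), function(g) list(g * y * (1 - y)))
}

op_add <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  ad_node(a$value + b$value, list(a, b), function(g) list(g, g))
}

op_scale <- function(x, k) {
  x <- as_node(x)
  ad_node(x$value * k, list(x), function(g) list(g * k))
}

op_add_const <- function(x, k) {
  x <- as_node(x)
  ad_node(x$value + k, list(x), function(g) list(g))
}

op_mul <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  av <- a$value; bv <- b$value
  ad_node(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

# elementwise product with a single-channel map broadcast across channels
op_mul_bchan <- function(x, a1) {
  x <- as_node(x); a1 <- as_node(a1)
  xv <- x$value; av <- a1$value
  ad_node(cpp_bcast_mul(xv, av), list(x, a1), function(g) {
    bk <- cpp_bcast_mul_backward(xv, av, g)
    list(bk$gx, bk$ga)
  })
}

op_concat_ch <- function(nodes) {
  nodes <- lapply(nodes, as_node)
  vals <- lapply(nodes, `[[`, "value")
  cs <- vapply(vals, function(v) dim(v)[3], integer(1))
  y <- cpp_concat_ch(vals)
  ad_node(y, nodes, function(g) cpp_split_ch(g, cs))
}

op_resize_bilinear <- function(x, oh, ow) {
  x <- as_node(x)
  d <- dim(x$value)
  if (d[1] == oh && d[2] == ow) return(x)
  y <- cpp_resize_bilinear(x$value, oh, ow)
  ad_node(y, list(x), function(g) {
    list(cpp_resize_bilinear_backward(g, d[1], d[2]))
  })
}

# channel-wise average and max summary maps (shared forward pass)
op_chan_summary <- function(x) {
  x <- as_node(x)
  xv <- x$value
  C <- dim(xv)[3]
  s <- cpp_chan_summary(xv)
  avg_node <- ad_node(s$avg, list(x), function(g) {
    list(cpp_chan_summary_backward(g, NULL, NULL, C))
  })
  max_node <- ad_node(s$max, list(x), function(g) {
    list(cpp_chan_summary_backward(g * 0, g, s$argmax, C))
  })
  list(avg = avg_node, max = max_node)
}

op_chan_avg <- function(x) op_chan_summary(x)$avg

op_chan_max <- function(x) op_chan_summary(x)$max

op_clamp <- function(x, lo, hi) {
  x <- as_node(x)
  xv <- x$value
  y <- pmin(pmax(xv, lo), hi)
  inside <- xv > lo & xv < hi
  ad_node(y, list(x), function(g) list(g * inside))
}

op_mean <- function(x) {
  x <- as_node(x)
  n <- length(x$value)
  ad_node(mean(x$value), list(x), function(g) {
    list(array(g / n, dim(x$value)))
  })
}

# sqrt(a^2 + b^2 + eps), elementwise; finite gradient at the origin
op_hypot_eps <- function(a, b, eps = 1e-12) {
  a <- as_node(a); b <- as_node(b)
  av <- a$value; bv <- b$value
  y <- sqrt(av * av + bv * bv + eps)
  ad_node(y, list(a, b), function(g) list(g * av / y, g * bv / y))
}

# mean |x - ref| against a fixed reference array
op_mae_const <- function(x, ref) {
  x <- as_node(x)
  dlt <- x$value - ref
  n <- length(dlt)
  ad_node(mean(abs(dlt)), list(x), function(g) list(g * sign(dlt) / n))
}

# soft Dice score (not loss): (2*sum(p*y) + eps) / (sum(p) + sum(y) + eps)
op_soft_dice <- function(p, y, eps = 1) {
  p <- as_node(p)
  yv <- node_value(y)
  pv <- p$value
  spy <- sum(pv * yv)
  sp <- sum(pv)
  sy <- sum(yv)
  den <- sp + sy + eps
  d <- (2 * spy + eps) / den
  ad_node(d, list(p), function(g) {
    list(g * (2 * yv * den - (2 * spy + eps)) / (den * den))
  })
}

# mean binary cross-entropy with probability clamping
op_bce_mean <- function(p, y, clamp = 1e-7) {
  p <- as_node(p)
  yv <- node_value(y)
  pv <- pmin(pmax(p$value, clamp), 1 - clamp)
  n <- length(pv)
  loss <- -mean(yv * log(pv) + (1 - yv) * log(1 - pv))
  inside <- p$value > clamp & p$value < 1 - clamp
  ad_node(loss, list(p), function(g) {
    list(g * inside * (pv - yv) / (pv * (1 - pv)) / n)
  })
}

# weighted sum of scalar nodes
op_wsum <- function(nodes, weights) {
  nodes <- lapply(nodes, as_node)
  v <- sum(vapply(seq_along(nodes),
                  function(i) weights[i] * nodes[[i]]$value, numeric(1)))
  ad_node(v, nodes, function(g) as.list(g * weights))
}
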