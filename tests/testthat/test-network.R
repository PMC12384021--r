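test_that("sobel enhancement matches a hand 3x3 convolution oracle", {
  # constant image: zero gradient
  expect_lt(max(sobel_enhance(matrix(0.7, 8, 8))[, , 2]), 1e-12)
  # vertical step: nonzero only on the two columns astride the step,
  # values from the per-pixel oracle
  step <- matrix(0, 4, 4); step[, 3:4] <- 1
  g <- sobel_enhance(step)[, , 2]
  want <- oracle_sobel_mag(step)
  expect_equal(g, want, tolerance = 1e-12)
  expect_lt(max(g[, c(1, 4)]), 1e-12)
  expect_true(all(g[, 2:3] > 0.1))
  # transposition symmetry of the magnitude
  set.seed(31)
  img <- matrix(runif(64), 8, 8)
  expect_equal(sobel_enhance(t(img))[, , 2], t(sobel_enhance(img)[, , 2]),
               tolerance = 1e-12)
  expect_equal(sobel_enhance(img)[, , 2], oracle_sobel_mag(img),
               tolerance = 1e-12)
})

test_that("encoder streams downsample in lockstep with the configured widths", {
  cfg <- tiny_network_config()
  m <- build_model(cfg, seed = 1)
  x <- array(rnorm(64 * 64), c(64, 64, 1))
  enc <- encode(m, x)
  for (l in 1:3) {
    dg <- dim(enc$global$levels[[l]])
    dl <- dim(enc$local$levels[[l]])
    expect_identical(dg[1:2], as.integer(c(64, 64) / 2^l))
    expect_identical(dl[1:2], dg[1:2])
    expect_identical(dg[3], cfg$global_channels[l])
    expect_identical(dl[3], cfg$local_channels[l])
  }
  expect_error(encode(m, array(rnorm(60 * 60), c(60, 60, 1))), "divisible")
})

test_that("zero-offset deformable convolution equals the dilated fallback", {
  cfg_d <- micro_cfg(use_deformable = TRUE)
  cfg_p <- micro_cfg(use_deformable = FALSE)
  md <- build_model(cfg_d, seed = 5)
  mp <- build_model(cfg_p, seed = 99)
  # transplant the deformable model's base weights; offsets are zero-init
  for (nm in ls(md$params)) {
    if (!grepl("^g_off", nm)) mp$params[[nm]]$value <- md$params[[nm]]$value
  }
  x <- array(rnorm(16 * 16), c(16, 16, 1))
  ed <- encode(md, x)
  ep <- encode(mp, x)
  for (l in 1:2)
    expect_equal(ed$global$levels[[l]], ep$global$levels[[l]],
                 tolerance = 1e-12)
})

test_that("fusion applies sigmoid attention and the hypercolumn width contract", {
  cfg <- micro_cfg()
  m <- build_model(cfg, seed = 2)
  x <- array(rnorm(16 * 16), c(16, 16, 1))
  enc <- nucleifuse:::.encode_graph(m, x)
  # attention maps strictly in (0, 1): rebuild them from the same pieces
  for (i in 1:2) {
    pg <- nucleifuse:::op_conv2d(enc$global[[i]],
                                 m$params[[paste0("h_pg", i, "_w")]],
                                 m$params[[paste0("h_pg", i, "_b")]])
    pl <- nucleifuse:::op_conv2d(enc$local[[i]],
                                 m$params[[paste0("h_pl", i, "_w")]],
                                 m$params[[paste0("h_pl", i, "_b")]])
    fcat <- nucleifuse:::op_concat_ch(list(pg, pl))
    ss <- nucleifuse:::op_chan_summary(fcat)
    desc <- nucleifuse:::op_concat_ch(list(ss$avg, ss$max))
    att <- nucleifuse:::node_value(nucleifuse:::op_sigmoid(
      nucleifuse:::op_conv2d(desc, m$params$h_att_w, m$params$h_att_b,
                             pad = 3L)))
    expect_true(all(att > 0 & att < 1))
  }
  fz <- nucleifuse:::.fuse_graph(m,
                                 enc$global, enc$local, c(4L, 4L))
  fused <- nucleifuse:::node_value(fz$fused)
  expect_identical(dim(fused)[1:3], c(4L, 4L, cfg$hyper_channels))
  # hypercolumn width before compression: 2 * C * L
  hw <- sum(vapply(fz$hyper, function(n) dim(nucleifuse:::node_value(n))[3],
                   integer(1)))
  expect_identical(hw, 2L * cfg$common_channels * cfg$levels)
  # public API with explicit pyramids
  enc_pub <- encode(m, x)
  f2 <- hfem_fuse(m, enc_pub$global, enc_pub$local)
  expect_identical(dim(f2)[1:2], c(4L, 4L))
  # out-of-sync pyramids rejected
  bad <- enc_pub$local
  bad$levels[[1]] <- bad$levels[[1]][1:4, 1:4, , , drop = FALSE]
  expect_error(hfem_fuse(m, enc_pub$global, bad), "out of sync")
})

test_that("identity attention reduces reweighting to a no-op", {
  cfg <- micro_cfg()
  m <- build_model(cfg, seed = 3)
  x <- array(rnorm(16 * 16 * 1 * 2), c(16, 16, 1, 2))
  enc <- nucleifuse:::.encode_graph(m, x)
  # drive the attention conv to a saturating bias: A ~ 1 => F_att = F_cat
  m$params$h_att_w$value[] <- 0
  m$params$h_att_b$value[] <- 1e4
  fcat_direct <- function(i) {
    pg <- nucleifuse:::op_conv2d(enc$global[[i]],
                                 m$params[[paste0("h_pg", i, "_w")]],
                                 m$params[[paste0("h_pg", i, "_b")]])
    pl <- nucleifuse:::op_conv2d(enc$local[[i]],
                                 m$params[[paste0("h_pl", i, "_w")]],
                                 m$params[[paste0("h_pl", i, "_b")]])
    nucleifuse:::node_value(nucleifuse:::op_concat_ch(list(pg, pl)))
  }
  fz <- nucleifuse:::.fuse_graph(m, enc$global, enc$local, c(8L, 8L))
  att1 <- nucleifuse:::node_value(fz$hyper[[1]])
  want <- cpp_resize_bilinear(fcat_direct(1), 8L, 8L)
  expect_equal(att1, want, tolerance = 1e-10)
})

test_that("decoders return maps at the network input size with conformable skips", {
  cfg <- tiny_network_config()
  m <- build_model(cfg, seed = 4)
  x <- array(rnorm(64 * 64 * 2), c(64, 64, 1, 2))
  b <- forward(m, x)
  expect_identical(dim(b$y_seg), c(64L, 64L, 2L))
  expect_identical(dim(b$y_edge), c(64L, 64L, 2L))
  # distinct decoder parameters give generally different maps
  expect_gt(max(abs(b$y_seg - b$y_edge)), 1e-6)
  # non-conformable skips are a hard error
  enc <- nucleifuse:::.encode_graph(m, x)
  fz <- nucleifuse:::.fuse_graph(m, enc$global, enc$local, c(8L, 8L))
  skips <- nucleifuse:::.skip_sources(cfg, enc)
  skips$seg[[1]] <- nucleifuse:::ad_const(
    array(0, c(5, 5, dim(nucleifuse:::node_value(skips$seg[[1]]))[3], 2)))
  expect_error(nucleifuse:::.decoder_graph(m, "s", fz$fused, skips$seg,
                                           FALSE),
               "skip at stage")
})

test_that("refinement follows the worked arithmetic and stays monotone", {
  expect_equal(refine(0.6, 1.0, 0.5), 0.9)
  expect_equal(refine(0.8, 1.0, 0.5), 1.0)  # 1.2 clamped
  y <- matrix(runif(25), 5, 5)
  expect_identical(refine(y, matrix(0, 5, 5), 0), y)
  e <- matrix(runif(25), 5, 5)
  for (lam in c(0, 0.3, 1)) {
    r <- refine(y, e, lam)
    expect_true(all(r >= pmin(y, 1) - 1e-12))
    expect_true(all(r >= 0 & r <= 1))
  }
  expect_error(refine(y, e, 1.5), "lambda")
})

test_that("forward is deterministic and bounded for any weights", {
  m <- build_model(tiny_network_config(), seed = 6)
  x <- array(rnorm(64 * 64), c(64, 64, 1))
  b1 <- forward(m, x)
  b2 <- forward(m, x)
  expect_identical(b1, b2)
  for (map in b1) expect_true(all(map >= 0 & map <= 1))
  # perturbed weights still give bounded outputs
  for (nm in ls(m$params)) m$params[[nm]]$value <-
    m$params[[nm]]$value + rnorm(length(m$params[[nm]]$value), sd = 2)
  b3 <- forward(m, x)
  for (map in b3) expect_true(all(map >= 0 & map <= 1))
})

test_that("architecture parameter count is deterministic", {
  a <- build_model(tiny_network_config(), seed = 1)
  b <- build_model(tiny_network_config(), seed = 2)
  expect_identical(parameter_count(a), parameter_count(b))
  expect_gt(parameter_count(a), 0)
})

test_that("every parameter group receives gradient from the total loss", {
  set.seed(8)
  m <- build_model(micro_cfg(), seed = 8)
  x <- array(rnorm(16 * 16 * 1 * 4), c(16, 16, 1, 4))
  rb <- array((array(runif(16 * 16 * 4), c(16, 16, 1, 4)) > 0.6) * 1,
              c(16, 16, 1, 4))
  g <- nucleifuse:::.forward_graph(m, x, training = TRUE)
  tl <- nucleifuse:::.total_loss_node(g$y_seg, g$y_edge, rb, rb,
                                      loss_weights())
  nucleifuse:::ad_backward(tl$node)
  dead <- character(0)
  for (nm in ls(m$params)) {
    gr <- m$params[[nm]]$grad
    if (is.null(gr) || all(gr == 0)) dead <- c(dead, nm)
  }
  expect_identical(dead, character(0))
})
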