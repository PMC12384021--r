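test_that("reinhard normalization matches reference LAB statistics", {
  set.seed(1)
  img <- array(runif(24 * 24 * 3, 0.2, 0.8), c(24, 24, 3))
  # fixed point: reference equal to the image's own stats
  own <- lab_stats(img)
  out <- reinhard_normalize(img, own)
  expect_lt(max(abs(out - img)), 0.02)
  # defining property: output stats equal the reference (non-saturating)
  ref <- list(mean = c(55, 5, -8), sd = c(12, 4, 5))
  out2 <- reinhard_normalize(img, ref)
  st <- lab_stats(out2)
  expect_lt(max(abs(st$mean - ref$mean)), 1.0)
  expect_lt(max(abs(st$sd - ref$sd)), 1.0)
  expect_error(reinhard_normalize(img[, , 1:2], ref), "3 channels")
})

test_that("constant-color images are shifted onto the reference means", {
  img <- array(0, c(10, 10, 3))
  img[, , 1] <- 0.4; img[, , 2] <- 0.5; img[, , 3] <- 0.6
  ref <- list(mean = c(60, 3, -5), sd = c(10, 3, 3))
  out <- reinhard_normalize(img, ref)
  st <- lab_stats(out)
  expect_lt(max(abs(st$mean - ref$mean)), 0.5)
  expect_lt(max(st$sd), 1e-6)  # still constant
})

test_that("standardization yields zero mean, unit variance and affine invariance", {
  set.seed(2)
  img <- matrix(runif(400), 20, 20)
  out <- standardize(img)
  expect_lt(abs(mean(out)), 1e-12)
  expect_lt(abs(sqrt(mean(out^2)) - 1), 1e-12)
  # affine invariance (a > 0)
  out2 <- standardize(2.7 * img + 0.3)
  expect_lt(max(abs(out - out2)), 1e-10)
  expect_warning(z <- standardize(matrix(0.5, 5, 5)), "constant")
  expect_true(all(z == 0))
  expect_error(standardize(numeric(0)), "empty")
})

test_that("bicubic resize hits target shapes and is identity at same size", {
  set.seed(3)
  img <- matrix(runif(512), 32, 16)
  sq <- matrix(runif(1024), 32, 32)
  expect_identical(dim(resize_bicubic(sq, 16)), c(16L, 16L))
  expect_lt(max(abs(resize_bicubic(sq, 32) - sq)), 1e-12)
  rgb <- array(runif(32 * 32 * 3), c(32, 32, 3))
  expect_identical(dim(resize_bicubic(rgb, 8)), c(8L, 8L, 3L))
})

test_that("mask resize is nearest-neighbor and strictly binary", {
  set.seed(4)
  m <- random_mask(32, 32)
  out <- resize_mask(m, 13)
  expect_true(all(out %in% c(0L, 1L)))
  expect_identical(resize_mask(m, 32), m)
  up <- resize_mask(m, 64)
  expect_true(all(up %in% c(0L, 1L)))
  # upsampling by 2 replicates pixels, preserving area fraction exactly
  expect_equal(mean(up), mean(m))
})

test_that("clean_mask agrees with per-pixel opening + component-filter oracle", {
  cfg <- preproc_config(target_size = 32, min_object_px = 10,
                        opening_radius = 1)
  se <- se_offsets_disk(1)
  set.seed(5)
  for (rep in 1:5) {
    m <- random_mask(32, 32, p = 0.45)
    got <- clean_mask(m, cfg)
    opened <- oracle_dilate1(oracle_erode1(m, se), se)
    lab <- oracle_components(opened)
    want <- opened
    if (max(lab) > 0) {
      sizes <- tabulate(lab[lab > 0])
      for (k in which(sizes < 10)) want[lab == k] <- 0L
    }
    expect_identical(got, want)
    # removal-only invariant: output subset of the opened mask
    expect_true(all(got <= opened))
  }
  # a 3-pixel component dies under min_object_px = 10 even without opening
  m <- matrix(0L, 16, 16); m[5, 5:7] <- 1L
  expect_true(all(clean_mask(m, preproc_config(min_object_px = 10,
                                               opening_radius = 0)) == 0))
  # an 8x8 solid square is opening-stable
  m <- matrix(0L, 16, 16); m[4:11, 4:11] <- 1L
  expect_identical(clean_mask(m, cfg), m)
})

test_that("edge_target equals the neighborhood-difference oracle", {
  se <- se_offsets_box()
  oracle_edge <- function(m, t) {
    dil <- m; ero <- m
    for (i in seq_len(t)) {
      dil <- oracle_dilate1(dil, se)
      ero <- oracle_erode1(ero, se)
    }
    ((dil - ero) > 0) * 1L
  }
  # empty mask
  expect_true(all(edge_target(matrix(0L, 9, 9)) == 0))
  # filled 5x5 square inside 9x9
  m <- matrix(0L, 9, 9); m[3:7, 3:7] <- 1L
  expect_identical(edge_target(m, 1L), oracle_edge(m, 1L))
  # full-frame mask: band only at the image border
  f <- matrix(1L, 9, 9)
  e <- edge_target(f, 1L)
  expect_identical(e, oracle_edge(f, 1L))
  expect_true(all(e[2:8, 2:8] == 0))
  expect_true(all(e[1, ] == 1))
  # random masks, thickness 1 and 2
  set.seed(6)
  for (t in 1:2) {
    m <- random_mask(20, 20)
    expect_identical(edge_target(m, t), oracle_edge(m, t))
  }
  # edge band never intersects the eroded interior
  m <- random_mask(24, 24)
  ero <- oracle_erode1(m, se)
  expect_true(all(edge_target(m, 1L) * ero == 0))
})

test_that("full preprocessing pipeline emits standardized inputs and binary masks", {
  spec <- tiny_spec(color = TRUE)
  s <- generate_sample(spec, 9)
  cfg <- preproc_config(target_size = 64,
                        reference_lab_stats = lab_stats(s$image))
  out <- preprocess_sample(s$image, s$region_mask, cfg)
  expect_identical(dim(out$x), c(64L, 64L, 1L))
  expect_lt(abs(mean(out$x)), 1e-10)
  expect_true(all(out$region %in% c(0L, 1L)))
  expect_true(all(out$edge %in% c(0L, 1L)))
})
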