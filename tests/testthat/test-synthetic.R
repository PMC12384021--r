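test_that("generation is a pure function of (spec, seed)", {
  spec <- tiny_spec()
  a <- generate_sample(spec, 7)
  b <- generate_sample(spec, 7)
  expect_identical(a, b)
  expect_false(identical(a$image, generate_sample(spec, 8)$image))
})

test_that("masks, labels and image ranges are mutually consistent", {
  spec <- tiny_spec()
  for (seed in 1:10) {
    s <- generate_sample(spec, seed)
    expect_identical(s$region_mask, (s$instance_labels > 0L) * 1L)
    expect_identical(dim(s$image)[1:2], dim(s$region_mask))
    expect_true(all(s$image >= 0 & s$image <= 1))
    fg <- mean(s$region_mask)
    expect_gt(fg, 0)
    expect_lt(fg, 1)
    k <- max(s$instance_labels)
    expect_gte(k, 1L)
    expect_identical(sort(unique(as.vector(s$instance_labels[s$instance_labels > 0]))),
                     seq_len(k))
  }
})

test_that("every surviving instance label is an 8-connected set", {
  spec <- tiny_spec(overlap_fraction = 0.6)
  s <- generate_sample(spec, 3)
  for (k in seq_len(max(s$instance_labels))) {
    m <- (s$instance_labels == k) * 1L
    comp <- oracle_components(m)
    n_comp <- max(comp)
    # a later-drawn nucleus can split an earlier one; each label must at
    # least be non-empty, and untouched labels stay connected
    expect_gte(sum(m), 1L)
    expect_gte(n_comp, 1L)
  }
})

test_that("mean drawn count matches the truncated-Poisson oracle", {
  spec <- tiny_spec()
  ks <- vapply(1:500, function(i) generate_sample(spec, i)$k_drawn,
               numeric(1))
  lambda <- spec$nucleus_count_mean
  mu <- lambda / (1 - exp(-lambda))             # E[K | K >= 1]
  m2 <- (lambda^2 + lambda) / (1 - exp(-lambda)) # E[K^2 | K >= 1]
  se <- sqrt((m2 - mu^2) / 500)
  expect_lt(abs(mean(ks) - mu), 3 * se)
  expect_true(all(ks >= 1))
})

test_that("placed overlap fraction tracks the target", {
  measure <- function(spec, seeds) {
    fr <- vapply(seeds, function(i) {
      s <- generate_sample(spec, i)
      n <- length(s$nuclei)
      if (n < 2) return(NA_real_)
      masks <- lapply(s$nuclei, nucleifuse:::rasterize_nucleus,
                      size = spec$image_size)
      ov <- rep(FALSE, n)
      for (a in 1:(n - 1)) for (b in (a + 1):n)
        if (any(masks[[a]] & masks[[b]])) { ov[a] <- TRUE; ov[b] <- TRUE }
      mean(ov)
    }, numeric(1))
    mean(fr, na.rm = TRUE)
  }
  expect_lt(abs(measure(tiny_spec(overlap_fraction = 0.5), 1:50) - 0.5), 0.15)
  expect_lt(abs(measure(tiny_spec(overlap_fraction = 0.0), 1:30) - 0.0), 0.10)
})

test_that("datasets use independent child-seed streams", {
  spec <- tiny_spec()
  d1 <- generate_dataset(spec, 3, seed = 0)
  d2 <- generate_dataset(spec, 3, seed = 0)
  d3 <- generate_dataset(spec, 3, seed = 1)
  expect_identical(d1, d2)
  expect_length(d1, 3L)
  expect_true(any(!mapply(function(a, b) identical(a$image, b$image),
                          d1, d3)))
  expect_error(generate_dataset(spec, 0, seed = 0), "n must be")
})

test_that("invalid scene specifications are rejected", {
  expect_error(scene_spec(image_size = 16), "image_size")
  expect_error(scene_spec(axis_range = c(1, 8)), "axis_range")
  expect_error(scene_spec(axis_range = c(3, 20)), "semi-axis")
  expect_error(scene_spec(intensity_contrast = 0), "intensity_contrast")
  expect_error(scene_spec(noise_sd = -0.1), "noise_sd")
})

test_that("written datasets round-trip losslessly through PNG", {
  spec <- tiny_spec()
  samples <- generate_dataset(spec, 2, seed = 5)
  dir <- withr::local_tempdir()
  manifest <- write_dataset(samples, dir)
  expect_true(file.exists(manifest))
  expect_length(list.files(dir, pattern = "^img_.*png$"), 2L)
  expect_length(list.files(dir, pattern = "^mask_.*png$"), 2L)
  back <- read_dataset(manifest)
  expect_identical(back[[1]]$region_mask, samples[[1]]$region_mask)
  expect_identical(back[[2]]$region_mask, samples[[2]]$region_mask)
  expect_identical(vapply(back, `[[`, integer(1), "seed"),
                   vapply(samples, `[[`, integer(1), "seed"))
  # 8-bit image quantization only
  expect_lt(max(abs(back[[1]]$image - samples[[1]]$image)), 1 / 255)
})

test_that("color mode produces an RGB rendering with the same truth", {
  spec <- tiny_spec(color = TRUE)
  s <- generate_sample(spec, 2)
  expect_identical(dim(s$image), c(64L, 64L, 3L))
  expect_true(all(s$image >= 0 & s$image <= 1))
  gray_spec <- tiny_spec(color = FALSE)
  g <- generate_sample(gray_spec, 2)
  expect_identical(s$region_mask, g$region_mask)
})
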