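test_that("cosine warm-restart schedule matches its closed form", {
  cfg <- train_config(lr = 1e-4, t0 = 20L, t_mult = 2, min_lr = 0)
  expect_equal(lr_at(0, cfg), 1e-4)
  expect_equal(lr_at(10, cfg), 5e-5)          # cos(pi/2) = 0
  expect_equal(lr_at(20, cfg), 1e-4)          # restart instant
  expect_equal(lr_at(20 + 20, cfg), 5e-5)     # second cycle has T = 40
  cfg2 <- train_config(lr = 1e-3, t0 = 10L, t_mult = 3, min_lr = 1e-5)
  t <- 7.3
  want <- 1e-5 + (1e-3 - 1e-5) * (1 + cos(pi * t / 10)) / 2
  expect_equal(lr_at(t, cfg2), want)
  expect_equal(lr_at(10 + 3 * 10, cfg2), 1e-3)  # second restart
  expect_error(lr_at(-1, cfg), ">= 0")
})

test_that("gradient clipping caps the global norm in isolation and in runs", {
  params <- new.env()
  params$a <- nucleifuse:::ad_param(matrix(0, 2, 2))
  params$b <- nucleifuse:::ad_param(rep(0, 3))
  params$a$grad <- matrix(3, 2, 2)
  params$b$grad <- rep(4, 3)
  gn0 <- sqrt(sum(params$a$grad^2) + sum(params$b$grad^2))
  gn <- nucleifuse:::.clip_gradients(params, 5)
  expect_equal(gn, 5)
  gn_after <- sqrt(sum(params$a$grad^2) + sum(params$b$grad^2))
  expect_equal(gn_after, 5, tolerance = 1e-12)
  # direction preserved
  expect_equal(params$a$grad[1] / params$b$grad[1], 3 / 4, tolerance = 1e-12)
  # below the ceiling: untouched
  params$a$grad <- matrix(0.1, 2, 2)
  params$b$grad <- rep(0.1, 3)
  gn2 <- nucleifuse:::.clip_gradients(params, 5)
  expect_lt(gn2, 5)
  expect_equal(params$a$grad[1], 0.1)
})

test_that("short seeded runs are bit-reproducible and respect the clip ceiling", {
  sets <- micro_train_sets()
  cfg <- tiny_train_config(max_epochs = 3L, patience = 3L, batch_size = 4L,
                           clip_norm = 1.0, seed = 7L)
  run <- function() {
    m <- build_model(micro_cfg(), seed = 7)
    train(m, sets$train, sets$val, cfg, loss_weights(),
          checkpoint_path = tempfile(fileext = ".ckpt"))
  }
  a <- run()
  b <- run()
  expect_identical(a$history$l_total, b$history$l_total)
  expect_identical(a$history$val_dice, b$history$val_dice)
  expect_true(all(a$history$max_grad_norm <= cfg$clip_norm + 1e-9))
})

test_that("early stopping fires after exactly `patience` flat epochs", {
  sets <- micro_train_sets()
  # an effectively frozen model: learning rate too small to move weights
  cfg <- tiny_train_config(lr = 1e-30, min_lr = 1e-32, max_epochs = 50L,
                           patience = 1L, seed = 3L, bn_momentum = 0)
  m <- build_model(micro_cfg(), seed = 3)
  st <- train(m, sets$train, sets$val, cfg, loss_weights())
  expect_identical(st$epoch, 2L)  # first epoch improves from -Inf, second stops
  expect_identical(st$epochs_since_improve, 1L)
  cfg3 <- tiny_train_config(lr = 1e-30, min_lr = 1e-32, max_epochs = 50L,
                            patience = 3L, seed = 3L, bn_momentum = 0)
  m3 <- build_model(micro_cfg(), seed = 3)
  st3 <- train(m3, sets$train, sets$val, cfg3, loss_weights())
  expect_identical(st3$epoch, 4L)
})

test_that("train state bookkeeping matches its history", {
  sets <- micro_train_sets()
  cfg <- tiny_train_config(max_epochs = 4L, patience = 4L, seed = 5L)
  m <- build_model(micro_cfg(), seed = 5)
  st <- train(m, sets$train, sets$val, cfg, loss_weights())
  expect_equal(st$best_val_dice, max(st$history$val_dice))
  expect_true(all(st$history$l_total >= 0))
  expect_identical(nrow(st$history), st$epoch)
})

test_that("checkpoint reload reproduces the saved validation dice exactly", {
  sets <- micro_train_sets()
  cfg <- tiny_train_config(max_epochs = 3L, patience = 3L, seed = 9L)
  m <- build_model(micro_cfg(), seed = 9)
  ckpt <- tempfile(fileext = ".ckpt")
  st <- train(m, sets$train, sets$val, cfg, loss_weights(),
              checkpoint_path = ckpt)
  best <- load_checkpoint(ckpt)
  vd <- validation_dice(best, sets$val, cfg$val_threshold)
  expect_identical(vd, st$best_val_dice)
  expect_identical(attr(best, "extra")$val_dice, st$best_val_dice)
})

test_that("training aborts with diagnostics on a non-finite loss", {
  sets <- micro_train_sets()
  cfg <- tiny_train_config(max_epochs = 2L, seed = 2L)
  m <- build_model(micro_cfg(), seed = 2)
  # poison one weight so the forward pass yields NaN
  m$params$s_head_w$value[1] <- NaN
  expect_error(train(m, sets$train, sets$val, cfg, loss_weights()),
               "non-finite loss at epoch")
})

test_that("ablation variants map to their documented structural changes", {
  base <- micro_cfg()
  w <- loss_weights()
  full <- build_variant("full", base, w)
  expect_identical(full$cfg, base)
  expect_identical(full$weights, w)
  ng <- build_variant("no_glga", base, w)
  expect_identical(ng$weights$gamma, 0)
  expect_identical(ng$cfg, base)
  nh <- build_variant("no_hfem", base, w)
  expect_false(nh$cfg$use_hfem)
  # fusion parameter count strictly smaller without attention reweighting
  count_fusion <- function(cfg) {
    m <- build_model(cfg, seed = 1)
    sum(vapply(grep("^h_", ls(m$params), value = TRUE),
               function(nm) length(m$params[[nm]]$value), numeric(1)))
  }
  expect_lt(count_fusion(nh$cfg), count_fusion(base))
  nb <- build_variant("no_boundary_decoder", base, w)
  expect_false(nb$cfg$use_boundary_decoder)
  expect_identical(nb$weights$beta, 0)
  expect_identical(nb$cfg$lambda_refine, 0)
  ngl <- build_variant("no_global", base, w)
  expect_identical(ngl$cfg$streams, "local")
  expect_error(build_variant("bogus", base, w), "unknown tag")
})

test_that("single-stream and additive-fusion variants train end to end", {
  sets <- micro_train_sets()
  cfg <- tiny_train_config(max_epochs = 1L, seed = 4L)
  for (tag in c("no_global", "no_local", "no_hfem", "no_boundary_decoder")) {
    v <- build_variant(tag, micro_cfg(), loss_weights())
    m <- build_model(v$cfg, seed = 4)
    st <- train(m, sets$train, sets$val, cfg, v$weights)
    expect_true(is.finite(st$best_val_dice))
    b <- forward(st$model, sets$val[[1]]$x)
    expect_true(all(b$y_seg >= 0 & b$y_seg <= 1))
  }
})

test_that("stratified folds cover all folds and balance foreground area", {
  spec <- tiny_spec(image_size = 32, nucleus_count_mean = 4,
                    axis_range = c(2, 7))
  samples <- generate_dataset(spec, 20, seed = 12)
  prepared <- prepare_training_set(samples, preproc_config(target_size = 32))
  folds <- stratified_folds(prepared, k = 5L, seed = 1)
  expect_identical(sort(unique(folds)), 1:5)
  expect_identical(length(folds), 20L)
})
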