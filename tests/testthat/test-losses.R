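test_that("loss weights validate and warn outside the recommended gamma band", {
  w <- loss_weights()
  expect_identical(c(w$alpha, w$beta, w$gamma), c(0.6, 0.2, 0.2))
  expect_error(loss_weights(alpha = -1), ">= 0")
  expect_error(loss_weights(alpha = 0, beta = 0, gamma = 0), "positive")
  expect_warning(loss_weights(gamma = 0.7), "band")
  expect_silent(loss_weights(gamma = 0))  # disabled term is fine
})

test_that("dice+bce follows its closed forms", {
  set.seed(41)
  y <- random_mask(8, 8)
  # perfect binary prediction: both terms vanish up to the clamp epsilon
  expect_lt(dice_bce_loss(y + 0, y, 0.5, eps = 1), 1e-5)
  # total complement: softDice = eps / (N + eps), BCE at the clamp ceiling
  n <- length(y)
  l <- dice_bce_loss(1 - y, y, dice_mix = 1, eps = 1)
  expect_equal(l, 1 - 1 / (n + 1), tolerance = 1e-12)
  lb <- dice_bce_loss(1 - y, y, dice_mix = 0, eps = 1)
  expect_equal(lb, -log(1e-7), tolerance = 1e-6)
  # all-background target with zero prediction: smoothing gives dice = 1
  z <- matrix(0, 6, 6)
  expect_equal(dice_bce_loss(z, z, dice_mix = 1, eps = 1), 0)
  expect_error(dice_bce_loss(matrix(0.5, 2, 2), matrix(0L, 3, 3)),
               "shape mismatch")
})

test_that("edge bce closed forms and symmetry", {
  set.seed(42)
  y <- random_mask(10, 10)
  expect_lt(edge_bce(y + 0, y), 1e-5)
  # p = 0.5 everywhere gives ln 2 for any target
  expect_equal(edge_bce(matrix(0.5, 10, 10), y), log(2), tolerance = 1e-12)
  # symmetric under simultaneous complement
  p <- matrix(runif(100), 10, 10)
  expect_equal(edge_bce(p, y), edge_bce(1 - p, 1 - y), tolerance = 1e-12)
})

test_that("gradient-aligned loss matches the hand Sobel oracle", {
  set.seed(43)
  y <- matrix(0, 8, 8); y[, 5:8] <- 1
  # identical maps: exactly zero (up to the magnitude epsilon)
  expect_lt(gradient_aligned_loss(y, y), 1e-6)
  p <- matrix(runif(64), 8, 8)
  expect_lt(gradient_aligned_loss(p, p), 1e-6)
  # constant prediction vs a step mask: loss = mean ground-truth magnitude
  want <- mean(oracle_sobel_mag(y))
  for (const in c(0, 0.37, 1))
    expect_equal(gradient_aligned_loss(matrix(const, 8, 8), y), want,
                 tolerance = 1e-6)
  # nonnegative for random pairs
  for (i in 1:5) {
    expect_gte(gradient_aligned_loss(matrix(runif(64), 8, 8),
                                     random_mask(8, 8)), 0)
  }
})

test_that("total loss composes the three terms with exact linearity", {
  set.seed(44)
  y <- random_mask(8, 8)
  e <- edge_target(y, 1L)
  pred <- list(y_seg = matrix(runif(64), 8, 8),
               y_edge = matrix(runif(64), 8, 8))
  w <- loss_weights()
  bd <- total_loss(pred, y, e, w)
  expect_equal(bd$l_total,
               w$alpha * bd$l_seg + w$beta * bd$l_edge + w$gamma * bd$l_glga)
  # doubling all weights doubles the total exactly
  w2 <- w; w2$alpha <- 2 * w$alpha; w2$beta <- 2 * w$beta
  w2$gamma <- 2 * w$gamma
  bd2 <- total_loss(pred, y, e, w2)
  expect_equal(bd2$l_total, 2 * bd$l_total, tolerance = 1e-12)
  # perfect binary prediction: everything vanishes
  bd3 <- total_loss(list(y_seg = y + 0, y_edge = e + 0), y, e, w)
  expect_lt(bd3$l_total, 1e-5)
  # every term nonnegative
  expect_true(all(c(bd$l_seg, bd$l_edge, bd$l_glga, bd$l_total) >= 0))
})

test_that("autodiff gradient of the total loss matches finite differences", {
  set.seed(45)
  y <- random_mask(8, 8)
  e <- edge_target(y, 1L)
  p_seg <- nucleifuse:::ad_param(nucleifuse:::as4d(
    matrix(runif(64, 0.05, 0.95), 8, 8)))
  p_edge <- nucleifuse:::ad_param(nucleifuse:::as4d(
    matrix(runif(64, 0.05, 0.95), 8, 8)))
  w <- loss_weights()
  loss_node <- function() nucleifuse:::.total_loss_node(
    p_seg, p_edge, nucleifuse:::as4d(y + 0), nucleifuse:::as4d(e + 0), w)$node
  nucleifuse:::ad_backward(loss_node())
  g_seg <- p_seg$grad
  g_edge <- p_edge$grad
  eps <- 1e-6
  for (idx in sample(64, 12)) {
    p_seg$value[idx] <- p_seg$value[idx] + eps
    lp <- nucleifuse:::node_value(loss_node())
    p_seg$value[idx] <- p_seg$value[idx] - 2 * eps
    lm <- nucleifuse:::node_value(loss_node())
    p_seg$value[idx] <- p_seg$value[idx] + eps
    fd <- (lp - lm) / (2 * eps)
    expect_lt(abs(fd - g_seg[idx]) / max(abs(fd), abs(g_seg[idx]), 1e-8),
              1e-3)
  }
  for (idx in sample(64, 6)) {
    p_edge$value[idx] <- p_edge$value[idx] + eps
    lp <- nucleifuse:::node_value(loss_node())
    p_edge$value[idx] <- p_edge$value[idx] - 2 * eps
    lm <- nucleifuse:::node_value(loss_node())
    p_edge$value[idx] <- p_edge$value[idx] + eps
    fd <- (lp - lm) / (2 * eps)
    expect_lt(abs(fd - g_edge[idx]) / max(abs(fd), abs(g_edge[idx]), 1e-8),
              1e-3)
  }
})
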