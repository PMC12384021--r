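test_that("confusion counts enumerate pixels exactly", {
  p <- matrix(0L, 3, 3); p[1, 1] <- 1L; p[1, 2] <- 1L; p[2, 1] <- 1L
  t <- matrix(0L, 3, 3); t[1, 1] <- 1L; t[1, 2] <- 1L; t[3, 3] <- 1L
  cc <- confusion_counts(p, t)
  expect_identical(unlist(cc), c(TP = 2L, FP = 1L, FN = 1L, TN = 5L))
  m <- random_mask(4, 4)
  expect_identical(confusion_counts(m, m)$FP, 0L)
  expect_identical(confusion_counts(1L - m, m)$TP, 0L)
  expect_error(confusion_counts(matrix(0, 2, 2), matrix(0, 3, 3)),
               "shape mismatch")
})

test_that("dice and iou substitution values and degenerate conventions", {
  cc <- list(TP = 2, FP = 1, FN = 1, TN = 5)
  expect_equal(dice(cc), 2 / 3)
  expect_equal(iou(cc), 1 / 2)
  m <- random_mask(5, 5)
  cc2 <- confusion_counts(m, m)
  expect_equal(dice(cc2), 1)
  pr <- precision_recall(cc2)
  expect_equal(unname(pr), c(1, 1))
  empty <- confusion_counts(matrix(0L, 4, 4), matrix(0L, 4, 4))
  expect_equal(as.numeric(dice(empty)), 1)
  expect_identical(attr(dice(empty), "flag"), "degenerate")
  expect_equal(as.numeric(iou(empty)), 1)
})

test_that("boundary extraction matches the 4-neighborhood oracle", {
  m <- matrix(0L, 5, 5); m[2:4, 2:4] <- 1L
  b <- extract_boundary(m)
  want <- oracle_boundary(m)
  expect_identical(nrow(b), 8L)  # centre excluded
  expect_setequal(paste(b[, 1], b[, 2]), paste(want[, 1], want[, 2]))
  single <- matrix(0L, 3, 3); single[2, 2] <- 1L
  expect_identical(unname(extract_boundary(single)[1, ]), c(2L, 2L))
  expect_identical(nrow(extract_boundary(matrix(0L, 3, 3))), 0L)
  set.seed(51)
  for (i in 1:10) {
    m <- random_mask(12, 12)
    got <- extract_boundary(m)
    want <- oracle_boundary(m)
    expect_identical(nrow(got), nrow(want))
    if (nrow(got) > 0)
      expect_setequal(paste(got[, 1], got[, 2]),
                      paste(want[, 1], want[, 2]))
  }
})

test_that("hausdorff distance is exact, symmetric and policy-flagged when empty", {
  P <- matrix(c(1, 1), 1, 2)
  expect_equal(hausdorff(P, P), 0)
  G <- matrix(c(4, 5), 1, 2)
  expect_equal(hausdorff(P, G), 5)
  set.seed(52)
  for (i in 1:20) {
    bp <- extract_boundary(random_mask(16, 16))
    bg <- extract_boundary(random_mask(16, 16))
    if (nrow(bp) == 0 || nrow(bg) == 0) next
    got <- hausdorff(bp, bg)
    expect_identical(got, oracle_hausdorff(bp, bg))
    expect_identical(got, hausdorff(bg, bp))
  }
  e <- matrix(numeric(0), 0, 2)
  hd <- hausdorff(e, G, metrics_config(), diag = 10)
  expect_equal(as.numeric(hd), 10)
  expect_identical(attr(hd, "flag"), "empty-boundary")
})

test_that("boundary F1 matches the within-delta oracle and is monotone in delta", {
  m <- matrix(0L, 12, 12); m[3:7, 3:7] <- 1L
  shifted <- matrix(0L, 12, 12); shifted[3:7, 6:10] <- 1L
  bp <- extract_boundary(m)
  bs <- extract_boundary(shifted)
  expect_equal(boundary_f1(bp, bp, 0), 1)
  for (d in c(0, 1, 2, 3))
    expect_equal(boundary_f1(bp, bs, d), oracle_bf1(bp, bs, d))
  set.seed(53)
  for (i in 1:10) {
    a <- extract_boundary(random_mask(14, 14))
    b <- extract_boundary(random_mask(14, 14))
    vals <- vapply(c(0, 1, 2, 4), function(d) {
      got <- boundary_f1(a, b, d)
      expect_equal(as.numeric(got), oracle_bf1(a, b, d))
      as.numeric(got)
    }, numeric(1))
    expect_true(all(diff(vals) >= -1e-12))
  }
})

test_that("dice and iou obey their algebraic identity on random counts", {
  set.seed(54)
  for (i in 1:200) {
    cc <- list(TP = sample(0:50, 1), FP = sample(0:50, 1),
               FN = sample(0:50, 1), TN = sample(0:50, 1))
    d <- as.numeric(dice(cc))
    j <- as.numeric(iou(cc))
    expect_equal(d, 2 * j / (1 + j), tolerance = 1e-12)
    expect_gte(d, j)
  }
})

test_that("evaluate produces a complete report with threshold semantics", {
  set.seed(55)
  truth <- random_mask(16, 16)
  r <- evaluate(truth + 0, truth)
  expect_equal(r$dice, 1)
  expect_equal(r$iou, 1)
  expect_equal(r$bf1, 1)
  expect_equal(r$precision, 1)
  expect_equal(r$recall, 1)
  expect_equal(r$hausdorff, 0)
  prob <- truth * 0.9 + 0.05  # 0.95 vs 0.05: same binarization at 0.5
  r2 <- evaluate(prob, truth)
  expect_equal(r2$dice, 1)
  # all metrics bounded
  p <- matrix(runif(256), 16, 16)
  r3 <- evaluate(p, truth)
  for (f in c("dice", "iou", "bf1", "precision", "recall"))
    expect_true(r3[[f]] >= 0 && r3[[f]] <= 1)
  expect_gte(r3$hausdorff, 0)
})

test_that("aggregation returns means, sample sds and degeneracy accounting", {
  mk <- function(d) structure(list(dice = d, iou = d, bf1 = d,
                                   precision = d, recall = d,
                                   hausdorff = 1 - d, flags = character(0)),
                              class = "metrics_report")
  ag <- aggregate_reports(list(mk(0.8), mk(0.9)))
  expect_equal(ag$mean[ag$metric == "dice"], 0.85)
  expect_equal(ag$sd[ag$metric == "dice"], sd(c(0.8, 0.9)))
  ag2 <- aggregate_reports(list(mk(0.7), mk(0.7), mk(0.7)))
  expect_equal(ag2$sd[ag2$metric == "dice"], 0)
  expect_equal(attr(ag, "hd_valid_fraction"), 1)
  expect_error(aggregate_reports(list()), "empty")
})
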