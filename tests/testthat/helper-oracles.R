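# Independent brute-force oracles. Everything here is written per pixel /
# per pair, with no reference to the package's implementation paths.

oracle_confusion <- function(p, t) {
  tp <- 0L; fp <- 0L; fn <- 0L; tn <- 0L
  for (i in seq_along(p)) {
    if (p[i] > 0 && t[i] > 0) tp <- tp + 1L
    else if (p[i] > 0) fp <- fp + 1L
    else if (t[i] > 0) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(TP = tp, FP = fp, FN = fn, TN = tn)
}

oracle_dice <- function(cc) {
  den <- 2 * cc$TP + cc$FP + cc$FN
  if (den == 0) 1.0 else 2 * cc$TP / den
}

oracle_iou <- function(cc) {
  den <- cc$TP + cc$FP + cc$FN
  if (den == 0) 1.0 else cc$TP / den
}

oracle_prec_rec <- function(cc) {
  prec <- if (cc$TP + cc$FP == 0) (if (cc$FN == 0) 1 else 0)
          else cc$TP / (cc$TP + cc$FP)
  rec <- if (cc$TP + cc$FN == 0) (if (cc$FP == 0) 1 else 0)
         else cc$TP / (cc$TP + cc$FN)
  c(prec, rec)
}

# inner 4-connectivity boundary, frame edge counts as background
oracle_boundary <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  out <- NULL
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (mask[i, j] <= 0) next
    edge <- i == 1 || i == h || j == 1 || j == w
    if (!edge) {
      edge <- mask[i - 1, j] <= 0 || mask[i + 1, j] <= 0 ||
        mask[i, j - 1] <= 0 || mask[i, j + 1] <= 0
    }
    if (edge) out <- rbind(out, c(i, j))
  }
  if (is.null(out)) matrix(numeric(0), 0, 2) else out
}

oracle_hausdorff <- function(P, G) {
  if (nrow(P) == 0 || nrow(G) == 0) return(NA_real_)
  directed <- function(A, B) {
    worst <- 0
    for (i in seq_len(nrow(A))) {
      best <- Inf
      for (j in seq_len(nrow(B))) {
        d <- sqrt((A[i, 1] - B[j, 1])^2 + (A[i, 2] - B[j, 2])^2)
        if (d < best) best <- d
      }
      if (best > worst) worst <- best
    }
    worst
  }
  max(directed(P, G), directed(G, P))
}

oracle_bf1 <- function(P, G, delta) {
  if (nrow(P) == 0 && nrow(G) == 0) return(1)
  if (nrow(P) == 0 || nrow(G) == 0) return(0)
  within <- function(A, B) {
    hits <- 0L
    for (i in seq_len(nrow(A))) {
      ok <- FALSE
      for (j in seq_len(nrow(B))) {
        if ((A[i, 1] - B[j, 1])^2 + (A[i, 2] - B[j, 2])^2 <= delta^2 + 1e-9) {
          ok <- TRUE; break
        }
      }
      if (ok) hits <- hits + 1L
    }
    hits / nrow(A)
  }
  prec <- within(P, G)
  rec <- within(G, P)
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}

# 8-connectivity component labelling by repeated scanning
oracle_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  for (si in seq_len(h)) for (sj in seq_len(w)) {
    if (mask[si, sj] <= 0 || lab[si, sj] != 0L) next
    cur <- cur + 1L
    queue <- list(c(si, sj))
    lab[si, sj] <- cur
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        qi <- p[1] + di; qj <- p[2] + dj
        if (qi < 1 || qi > h || qj < 1 || qj > w) next
        if (mask[qi, qj] > 0 && lab[qi, qj] == 0L) {
          lab[qi, qj] <- cur
          queue[[length(queue) + 1]] <- c(qi, qj)
        }
      }
    }
  }
  lab
}

# per-pixel morphology with outside-the-frame pixels treated as background
oracle_dilate1 <- function(mask, se_offsets) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(0L, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    v <- 0L
    for (k in seq_len(nrow(se_offsets))) {
      qi <- i - se_offsets[k, 1]; qj <- j - se_offsets[k, 2]
      if (qi >= 1 && qi <= h && qj >= 1 && qj <= w && mask[qi, qj] > 0) {
        v <- 1L; break
      }
    }
    out[i, j] <- v
  }
  out
}

oracle_erode1 <- function(mask, se_offsets) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(1L, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    for (k in seq_len(nrow(se_offsets))) {
      qi <- i + se_offsets[k, 1]; qj <- j + se_offsets[k, 2]
      bad <- qi < 1 || qi > h || qj < 1 || qj > w || mask[qi, qj] <= 0
      if (bad) { out[i, j] <- 0L; break }
    }
  }
  out
}

se_offsets_disk <- function(r) {
  out <- NULL
  for (dy in -r:r) for (dx in -r:r)
    if (dy * dy + dx * dx <= (r + 0.5)^2) out <- rbind(out, c(dy, dx))
  out
}

se_offsets_box <- function() as.matrix(expand.grid(-1:1, -1:1))

# hand 3x3 correlation with replicate padding
oracle_filter3 <- function(img, kern) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    acc <- 0
    for (a in -1:1) for (b in -1:1) {
      qi <- min(max(i + a, 1), h)
      qj <- min(max(j + b, 1), w)
      acc <- acc + img[qi, qj] * kern[a + 2, b + 2]
    }
    out[i, j] <- acc
  }
  out
}

oracle_sobel_mag <- function(img) {
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  ky <- t(kx)
  gx <- oracle_filter3(img, kx)
  gy <- oracle_filter3(img, ky)
  sqrt(gx^2 + gy^2)
}

random_mask <- function(h, w, p = 0.4) {
  matrix((runif(h * w) < p) * 1L, h, w)
}
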