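# Training engine: AdamW with decoupled weight decay, cosine annealing
# with warm restarts, global gradient-norm clipping, per-epoch validation
# Dice, best-checkpoint saving and early stopping. Fully seeded: weight
# init, batch order and augmentation each use their own derived stream, so
# a run is bit-reproducible from its config.

#' Training configuration
#'
#' Defaults mirror a GPU-scale regime (learning rate 1e-4, batch 16, 200
#' epochs); [tiny_train_config()] holds the CPU-scale preset used by the
#' package's own experiments.
#'
#' @param lr Initial (maximum) learning rate.
#' @param weight_decay Decoupled weight-decay coefficient (applied to
#'   convolution kernels only, not biases or batch-norm).
#' @param batch_size Mini-batch size.
#' @param max_epochs Epoch cap.
#' @param patience Epochs without validation-Dice improvement before
#'   stopping.
#' @param clip_norm Global gradient-norm ceiling.
#' @param t0 First cosine cycle length in epochs.
#' @param t_mult Cycle-length multiplier at each warm restart.
#' @param min_lr Learning-rate floor of the cosine schedule.
#' @param seed Master seed of the run.
#' @param supervise_refined Supervise the refined map instead of the raw
#'   region map (off by default; refinement is an inference-time step).
#' @param bn_momentum Momentum of the batch-norm running-moment updates
#'   (0 freezes the running statistics).
#' @param val_threshold Binarization threshold for validation Dice.
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 1e-4, weight_decay = 0.01, batch_size = 16L,
                         max_epochs = 200L, patience = 15L, clip_norm = 5.0,
                         t0 = 20L, t_mult = 2, min_lr = 1e-6, seed = 42L,
                         supervise_refined = FALSE, val_threshold = 0.5,
                         bn_momentum = 0.1) {
  cfg <- list(lr = lr, weight_decay = weight_decay,
              batch_size = as.integer(batch_size),
              max_epochs = as.integer(max_epochs),
              patience = as.integer(patience), clip_norm = clip_norm,
              t0 = as.integer(t0), t_mult = t_mult, min_lr = min_lr,
              seed = as.integer(seed),
              supervise_refined = isTRUE(supervise_refined),
              val_threshold = val_threshold, bn_momentum = bn_momentum)
  if (cfg$lr <= 0) stop("train_config: lr must be > 0")
  if (cfg$patience < 1L) stop("train_config: patience must be >= 1")
  if (cfg$clip_norm <= 0) stop("train_config: clip_norm must be > 0")
  class(cfg) <- "train_config"
  cfg
}

#' CPU-scale training preset
#'
#' Learning rate 1e-3 and batch size 8, standard for the small models and
#' batches used in the package's synthetic experiments; shorter cycles and
#' patience to match the reduced epoch budget.
#'
#' @param ... Overrides passed to [train_config()].
#' @export
tiny_train_config <- function(...) {
  args <- list(lr = 1e-3, batch_size = 8L, max_epochs = 30L, patience = 8L,
               t0 = 10L, t_mult = 2, min_lr = 1e-5)
  over <- list(...)
  args[names(over)] <- over
  do.call(train_config, args)
}

#' Learning rate of the cosine warm-restart schedule
#'
#' Within a cycle of length `T_i`,
#' `lr = min_lr + (lr_max - min_lr) * (1 + cos(pi * t / T_i)) / 2`; at
#' each restart the cycle length is multiplied by `t_mult`.
#'
#' @param epoch_fraction Nonnegative position in epochs (fractions allowed).
#' @param cfg A [train_config()].
#' @return Learning rate.
#' @export
lr_at <- function(epoch_fraction, cfg = train_config()) {
  if (epoch_fraction < 0) stop("lr_at: epoch_fraction must be >= 0")
  t <- epoch_fraction
  ti <- cfg$t0
  while (t >= ti) {
    t <- t - ti
    ti <- ti * cfg$t_mult
  }
  cfg$min_lr + (cfg$lr - cfg$min_lr) * (1 + cos(pi * t / ti)) / 2
}

# flatten parameter gradients, compute global norm, scale in place
.clip_gradients <- function(params, clip_norm) {
  nms <- ls(params)
  sq <- 0
  for (nm in nms) {
    g <- params[[nm]]$grad
    if (!is.null(g)) sq <- sq + sum(g * g)
  }
  gn <- sqrt(sq)
  if (is.finite(gn) && gn > clip_norm) {
    sc <- clip_norm / gn
    for (nm in nms) {
      g <- params[[nm]]$grad
      if (!is.null(g)) params[[nm]]$grad <- g * sc
    }
    return(clip_norm)
  }
  gn
}

.adamw_step <- function(params, state, lr, wd, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in ls(params)) {
    p <- params[[nm]]
    g <- p$grad
    if (is.null(g)) next
    st <- state[[nm]]
    if (is.null(st)) st <- list(m = g * 0, v = g * 0)
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g * g
    state[[nm]] <- st
    upd <- (st$m / bc1) / (sqrt(st$v / bc2) + eps)
    decay <- if (grepl("_w$", nm)) wd * p$value else 0
    p$value <- p$value - lr * (upd + decay)
  }
  invisible()
}

# stack a list of per-sample tensors into (H, W, C, N)
.stack_batch <- function(xs) {
  d <- dim(xs[[1]])
  out <- array(0, c(d, length(xs)))
  for (i in seq_along(xs)) out[, , , i] <- xs[[i]]
  out
}

.stack_masks <- function(ms) {
  d <- dim(ms[[1]])
  out <- array(0, c(d[1], d[2], 1L, length(ms)))
  for (i in seq_along(ms)) out[, , 1, i] <- ms[[i]]
  out
}

#' Validation Dice of a model over a dataset
#'
#' @param model An `nf_model`.
#' @param dataset List of samples (`x`, `region`).
#' @param threshold Binarization cutoff.
#' @param batch_size Forward batch size.
#' @return Mean Dice over the dataset.
#' @export
validation_dice <- function(model, dataset, threshold = 0.5,
                            batch_size = 8L) {
  ds <- vapply(seq_along(dataset), function(i) {
    NA_real_
  }, numeric(1))
  idx <- seq_along(dataset)
  for (start in seq(1, length(dataset), by = batch_size)) {
    take <- idx[start:min(start + batch_size - 1, length(dataset))]
    xb <- .stack_batch(lapply(dataset[take], `[[`, "x"))
    g <- .forward_graph(model, xb, training = FALSE)
    ys <- node_value(g$y_seg)
    for (k in seq_along(take)) {
      cc <- confusion_counts((ys[, , 1, k] > threshold) * 1L,
                             dataset[[take[k]]]$region)
      ds[take[k]] <- as.numeric(dice(cc))
    }
  }
  mean(ds)
}

#' Train a model
#'
#' Shuffled mini-batches, forward pass, total loss, backward pass, global
#' gradient clipping and an AdamW step with the cosine warm-restart
#' schedule; per-epoch validation Dice drives best-checkpoint saving and
#' early stopping. A non-finite loss aborts with the offending batch index
#' and loss breakdown.
#'
#' @param model An `nf_model` (modified in place and returned in the
#'   state).
#' @param train_set,val_set Lists of samples as produced by
#'   [prepare_training_set()] (`x`, `region`, `edge`).
#' @param cfg A [train_config()].
#' @param weights A [loss_weights()].
#' @param augment_cfg Optional [augment_config()] applied on the fly.
#' @param checkpoint_path Where the best checkpoint is written.
#' @param verbose Print one line per epoch?
#' @return A `train_state`: `epoch`, `best_val_dice`,
#'   `epochs_since_improve`, `history` (per-epoch data frame),
#'   `checkpoint_path`, `model`.
#' @export
train <- function(model, train_set, val_set, cfg = train_config(),
                  weights = loss_weights(), augment_cfg = NULL,
                  checkpoint_path = tempfile(fileext = ".ckpt"),
                  verbose = FALSE) {
  if (length(train_set) < 1 || length(val_set) < 1)
    stop("train: datasets must be non-empty")
  state <- new.env(parent = emptyenv())
  state$t <- 0L
  model$bn_momentum <- cfg$bn_momentum
  order_rng <- make_rng(child_seed(cfg$seed, 101L))
  aug_rng <- make_rng(child_seed(cfg$seed, 202L))
  best <- -Inf
  since <- 0L
  history <- list()
  step <- 0L
  n <- length(train_set)
  n_batches <- ceiling(n / cfg$batch_size)
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- order_rng$sample_int(n)
    ep_loss <- c(l_seg = 0, l_edge = 0, l_glga = 0, l_total = 0)
    max_gnorm <- 0
    for (bi in seq_len(n_batches)) {
      take <- ord[((bi - 1) * cfg$batch_size + 1):min(bi * cfg$batch_size, n)]
      xs <- list(); rs <- list(); es <- list()
      for (k in seq_along(take)) {
        s <- train_set[[take[k]]]
        if (!is.null(augment_cfg)) {
          a <- augment(s$x[, , 1], s$region, s$edge, augment_cfg, aug_rng)
          xs[[k]] <- array(a$image, c(dim(a$image), 1L))
          rs[[k]] <- a$region_mask
          es[[k]] <- a$edge_mask
        } else {
          xs[[k]] <- s$x
          rs[[k]] <- s$region
          es[[k]] <- s$edge
        }
      }
      xb <- .stack_batch(xs)
      rb <- .stack_masks(rs)
      eb <- .stack_masks(es)
      g <- .forward_graph(model, xb, training = TRUE)
      y_for_seg <- if (cfg$supervise_refined)
        op_clamp(op_mul(g$y_seg,
                        op_add_const(op_scale(g$y_edge,
                                              model$cfg$lambda_refine), 1)),
                 0, 1)
      else g$y_seg
      tl <- .total_loss_node(y_for_seg, g$y_edge, rb, eb, weights)
      if (!is.finite(tl$breakdown["l_total"]))
        stop(sprintf(
          "train: non-finite loss at epoch %d batch %d (seg %.4g, edge %.4g, glga %.4g)",
          epoch, bi, tl$breakdown["l_seg"], tl$breakdown["l_edge"],
          tl$breakdown["l_glga"]))
      ad_backward(tl$node)
      gn <- .clip_gradients(model$params, cfg$clip_norm)
      max_gnorm <- max(max_gnorm, gn)
      lr <- lr_at(epoch - 1 + (bi - 1) / n_batches, cfg)
      .adamw_step(model$params, state, lr, cfg$weight_decay)
      for (nm in ls(model$params)) model$params[[nm]]$grad <- NULL
      ep_loss <- ep_loss + tl$breakdown * length(take)
      step <- step + 1L
    }
    ep_loss <- ep_loss / n
    vd <- validation_dice(model, val_set, cfg$val_threshold)
    improved <- vd > best
    if (improved) {
      best <- vd
      since <- 0L
      save_checkpoint(model, checkpoint_path,
                      extra = list(epoch = epoch, val_dice = vd,
                                   train_cfg = cfg))
    } else {
      since <- since + 1L
    }
    history[[epoch]] <- data.frame(
      epoch = epoch, l_seg = ep_loss["l_seg"], l_edge = ep_loss["l_edge"],
      l_glga = ep_loss["l_glga"], l_total = ep_loss["l_total"],
      val_dice = vd, lr = lr_at(epoch - 1, cfg),
      max_grad_norm = max_gnorm, row.names = NULL)
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  val dice %.4f%s", epoch,
                      ep_loss["l_total"], vd, if (improved) " *" else ""))
    if (since >= cfg$patience) break
  }
  structure(list(epoch = epoch, best_val_dice = best,
                 epochs_since_improve = since,
                 history = do.call(rbind, history),
                 checkpoint_path = checkpoint_path, model = model),
            class = "train_state")
}

#' @export
print.train_state <- function(x, ...) {
  cat(sprintf("train_state: %d epochs, best val dice %.4f (checkpoint %s)\n",
              x$epoch, x$best_val_dice, x$checkpoint_path))
  invisible(x)
}

#' Save model weights, running statistics and config
#'
#' @param model An `nf_model`.
#' @param path Output file.
#' @param extra Named list stored alongside (epoch, validation Dice, ...).
#' @export
save_checkpoint <- function(model, path, extra = list()) {
  vals <- lapply(as.list(model$params), function(p) p$value)
  bufs <- as.list(model$buffers)
  saveRDS(list(values = vals, buffers = bufs, cfg = model$cfg,
               seed = model$seed, extra = extra), path)
  invisible(path)
}

#' Load a checkpoint into a fresh model
#'
#' @param path Checkpoint written by [save_checkpoint()].
#' @return An `nf_model` with restored weights and running statistics;
#'   the stored `extra` list is attached as an attribute.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_model(ck$cfg, seed = ck$seed)
  for (nm in names(ck$values)) {
    if (is.null(model$params[[nm]]))
      stop("load_checkpoint: parameter shape mismatch, unknown ", nm)
    model$params[[nm]]$value <- ck$values[[nm]]
  }
  for (nm in names(ck$buffers)) model$buffers[[nm]] <- ck$buffers[[nm]]
  attr(model, "extra") <- ck$extra
  model
}

#' Convert raw samples into training tensors
#'
#' Runs [preprocess_sample()] over a list of synthetic or loaded samples.
#'
#' @param samples List with `image` and `region_mask` elements.
#' @param cfg A [preproc_config()].
#' @return List of `(x, region, edge)` training samples.
#' @export
prepare_training_set <- function(samples, cfg = preproc_config()) {
  lapply(samples, function(s) preprocess_sample(s$image, s$region_mask, cfg))
}

#' Stratified cross-validation folds
#'
#' Stratifies by foreground-area quantile so each fold spans the
#' morphological range of the data.
#'
#' @param samples List of samples with `region` or `region_mask`.
#' @param k Number of folds.
#' @param seed RNG seed.
#' @return Integer vector of fold assignments (1..k).
#' @export
stratified_folds <- function(samples, k = 5L, seed = 42L) {
  area <- vapply(samples, function(s) {
    m <- if (!is.null(s$region)) s$region else s$region_mask
    mean(m)
  }, numeric(1))
  strata <- cut(rank(area, ties.method = "first"),
                breaks = k, labels = FALSE)
  rng <- make_rng(seed)
  folds <- integer(length(samples))
  cnt <- 0L
  for (s in sort(unique(strata))) {
    idx <- which(strata == s)
    shuf <- idx[rng$sample_int(length(idx))]
    for (p in shuf) {
      folds[p] <- (cnt %% k) + 1L
      cnt <- cnt + 1L
    }
  }
  folds
}
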