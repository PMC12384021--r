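# Ablation harness: construct the documented structural variants and
# train/evaluate each under identical data and seeds.

.variant_tags <- c("full", "no_global", "no_local", "no_hfem",
                   "no_boundary_decoder", "no_glga")

#' Build an ablation variant
#'
#' Maps a tag to one documented structural change:
#' \describe{
#'   \item{full}{configs unchanged.}
#'   \item{no_global / no_local}{single-stream encoder; fusion degrades to
#'     single-input fusion.}
#'   \item{no_hfem}{attention fusion replaced by simple additive fusion of
#'     the 1x1-matched streams (strictly fewer fusion parameters).}
#'   \item{no_boundary_decoder}{boundary head and its loss removed;
#'     refinement weight forced to 0.}
#'   \item{no_glga}{gradient-aligned loss weight set to 0; architecture
#'     unchanged.}
#' }
#'
#' @param tag One of `"full"`, `"no_global"`, `"no_local"`, `"no_hfem"`,
#'   `"no_boundary_decoder"`, `"no_glga"`.
#' @param base_cfg A [network_config()].
#' @param base_weights A [loss_weights()].
#' @return List `(cfg, weights, tag)`.
#' @export
build_variant <- function(tag, base_cfg = network_config(),
                          base_weights = loss_weights()) {
  if (!tag %in% .variant_tags)
    stop("build_variant: unknown tag '", tag, "' (known: ",
         paste(.variant_tags, collapse = ", "), ")")
  cfg <- base_cfg
  w <- base_weights
  if (tag == "no_global") cfg$streams <- "local"
  if (tag == "no_local") cfg$streams <- "global"
  if (tag == "no_hfem") cfg$use_hfem <- FALSE
  if (tag == "no_boundary_decoder") {
    cfg$use_boundary_decoder <- FALSE
    cfg$lambda_refine <- 0
    w$beta <- 0
  }
  if (tag == "no_glga") w$gamma <- 0
  list(cfg = cfg, weights = w, tag = tag)
}

#' Train and evaluate a set of ablation variants
#'
#' Each variant is trained with the same data, training config and seed,
#' then evaluated on the validation set; one row of aggregate metrics per
#' variant is returned (and optionally written as TSV). Directional
#' differences between variants are reported, not asserted.
#'
#' @param variants Character vector of variant tags.
#' @param train_set,val_set Prepared sample lists (see
#'   [prepare_training_set()]).
#' @param base_cfg A [network_config()] the variants derive from.
#' @param train_cfg A [train_config()].
#' @param base_weights A [loss_weights()].
#' @param out_tsv Optional output path for the table.
#' @return Data frame: variant, dice, iou, bf1, hausdorff (means over the
#'   validation set), with sds in `*_sd` columns.
#' @export
run_ablation <- function(variants, train_set, val_set,
                         base_cfg = tiny_network_config(),
                         train_cfg = tiny_train_config(),
                         base_weights = loss_weights(),
                         out_tsv = NULL) {
  if (length(variants) < 1) stop("run_ablation: need at least one variant")
  rows <- list()
  for (tag in variants) {
    v <- build_variant(tag, base_cfg, base_weights)
    model <- build_model(v$cfg, seed = train_cfg$seed)
    st <- train(model, train_set, val_set, train_cfg, v$weights)
    best <- load_checkpoint(st$checkpoint_path)
    reports <- lapply(val_set, function(s) {
      b <- forward(best, s$x)
      evaluate(b$y_refined, s$region,
               metrics_config(threshold = train_cfg$val_threshold))
    })
    ag <- aggregate_reports(reports)
    pick <- function(m, col) ag[ag$metric == m, col]
    rows[[tag]] <- data.frame(
      variant = tag,
      dice = pick("dice", "mean"), dice_sd = pick("dice", "sd"),
      iou = pick("iou", "mean"), iou_sd = pick("iou", "sd"),
      bf1 = pick("bf1", "mean"), bf1_sd = pick("bf1", "sd"),
      hausdorff = pick("hausdorff", "mean"),
      hausdorff_sd = pick("hausdorff", "sd"))
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (!is.null(out_tsv))
    utils::write.table(out, out_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}
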