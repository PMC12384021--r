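# YAML run configuration: nested sections mirroring the module configs.
# Unknown keys are rejected, and every command writes its fully-resolved
# config next to its outputs.

.default_run_config <- function() {
  list(
    preprocess = list(target_size = 64L, grayscale = TRUE,
                      use_reinhard = TRUE, min_object_px = 10L,
                      opening_radius = 1L, edge_thickness = 1L),
    augment = list(enabled = FALSE, p_flip_h = 0.5, p_flip_v = 0.5,
                   p_rotate = 0.5, p_elastic = 0.3, p_contrast = 0.3,
                   rotate_max_deg = 30, elastic_alpha = 20,
                   elastic_sigma = 4, contrast_range = c(0.8, 1.2)),
    model = list(preset = "tiny", levels = NULL, in_channels = NULL,
                 global_channels = NULL, local_channels = NULL,
                 common_channels = NULL, hyper_channels = NULL,
                 dilation_rates = NULL, use_deformable = NULL,
                 lambda_refine = NULL, attention_kernel = NULL),
    loss = list(alpha = 0.6, beta = 0.2, gamma = 0.2, dice_mix = 0.5,
                eps = 1),
    train = list(preset = "tiny", lr = NULL, weight_decay = NULL,
                 batch_size = NULL, max_epochs = NULL, patience = NULL,
                 clip_norm = NULL, t0 = NULL, t_mult = NULL, min_lr = NULL,
                 seed = 42L, supervise_refined = NULL, val_threshold = NULL),
    metrics = list(threshold = 0.5, bf1_tolerance = 2,
                   hd_empty_policy = "diagonal"))
}

.merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (path == "") key else paste0(path, ".", key)
    if (!key %in% names(defaults))
      stop("run config: unknown key '", full, "'")
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]]))
        stop("run config: '", full, "' must be a section")
      defaults[[key]] <- .merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Read and resolve a run configuration
#'
#' Merges the user YAML over the package defaults, rejecting unknown keys.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return A `run_config` list with sections `preprocess`, `augment`,
#'   `model`, `loss`, `train`, `metrics`.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- .default_run_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- .merge_config(cfg, user)
  }
  class(cfg) <- "run_config"
  cfg
}

#' Write a resolved run configuration as YAML
#'
#' @param cfg A `run_config`.
#' @param path Output file.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

.drop_null <- function(x) x[!vapply(x, is.null, logical(1))]

# materialize section configs from a run_config
resolve_network_config <- function(cfg) {
  m <- cfg$model
  base <- if (identical(m$preset, "tiny")) tiny_network_config
          else network_config
  args <- .drop_null(m[setdiff(names(m), "preset")])
  do.call(base, args)
}

resolve_train_config <- function(cfg) {
  t <- cfg$train
  base <- if (identical(t$preset, "tiny")) tiny_train_config
          else train_config
  args <- .drop_null(t[setdiff(names(t), "preset")])
  do.call(base, args)
}

resolve_loss_weights <- function(cfg) do.call(loss_weights, cfg$loss)

resolve_preproc_config <- function(cfg) do.call(preproc_config, cfg$preprocess)

resolve_metrics_config <- function(cfg) do.call(metrics_config, cfg$metrics)

resolve_augment_config <- function(cfg) {
  a <- cfg$augment
  if (!isTRUE(a$enabled)) return(NULL)
  do.call(augment_config, a[setdiff(names(a), "enabled")])
}
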