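# Shared tiny fixtures. Everything is generated in code at test time.

tiny_spec <- function(...) {
  args <- list(image_size = 64L, nucleus_count_mean = 8)
  over <- list(...)
  args[names(over)] <- over
  do.call(scene_spec, args)
}

# a very small model for shape/gradient tests (fast to build and run)
micro_cfg <- function(...) {
  tiny_network_config(levels = 2L, global_channels = c(4L, 8L),
                      local_channels = c(4L, 8L), common_channels = 4L,
                      hyper_channels = 8L, dilation_rates = c(1L, 2L), ...)
}

micro_train_sets <- function(n_train = 4L, n_val = 2L, size = 32L,
                             seed = 11L) {
  spec <- tiny_spec(image_size = size, nucleus_count_mean = 4,
                    axis_range = c(2, size / 4 - 1))
  samples <- generate_dataset(spec, n_train + n_val, seed)
  prepared <- prepare_training_set(samples,
                                   preproc_config(target_size = size))
  list(train = prepared[seq_len(n_train)],
       val = prepared[n_train + seq_len(n_val)])
}
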