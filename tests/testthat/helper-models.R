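# Shared fixtures. Training the segmentation network dominates test runtime,
# so a light model (for contract/unit tests) and the full-configuration model
# (for the recovery experiments) are each trained at most once per run.

quick_seg_model <- local({
  model <- NULL
  function() {
    if (is.null(model))
      model <<- train_parasagittal_model(
        make_training_pairs(4, seed = 101),
        seg_model_config(epochs = 6L, patches_per_volume = 28L, seed = 11))
    model
  }
})

full_seg_model <- local({
  model <- NULL
  function() {
    if (is.null(model))
      model <<- train_parasagittal_model(
        make_training_pairs(10, seed = 42), seg_model_config(seed = 7))
    model
  }
})

# small noise-free phantom pair used by several contract tests
noise_free_phantom <- local({
  ph <- NULL
  function() {
    if (is.null(ph))
      ph <<- generate_head_phantom(
        head_phantom_params(class_sds = rep(0, 6), bias_amplitude = 0,
                            seed = 3))
    ph
  }
})
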