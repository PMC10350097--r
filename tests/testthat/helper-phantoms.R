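# Shared fixtures built in code. The desk-scale model (two-tract 32^3
# phantoms, depth-2 width-8 network) is expensive to train, so it is built
# once per test run and cached for every test that needs it.

desk_cache <- new.env(parent = emptyenv())

make_case <- function(seed, snr = 20, grid = c(32, 32, 32), n_tracts = 2) {
  ph <- simulate_dwi(random_phantom_spec(grid, n_tracts, seed = seed,
                                         snr = snr))
  list(dwi = b0_normalize(ph$dwi), labels = ph$labels)
}

# 8 training phantoms + 1 validation + 2 held-out, snr 20, trained ~5-6 min
desk_model <- function() {
  if (!is.null(desk_cache$model)) return(desk_cache$model)
  cases <- lapply(1:11, make_case)
  cfg <- unet_config(patch_shape = c(32, 32, 32), out_labels = 2, depth = 2,
                     base_width = 8, learning_rate = 1e-3,
                     lr_halve_patience = 3, seed = 1)
  model <- train_segmenter(unet3d(cfg), cases[1:8], cases[9], n_epochs = 40)
  desk_cache$model <- model
  desk_cache$holdout <- cases[10:11]
  model
}

desk_holdout <- function() {
  desk_model()
  desk_cache$holdout
}

mean_label_dice <- function(bin_pred, labels) {
  mean(vapply(seq_len(dim(labels)[4]), function(l)
    dice_coefficient(bin_pred[, , , l], labels[, , , l]), numeric(1)))
}

# a tiny trained model for CLI/prediction contract tests (seconds, not
# minutes); accuracy is irrelevant there
tiny_model <- function() {
  if (!is.null(desk_cache$tiny)) return(desk_cache$tiny)
  cases <- lapply(1:3, function(s) make_case(s, grid = c(16, 16, 16)))
  cfg <- unet_config(patch_shape = c(16, 16, 16), out_labels = 2, depth = 2,
                     base_width = 2, learning_rate = 1e-3, seed = 2)
  desk_cache$tiny <- train_segmenter(unet3d(cfg), cases[1:2], cases[3],
                                     n_epochs = 2)
  desk_cache$tiny
}
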