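#' Soft Dice loss
#'
#' `1 - (2 * sum(pred * target) + eps) / (sum(pred) + sum(target) + eps)`,
#' computed per label channel and averaged over channels. The smoothing
#' constant keeps the loss defined for empty channels. Training maximizes the
#' Dice similarity coefficient between prediction and ground truth by
#' minimizing this loss.
#'
#' @param pred (n x L) probability matrix or array
#' @param target (n x L) binary matrix or array of the same shape
#' @param eps smoothing constant
#' @param gradient also return the gradient w.r.t. `pred`
#' @return the scalar loss, or a list `(loss, grad)` when `gradient = TRUE`
#' @export
soft_dice_loss <- function(pred, target, eps = 1e-5, gradient = FALSE) {
  if (!identical(dim(pred), dim(target)) &&
      !identical(length(pred), length(target)))
    stop("pred and target shapes differ")
  P <- if (is.null(dim(pred)) || length(dim(pred)) != 2L)
    matrix(pred, ncol = if (is.null(dim(pred))) 1L else dim(pred)[length(dim(pred))])
  else pred
  Tm <- matrix(target, nrow = nrow(P))
  A <- 2 * colSums(P * Tm) + eps
  B <- colSums(P) + colSums(Tm) + eps
  loss <- mean(1 - A / B)
  if (!gradient) return(loss)
  L <- ncol(P)
  grad <- -(sweep(Tm, 2L, 2 / B, `*`) - matrix(A / B^2, nrow(P), L, byrow = TRUE)) / L
  list(loss = loss, grad = array(grad, dim = dim(pred)))
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

# extract a patch (and matching rows) from a flat (n_voxel x c) matrix
patch_rows <- function(dims, start, patch) {
  xs <- start[1]:(start[1] + patch[1] - 1L)
  ys <- start[2]:(start[2] + patch[2] - 1L)
  zs <- start[3]:(start[3] + patch[3] - 1L)
  idx <- outer(outer(xs, (ys - 1L) * dims[1], `+`),
               (zs - 1L) * dims[1] * dims[2], `+`)
  as.vector(idx)
}

# training patch origin: half the draws centered on a random foreground
# voxel, half uniform — standard for sparse labels
sample_patch_start <- function(dims, patch, fg_voxels) {
  if (all(dims == patch)) return(c(1L, 1L, 1L))
  maxs <- dims - patch + 1L
  if (length(fg_voxels) > 0L && runif(1) < 0.5) {
    v <- fg_voxels[sample.int(length(fg_voxels), 1L)] - 1L
    ctr <- c(v %% dims[1], (v %/% dims[1]) %% dims[2],
             v %/% (dims[1] * dims[2])) + 1L
    pmin(pmax(ctr - patch %/% 2L, 1L), maxs)
  } else {
    c(sample.int(maxs[1], 1L), sample.int(maxs[2], 1L), sample.int(maxs[3], 1L))
  }
}

#' Train the segmentation network with q-space subset augmentation
#'
#' Each iteration draws a fresh well-spread measurement subset from the
#' sampler, projects the chosen case onto the SH basis using only that
#' subset, samples a 3D patch, and takes one Adam step on the soft Dice
#' loss — so the network sees a different q-space view of the data at every
#' iteration and learns to segment from any adequate subset. After each
#' epoch the loss is evaluated on the validation cases (each with a fixed
#' subset, so epochs are comparable); when the validation loss fails to
#' improve for `lr_halve_patience` consecutive epochs the learning rate is
#' halved.
#'
#' @param model a [unet3d()]
#' @param train_cases,val_cases lists of cases; each case is a list with
#'   `dwi` (a b0-normalized [dwi_series()]) and `labels` (x,y,z,L binary
#'   array matching `config$out_labels`)
#' @param n_epochs number of epochs
#' @param iterations_per_epoch optimizer steps per epoch (default: one per
#'   training case)
#' @param sampler subset sampler, default
#'   `training_subset_sampler(gtab, 6, 12, seed)` on the first case's table
#' @param size_min,size_max subset-size bounds for the default sampler
#' @param verbose print per-epoch progress
#' @return the trained `unet3d`, with a `log` data.frame (epoch, train_loss,
#'   val_loss, lr) attached as `model$log`
#' @export
train_segmenter <- function(model, train_cases, val_cases, n_epochs = 10,
                            iterations_per_epoch = NULL, sampler = NULL,
                            size_min = 6, size_max = 12, verbose = FALSE) {
  stopifnot(inherits(model, "unet3d"))
  if (length(train_cases) < 1L || length(val_cases) < 1L)
    stop("need at least one training and one validation case")
  cfg <- model$config
  if (is.null(iterations_per_epoch))
    iterations_per_epoch <- length(train_cases)
  gtab <- train_cases[[1]]$dwi$gtab
  if (is.null(sampler))
    sampler <- training_subset_sampler(gtab, size_min, size_max,
                                       rng_seed = cfg$seed)
  prep <- function(case) {
    d <- dim(case$dwi$data)
    list(S = matrix(case$dwi$data, ncol = d[4]),
         gtab = case$dwi$gtab, dims = d[1:3],
         Tm = matrix(case$labels, ncol = cfg$out_labels),
         fg = which(rowSums(matrix(case$labels,
                                   ncol = cfg$out_labels)) > 0))
  }
  tr <- lapply(train_cases, prep)
  va <- lapply(val_cases, prep)
  # one fixed subset per validation case, so validation is comparable
  val_sub <- lapply(seq_along(va), function(i)
    select_spread_subset(va[[i]]$gtab, size_min,
                         rng_seed = cfg$seed + 131L * i))
  val_sh <- lapply(seq_along(va), function(i) {
    B <- va[[i]]$gtab$bvecs[val_sub[[i]]$indices, , drop = FALSE]
    fit_sh(va[[i]]$S[, val_sub[[i]]$indices, drop = FALSE], B, cfg$sh_order)
  })

  set.seed(cfg$seed)
  state <- adam_init(model$params)
  lr <- cfg$learning_rate
  best_val <- Inf
  stall <- 0L
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_loss = numeric(), lr = numeric())
  for (epoch in seq_len(n_epochs)) {
    order_cases <- sample(rep(seq_along(tr),
                              length.out = iterations_per_epoch * cfg$batch_size))
    ep_loss <- 0
    it <- 0L
    for (step in seq_len(iterations_per_epoch)) {
      gacc <- NULL
      lacc <- 0
      for (bi in seq_len(cfg$batch_size)) {
        it <- it + 1L
        case <- tr[[order_cases[it]]]
        sub <- sampler()
        Bm <- case$gtab$bvecs[sub$indices, , drop = FALSE]
        C <- fit_sh(case$S[, sub$indices, drop = FALSE], Bm, cfg$sh_order)
        start <- sample_patch_start(case$dims, cfg$patch_shape, case$fg)
        rows <- if (all(case$dims == cfg$patch_shape)) seq_len(nrow(C))
                else patch_rows(case$dims, start, cfg$patch_shape)
        X <- C[rows, , drop = FALSE]
        Tm <- case$Tm[rows, , drop = FALSE]
        fw <- unet_forward(model, X, cfg$patch_shape, want_cache = TRUE)
        dl <- soft_dice_loss(fw$y, Tm, gradient = TRUE)
        if (!is.finite(dl$loss))
          stop("non-finite training loss at epoch ", epoch,
               ", step ", step, "; aborting")
        g <- unet_backward(model, matrix(dl$grad, nrow = nrow(fw$y)), fw$cache)
        lacc <- lacc + dl$loss
        gacc <- if (is.null(gacc)) g
                else Map(`+`, gacc, g)
      }
      if (cfg$batch_size > 1L)
        gacc <- lapply(gacc, function(x) x / cfg$batch_size)
      st <- adam_step(model$params, gacc, state, lr)
      model$params <- st$params
      state <- st$state
      ep_loss <- ep_loss + lacc / cfg$batch_size
    }
    ep_loss <- ep_loss / iterations_per_epoch
    val_loss <- mean(vapply(seq_along(va), function(i) {
      y <- predict_volume(model, val_sh[[i]], va[[i]]$dims)
      soft_dice_loss(y, va[[i]]$Tm)
    }, numeric(1)))
    if (val_loss < best_val - 1e-6) {
      best_val <- val_loss
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= cfg$lr_halve_patience) {
        lr <- lr / 2
        stall <- 0L
      }
    }
    log <- rbind(log, data.frame(epoch = epoch, train_loss = ep_loss,
                                 val_loss = val_loss, lr = lr))
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f  lr %.2e",
                      epoch, ep_loss, val_loss, lr))
  }
  model$log <- log
  model
}

# whole-volume prediction on flat SH coefficients (n_voxel x in_channels),
# used for validation; tiles via sliding window when the volume exceeds the
# training patch
predict_volume <- function(model, C, dims) {
  cfg <- model$config
  if (all(dims %% 2^cfg$depth == 0) && prod(dims) <= prod(cfg$patch_shape))
    return(unet_forward(model, C, dims)$y)
  sw <- sliding_window_predict(model,
                               array(C, dim = c(dims, ncol(C))))
  matrix(sw, ncol = cfg$out_labels)
}

#' Save / load a trained model
#'
#' The checkpoint is R's native serialization of the parameters plus a JSON
#' sidecar describing the configuration and SH basis, so a stored model can
#' only be applied to inputs built with the same convention.
#'
#' @param model a `unet3d`
#' @param path checkpoint path (`.rds`); sidecar written next to it
#' @export
save_model <- function(model, path) {
  saveRDS(model[c("config", "params", "log")], path)
  jsonlite::write_json(
    c(unclass(model$config), list(basis_name = "real_sym_descoteaux",
                                  n_parameters = n_params(model))),
    paste0(sub("\\.rds$", "", path), ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  structure(list(config = obj$config, params = obj$params, log = obj$log),
            class = "unet3d")
}
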