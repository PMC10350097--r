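#' Whole-volume prediction by sliding-window tiling
#'
#' Tiles the volume with patches of the model's training size (default 50%
#' overlap), runs the network on each patch and averages overlapping
#' predictions, so every voxel is covered at least once. Volumes smaller
#' than the patch along any axis are padded reflectively, predicted, and
#' cropped back.
#'
#' @param model a [unet3d()]
#' @param sh_input an `sh_volume` from [sh_project()] or a 4D coefficient
#'   array (x, y, z, in_channels)
#' @param overlap fraction of patch overlap between neighbouring tiles
#' @return 4D probability array (x, y, z, out_labels), values in `[0, 1]`
#' @export
sliding_window_predict <- function(model, sh_input, overlap = 0.5) {
  cfg <- model$config
  coeffs <- if (inherits(sh_input, "sh_volume")) sh_input$coeffs else sh_input
  d <- dim(coeffs)
  if (length(d) != 4L || d[4] != cfg$in_channels)
    stop("input must have ", cfg$in_channels, " coefficient channels")
  dims <- d[1:3]
  patch <- cfg$patch_shape
  if (any(dims < patch)) {
    idx <- lapply(1:3, function(a) reflect_index(dims[a], max(dims[a], patch[a])))
    padded <- coeffs[idx[[1]], idx[[2]], idx[[3]], , drop = FALSE]
    out <- sliding_window_predict(model, padded, overlap)
    return(out[seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]), ,
               drop = FALSE])
  }
  stride <- pmax(1L, as.integer(floor(patch * (1 - overlap))))
  starts <- lapply(1:3, function(a) {
    s <- unique(c(seq(1L, dims[a] - patch[a] + 1L, by = stride[a]),
                  dims[a] - patch[a] + 1L))
    as.integer(s)
  })
  flat <- matrix(coeffs, ncol = cfg$in_channels)
  acc <- matrix(0, prod(dims), cfg$out_labels)
  cnt <- numeric(prod(dims))
  for (sz in starts[[3]]) for (sy in starts[[2]]) for (sx in starts[[1]]) {
    rows <- patch_rows(dims, c(sx, sy, sz), patch)
    y <- unet_forward(model, flat[rows, , drop = FALSE], patch)$y
    acc[rows, ] <- acc[rows, ] + y
    cnt[rows] <- cnt[rows] + 1
  }
  array(acc / cnt, dim = c(dims, cfg$out_labels))
}

# index vector of length target mirroring a 1..n sequence (reflection
# padding without repeating the edge sample; degenerate n = 1 repeats)
reflect_index <- function(n, target) {
  if (n >= target) return(seq_len(target))
  if (n == 1L) return(rep(1L, target))
  period <- 2L * n - 2L
  j <- (seq_len(target) - 1L) %% period
  ifelse(j < n, j + 1L, 2L * n - 1L - j)
}

#' Ensemble prediction over measurement subsets
#'
#' Test-time augmentation: draws `n` well-spread subsets of `k` diffusion
#' measurements, projects each onto the SH basis, predicts a segmentation
#' from each, and averages the member probability maps voxel-wise into the
#' final prediction. The members' spread around the mean feeds the
#' uncertainty statistic ([compute_uncertainty()]).
#'
#' @param model a [unet3d()]
#' @param dwi a b0-normalized [dwi_series()]
#' @param k measurements per subset
#' @param n ensemble size (number of subsets)
#' @param rng_seed subset-selection seed
#' @param disjoint force the subsets to be disjoint
#' @param subsets optionally, a pre-built list of `subset_spec` (overrides
#'   k/n/rng_seed/disjoint), e.g. read back from [read_subsets()]
#' @return an `ensemble_prediction`: list with `members` (list of 4D
#'   probability arrays), `mean` (their voxel-wise average), `subsets`
#' @export
ensemble_predict <- function(model, dwi, k = 6, n = 10, rng_seed = 1,
                             disjoint = FALSE, subsets = NULL) {
  stopifnot(inherits(model, "unet3d"), inherits(dwi, "dwi_series"))
  if (is.null(subsets))
    subsets <- test_subsets(dwi$gtab, k = k, n = n, rng_seed = rng_seed,
                            disjoint = disjoint)
  members <- lapply(subsets, function(s) {
    shv <- sh_project(dwi, subset = s$indices, order = model$config$sh_order)
    sliding_window_predict(model, shv)
  })
  mean_vol <- Reduce(`+`, members) / length(members)
  structure(list(members = members, mean = mean_vol, subsets = subsets),
            class = "ensemble_prediction")
}

#' @export
print.ensemble_prediction <- function(x, ...) {
  d <- dim(x$mean)
  cat(sprintf("ensemble_prediction: %d members, grid %d x %d x %d, %d labels\n",
              length(x$members), d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Threshold a probability volume into binary masks
#'
#' @param prob probability array, values in `[0, 1]`
#' @param threshold inclusion cutoff; voxels with `prob >= threshold` are set
#' @return 0/1 array of the same shape
#' @export
binarize_probability <- function(prob, threshold = 0.5) {
  if (any(prob < 0 | prob > 1)) stop("probabilities must lie in [0, 1]")
  array(as.numeric(prob >= threshold), dim = dim(prob))
}
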