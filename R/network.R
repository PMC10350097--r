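#' Configure the 3D segmentation network
#'
#' A plain U-Net-style fully convolutional encoder-decoder: `depth`
#' resolution levels of two 3x3x3 convolutions with instance normalization
#' and ReLU, 2x average-pool downsampling, nearest-neighbour upsampling with
#' skip-connection concatenation, and a per-voxel multi-label sigmoid head.
#' Tracts overlap where they cross, so output channels are independent
#' sigmoids rather than a softmax. The input is the order-`sh_order` SH
#' coefficient volume (6 channels at order 2).
#'
#' @param patch_shape 3 integers, each divisible by 2^depth (default 96^3)
#' @param out_labels number of output channels (one per tract)
#' @param sh_order even SH order of the input; in_channels follows from it
#' @param depth number of downsampling levels
#' @param base_width channels of the first encoder level; doubles per level
#' @param learning_rate Adam step size
#' @param lr_halve_patience epochs without validation-loss improvement before
#'   the learning rate is halved
#' @param batch_size patches per optimizer step
#' @param seed seed for deterministic weight initialization
#' @return a `unet_config` list
#' @export
unet_config <- function(patch_shape = c(96, 96, 96), out_labels = 2,
                        sh_order = 2, depth = 3, base_width = 16,
                        learning_rate = 1e-4, lr_halve_patience = 1,
                        batch_size = 1, seed = 1) {
  patch_shape <- as.integer(patch_shape)
  if (length(patch_shape) == 1L) patch_shape <- rep(patch_shape, 3L)
  if (any(patch_shape %% (2^depth) != 0))
    stop("patch_shape must be divisible by 2^depth")
  in_channels <- sh_n_coef(sh_order)
  structure(list(patch_shape = patch_shape, in_channels = in_channels,
                 out_labels = as.integer(out_labels), sh_order = sh_order,
                 depth = as.integer(depth), base_width = as.integer(base_width),
                 learning_rate = learning_rate,
                 lr_halve_patience = lr_halve_patience,
                 batch_size = as.integer(batch_size), seed = seed),
            class = "unet_config")
}

# channel widths: encoder level i has base_width * 2^(i-1); bottleneck doubles
# the deepest level. Conv weights are stored ready for the im2col gemm:
# a (27 * c_in) x c_out matrix.
unet_layer_dims <- function(config) {
  w <- config$base_width; d <- config$depth
  widths <- w * 2^(seq_len(d) - 1L)
  list(widths = widths, bottleneck = w * 2^d)
}

conv_init <- function(c_in, c_out, taps = 27L) {
  matrix(rnorm(taps * c_in * c_out, sd = sqrt(2 / (taps * c_in))),
         taps * c_in, c_out)
}

#' Build a segmentation network
#'
#' Initializes all weights deterministically from `config$seed` (He-style
#' normal initialization for convolutions, unit gain / zero shift for the
#' instance norms).
#'
#' @param config a [unet_config()]
#' @return a `unet3d` object: list with `config` and a flat named parameter
#'   list `params`
#' @export
unet3d <- function(config) {
  stopifnot(inherits(config, "unet_config"))
  set.seed(config$seed)
  ld <- unet_layer_dims(config)
  P <- list()
  add_block <- function(P, name, c_in, c_mid) {
    P[[paste0(name, ".conv1.W")]] <- conv_init(c_in, c_mid)
    P[[paste0(name, ".conv1.b")]] <- rep(0, c_mid)
    P[[paste0(name, ".in1.g")]] <- rep(1, c_mid)
    P[[paste0(name, ".in1.b")]] <- rep(0, c_mid)
    P[[paste0(name, ".conv2.W")]] <- conv_init(c_mid, c_mid)
    P[[paste0(name, ".conv2.b")]] <- rep(0, c_mid)
    P[[paste0(name, ".in2.g")]] <- rep(1, c_mid)
    P[[paste0(name, ".in2.b")]] <- rep(0, c_mid)
    P
  }
  c_prev <- config$in_channels
  for (i in seq_len(config$depth)) {
    P <- add_block(P, paste0("enc", i), c_prev, ld$widths[i])
    c_prev <- ld$widths[i]
  }
  P <- add_block(P, "bottleneck", c_prev, ld$bottleneck)
  for (i in rev(seq_len(config$depth)))
    P <- add_block(P, paste0("dec", i), 3L * ld$widths[i], ld$widths[i])
  P[["head.W"]] <- matrix(rnorm(ld$widths[1] * config$out_labels,
                                sd = sqrt(1 / ld$widths[1])),
                          ld$widths[1], config$out_labels)
  P[["head.b"]] <- rep(0, config$out_labels)
  structure(list(config = config, params = P), class = "unet3d")
}

#' @export
print.unet3d <- function(x, ...) {
  cat(sprintf(
    "unet3d: depth %d, base width %d, %d -> %d channels, %s parameters\n",
    x$config$depth, x$config$base_width, x$config$in_channels,
    x$config$out_labels, format(n_params(x), big.mark = ",")))
  invisible(x)
}

#' Number of trainable parameters
#' @param model a `unet3d`
#' @export
n_params <- function(model) sum(vapply(model$params, length, numeric(1)))

## ---- layer primitives (n_voxel x channel matrices, cached for backward) ----

add_bias <- function(Y, b) Y + matrix(b, nrow(Y), length(b), byrow = TRUE)

inorm_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  inv <- 1 / sqrt(colMeans(Xc^2) + eps)
  xhat <- sweep(Xc, 2L, inv, `*`)
  list(y = add_bias(sweep(xhat, 2L, g, `*`), b), xhat = xhat, inv = inv)
}

inorm_bwd <- function(dY, cache, g) {
  xhat <- cache$xhat
  n <- nrow(dY)
  dxhat <- sweep(dY, 2L, g, `*`)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * xhat)
  dX <- sweep(dxhat - matrix(s1 / n, n, length(s1), byrow = TRUE) -
                sweep(xhat, 2L, s2 / n, `*`), 2L, cache$inv, `*`)
  list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
}

pool_cache <- new.env(parent = emptyenv())

pool_indices <- function(dims) {
  key <- paste(dims, collapse = "x")
  if (!is.null(pool_cache[[key]])) return(pool_cache[[key]])
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  mx <- nx %/% 2L; my <- ny %/% 2L; mz <- nz %/% 2L
  cx <- rep(seq_len(mx), times = my * mz)
  cy <- rep(rep(seq_len(my), each = mx), times = mz)
  cz <- rep(seq_len(mz), each = mx * my)
  child <- vector("list", 8L)
  j <- 0L
  for (c in 0:1) for (b in 0:1) for (a in 0:1) {
    j <- j + 1L
    child[[j]] <- (2L * cx - 2L + a) + nx * ((2L * cy - 2L + b) +
                                               ny * (2L * cz - 2L + c)) + 1L
  }
  fx <- rep(seq_len(nx), times = ny * nz)
  fy <- rep(rep(seq_len(ny), each = nx), times = nz)
  fz <- rep(seq_len(nz), each = nx * ny)
  parent <- ((fx - 1L) %/% 2L) + mx * (((fy - 1L) %/% 2L) +
                                         my * ((fz - 1L) %/% 2L)) + 1L
  out <- list(child = child, parent = parent, coarse = c(mx, my, mz))
  pool_cache[[key]] <- out
  out
}

pool_fwd <- function(X, dims) {
  pi <- pool_indices(dims)
  Y <- X[pi$child[[1]], , drop = FALSE]
  for (j in 2:8) Y <- Y + X[pi$child[[j]], , drop = FALSE]
  list(y = Y / 8, dims = pi$coarse)
}

pool_bwd <- function(dY, dims) {
  pi <- pool_indices(dims)
  dX <- matrix(0, prod(dims), ncol(dY))
  for (j in 1:8) dX[pi$child[[j]], ] <- dY / 8
  dX
}

upsample_fwd <- function(X, coarse_dims, fine_dims) {
  pi <- pool_indices(fine_dims)
  X[pi$parent, , drop = FALSE]
}

upsample_bwd <- function(dY, fine_dims) {
  pi <- pool_indices(fine_dims)
  rowsum(dY, pi$parent)
}

conv_block_fwd <- function(X, dims, P, name, cache) {
  C1 <- im2col3(X, dims)
  z1 <- add_bias(C1 %*% P[[paste0(name, ".conv1.W")]],
                 P[[paste0(name, ".conv1.b")]])
  n1 <- inorm_fwd(z1, P[[paste0(name, ".in1.g")]], P[[paste0(name, ".in1.b")]])
  a1 <- n1$y * (n1$y > 0)
  C2 <- im2col3(a1, dims)
  z2 <- add_bias(C2 %*% P[[paste0(name, ".conv2.W")]],
                 P[[paste0(name, ".conv2.b")]])
  n2 <- inorm_fwd(z2, P[[paste0(name, ".in2.g")]], P[[paste0(name, ".in2.b")]])
  y <- n2$y * (n2$y > 0)
  if (!is.null(cache))
    cache[[name]] <- list(C1 = C1, n1 = n1, a1 = a1, C2 = C2, n2 = n2,
                          dims = dims, c_in = ncol(X))
  y
}

conv_block_bwd <- function(dY, P, name, cache, grads) {
  cc <- cache[[name]]
  dY <- dY * (cc$n2$y > 0)
  nb <- inorm_bwd(dY, cc$n2, P[[paste0(name, ".in2.g")]])
  grads[[paste0(name, ".in2.g")]] <- nb$dg
  grads[[paste0(name, ".in2.b")]] <- nb$db
  dz2 <- nb$dX
  grads[[paste0(name, ".conv2.W")]] <- crossprod(cc$C2, dz2)
  grads[[paste0(name, ".conv2.b")]] <- colSums(dz2)
  dC2 <- dz2 %*% t(P[[paste0(name, ".conv2.W")]])
  da1 <- col2im3(dC2, cc$dims, ncol(cc$a1))
  da1 <- da1 * (cc$n1$y > 0)
  nb1 <- inorm_bwd(da1, cc$n1, P[[paste0(name, ".in1.g")]])
  grads[[paste0(name, ".in1.g")]] <- nb1$dg
  grads[[paste0(name, ".in1.b")]] <- nb1$db
  dz1 <- nb1$dX
  grads[[paste0(name, ".conv1.W")]] <- crossprod(cc$C1, dz1)
  grads[[paste0(name, ".conv1.b")]] <- colSums(dz1)
  dC1 <- dz1 %*% t(P[[paste0(name, ".conv1.W")]])
  dX <- col2im3(dC1, cc$dims, cc$c_in)
  list(dX = dX, grads = grads)
}

#' Forward pass of the segmentation network
#'
#' @param model a [unet3d()]
#' @param X (n_voxel x in_channels) matrix, voxels in column-major grid order
#' @param dims patch grid dimensions
#' @param want_cache keep intermediates for [unet_backward()]
#' @return list with `y` (n_voxel x out_labels sigmoid probabilities) and,
#'   when requested, `cache`
#' @export
unet_forward <- function(model, X, dims, want_cache = FALSE) {
  P <- model$params
  d <- model$config$depth
  cache <- if (want_cache) new.env(parent = emptyenv()) else NULL
  dims_i <- as.integer(dims)
  skips <- vector("list", d)
  dims_lvl <- vector("list", d + 1L)
  h <- X
  for (i in seq_len(d)) {
    dims_lvl[[i]] <- dims_i
    h <- conv_block_fwd(h, dims_i, P, paste0("enc", i), cache)
    skips[[i]] <- h
    pf <- pool_fwd(h, dims_i)
    h <- pf$y
    dims_i <- pf$dims
  }
  dims_lvl[[d + 1L]] <- dims_i
  h <- conv_block_fwd(h, dims_i, P, "bottleneck", cache)
  for (i in rev(seq_len(d))) {
    fine <- dims_lvl[[i]]
    h <- upsample_fwd(h, dims_lvl[[i + 1L]], fine)
    h <- cbind(h, skips[[i]])
    h <- conv_block_fwd(h, fine, P, paste0("dec", i), cache)
  }
  logits <- add_bias(h %*% P[["head.W"]], P[["head.b"]])
  y <- 1 / (1 + exp(-logits))
  if (want_cache) {
    cache$top <- list(h = h, y = y, dims_lvl = dims_lvl)
  }
  list(y = y, cache = cache)
}

#' Backward pass: gradients of a scalar loss w.r.t. all parameters
#'
#' @param model a [unet3d()]
#' @param dY gradient of the loss w.r.t. the sigmoid output (n_voxel x
#'   out_labels)
#' @param cache the cache from `unet_forward(..., want_cache = TRUE)`
#' @return flat named list of gradients matching `model$params`
#' @export
unet_backward <- function(model, dY, cache) {
  P <- model$params
  d <- model$config$depth
  top <- cache$top
  grads <- list()
  dlogit <- dY * top$y * (1 - top$y)
  grads[["head.W"]] <- crossprod(top$h, dlogit)
  grads[["head.b"]] <- colSums(dlogit)
  dh <- dlogit %*% t(P[["head.W"]])
  dskip <- vector("list", d)
  for (i in seq_len(d)) {
    bb <- conv_block_bwd(dh, P, paste0("dec", i), cache, grads)
    grads <- bb$grads
    w_i <- ncol(bb$dX) %/% 3L * 2L       # upsampled part: 2 * w_i channels
    dup <- bb$dX[, seq_len(w_i), drop = FALSE]
    dskip[[i]] <- bb$dX[, (w_i + 1L):ncol(bb$dX), drop = FALSE]
    dh <- upsample_bwd(dup, top$dims_lvl[[i]])
  }
  bb <- conv_block_bwd(dh, P, "bottleneck", cache, grads)
  grads <- bb$grads
  dh <- bb$dX
  for (i in rev(seq_len(d))) {
    dh <- pool_bwd(dh, top$dims_lvl[[i]]) + dskip[[i]]
    bb <- conv_block_bwd(dh, P, paste0("enc", i), cache, grads)
    grads <- bb$grads
    dh <- bb$dX
  }
  grads
}
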