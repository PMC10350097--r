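test_that("the network emits one sigmoid channel per tract at input shape", {
  cfg <- unet_config(patch_shape = c(8, 8, 8), out_labels = 41, depth = 1,
                     base_width = 2, seed = 1)
  m <- unet3d(cfg)
  X <- matrix(0, 512, cfg$in_channels)
  y <- unet_forward(m, X, cfg$patch_shape)$y
  expect_equal(dim(y), c(512L, 41L))
  expect_true(all(is.finite(y)))
  expect_true(all(y >= 0 & y <= 1))
  expect_error(unet_config(patch_shape = c(10, 10, 10), depth = 2),
               "divisible")
})

test_that("parameter count matches the layer formula and scales ~4x with width", {
  count_expected <- function(w, depth, c_in, L) {
    conv <- function(ci, co) 27 * ci * co + co
    block <- function(ci, cm) conv(ci, cm) + conv(cm, cm) + 4 * cm
    widths <- w * 2^(seq_len(depth) - 1)
    total <- 0
    cp <- c_in
    for (i in seq_len(depth)) {
      total <- total + block(cp, widths[i]); cp <- widths[i]
    }
    total <- total + block(cp, w * 2^depth)
    for (i in seq_len(depth)) total <- total + block(3 * widths[i], widths[i])
    total + w * L + L
  }
  cfg8 <- unet_config(patch_shape = c(32, 32, 32), out_labels = 2, depth = 2,
                      base_width = 8)
  cfg16 <- unet_config(patch_shape = c(32, 32, 32), out_labels = 2, depth = 2,
                       base_width = 16)
  n8 <- n_params(unet3d(cfg8))
  n16 <- n_params(unet3d(cfg16))
  expect_equal(n8, count_expected(8, 2, 6, 2))
  expect_equal(n16, count_expected(16, 2, 6, 2))
  expect_gt(n16 / n8, 3.5)
  expect_lt(n16 / n8, 4.5)
})

test_that("initialization and forward passes are seed-deterministic", {
  cfg <- unet_config(patch_shape = c(8, 8, 8), out_labels = 2, depth = 1,
                     base_width = 3, seed = 77)
  m1 <- unet3d(cfg); m2 <- unet3d(cfg)
  expect_identical(m1$params, m2$params)
  set.seed(1)
  X <- matrix(rnorm(512 * 6), 512, 6)
  expect_identical(unet_forward(m1, X, cfg$patch_shape)$y,
                   unet_forward(m2, X, cfg$patch_shape)$y)
})

test_that("soft Dice loss matches its formula and handles the extremes", {
  t <- array(0, dim = c(4, 4, 4, 2))
  t[1:2, , , 1] <- 1
  t[3:4, , , 2] <- 1
  expect_lt(soft_dice_loss(t, t), 1e-4)               # perfect overlap
  disj <- t[, , , 2:1]
  expect_gt(soft_dice_loss(disj, t), 0.999)           # disjoint masks
  set.seed(6)
  p <- array(runif(128), dim = c(4, 4, 4, 2))
  eps <- 1e-5
  manual <- mean(sapply(1:2, function(l) {
    pp <- p[, , , l]; tt <- t[, , , l]
    1 - (2 * sum(pp * tt) + eps) / (sum(pp) + sum(tt) + eps)
  }))
  expect_equal(soft_dice_loss(p, t), manual, tolerance = 1e-12)
  expect_error(soft_dice_loss(p, t[, , 1:2, ]), "differ")
})

test_that("loss gradients agree with finite differences", {
  set.seed(2)
  p <- matrix(runif(40, 0.05, 0.95), 20, 2)
  t <- matrix(rbinom(40, 1, 0.4), 20, 2)
  g <- soft_dice_loss(p, t, gradient = TRUE)$grad
  eps <- 1e-7
  for (j in sample(40, 8)) {
    p2 <- p; p2[j] <- p[j] + eps
    p3 <- p; p3[j] <- p[j] - eps
    num <- (soft_dice_loss(p2, t) - soft_dice_loss(p3, t)) / (2 * eps)
    expect_equal(g[j], num, tolerance = 1e-5)
  }
})

test_that("backpropagation matches finite-difference network gradients", {
  set.seed(42)
  cfg <- unet_config(patch_shape = c(4, 4, 4), out_labels = 2, depth = 1,
                     base_width = 3, seed = 7)
  m <- unet3d(cfg)
  X <- matrix(rnorm(64 * 6), 64, 6)
  Tm <- matrix(rbinom(128, 1, 0.3), 64, 2)
  lossfun <- function(model)
    soft_dice_loss(unet_forward(model, X, cfg$patch_shape)$y, Tm)
  fw <- unet_forward(m, X, cfg$patch_shape, want_cache = TRUE)
  dl <- soft_dice_loss(fw$y, Tm, gradient = TRUE)
  g <- unet_backward(m, dl$grad, fw$cache)
  eps <- 1e-5
  for (nm in c("enc1.conv1.W", "enc1.in1.g", "bottleneck.conv2.W",
               "dec1.conv1.W", "head.W", "head.b")) {
    for (j in sample(length(m$params[[nm]]), min(3, length(m$params[[nm]])))) {
      m2 <- m; m2$params[[nm]][j] <- m$params[[nm]][j] + eps
      m3 <- m; m3$params[[nm]][j] <- m$params[[nm]][j] - eps
      num <- (lossfun(m2) - lossfun(m3)) / (2 * eps)
      expect_equal(g[[nm]][j], num, tolerance = 1e-3)
    }
  }
})

test_that("training reduces the loss and is reproducible", {
  cases <- lapply(1:2, function(s) make_case(s, snr = Inf,
                                             grid = c(16, 16, 16)))
  cfg <- unet_config(patch_shape = c(16, 16, 16), out_labels = 2, depth = 2,
                     base_width = 4, learning_rate = 1e-3, seed = 3)
  run <- function() train_segmenter(unet3d(cfg), cases[1], cases[2],
                                    n_epochs = 15, iterations_per_epoch = 4)
  m1 <- run()
  expect_lt(tail(m1$log$train_loss, 1), m1$log$train_loss[1])
  m2 <- run()
  expect_identical(m1$log, m2$log)
  expect_identical(m1$params, m2$params)
})

test_that("the learning rate halves after a validation plateau", {
  cases <- lapply(1:2, function(s) make_case(s, grid = c(16, 16, 16)))
  cfg <- unet_config(patch_shape = c(16, 16, 16), out_labels = 2, depth = 2,
                     base_width = 2, learning_rate = 1e-12,
                     lr_halve_patience = 2, seed = 4)
  m <- train_segmenter(unet3d(cfg), cases[1], cases[2], n_epochs = 5,
                       iterations_per_epoch = 1)
  # a vanishing step keeps the validation loss constant: the first epoch sets
  # the best, the plateau counter then fires every `patience` epochs
  expect_equal(m$log$lr, 1e-12 * c(1, 1, 0.5, 0.5, 0.25))
})

test_that("training aborts on non-finite loss and needs both case lists", {
  cases <- lapply(1:2, function(s) make_case(s, grid = c(16, 16, 16)))
  cfg <- unet_config(patch_shape = c(16, 16, 16), out_labels = 2, depth = 1,
                     base_width = 2, seed = 1)
  expect_error(train_segmenter(unet3d(cfg), list(), cases[2]), "at least one")
  bad <- unet3d(cfg)
  bad$params[["head.W"]][] <- NaN
  expect_error(train_segmenter(bad, cases[1], cases[2], n_epochs = 1),
               "non-finite")
})

test_that("checkpoints round-trip through save/load with a sidecar", {
  cfg <- unet_config(patch_shape = c(8, 8, 8), out_labels = 3, depth = 1,
                     base_width = 2, seed = 5)
  m <- unet3d(cfg)
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(m2$params, m$params)
  side <- jsonlite::read_json(sub("\\.rds$", ".json", path),
                              simplifyVector = TRUE)
  expect_equal(side$out_labels, 3)
  expect_equal(side$n_parameters, n_params(m))
})
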