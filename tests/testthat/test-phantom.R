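straight_tube_spec <- function(grid = c(20, 11, 11), radius = 2,
                               snr = Inf, ...) {
  ctr <- (grid[2] + 1) / 2
  phantom_spec(grid_shape = grid,
               tracts = list(list(label = 1L,
                                  points = cbind(c(1, grid[1]), ctr, ctr),
                                  radius = radius)),
               snr = snr, ...)
}

test_that("a straight tube rasterizes to an exact cylinder with x tangents", {
  spec <- straight_tube_spec()
  ras <- rasterize_tracts(spec)
  g <- spec$grid_shape
  ctr <- (g[2] + 1) / 2
  idx <- expand.grid(x = seq_len(g[1]), y = seq_len(g[2]), z = seq_len(g[3]))
  inside <- (idx$y - ctr)^2 + (idx$z - ctr)^2 <= 2^2
  expect_equal(as.vector(ras$labels[, , , 1]) == 1, inside)
  tan_in <- ras$tangents[[1]][inside, , drop = FALSE]
  expect_true(all(abs(abs(tan_in %*% c(1, 0, 0)) - 1) < 1e-12))
})

test_that("crossing tubes stack labels at the intersection", {
  g <- c(15, 15, 7)
  ctr <- 4
  spec <- phantom_spec(grid_shape = g, tracts = list(
    list(label = 1L, points = cbind(c(1, g[1]), 8, ctr), radius = 2),
    list(label = 2L, points = cbind(8, c(1, g[2]), ctr), radius = 2)))
  ras <- rasterize_tracts(spec)
  expect_equal(ras$labels[8, 8, ctr, ], c(1, 1))
  expect_equal(ras$labels[2, 8, ctr, ], c(1, 0))
  expect_equal(ras$labels[8, 2, ctr, ], c(0, 1))
  expect_error(rasterize_tracts(phantom_spec(grid_shape = g, tracts = list(
    list(label = 1L, points = cbind(3, 3, 3), radius = 2)))), "degenerate")
})

test_that("curved-tube tangents track the analytic circle tangent", {
  g <- c(24, 24, 7)
  th <- seq(0, pi / 2, length.out = 60)
  R <- 16
  pts <- cbind(2 + R * cos(th), 2 + R * sin(th), 4)
  spec <- phantom_spec(grid_shape = g,
                       tracts = list(list(label = 1L, points = pts,
                                          radius = 2)))
  ras <- rasterize_tracts(spec)
  inside <- which(ras$labels[, , , 1] == 1)
  idx <- which(ras$labels[, , , 1] == 1, arr.ind = TRUE)
  for (i in seq_along(inside)) {
    v <- idx[i, ]
    ang <- atan2(v[2] - 2, v[1] - 2)
    tan_true <- c(-sin(ang), cos(ang), 0)
    tan_got <- ras$tangents[[1]][inside[i], ]
    dev <- acos(pmin(1, abs(sum(tan_true * tan_got))))
    expect_lt(dev, 15 * pi / 180)
  }
})

test_that("noiseless signals follow the closed-form tensor decay", {
  spec <- straight_tube_spec(snr = Inf, background_adc = 1e-3, b_value = 1000)
  ph <- simulate_dwi(spec)
  nb0 <- spec$n_b0
  # b0 channels equal s0 everywhere
  expect_true(all(ph$dwi$data[, , , seq_len(nb0)] == spec$s0))
  # background voxel: isotropic exp(-b * adc) in every direction
  bg <- ph$dwi$data[1, 1, 1, (nb0 + 1):dim(ph$dwi$data)[4]]
  expect_equal(bg, rep(spec$s0 * exp(-1), spec$n_directions),
               tolerance = 1e-12)
  # signals in (0, s0]
  expect_true(all(ph$dwi$data > 0 & ph$dwi$data <= spec$s0))
  # tract voxel: minimum signal along the fiber direction (fastest decay)
  ctr <- c(10, 6, 6)
  sig <- ph$dwi$data[ctr[1], ctr[2], ctr[3], (nb0 + 1):dim(ph$dwi$data)[4]]
  dirs <- ph$dwi$gtab$bvecs[ph$dwi$gtab$bvals > 50, ]
  align <- abs(dirs[, 1])
  expect_equal(which.min(sig), which.max(align))
})

test_that("a log-linear tensor fit recovers the ground-truth diffusivities", {
  spec <- straight_tube_spec(snr = Inf)
  ph <- simulate_dwi(spec)
  norm <- b0_normalize(ph$dwi)
  ctr <- c(10, 6, 6)
  s <- norm$data[ctr[1], ctr[2], ctr[3], ]
  G <- norm$gtab$bvecs
  y <- -log(s) / spec$b_value
  X <- cbind(G[, 1]^2, G[, 2]^2, G[, 3]^2,
             2 * G[, 1] * G[, 2], 2 * G[, 1] * G[, 3], 2 * G[, 2] * G[, 3])
  d <- solve(crossprod(X), crossprod(X, y))
  D <- matrix(c(d[1], d[4], d[5], d[4], d[2], d[6], d[5], d[6], d[3]), 3, 3)
  ev <- sort(eigen(D, symmetric = TRUE)$values, decreasing = TRUE)
  expect_equal(ev[1], spec$diffusivities[1], tolerance = 1e-6)
  expect_equal(ev[2], spec$diffusivities[2], tolerance = 1e-6)
  expect_equal(ev[3], spec$diffusivities[2], tolerance = 1e-6)
})

test_that("noise is Rician, seeded, and vanishes as snr grows", {
  spec20a <- straight_tube_spec(grid = c(10, 7, 7), snr = 20, seed = 5)
  spec20b <- straight_tube_spec(grid = c(10, 7, 7), snr = 20, seed = 5)
  expect_identical(simulate_dwi(spec20a)$dwi$data,
                   simulate_dwi(spec20b)$dwi$data)
  clean <- simulate_dwi(straight_tube_spec(grid = c(10, 7, 7), snr = Inf))
  mad_at <- function(snr) {
    noisy <- simulate_dwi(straight_tube_spec(grid = c(10, 7, 7), snr = snr,
                                             seed = 5))
    mean(abs(noisy$dwi$data - clean$dwi$data))
  }
  m10 <- mad_at(10); m100 <- mad_at(100); m10000 <- mad_at(10000)
  expect_gt(m10, m100)
  expect_gt(m100, m10000)
  expect_lt(m10000, 1e-3 * spec20a$s0)
})

test_that("phantoms round-trip through their on-disk representation", {
  out <- file.path(tempdir(), "ph_roundtrip")
  spec <- random_phantom_spec(c(12, 12, 12), 2, seed = 3, snr = 15)
  ph <- simulate_dwi(spec)
  write_phantom(ph, out)
  spec2 <- read_phantom_spec(file.path(out, "phantom_spec.yaml"))
  ph2 <- simulate_dwi(spec2)
  expect_equal(ph2$dwi$data, ph$dwi$data, tolerance = 1e-12)
  expect_identical(ph2$labels, ph$labels)
  # and the written DWI reads back with its gradient table
  back <- read_dwi(file.path(out, "phantom_dwi.nii.gz"),
                   file.path(out, "phantom.bval"),
                   file.path(out, "phantom.bvec"))
  expect_equal(dim(back$data), dim(ph$dwi$data))
  expect_equal(max(abs(back$data - ph$dwi$data)), 0, tolerance = 1e-4)
})
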