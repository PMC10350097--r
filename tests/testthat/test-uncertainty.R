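test_that("cubic downsampling reduces shape and reproduces smooth fields", {
  set.seed(1)
  v <- array(runif(4 * 4 * 4), dim = c(4, 4, 4))
  expect_identical(downsample_volume(v, 1), v)
  const <- array(0.42, dim = c(8, 8, 4))
  dc <- downsample_volume(const, 2)
  expect_equal(dim(dc), c(4L, 4L, 2L))
  expect_true(all(abs(dc - 0.42) < 1e-12))
  # linear ramp: coarse values equal the ramp at the coarse voxel centers
  n <- 32
  ramp <- array(rep((seq_len(n) - 0.5) / n, times = 8 * 8), dim = c(n, 8, 8))
  dr <- downsample_volume(ramp, 4)
  expect_equal(dim(dr), c(8L, 2L, 2L))
  centers <- (seq_len(8) - 0.5) / 8
  expect_equal(dr[, 1, 1], centers, tolerance = 1e-3)
  # output stays within [0, 1] even where the spline overshoots
  spike <- array(0, dim = c(12, 4, 4)); spike[6, , ] <- 1
  expect_true(all(downsample_volume(spike, 2) >= 0))
  expect_error(downsample_volume(ramp, 0), "factor")
})

test_that("unit-sum normalization rescales mass and rejects empty volumes", {
  set.seed(2)
  v <- array(runif(27), dim = c(3, 3, 3)) * 5
  expect_equal(sum(unit_sum_normalize(v)), 1, tolerance = 1e-9)
  expect_equal(unit_sum_normalize(v), v / sum(v), tolerance = 1e-12)
  single <- array(0, dim = c(3, 3, 3)); single[2, 3, 1] <- 7
  expect_equal(unit_sum_normalize(single)[2, 3, 1], 1)
  expect_error(unit_sum_normalize(array(0, dim = c(2, 2, 2))), "empty-mass")
})

test_that("unfolding is serpentine and adjacency-preserving", {
  expect_identical(unfold(1:7), 1:7)
  # the canonical 3x3 slice: rows alternate direction
  m <- matrix(1:9, 3, 3)           # column-major: m[x, y]
  expect_identical(unfold(m), c(m[1, 1], m[2, 1], m[3, 1],
                                m[3, 2], m[2, 2], m[1, 2],
                                m[1, 3], m[2, 3], m[3, 3]))
  # consecutive positions in a 3D traversal are grid neighbours
  for (dims in list(c(3, 4, 2), c(5, 2, 3), c(1, 4, 3))) {
    ord <- unfold_order(dims)
    coords <- arrayInd(ord, dims)
    steps <- abs(diff(coords))
    expect_true(all(rowSums(steps) == 1))
  }
})

test_that("unfolded EMD matches hand-computed transport and is a metric surrogate", {
  # all mass moved L-1 steps
  L <- 9
  p <- c(1, rep(0, L - 1)); q <- c(rep(0, L - 1), 1)
  expect_equal(emd_unfolded(p, q), L - 1)
  expect_equal(emd_unfolded(q, p), L - 1)           # symmetry
  expect_equal(emd_unfolded(p, p), 0)               # identity
  set.seed(3)
  for (i in 1:20) {
    d <- c(sample(2:4, 1), sample(1:4, 1), sample(1:3, 1))
    a <- array(runif(prod(d)), dim = d); a <- a / sum(a)
    b <- array(runif(prod(d)), dim = d); b <- b / sum(b)
    expect_equal(emd_unfolded(a, b), emd_unfolded(b, a), tolerance = 1e-12)
    expect_gte(emd_unfolded(a, b), 0)
    expect_equal(emd_unfolded(a, a), 0)
    # triangle inequality (exact 1D Wasserstein along the unfolded path)
    cdum <- array(runif(prod(d)), dim = d); cdum <- cdum / sum(cdum)
    expect_lte(emd_unfolded(a, b),
               emd_unfolded(a, cdum) + emd_unfolded(cdum, b) + 1e-12)
  }
  expect_error(emd_unfolded(p, q[1:5]), "same shape")
  expect_error(emd_unfolded(p * 2, q), "unit mass")
  # the l2 pairing variant is the root-sum-of-squares of the same terms
  set.seed(4)
  a <- runif(8); a <- a / sum(a); b <- runif(8); b <- b / sum(b)
  P <- cumsum(a); Q <- cumsum(b)
  expect_equal(emd_unfolded(a, b, dist = "l2"), sqrt(sum((P - Q)^2)),
               tolerance = 1e-12)
})

test_that("u is the mean member-to-mean EMD and zero for identical members", {
  tm_dims <- c(6, 6, 6)
  mk_member <- function(f) {
    v <- array(0, dim = c(tm_dims, 1))
    v[, , , 1] <- f
    v
  }
  set.seed(5)
  base <- array(runif(prod(tm_dims)), dim = tm_dims)
  same <- structure(list(members = list(mk_member(base), mk_member(base),
                                        mk_member(base)),
                         mean = mk_member(base), subsets = NULL),
                    class = "ensemble_prediction")
  rep0 <- compute_uncertainty(same, downsample_factor = 1)
  expect_equal(rep0$u, 0)
  expect_false(rep0$flag)
  # three random members: u equals the mean of independently computed EMDs
  ms <- lapply(1:3, function(i) array(runif(prod(tm_dims)), dim = tm_dims))
  ens <- structure(list(members = lapply(ms, mk_member),
                        mean = mk_member(Reduce(`+`, ms) / 3), subsets = NULL),
                   class = "ensemble_prediction")
  rep1 <- compute_uncertainty(ens, downsample_factor = 1)
  ybar <- unit_sum_normalize(Reduce(`+`, ms) / 3)
  manual <- mean(sapply(ms, function(m)
    emd_unfolded(unit_sum_normalize(m), ybar)))
  expect_equal(rep1$u, manual, tolerance = 1e-9)
  # invariance under member permutation
  ens_p <- ens; ens_p$members <- ens_p$members[c(2, 3, 1)]
  expect_equal(compute_uncertainty(ens_p, downsample_factor = 1)$u, rep1$u)
})

test_that("translated members give u of half the shift distance", {
  # two unit point masses t steps apart along the fastest unfolding axis:
  # each member is t/2 from the mean
  for (t in 1:4) {
    v1 <- array(0, dim = c(6, 1, 1, 1)); v1[1, 1, 1, 1] <- 1
    v2 <- array(0, dim = c(6, 1, 1, 1)); v2[1 + t, 1, 1, 1] <- 1
    ens <- structure(list(members = list(v1, v2), mean = (v1 + v2) / 2,
                          subsets = NULL), class = "ensemble_prediction")
    rep <- compute_uncertainty(ens, downsample_factor = 1)
    expect_equal(rep$u, t / 2, tolerance = 1e-9)
  }
})

test_that("empty-mass members leave u undefined and flag the label", {
  v <- array(0, dim = c(4, 4, 4, 1)); v[2, 2, 2, 1] <- 1
  zero <- array(0, dim = c(4, 4, 4, 1))
  ens <- structure(list(members = list(v, zero), mean = (v + zero) / 2,
                        subsets = NULL), class = "ensemble_prediction")
  rep <- compute_uncertainty(ens, downsample_factor = 1)
  expect_true(is.na(rep$u))
  expect_true(rep$flag)
})

test_that("flagging thresholds u and sweeps to a monotone sensitivity", {
  expect_false(flag_inaccurate(0, 0.30))
  expect_true(flag_inaccurate(0.31, 0.30))
  expect_false(flag_inaccurate(0.30, 0.30))
  set.seed(6)
  u <- c(runif(30, 0, 0.6), runif(20, 0.2, 1.5))
  inaccurate <- c(rep(FALSE, 30), rep(TRUE, 20))
  thresholds <- sort(unique(u))
  sens <- sapply(thresholds, function(th)
    mean(flag_inaccurate(u[inaccurate], th)))
  expect_true(all(diff(sens) <= 1e-12))
})

test_that("uncertainty reports serialize with their member terms", {
  v1 <- array(runif(64), dim = c(4, 4, 4, 1))
  v2 <- array(runif(64), dim = c(4, 4, 4, 1))
  ens <- structure(list(members = list(v1, v2), mean = (v1 + v2) / 2,
                        subsets = NULL), class = "ensemble_prediction")
  rep <- compute_uncertainty(ens, downsample_factor = 2, threshold = 0.1)
  csvf <- tempfile(fileext = ".csv"); jsonf <- tempfile(fileext = ".json")
  write_uncertainty_report(rep, csvf, jsonf)
  back <- read.csv(csvf)
  expect_equal(back$u, rep$u, tolerance = 1e-12)
  expect_equal(back$threshold, 0.1)
  js <- jsonlite::read_json(jsonf, simplifyVector = TRUE)
  expect_equal(mean(unlist(js$per_member)), rep$u, tolerance = 1e-9)
})
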