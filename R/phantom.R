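#' Specify a synthetic multi-tensor DWI phantom
#'
#' The phantom emulates a DTI-style single-shell acquisition: tract-shaped
#' tubular label regions (possibly crossing), anisotropic Gaussian (tensor)
#' signal decay along each tract's local tangent, an isotropic background
#' compartment, quasi-uniform gradient directions on the half-sphere, and
#' Rician noise. Every downstream stage — SH projection, training, ensemble
#' prediction, uncertainty — can therefore be exercised against known ground
#' truth.
#'
#' @param grid_shape 3 positive integers (voxels)
#' @param voxel_size voxel edge lengths (mm)
#' @param tracts list of tracts; each a list with `label` (integer >= 1),
#'   `points` (n x 3 matrix of centerline control points, voxel units) and
#'   `radius` (mm-equivalent in voxel units)
#' @param b_value diffusion weighting (s/mm^2)
#' @param n_directions number of diffusion-weighted measurements
#' @param n_b0 number of b=0 volumes
#' @param s0 baseline (b=0) intensity
#' @param diffusivities c(axial, radial) tensor eigenvalues (mm^2/s)
#' @param background_adc isotropic background diffusivity (mm^2/s)
#' @param snr signal-to-noise ratio relative to s0, or `Inf` for noiseless
#' @param seed RNG seed for noise (and nothing else)
#' @return a `phantom_spec` object
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 64), voxel_size = c(1, 1, 1),
                         tracts = NULL, b_value = 1000,
                         n_directions = 30, n_b0 = 3, s0 = 1000,
                         diffusivities = c(1.7e-3, 0.3e-3),
                         background_adc = 1.0e-3, snr = 20, seed = 1) {
  if (is.null(tracts)) tracts <- default_tracts(grid_shape)
  if (diffusivities[1] < diffusivities[2] || diffusivities[2] <= 0)
    stop("need axial diffusivity >= radial diffusivity > 0")
  labs <- vapply(tracts, function(t) as.integer(t$label), integer(1))
  if (any(labs < 1L) || anyDuplicated(labs))
    stop("tract labels must be distinct integers >= 1 (0 is background)")
  for (t in tracts) {
    if (t$radius <= 0) stop("tract radius must be positive")
    if (nrow(as.matrix(t$points)) < 2L)
      stop("degenerate centerline: need at least two control points")
  }
  structure(list(grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
                 tracts = tracts, b_value = b_value,
                 n_directions = as.integer(n_directions),
                 n_b0 = as.integer(n_b0),
                 s0 = s0, diffusivities = diffusivities,
                 background_adc = background_adc, snr = snr, seed = seed),
            class = "phantom_spec")
}

#' Randomized phantom geometry
#'
#' Draws a [phantom_spec()] whose tract geometry varies deterministically
#' with `seed`: a straight tube spanning the grid along x (random offset and
#' slope) and, alternating, curved arcs crossing it in-plane. Radii scale
#' with the grid so tract volume fractions stay comparable across sizes.
#' Used to produce families of training/validation/test phantoms that share
#' the acquisition scheme but differ in geometry.
#'
#' @param grid_shape 3 positive integers
#' @param n_tracts number of tracts (alternating straight/curved)
#' @param seed drives both geometry and the noise realization
#' @param ... further arguments to [phantom_spec()] (snr, b_value, ...)
#' @return a `phantom_spec`
#' @export
random_phantom_spec <- function(grid_shape = c(32, 32, 32), n_tracts = 2,
                                seed = 1, ...) {
  g <- grid_shape
  set.seed(seed)
  tracts <- vector("list", n_tracts)
  for (i in seq_len(n_tracts)) {
    if (i %% 2L == 1L) {
      y0 <- g[2] * runif(1, 0.25, 0.5); z0 <- g[3] * runif(1, 0.35, 0.65)
      slope <- g[2] * runif(1, -0.1, 0.1)
      pts <- cbind(seq(1, g[1], length.out = 20),
                   y0 + slope * seq(-1, 1, length.out = 20), z0)
    } else {
      th <- seq(0, pi / 2, length.out = 20)
      cx <- g[1] * runif(1, 0.4, 0.6)
      pts <- cbind(cx + g[1] * runif(1, 0.4, 0.5) * cos(th),
                   g[2] * runif(1, 0.1, 0.2) + g[2] * runif(1, 0.65, 0.8) * sin(th),
                   g[3] * runif(1, 0.4, 0.6))
    }
    pts[, 1] <- pmin(pmax(pts[, 1], 1), g[1])
    pts[, 2] <- pmin(pmax(pts[, 2], 1), g[2])
    pts[, 3] <- pmin(pmax(pts[, 3], 1), g[3])
    tracts[[i]] <- list(label = i, points = pts,
                        radius = max(2, g[1] / 10 * runif(1, 0.8, 1.1)))
  }
  phantom_spec(grid_shape = grid_shape, tracts = tracts, seed = seed, ...)
}

# two crossing tubes spanning the grid: one straight along x, one curved
default_tracts <- function(grid_shape) {
  g <- grid_shape
  t1 <- cbind(seq(1, g[1], length.out = 20), g[2] * 0.35, g[3] * 0.5)
  th <- seq(0, pi / 2, length.out = 20)
  t2 <- cbind(g[1] * 0.5 + g[1] * 0.45 * cos(th),
              g[2] * 0.15 + g[2] * 0.8 * sin(th) * 0.9,
              g[3] * 0.5 + 0 * th)
  list(list(label = 1L, points = t1, radius = max(2, g[1] / 10)),
       list(label = 2L, points = t2, radius = max(2, g[1] / 12)))
}

#' Quasi-uniform gradient directions on the half-sphere
#'
#' Fibonacci-spiral points on the sphere, folded to z >= 0 (directions are
#' antipodally symmetric, so the half-sphere carries all the information).
#'
#' @param n number of directions
#' @return n x 3 matrix of unit vectors
#' @export
halfsphere_directions <- function(n) {
  i <- seq_len(n) - 0.5
  # golden-angle spiral over the upper hemisphere only
  z <- i / n               # cos(theta) in (0, 1): upper half
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# squared distance from each row of P (voxel centers) to segment [a, b],
# plus the segment tangent
point_segment_dist2 <- function(P, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 < 1e-12) {
    d2 <- rowSums(sweep(P, 2, a)^2)
    return(list(d2 = d2, t = pmin(1, pmax(0, 0))))
  }
  tt <- pmin(1, pmax(0, (sweep(P, 2, a) %*% ab) / len2))
  proj <- outer(drop(tt), ab) + matrix(a, nrow(P), 3, byrow = TRUE)
  list(d2 = rowSums((P - proj)^2), t = drop(tt))
}

#' Rasterize tract centerlines into labels and tangents
#'
#' Each tract is a tube of the given radius around its piecewise-linear
#' centerline. A voxel may belong to several tracts where tubes cross; the
#' per-label tangent at a voxel is the unit tangent of the nearest centerline
#' segment.
#'
#' @param spec a [phantom_spec()]
#' @return list with `labels` (4D 0/1 array x,y,z,tract, one channel per
#'   tract in `spec$tracts` order), `tangents` (list per tract: n_voxel x 3
#'   matrix of unit tangents, rows only meaningful inside the tract) and
#'   `label_ids`
#' @export
rasterize_tracts <- function(spec) {
  g <- spec$grid_shape
  P <- as.matrix(expand.grid(x = seq_len(g[1]), y = seq_len(g[2]),
                             z = seq_len(g[3])))
  n_vox <- nrow(P)
  n_tr <- length(spec$tracts)
  labels <- array(0, dim = c(g, n_tr))
  tangents <- vector("list", n_tr)
  for (ti in seq_len(n_tr)) {
    tr <- spec$tracts[[ti]]
    pts <- as.matrix(tr$points)
    if (nrow(pts) < 2L) stop("degenerate centerline: need >= 2 points")
    best_d2 <- rep(Inf, n_vox)
    best_tan <- matrix(0, n_vox, 3)
    for (si in seq_len(nrow(pts) - 1L)) {
      a <- pts[si, ]; b <- pts[si + 1L, ]
      seg <- point_segment_dist2(P, a, b)
      tan <- (b - a) / sqrt(sum((b - a)^2))
      upd <- seg$d2 < best_d2
      if (any(upd)) {
        best_d2[upd] <- seg$d2[upd]
        best_tan[upd, ] <- matrix(tan, sum(upd), 3, byrow = TRUE)
      }
    }
    inside <- best_d2 <= tr$radius^2
    labels[, , , ti][inside] <- 1
    tangents[[ti]] <- best_tan
  }
  list(labels = labels, tangents = tangents,
       label_ids = vapply(spec$tracts, function(t) as.integer(t$label),
                          integer(1)))
}

#' Simulate a DWI series from a phantom specification
#'
#' Noiseless signal per voxel and direction g:
#' \eqn{S(g) = s0 \cdot mean_c \exp(-b \, g^T D_c g)} over the compartments
#' c occupying the voxel — a cylindrically symmetric tensor per tract (axial
#' eigenvalue along the local tangent, radial elsewhere), an isotropic tensor
#' for pure background. b=0 volumes equal s0. Rician noise adds independent
#' Gaussian noise of sd s0/snr on two quadrature channels and takes the
#' magnitude. b=0 volumes come first in the series.
#'
#' @param spec a [phantom_spec()]
#' @return list with `dwi` (a [dwi_series()]), `labels` (4D 0/1 array per
#'   tract), `label_ids`, and `spec`
#' @export
simulate_dwi <- function(spec) {
  g <- spec$grid_shape
  ras <- rasterize_tracts(spec)
  n_vox <- prod(g)
  n_tr <- length(spec$tracts)
  dirs <- halfsphere_directions(spec$n_directions)
  ad <- spec$diffusivities[1]; rd <- spec$diffusivities[2]
  b <- spec$b_value

  occ <- matrix(ras$labels, nrow = n_vox)        # n_vox x n_tr occupancy
  n_comp <- rowSums(occ)
  sig <- matrix(0, n_vox, spec$n_directions)
  bg <- n_comp == 0
  if (any(bg))
    sig[bg, ] <- exp(-b * spec$background_adc)
  for (ti in seq_len(n_tr)) {
    inside <- occ[, ti] == 1
    if (!any(inside)) next
    # g^T D g = rd + (ad - rd) (g . t)^2 for a cylindrical tensor
    ct <- tcrossprod(ras$tangents[[ti]][inside, , drop = FALSE], dirs)
    dec <- exp(-b * (rd + (ad - rd) * ct^2))
    sig[inside, ] <- sig[inside, ] + dec / n_comp[inside]
  }
  sig <- spec$s0 * sig
  dat <- cbind(matrix(spec$s0, n_vox, spec$n_b0), sig)
  if (is.finite(spec$snr)) {
    set.seed(spec$seed)
    sdn <- spec$s0 / spec$snr
    dat <- sqrt((dat + matrix(rnorm(length(dat), 0, sdn), nrow(dat)))^2 +
                  matrix(rnorm(length(dat), 0, sdn), nrow(dat))^2)
  }
  bvals <- c(rep(0, spec$n_b0), rep(b, spec$n_directions))
  bvecs <- rbind(matrix(0, spec$n_b0, 3), dirs)
  dwi <- dwi_series(array(dat, dim = c(g, spec$n_b0 + spec$n_directions)),
                    gradient_table(bvals, bvecs),
                    voxel_size = spec$voxel_size)
  list(dwi = dwi, labels = ras$labels, label_ids = ras$label_ids, spec = spec)
}

#' Write a simulated phantom to disk
#'
#' DWI as NIfTI + FSL bval/bvec, labels as one 4D 0/1 NIfTI, the spec as YAML.
#'
#' @param phantom result of [simulate_dwi()]
#' @param out_dir output directory (created if missing)
#' @param prefix file-name prefix
#' @export
write_phantom <- function(phantom, out_dir, prefix = "phantom") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(ext) file.path(out_dir, paste0(prefix, ext))
  write_dwi(phantom$dwi, p("_dwi.nii.gz"), p(".bval"), p(".bvec"))
  write_volume(phantom$labels, p("_labels.nii.gz"),
               voxel_size = phantom$dwi$voxel_size)
  spec <- phantom$spec
  yaml::write_yaml(list(
    grid_shape = spec$grid_shape, voxel_size = spec$voxel_size,
    tracts = lapply(spec$tracts, function(t) {
      pts <- as.matrix(t$points)
      list(label = t$label,
           points = lapply(seq_len(nrow(pts)), function(i) as.numeric(pts[i, ])),
           radius = t$radius)
    }),
    b_value = spec$b_value, n_directions = spec$n_directions,
    n_b0 = spec$n_b0, s0 = spec$s0,
    diffusivities = spec$diffusivities,
    background_adc = spec$background_adc,
    snr = if (is.finite(spec$snr)) spec$snr else "Inf",
    seed = spec$seed), p("_spec.yaml"), precision = 17L)
  invisible(out_dir)
}

#' @rdname write_phantom
#' @param path a `_spec.yaml` written by [write_phantom()]
#' @export
read_phantom_spec <- function(path) {
  y <- yaml::read_yaml(path)
  phantom_spec(
    grid_shape = unlist(y$grid_shape), voxel_size = unlist(y$voxel_size),
    tracts = lapply(y$tracts, function(t)
      list(label = as.integer(t$label),
           points = do.call(rbind, lapply(t$points, unlist)),
           radius = t$radius)),
    b_value = y$b_value, n_directions = y$n_directions, n_b0 = y$n_b0,
    s0 = y$s0, diffusivities = unlist(y$diffusivities),
    background_adc = y$background_adc,
    snr = if (identical(y$snr, "Inf")) Inf else y$snr, seed = y$seed)
}
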