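#' Real symmetric spherical-harmonics design matrix
#'
#' Evaluates the real, even-degree (antipodally symmetric) spherical-harmonics
#' basis at a set of unit directions. The basis is ordered degree-major:
#' l = 0; then l = 2, m = -2..2; and so on for higher even degrees — the
#' ordering used by most diffusion-MRI toolchains ("modified-descoteaux"
#' style). Basis functions are orthonormal on the unit sphere. For order 2
#' the basis has (2+1)(2+2)/2 = 6 functions, so any set of >= 6 directions
#' maps to exactly 6 coefficients.
#'
#' Only even degrees appear, so every row satisfies B(-v) = B(v): the
#' diffusion signal's antipodal symmetry is built into the representation.
#'
#' @param directions m x 3 matrix of unit direction vectors
#' @param order maximum (even) spherical-harmonics degree
#' @return an m x n_coef matrix, n_coef = (order+1)(order+2)/2
#' @export
sh_design_matrix <- function(directions, order = 2) {
  directions <- as.matrix(directions)
  if (ncol(directions) != 3L) stop("directions must be an m x 3 matrix")
  if (length(order) != 1L || order < 0 || order %% 2 != 0)
    stop("order must be an even non-negative integer")
  nrm <- sqrt(rowSums(directions^2))
  if (any(nrm < 1e-8)) stop("zero-norm direction")
  v <- directions / nrm
  x <- v[, 1]; y <- v[, 2]; z <- v[, 3]
  cols <- list(rep(0.5 / sqrt(pi), nrow(v)))          # l = 0
  if (order >= 2) {
    c2 <- 0.5 * sqrt(15 / pi)
    cols <- c(cols, list(
      c2 * x * y,                                     # l = 2, m = -2
      c2 * y * z,                                     # l = 2, m = -1
      0.25 * sqrt(5 / pi) * (3 * z^2 - 1),            # l = 2, m =  0
      c2 * x * z,                                     # l = 2, m =  1
      0.5 * c2 * (x^2 - y^2)))                        # l = 2, m =  2
  }
  if (order >= 4) {
    # associated-Legendre route for degrees the closed forms above don't cover
    theta <- acos(pmin(pmax(z, -1), 1))
    phi <- atan2(y, x)
    for (l in seq(4, order, by = 2)) {
      for (m in -l:l) {
        plm <- legendre_plm(l, abs(m), cos(theta))
        nlm <- sqrt((2 * l + 1) / (4 * pi) *
                      exp(lgamma(l - abs(m) + 1) - lgamma(l + abs(m) + 1)))
        f <- if (m < 0) sqrt(2) * nlm * plm * sin(abs(m) * phi)
             else if (m == 0) nlm * plm
             else sqrt(2) * nlm * plm * cos(m * phi)
        cols <- c(cols, list(f))
      }
    }
  }
  do.call(cbind, cols)
}

# associated Legendre P_l^m(x) (no Condon-Shortley phase applied twice;
# standard recursion with phase, m >= 0)
legendre_plm <- function(l, m, x) {
  pmm <- rep(1, length(x))
  if (m > 0) {
    somx2 <- sqrt(pmax(0, 1 - x^2))
    fact <- 1
    for (i in seq_len(m)) {
      pmm <- -pmm * fact * somx2
      fact <- fact + 2
    }
  }
  if (l == m) return(pmm)
  pmmp1 <- x * (2 * m + 1) * pmm
  if (l == m + 1) return(pmmp1)
  pll <- pmmp1
  for (ll in seq(m + 2, l)) {
    pll <- (x * (2 * ll - 1) * pmmp1 - (ll + m - 1) * pmm) / (ll - m)
    pmm <- pmmp1
    pmmp1 <- pll
  }
  pll
}

sh_n_coef <- function(order) (order + 1) * (order + 2) / 2

sh_degrees <- function(order) {
  unlist(lapply(seq(0, order, by = 2), function(l) rep(l, 2 * l + 1)))
}

#' Fit spherical-harmonics coefficients to directional signals
#'
#' Least-squares projection of per-voxel signals measured on a set of
#' directions onto the even real SH basis, with optional Laplace-Beltrami
#' regularization: minimizes ||B c - s||^2 + reg_lambda * sum_l l^2(l+1)^2 c_l^2.
#' With `reg_lambda = 0` and at least n_coef directions the fit is the plain
#' least-squares solution (exact interpolation when the system is square).
#'
#' @param signals numeric vector of length m (one voxel) or an n x m matrix
#'   (n voxels, m directions)
#' @param directions m x 3 matrix of unit directions
#' @param order even SH order
#' @param reg_lambda non-negative Laplace-Beltrami regularization weight
#' @return coefficient vector (length n_coef) or n x n_coef matrix
#' @export
fit_sh <- function(signals, directions, order = 2, reg_lambda = 0) {
  B <- sh_design_matrix(directions, order)
  nc <- ncol(B)
  single <- is.null(dim(signals))
  S <- if (single) matrix(signals, nrow = 1L) else as.matrix(signals)
  if (ncol(S) != nrow(B))
    stop("number of signals per voxel must equal the number of directions")
  if (reg_lambda < 0) stop("reg_lambda must be non-negative")
  if (nrow(B) < nc && reg_lambda == 0)
    stop("under-determined fit: fewer directions than coefficients; ",
         "use reg_lambda > 0 or more directions")
  l <- sh_degrees(order)
  A <- crossprod(B) + reg_lambda * diag(l^2 * (l + 1)^2, nc)
  C <- t(solve(A, t(B) %*% t(S)))
  if (single) drop(C) else C
}

#' Project a b0-normalized DWI series onto the SH basis
#'
#' Applies [fit_sh()] voxel-wise over a chosen measurement subset, producing
#' the fixed-size coefficient volume the segmentation network consumes: the
#' channel count depends only on `order`, never on the subset size.
#'
#' @param dwi a b0-normalized [dwi_series()]
#' @param subset indices of the measurements to use (default: all); must not
#'   include b=0 measurements
#' @param order even SH order (default 2: 6 channels)
#' @param reg_lambda Laplace-Beltrami regularization weight
#' @return an `sh_volume`: list with `coeffs` (4D array x,y,z,n_coef),
#'   `order`, `basis_name`, `subset`, `reg_lambda`, `voxel_size`, `affine`
#' @export
sh_project <- function(dwi, subset = NULL, order = 2, reg_lambda = 0) {
  stopifnot(inherits(dwi, "dwi_series"))
  d <- dim(dwi$data)
  if (is.null(subset)) subset <- seq_len(d[4])
  subset <- as.integer(subset)
  if (any(subset < 1L | subset > d[4])) stop("subset index out of range")
  if (any(dwi$gtab$bvals[subset] <= dwi$gtab$b0_threshold))
    stop("subset contains b=0 measurements; normalize and exclude them first")
  S <- matrix(dwi$data, ncol = d[4])[, subset, drop = FALSE]
  C <- fit_sh(S, dwi$gtab$bvecs[subset, , drop = FALSE], order, reg_lambda)
  structure(list(coeffs = array(C, dim = c(d[1:3], ncol(C))),
                 order = order,
                 basis_name = "real_sym_descoteaux",
                 subset = subset, reg_lambda = reg_lambda,
                 voxel_size = dwi$voxel_size, affine = dwi$affine),
            class = "sh_volume")
}

#' @export
print.sh_volume <- function(x, ...) {
  d <- dim(x$coeffs)
  cat(sprintf(
    "sh_volume: order %d (%d channels), grid %d x %d x %d, basis %s\n",
    x$order, d[4], d[1], d[2], d[3], x$basis_name))
  invisible(x)
}

#' Write an SH coefficient volume as NIfTI plus a JSON sidecar
#'
#' The sidecar records the SH order, basis convention, measurement subset and
#' regularization so a prediction can be reproduced exactly.
#'
#' @param shvol an `sh_volume` from [sh_project()]
#' @param path output NIfTI path; the sidecar is written next to it as .json
#' @export
write_sh_volume <- function(shvol, path) {
  stopifnot(inherits(shvol, "sh_volume"))
  write_volume(shvol$coeffs, path, shvol$voxel_size, shvol$affine)
  side <- sub("\\.nii(\\.gz)?$", "", path)
  jsonlite::write_json(
    list(order = shvol$order, basis_name = shvol$basis_name,
         subset = shvol$subset, reg_lambda = shvol$reg_lambda),
    paste0(side, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
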