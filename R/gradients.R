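#' Gradient tables and diffusion-weighted series
#'
#' A `gradient_table` holds, for each measurement of a diffusion-weighted
#' scan, its b-value (s/mm^2) and unit gradient direction. A `dwi_series`
#' couples a 4D intensity array (x, y, z, measurement) with its gradient
#' table and voxel geometry. Directions are treated as antipodally symmetric
#' throughout: q and -q encode the same diffusion measurement.
#'
#' @param bvals numeric vector of b-values, length m
#' @param bvecs m x 3 numeric matrix of gradient directions; rows with b-value
#'   above `b0_threshold` are re-normalized to unit length
#' @param b0_threshold b-values at or below this are non-diffusion-weighted
#'   (b=0) measurements; their direction rows may be zero
#' @return an object of class `gradient_table` with elements `bvals` (numeric)
#'   and `bvecs` (m x 3 matrix)
#' @export
gradient_table <- function(bvals, bvecs, b0_threshold = 50) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (is.null(dim(bvecs)) || ncol(bvecs) != 3L)
    stop("bvecs must be an m x 3 matrix")
  if (length(bvals) != nrow(bvecs))
    stop("bvals and bvecs disagree on the number of measurements")
  if (length(bvals) < 1L) stop("at least one measurement is required")
  if (any(!is.finite(bvals)) || any(!is.finite(bvecs)))
    stop("bvals and bvecs must be finite")
  if (any(bvals < 0)) stop("b-values must be non-negative")
  nrm <- sqrt(rowSums(bvecs^2))
  dw <- bvals > b0_threshold
  if (any(dw & nrm < 1e-8))
    stop("diffusion-weighted rows must have non-zero gradient directions")
  fix <- dw & abs(nrm - 1) > 1e-3
  if (any(fix)) bvecs[fix, ] <- bvecs[fix, , drop = FALSE] / nrm[fix]
  structure(list(bvals = bvals, bvecs = bvecs, b0_threshold = b0_threshold),
            class = "gradient_table")
}

#' @export
print.gradient_table <- function(x, ...) {
  nb0 <- length(identify_b0s(x))
  cat(sprintf("gradient_table: %d measurements (%d b=0), b-values %s s/mm^2\n",
              length(x$bvals), nb0,
              paste(unique(round(x$bvals)), collapse = "/")))
  invisible(x)
}

parse_numeric_table <- function(source) {
  lines <- if (length(source) == 1L && file.exists(source)) readLines(source)
           else unlist(strsplit(source, "\n", fixed = TRUE))
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, function(l) {
    tok <- strsplit(trimws(l), "[ \t]+")[[1]]
    val <- suppressWarnings(as.numeric(tok))
    if (anyNA(val)) stop("non-numeric token in gradient table: ",
                         tok[which(is.na(val))[1]])
    val
  })
  rows
}

#' Read an FSL-style bval/bvec pair
#'
#' `bval` files hold one whitespace-separated row of m b-values; `bvec` files
#' hold three rows of m components (x, y, z).
#'
#' @param bval_source,bvec_source file path or character string in FSL layout
#' @inheritParams gradient_table
#' @return a [gradient_table()]
#' @export
read_gradient_table <- function(bval_source, bvec_source, b0_threshold = 50) {
  bv <- parse_numeric_table(bval_source)
  if (length(bv) != 1L) stop("bval source must contain exactly one row")
  gv <- parse_numeric_table(bvec_source)
  if (length(gv) != 3L) stop("bvec source must contain exactly three rows")
  n <- vapply(gv, length, integer(1))
  if (any(n != length(bv[[1]])))
    stop("bvals and bvecs disagree on the number of measurements")
  gradient_table(bv[[1]], cbind(gv[[1]], gv[[2]], gv[[3]]),
                 b0_threshold = b0_threshold)
}

#' Write a gradient table as FSL bval/bvec files
#'
#' @param gtab a [gradient_table()]
#' @param bval_path,bvec_path output file paths
#' @export
write_gradient_table <- function(gtab, bval_path, bvec_path) {
  stopifnot(inherits(gtab, "gradient_table"))
  writeLines(paste(format(gtab$bvals, scientific = FALSE, trim = TRUE),
                   collapse = " "), bval_path)
  writeLines(apply(t(gtab$bvecs), 1L, function(r)
    paste(sprintf("%.10f", r), collapse = " ")), bvec_path)
  invisible(c(bval_path, bvec_path))
}

#' Indices of non-diffusion-weighted (b=0) measurements
#'
#' @param gtab a [gradient_table()]
#' @param b0_threshold measurements with b-value at or below this (s/mm^2)
#'   count as b=0
#' @return integer vector of b=0 indices (possibly empty)
#' @export
identify_b0s <- function(gtab, b0_threshold = gtab$b0_threshold) {
  which(gtab$bvals <= b0_threshold)
}

#' Construct a diffusion-weighted image series
#'
#' @param data 4D numeric array (x, y, z, measurement)
#' @param gtab a [gradient_table()] whose length matches `dim(data)[4]`
#' @param voxel_size voxel edge lengths in mm (length 3, positive)
#' @param affine 4x4 voxel-to-world transform, carried through unchanged
#' @return an object of class `dwi_series`
#' @export
dwi_series <- function(data, gtab, voxel_size = c(1, 1, 1), affine = NULL) {
  stopifnot(inherits(gtab, "gradient_table"))
  if (length(dim(data)) != 4L)
    stop("data must be a 4D array (x, y, z, measurement)")
  if (dim(data)[4] != length(gtab$bvals))
    stop("fourth dimension of data must equal the number of measurements")
  if (any(!is.finite(data))) stop("intensities must be finite")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("voxel_size must be three positive lengths (mm)")
  if (is.null(affine)) affine <- diag(c(voxel_size, 1))
  structure(list(data = data, gtab = gtab, voxel_size = voxel_size,
                 affine = affine),
            class = "dwi_series")
}

#' @export
print.dwi_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("dwi_series: %d x %d x %d grid, %d measurements, voxel %s mm\n",
              d[1], d[2], d[3], d[4],
              paste(signif(x$voxel_size, 3), collapse = " x ")))
  invisible(x)
}

#' Normalize a DWI series by its b=0 signal
#'
#' Divides every diffusion-weighted volume voxel-wise by the mean of the b=0
#' volumes and drops the b=0 measurements from the result. The divisor is
#' floored at `epsilon`, and normalized intensities are clipped to
#' `[0, clip_max]`: physical attenuation is at most 1, so larger values only
#' arise from noise.
#'
#' @param dwi a [dwi_series()]
#' @param b0_threshold b-value cutoff for b=0 detection (s/mm^2)
#' @param epsilon floor applied to the b=0 divisor
#' @param clip_max upper clip for normalized intensities
#' @return a `dwi_series` with the b=0 measurements removed and intensities
#'   expressed as attenuation relative to b=0
#' @export
b0_normalize <- function(dwi, b0_threshold = dwi$gtab$b0_threshold,
                         epsilon = 1e-6, clip_max = 2) {
  stopifnot(inherits(dwi, "dwi_series"))
  b0 <- identify_b0s(dwi$gtab, b0_threshold)
  if (length(b0) == 0L)
    stop("no b=0 measurement found; cannot normalize")
  d <- dim(dwi$data)
  m <- d[4]
  keep <- setdiff(seq_len(m), b0)
  if (length(keep) == 0L) stop("series contains only b=0 measurements")
  flat <- matrix(dwi$data, ncol = m)
  ref <- rowMeans(flat[, b0, drop = FALSE])
  ref <- pmax(ref, epsilon)
  out <- flat[, keep, drop = FALSE] / ref
  out[out > clip_max] <- clip_max
  out[out < 0] <- 0
  gtab <- gradient_table(dwi$gtab$bvals[keep],
                         dwi$gtab$bvecs[keep, , drop = FALSE],
                         b0_threshold = b0_threshold)
  dwi_series(array(out, dim = c(d[1:3], length(keep))), gtab,
             voxel_size = dwi$voxel_size, affine = dwi$affine)
}

#' Read / write DWI volumes as NIfTI
#'
#' Thin wrappers over RNifti; the affine of the input image is carried on the
#' returned series and written back unchanged.
#'
#' @param nifti_path path to a 4D NIfTI file
#' @param bval_path,bvec_path FSL gradient table paths
#' @inheritParams gradient_table
#' @return [read_dwi()]: a [dwi_series()]
#' @export
read_dwi <- function(nifti_path, bval_path, bvec_path, b0_threshold = 50) {
  img <- RNifti::readNifti(nifti_path)
  gtab <- read_gradient_table(bval_path, bvec_path, b0_threshold)
  vs <- RNifti::pixdim(img)[1:3]
  dwi_series(array(as.numeric(img), dim = dim(img)), gtab,
             voxel_size = vs, affine = RNifti::xform(img))
}

#' @param dwi a [dwi_series()]
#' @rdname read_dwi
#' @export
write_dwi <- function(dwi, nifti_path, bval_path = NULL, bvec_path = NULL) {
  stopifnot(inherits(dwi, "dwi_series"))
  img <- RNifti::asNifti(dwi$data)
  RNifti::pixdim(img) <- c(dwi$voxel_size, 1)
  RNifti::qform(img) <- structure(dwi$affine, code = 2L)
  RNifti::writeNifti(img, nifti_path)
  if (!is.null(bval_path))
    write_gradient_table(dwi$gtab, bval_path, bvec_path)
  invisible(nifti_path)
}

#' Write a 3D or 4D array as NIfTI with a given affine
#' @param vol numeric array
#' @param path output path
#' @param voxel_size voxel edge lengths (mm)
#' @param affine 4x4 voxel-to-world matrix or NULL
#' @export
write_volume <- function(vol, path, voxel_size = c(1, 1, 1), affine = NULL) {
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- c(voxel_size, rep(1, length(dim(vol)) - 3L))
  if (!is.null(affine)) RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
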