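#' Dice similarity coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)` for two binary masks of the same shape.
#' Defined as 1 when both masks are empty and 0 when exactly one is.
#'
#' @param a,b binary arrays of identical shape
#' @return scalar in `[0, 1]`
#' @export
dice_coefficient <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  sa <- sum(a != 0); sb <- sum(b != 0)
  if (sa + sb == 0) return(1)
  2 * sum(a != 0 & b != 0) / (sa + sb)
}

# boundary voxels: mask minus its 6-connected erosion (voxels on the array
# border with the mask count as boundary)
mask_boundary <- function(mask) {
  d <- dim(mask)
  m <- mask != 0
  interior <- m
  for (axis in 1:3) {
    n <- d[axis]
    if (n == 1L) { interior <- interior & FALSE; next }
    idx_lo <- c(2:n, n); idx_hi <- c(1, 1:(n - 1))
    if (axis == 1) { lo <- m[idx_lo, , , drop = FALSE]; hi <- m[idx_hi, , , drop = FALSE] }
    if (axis == 2) { lo <- m[, idx_lo, , drop = FALSE]; hi <- m[, idx_hi, , drop = FALSE] }
    if (axis == 3) { lo <- m[, , idx_lo, drop = FALSE]; hi <- m[, , idx_hi, drop = FALSE] }
    # clamped-index trick would wrongly treat border voxels as interior;
    # mark out-of-grid neighbours as background explicitly
    if (axis == 1) { lo[n, , ] <- FALSE; hi[1, , ] <- FALSE }
    if (axis == 2) { lo[, n, ] <- FALSE; hi[, 1, ] <- FALSE }
    if (axis == 3) { lo[, , n] <- FALSE; hi[, , 1] <- FALSE }
    interior <- interior & lo & hi
  }
  m & !interior
}

#' Directed surface distances between two masks
#'
#' Boundary voxels are the mask minus its 6-connected erosion; distances are
#' Euclidean between boundary voxel centers, scaled per-axis by `voxel_size`
#' (anisotropy-aware). Returns both directed distance multisets.
#'
#' @param a,b non-empty binary arrays of identical shape
#' @param voxel_size voxel edge lengths in mm
#' @return list with `a_to_b` and `b_to_a` numeric vectors (mm)
#' @export
surface_distances <- function(a, b, voxel_size = c(1, 1, 1)) {
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  if (sum(a != 0) == 0 || sum(b != 0) == 0)
    stop("surface distances are undefined for an empty mask", call. = FALSE)
  pa <- which(mask_boundary(a), arr.ind = TRUE)
  pb <- which(mask_boundary(b), arr.ind = TRUE)
  pa <- sweep(pa, 2L, voxel_size, `*`)
  pb <- sweep(pb, 2L, voxel_size, `*`)
  # pairwise squared distances in blocks to bound memory
  nearest <- function(P, Q) {
    out <- numeric(nrow(P))
    step <- 1024L
    for (s in seq(1L, nrow(P), by = step)) {
      e <- min(s + step - 1L, nrow(P))
      blk <- P[s:e, , drop = FALSE]
      d2 <- outer(blk[, 1], Q[, 1], `-`)^2 +
        outer(blk[, 2], Q[, 2], `-`)^2 +
        outer(blk[, 3], Q[, 3], `-`)^2
      out[s:e] <- sqrt(apply(d2, 1L, min))
    }
    out
  }
  list(a_to_b = nearest(pa, pb), b_to_a = nearest(pb, pa))
}

#' 95th-percentile Hausdorff distance and average symmetric surface distance
#'
#' `hd95` is the maximum of the two directed 95th percentiles (linear
#' interpolation); `assd` is the mean over the pooled symmetric distance
#' multiset. Both are undefined (error) when either mask is empty.
#'
#' @inheritParams surface_distances
#' @return distance in mm
#' @export
hd95 <- function(a, b, voxel_size = c(1, 1, 1)) {
  sd <- surface_distances(a, b, voxel_size)
  max(quantile(sd$a_to_b, 0.95, names = FALSE),
      quantile(sd$b_to_a, 0.95, names = FALSE))
}

#' @rdname hd95
#' @export
assd <- function(a, b, voxel_size = c(1, 1, 1)) {
  sd <- surface_distances(a, b, voxel_size)
  mean(c(sd$a_to_b, sd$b_to_a))
}

#' Per-label segmentation metrics report
#'
#' Computes DSC, HD95 and ASSD for each label channel of a predicted mask
#' volume against the ground truth, plus an unweighted mean row over the
#' labels present in the ground truth. Distance metrics are reported as `NA`
#' (missing, not zero) when either mask of a label is empty.
#'
#' @param pred 4D binary array (x, y, z, label)
#' @param truth 4D binary array of the same shape
#' @param voxel_size voxel edge lengths (mm)
#' @return a `metrics_report` data.frame: label, dsc, hd95, assd
#' @export
evaluate_segmentation <- function(pred, truth, voxel_size = c(1, 1, 1)) {
  if (!identical(dim(pred), dim(truth))) stop("shapes differ")
  L <- dim(pred)[4]
  rows <- lapply(seq_len(L), function(l) {
    p <- pred[, , , l]; t <- truth[, , , l]
    d <- dice_coefficient(p, t)
    if (sum(p != 0) > 0 && sum(t != 0) > 0)
      data.frame(label = l, dsc = d, hd95 = hd95(p, t, voxel_size),
                 assd = assd(p, t, voxel_size))
    else
      data.frame(label = l, dsc = d, hd95 = NA_real_, assd = NA_real_)
  })
  rep <- do.call(rbind, rows)
  present <- vapply(seq_len(L), function(l) sum(truth[, , , l] != 0) > 0,
                    logical(1))
  mean_row <- data.frame(label = NA_integer_,
                         dsc = mean(rep$dsc[present]),
                         hd95 = mean(rep$hd95[present]),
                         assd = mean(rep$assd[present]))
  out <- rbind(rep, mean_row)
  attr(out, "voxel_size") <- voxel_size
  class(out) <- c("metrics_report", "data.frame")
  out
}

#' Write a metrics report as CSV and JSON
#' @param report a `metrics_report`
#' @param csv_path,json_path output paths (either may be NULL)
#' @export
write_metrics_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) write.csv(as.data.frame(report), csv_path,
                                    row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(metrics = as.data.frame(report),
                              voxel_size = attr(report, "voxel_size")),
                         json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  invisible(report)
}
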