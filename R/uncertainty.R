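#' Downsample a probability volume by cubic interpolation
#'
#' Reduces each axis by an integer factor (output length `ceiling(n/factor)`)
#' using separable natural cubic splines sampled at the coarse voxel centers,
#' then clips to `[0, 1]` (cubic interpolation can overshoot). Used to shrink
#' segmentation volumes before the EMD computation.
#'
#' @param vol 3D numeric array
#' @param factor integer >= 1
#' @return 3D array of reduced shape
#' @export
downsample_volume <- function(vol, factor = 4) {
  if (length(dim(vol)) != 3L) stop("vol must be a 3D array")
  if (factor < 1 || factor != round(factor)) stop("factor must be an integer >= 1")
  factor <- as.integer(factor)
  if (factor == 1L) return(vol)
  out <- vol
  for (axis in 1:3) {
    n <- dim(out)[axis]
    m <- as.integer(ceiling(n / factor))
    if (m == n) next
    src <- (seq_len(n) - 0.5) / n
    dst <- (seq_len(m) - 0.5) / m            # coarse voxel centers in [0,1]
    resample <- function(v) {
      if (length(v) == 1L) return(rep(v, m))
      splinefun(src, v, method = "natural")(dst)
    }
    perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    a <- aperm(out, perm)
    da <- dim(a)
    mat <- matrix(a, nrow = da[1])
    res <- apply(mat, 2L, resample)
    res <- matrix(res, nrow = m)
    a2 <- array(res, dim = c(m, da[2], da[3]))
    out <- aperm(a2, order(perm))
  }
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Normalize a non-negative volume to unit total mass
#'
#' The EMD compares probability distributions, so both inputs must carry the
#' same total mass; segmentations are therefore rescaled to sum to one.
#'
#' @param vol non-negative numeric array
#' @return array of the same shape summing to 1
#' @export
unit_sum_normalize <- function(vol) {
  if (any(vol < 0)) stop("volume must be non-negative")
  s <- sum(vol)
  if (s <= 0)
    stop("empty-mass volume: the segmentation predicted nothing",
         call. = FALSE)
  vol / s
}

unfold_cache <- new.env(parent = emptyenv())

#' Serpentine (boustrophedon) unfolding order of a 3D grid
#'
#' Returns the voxel visiting order of an adjacency-preserving traversal:
#' slices in ascending z; within slice z, rows in ascending y when z is even
#' (0-based) and descending otherwise; within each row, x ascending when
#' (y + z) is even and descending otherwise. Every pair of consecutive
#' positions differs by exactly one grid step, so the cumulative-sum EMD
#' approximation below measures transport along a connected path.
#'
#' @param dims grid dimensions (length 1-3; trailing singleton axes implied)
#' @return integer permutation of `1:prod(dims)` (column-major voxel indices)
#' @export
unfold_order <- function(dims) {
  dims <- as.integer(c(dims, rep(1L, 3L - length(dims))))
  key <- paste(dims, collapse = "x")
  if (!is.null(unfold_cache[[key]])) return(unfold_cache[[key]])
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  ord <- integer(nx * ny * nz)
  pos <- 0L
  for (z in 0:(nz - 1L)) {
    ys <- if (z %% 2L == 0L) 0:(ny - 1L) else (ny - 1L):0
    for (y in ys) {
      xs <- if ((y + z) %% 2L == 0L) 1:nx else nx:1
      ord[pos + seq_len(nx)] <- xs + nx * (y + ny * z)
      pos <- pos + nx
    }
  }
  unfold_cache[[key]] <- ord
  ord
}

#' Unfold a volume into a 1D sequence
#'
#' @param vol numeric array (1D-3D)
#' @return numeric vector in serpentine order ([unfold_order()])
#' @export
unfold <- function(vol) {
  d <- if (is.null(dim(vol))) length(vol) else dim(vol)
  as.vector(vol)[unfold_order(d)]
}

#' Earth mover's distance via serpentine unfolding
#'
#' Both mass volumes are unfolded along the same adjacency-preserving
#' serpentine path and their cumulative sums P, Q compared position-wise:
#' `EMD = sum_t |P(t) - Q(t)|` (for scalar P(t), Q(t) the l2 distance is the
#' absolute difference; a root-sum-of-squares variant is available via
#' `dist = "l2"`). For 1D inputs this is the exact Wasserstein-1 distance
#' with unit ground metric; in 3D it approximates transport cost along the
#' unfolded path. The distance unit is one unfolded (grid) step.
#'
#' @param p,q non-negative arrays of identical shape, each of unit total mass
#' @param dist `"l1"` (default; exact 1D Wasserstein) or `"l2"`
#'   (root-sum-of-squares over positions)
#' @param mass_tol allowed deviation of each input's total mass from 1
#' @return non-negative scalar; 0 iff `p == q` elementwise
#' @export
emd_unfolded <- function(p, q, dist = c("l1", "l2"), mass_tol = 1e-6) {
  dist <- match.arg(dist)
  dp <- if (is.null(dim(p))) length(p) else dim(p)
  dq <- if (is.null(dim(q))) length(q) else dim(q)
  if (!identical(dp, dq)) stop("p and q must have the same shape")
  if (abs(sum(p) - 1) > mass_tol || abs(sum(q) - 1) > mass_tol)
    stop("p and q must each have unit mass (use unit_sum_normalize)")
  ord <- unfold_order(dp)
  delta <- cumsum(as.vector(p)[ord] - as.vector(q)[ord])
  if (dist == "l1") sum(abs(delta)) else sqrt(sum(delta^2))
}

#' Ensemble-disagreement uncertainty statistic
#'
#' For each label, every ensemble member and the ensemble mean are
#' downsampled (factor `downsample_factor` per axis, cubic), normalized to
#' unit mass, and compared by [emd_unfolded()]; the uncertainty is
#' `u = mean_k EMD(y_k, ybar)`. Large u means the subset-based predictions
#' disagree about where the tract is — an indicator of an unreliable
#' segmentation. A member (or mean) with no predicted mass leaves its EMD
#' undefined and flags the label outright.
#'
#' @param pred an [ensemble_predict()] result
#' @param labels which label channels to report (default all)
#' @param downsample_factor per-axis reduction before the EMD
#' @param threshold flag cutoff on u
#' @param dist passed to [emd_unfolded()]
#' @return an `uncertainty_report`: data.frame with one row per label
#'   (label, u, flag, n_members, threshold, downsample_factor) plus a
#'   `per_member` attribute holding each member's EMD term
#' @export
compute_uncertainty <- function(pred, labels = NULL, downsample_factor = 4,
                                threshold = 0.30, dist = "l1") {
  stopifnot(inherits(pred, "ensemble_prediction"))
  L <- dim(pred$mean)[4]
  if (is.null(labels)) labels <- seq_len(L)
  n <- length(pred$members)
  per_member <- matrix(NA_real_, length(labels), n,
                       dimnames = list(labels, NULL))
  u <- numeric(length(labels))
  flag <- logical(length(labels))
  channel <- function(v, lab) array(v[, , , lab], dim = dim(v)[1:3])
  for (li in seq_along(labels)) {
    lab <- labels[li]
    ybar <- downsample_volume(channel(pred$mean, lab), downsample_factor)
    ybar_ok <- sum(ybar) > 0
    emds <- rep(NA_real_, n)
    for (kk in seq_len(n)) {
      yk <- downsample_volume(channel(pred$members[[kk]], lab),
                              downsample_factor)
      if (!ybar_ok || sum(yk) <= 0) next
      emds[kk] <- emd_unfolded(unit_sum_normalize(yk),
                               unit_sum_normalize(ybar), dist = dist)
    }
    per_member[li, ] <- emds
    if (anyNA(emds)) {
      u[li] <- NA_real_
      flag[li] <- TRUE            # empty-mass prediction: unreliable
    } else {
      u[li] <- mean(emds)
      flag[li] <- flag_inaccurate(u[li], threshold)
    }
  }
  rep <- data.frame(label = labels, u = u, flag = flag, n_members = n,
                    threshold = threshold,
                    downsample_factor = downsample_factor)
  attr(rep, "per_member") <- per_member
  attr(rep, "unfold_order") <- "serpentine_zyx"
  class(rep) <- c("uncertainty_report", "data.frame")
  rep
}

#' Flag an inaccurate segmentation from its uncertainty
#'
#' @param u non-negative uncertainty statistic
#' @param threshold cutoff; the default 0.30 detects low-quality
#'   segmentations with high sensitivity and specificity
#' @return `TRUE` iff `u > threshold`
#' @export
flag_inaccurate <- function(u, threshold = 0.30) {
  if (any(u < 0, na.rm = TRUE)) stop("u must be non-negative")
  u > threshold
}

#' Write an uncertainty report as CSV and JSON
#' @param report an `uncertainty_report`
#' @param csv_path,json_path output paths (either may be NULL)
#' @export
write_uncertainty_report <- function(report, csv_path = NULL,
                                     json_path = NULL) {
  if (!is.null(csv_path)) {
    df <- as.data.frame(report)
    df$unfold_order <- attr(report, "unfold_order")
    write.csv(df, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(report = as.data.frame(report),
           per_member = apply(attr(report, "per_member"), 1L, as.numeric,
                              simplify = FALSE),
           unfold_order = attr(report, "unfold_order")),
      json_path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(report)
}
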