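#' Angular distance between gradient directions
#'
#' Diffusion measurements along q and -q are equivalent, so the distance
#' between two directions is the acute angle between their lines:
#' min(theta, pi - theta), in `[0, pi/2]`.
#'
#' @param u,v unit 3-vectors
#' @return angle in radians
#' @export
angular_distance <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-8 || nv < 1e-8) stop("zero-norm direction")
  th <- acos(pmin(1, pmax(-1, abs(sum(u * v)) / (nu * nv))))
  th
}

# pairwise acute-angle matrix for the rows of V (antipodally symmetric)
angular_distance_matrix <- function(V) {
  nrm <- sqrt(rowSums(V^2))
  if (any(nrm < 1e-8)) stop("zero-norm direction")
  Vn <- V / nrm
  acos(pmin(abs(tcrossprod(Vn)), 1))
}

#' Select a well-spread measurement subset
#'
#' Maximizes the minimum (antipodally symmetric) pairwise angular distance of
#' the chosen subset while staying stochastic, so repeated draws give the
#' varied q-space views wanted for augmentation. Small pools are scored
#' exhaustively and the subset drawn uniformly among those within 95% of the
#' optimal spread; larger pools use several randomized farthest-point
#' restarts with steepest-ascent swap refinement and draw among the
#' best-scoring restarts. Either way every returned pair of directions is
#' far apart in q-space and the selection is deterministic given `rng_seed`.
#'
#' @param gtab a [gradient_table()]
#' @param k subset size
#' @param rng_seed integer seed; the selection is deterministic given it
#' @param exclude indices that must not be selected (on top of b=0 ones)
#' @return a `subset_spec`: list with `indices` (in selection order), `size`,
#'   `seed`
#' @export
select_spread_subset <- function(gtab, k, rng_seed = NULL, exclude = integer(0)) {
  stopifnot(inherits(gtab, "gradient_table"))
  pool <- setdiff(setdiff(seq_along(gtab$bvals), identify_b0s(gtab)), exclude)
  if (k > length(pool))
    stop("k exceeds the number of available diffusion-weighted measurements")
  if (k < 1L) stop("k must be at least 1")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  D <- angular_distance_matrix(gtab$bvecs[pool, , drop = FALSE])
  n <- length(pool)
  if (k == 1L) {
    sel <- sample.int(n, 1L)
  } else if (choose(n, k) <= 20000) {
    # small pools: score every subset exactly and draw uniformly among the
    # near-optimal ones — maximal spread with retained stochasticity
    combs <- utils::combn(n, k)
    pr <- utils::combn(k, 2)
    q <- apply(combs, 2L, function(ix)
      min(D[cbind(ix[pr[1L, ]], ix[pr[2L, ]])]))
    good <- which(q >= 0.95 * max(q))
    pick <- if (length(good) == 1L) good else sample(good, 1L)
    sel <- combs[, pick]
  } else {
    # large pools: several random farthest-point restarts with swap
    # refinement; the returned subset is drawn among the restarts that come
    # close to the best one, so repeated draws stay diverse
    restarts <- lapply(seq_len(6L), function(i)
      refine_subset_swaps(greedy_from(sample.int(n, 1L), D, k), D))
    q <- vapply(restarts, subset_min_angle, numeric(1), D = D)
    good <- which(q >= 0.9 * max(q))
    pick <- if (length(good) == 1L) good else sample(good, 1L)
    sel <- restarts[[pick]]
  }
  structure(list(indices = pool[sel], size = k, seed = rng_seed),
            class = "subset_spec")
}

subset_min_angle <- function(ix, D) {
  M <- D[ix, ix, drop = FALSE]
  min(M[upper.tri(M)])
}

# deterministic farthest-point growth from a given start index
greedy_from <- function(start, D, k) {
  sel <- integer(k)
  sel[1] <- start
  mind <- D[, start]
  for (i in 2:k) {
    mind[sel[seq_len(i - 1L)]] <- -Inf
    sel[i] <- which.max(mind)
    mind <- pmin(mind, D[, sel[i]])
  }
  sel
}

# greedy growth from a random start can land in a poor local configuration;
# steepest-ascent swaps on the min pairwise angle fix the worst cases while
# staying close to the (random) starting subset
refine_subset_swaps <- function(sel, D, max_pass = 25L) {
  min_angle <- function(ix) min(D[ix, ix][upper.tri(diag(length(ix)))])
  cur <- min_angle(sel)
  cand_all <- seq_len(nrow(D))
  for (pass in seq_len(max_pass)) {
    best_gain <- 0
    best_swap <- NULL
    outside <- setdiff(cand_all, sel)
    for (i in seq_along(sel)) {
      for (cnd in outside) {
        trial <- sel
        trial[i] <- cnd
        v <- min_angle(trial)
        if (v - cur > best_gain + 1e-12) {
          best_gain <- v - cur
          best_swap <- c(i, cnd)
        }
      }
    }
    if (is.null(best_swap)) break
    sel[best_swap[1]] <- best_swap[2]
    cur <- cur + best_gain
  }
  sel
}

#' Training-time subset sampler
#'
#' Returns a closure that, on each call, draws a subset size uniformly from
#' `[size_min, size_max]` and then a well-spread subset of that size via
#' [select_spread_subset()], presenting the network with a different q-space
#' view of the same scan on every training iteration. The stream is
#' reproducible given `rng_seed`.
#'
#' @param gtab a [gradient_table()]
#' @param size_min,size_max inclusive subset-size bounds (default 6-12)
#' @param rng_seed stream seed
#' @return a function of no arguments returning a `subset_spec`
#' @export
training_subset_sampler <- function(gtab, size_min = 6, size_max = 12,
                                    rng_seed = 1) {
  stopifnot(inherits(gtab, "gradient_table"))
  n_dw <- length(gtab$bvals) - length(identify_b0s(gtab))
  if (size_min < 1 || size_max < size_min)
    stop("invalid subset size bounds")
  if (size_max > n_dw)
    stop("size_max exceeds the number of diffusion-weighted measurements")
  counter <- 0L
  function() {
    counter <<- counter + 1L
    seed <- (rng_seed * 10007L + counter) %% .Machine$integer.max
    set.seed(seed)
    k <- size_min + sample.int(size_max - size_min + 1L, 1L) - 1L
    select_spread_subset(gtab, k, rng_seed = seed + 1L)
  }
}

#' Inference-time measurement subsets
#'
#' Draws `n` well-spread subsets of fixed size `k` for ensemble prediction.
#' With `disjoint = TRUE` subsets share no measurement (each selection is
#' restricted to the still-unused indices), as used to probe reproducibility
#' across independent sub-scans.
#'
#' @param gtab a [gradient_table()]
#' @param k subset size
#' @param n number of subsets (ensemble size)
#' @param rng_seed integer seed
#' @param disjoint forbid index reuse across subsets
#' @return list of `n` `subset_spec` objects
#' @export
test_subsets <- function(gtab, k, n = 10, rng_seed = 1, disjoint = FALSE) {
  stopifnot(inherits(gtab, "gradient_table"))
  n_dw <- length(gtab$bvals) - length(identify_b0s(gtab))
  if (disjoint && n * k > n_dw)
    stop("disjoint subsets infeasible: n * k exceeds available measurements")
  if (k > n_dw) stop("k exceeds the number of available measurements")
  used <- integer(0)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    seed <- (rng_seed * 7919L + i - 1L) %% .Machine$integer.max
    out[[i]] <- select_spread_subset(gtab, k, rng_seed = seed,
                                     exclude = if (disjoint) used else integer(0))
    used <- c(used, out[[i]]$indices)
  }
  out
}

#' Serialize subset specifications to JSON
#' @param subsets a `subset_spec` or list of them
#' @param path output path
#' @export
write_subsets <- function(subsets, path) {
  if (inherits(subsets, "subset_spec")) subsets <- list(subsets)
  jsonlite::write_json(
    lapply(subsets, function(s)
      list(indices = s$indices, size = s$size, seed = s$seed)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_subsets
#' @export
read_subsets <- function(path) {
  lapply(jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE),
         function(s) structure(list(indices = as.integer(s$indices),
                                    size = as.integer(s$size),
                                    seed = s$seed),
                               class = "subset_spec"))
}
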