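# Independent oracles used to check package computations.

# Exact optimal-transport cost between two 1D mass vectors with unit ground
# metric |i - j|, solved as a linear program (HiGHS via scipy.optimize.linprog)
# in a single python subprocess. `pairs` is a list of list(p = ..., q = ...);
# returns the vector of optimal costs.
lp_transport_costs <- function(pairs) {
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  jsonlite::write_json(lapply(pairs, function(pr)
    list(p = as.numeric(pr$p), q = as.numeric(pr$q))),
    infile, digits = NA)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import json, sys",
    "import numpy as np",
    "from scipy.optimize import linprog",
    "pairs = json.load(open(sys.argv[1]))",
    "out = []",
    "for pr in pairs:",
    "    p = np.asarray(pr['p'], float); q = np.asarray(pr['q'], float)",
    "    L = len(p)",
    "    C = np.abs(np.subtract.outer(np.arange(L), np.arange(L))).ravel()",
    "    A = []",
    "    for i in range(L):",
    "        row = np.zeros((L, L)); row[i, :] = 1; A.append(row.ravel())",
    "    for j in range(L):",
    "        col = np.zeros((L, L)); col[:, j] = 1; A.append(col.ravel())",
    "    res = linprog(C, A_eq=np.asarray(A), b_eq=np.concatenate([p, q]),",
    "                  bounds=(0, None), method='highs')",
    "    assert res.status == 0",
    "    out.append(float(res.fun))",
    "json.dump(out, open(sys.argv[2], 'w'))"), script)
  status <- system2("python", c(script, infile, outfile))
  if (status != 0) stop("LP oracle subprocess failed")
  as.numeric(jsonlite::read_json(outfile, simplifyVector = TRUE))
}

# brute-force surface-distance metrics straight from their definitions:
# boundary = mask voxels with some 6-neighbour outside the mask (or outside
# the grid); distances by a double loop over boundary voxel centers.
brute_force_surface_metrics <- function(a, b, voxel_size = c(1, 1, 1)) {
  boundary_pts <- function(m) {
    d <- dim(m)
    idx <- which(m != 0, arr.ind = TRUE)
    keep <- apply(idx, 1L, function(v) {
      for (ax in 1:3) for (s in c(-1L, 1L)) {
        w <- v
        w[ax] <- w[ax] + s
        if (w[ax] < 1L || w[ax] > d[ax]) return(TRUE)
        if (m[w[1], w[2], w[3]] == 0) return(TRUE)
      }
      FALSE
    })
    idx[keep, , drop = FALSE]
  }
  pa <- sweep(boundary_pts(a), 2L, voxel_size, `*`)
  pb <- sweep(boundary_pts(b), 2L, voxel_size, `*`)
  directed <- function(P, Q) {
    vapply(seq_len(nrow(P)), function(i)
      sqrt(min(colSums((t(Q) - P[i, ])^2))), numeric(1))
  }
  dab <- directed(pa, pb)
  dba <- directed(pb, pa)
  list(
    hd95 = max(quantile(dab, 0.95, names = FALSE),
               quantile(dba, 0.95, names = FALSE)),
    assd = mean(c(dab, dba)),
    a_to_b = dab, b_to_a = dba)
}

# quasi-uniform points on the full sphere (spiral), for quadrature checks
fibonacci_sphere <- function(n) {
  i <- seq_len(n)
  z <- 1 - (2 * i - 1) / n
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# random unit vectors
random_directions <- function(n) {
  v <- matrix(rnorm(3 * n), n, 3)
  v / sqrt(rowSums(v^2))
}
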