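# Independent oracles and small utilities shared by the tests. These stay
# deliberately naive (double loops, dense grids) so they cannot share a bug
# with the implementation they check.

random_orthogonal <- function(d, seed) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(d * d), d, d)))
}

# Brute-force coranking: explicit double loop over ordered pairs.
coranking_bruteforce <- function(D_high, D_low) {
  n <- nrow(D_high)
  m <- n - 1L
  rank_of <- function(D, i, j) {
    # number of k with d(i,k) < d(i,j), or equal distance and k < j (k != i)
    cnt <- 0L
    for (k in seq_len(n)) {
      if (k == i) next
      if (D[i, k] < D[i, j] || (D[i, k] == D[i, j] && k < j)) cnt <- cnt + 1L
    }
    cnt + ifelse(D[i, j] < D[i, i], 0L, 0L)  # self never counted
  }
  Q <- matrix(0L, m, m)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    k <- rank_of(D_high, i, j) + 1L
    l <- rank_of(D_low, i, j) + 1L
    Q[k, l] <- Q[k, l] + 1L
  }
  Q
}

# Dense numerical minimization of ||x - y||^2 over the embedded sphere
# S_I(c, r) in d <= 3, by fine parameter grids plus local refinement.
oracle_sphere_sqdist <- function(x, cen, r, idx) {
  d <- length(x)
  comp <- setdiff(seq_len(d), idx)
  point_at <- function(u) {
    y <- cen
    y[idx] <- cen[idx] + r * u
    y
  }
  if (length(idx) == 2L) {
    obj <- function(th) sum((x - point_at(c(cos(th), sin(th))))^2)
    grid <- seq(-pi, pi, length.out = 4001L)
    vals <- vapply(grid, obj, numeric(1))
    k <- which.min(vals)
    lo <- grid[max(1L, k - 2L)]; hi <- grid[min(length(grid), k + 2L)]
    stats::optimize(obj, c(lo, hi), tol = 1e-12)$objective
  } else if (length(idx) == 3L) {
    obj <- function(p) {
      u <- c(cos(p[2]) * cos(p[1]), cos(p[2]) * sin(p[1]), sin(p[2]))
      sum((x - point_at(u))^2)
    }
    grid <- expand.grid(az = seq(-pi, pi, length.out = 181L),
                        el = seq(-pi / 2, pi / 2, length.out = 91L))
    vals <- apply(grid, 1L, obj)
    k <- which.min(vals)
    res <- stats::optim(as.numeric(grid[k, ]), obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 2000))
    res$value
  } else {
    stop("oracle supports |I| in {2, 3} only")
  }
}

# Orthomax criterion used by the 2-column grid oracle.
orthomax_crit <- function(L, gamma) {
  sum(L^4) - (gamma / nrow(L)) * sum(colSums(L^2)^2)
}

# Exhaustive 1-angle search for the best orthogonal rotation of a 2-column
# loading matrix under the orthomax criterion.
orthomax_grid_best <- function(L, gamma) {
  obj <- function(phi) {
    G <- matrix(c(cos(phi), -sin(phi), sin(phi), cos(phi)), 2L, 2L)
    orthomax_crit(L %*% G, gamma)
  }
  grid <- seq(-pi / 4, pi / 4, length.out = 721L)
  vals <- vapply(grid, obj, numeric(1))
  k <- which.min(-vals)
  best <- stats::optimize(function(p) -obj(p),
                          c(grid[max(1L, k - 2L)], grid[min(length(grid), k + 2L)]),
                          tol = 1e-12)
  -best$objective
}
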