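# Embedding-quality metrics: MSE, the coranking matrix with Q_NX/R_NX
# curves and their (weighted) areas, cophenetic correlation, cluster
# separation scores, and a circular rank correlation for cyclic structure.

#' Mean squared reconstruction error
#'
#' \eqn{(1/n) \sum_i \|x_i - \hat x_i\|^2} between an original matrix and its
#' reconstruction in the same space.
#'
#' @param X,X_hat Numeric matrices of identical shape.
#' @return Non-negative scalar.
#' @export
reconstruction_mse <- function(X, X_hat) {
  X <- as.matrix(X); X_hat <- as.matrix(X_hat)
  if (!all(dim(X) == dim(X_hat))) stop("'X' and 'X_hat' must have the same shape")
  mean(rowSums((X - X_hat)^2))
}

.check_distance_matrix <- function(D, arg) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop(sprintf("'%s' must be square", arg))
  if (max(abs(D - t(D))) > 1e-8) stop(sprintf("'%s' must be symmetric", arg))
  if (max(abs(diag(D))) > 1e-12) stop(sprintf("'%s' must have a zero diagonal", arg))
  D
}

#' Coranking matrix of two distance matrices
#'
#' For every point i the remaining points are ranked by distance in the
#' original and in the reduced space (ties broken by the smaller index); the
#' entry \eqn{Q_{kl}} counts pairs (i, j) whose original-space rank is k and
#' reduced-space rank is l. The result is an (n-1) x (n-1) integer matrix
#' whose entries sum to n(n-1), with every row and column summing to n.
#'
#' @param D_high,D_low Symmetric n x n distance matrices (or `dist`
#'   objects) for the original and reduced spaces.
#' @return Object of class `srca_coranking`: the matrix `Q` with attribute
#'   `n`.
#' @export
coranking <- function(D_high, D_low) {
  if (inherits(D_high, "dist")) D_high <- as.matrix(D_high)
  if (inherits(D_low, "dist")) D_low <- as.matrix(D_low)
  D_high <- .check_distance_matrix(D_high, "D_high")
  D_low <- .check_distance_matrix(D_low, "D_low")
  n <- nrow(D_high)
  if (nrow(D_low) != n) stop("distance matrices must have the same size")
  if (n < 3L) stop("need at least 3 points")
  m <- n - 1L
  counts <- integer(m * m)
  for (i in seq_len(n)) {
    rh <- rank(D_high[i, -i], ties.method = "first")
    rl <- rank(D_low[i, -i], ties.method = "first")
    cell <- rh + (rl - 1L) * m
    tab <- tabulate(cell, nbins = m * m)
    counts <- counts + tab
  }
  Q <- matrix(counts, m, m)
  structure(Q, n = n, class = c("srca_coranking", "matrix"))
}

#' Rank-preservation curves and areas from a coranking matrix
#'
#' \eqn{Q_{NX}(K) = (1/(Kn)) \sum_{k \le K, l \le K} Q_{kl}} is the fraction
#' of preserved K-ary neighbours; \eqn{R_{NX}(K) = ((n-1) Q_{NX}(K) - K) /
#' (n-1-K)} rescales it so that a random embedding scores ~0 and a perfect
#' one scores 1. `auc` is the flat mean of \eqn{R_{NX}} over K = 1..n-2 and
#' `wauc` the 1/K-weighted mean (emphasizing small neighbourhoods).
#'
#' @param Q An [coranking()] result.
#' @return List with vectors `qnx`, `rnx` and scalars `auc`, `wauc`.
#' @export
rnx_scores <- function(Q) {
  stopifnot(inherits(Q, "srca_coranking"))
  n <- attr(Q, "n")
  if (n < 4L) stop("need at least 4 points for R_NX scores")
  m <- n - 1L
  cs <- apply(apply(unclass(Q), 2L, cumsum), 1L, cumsum)  # cs[K, K] = block sum
  SK <- diag(cs)
  K <- seq_len(m)
  qnx <- SK / (K * n)
  Kr <- seq_len(n - 2L)
  rnx <- ((n - 1) * qnx[Kr] - Kr) / (n - 1 - Kr)
  list(qnx = qnx, rnx = rnx,
       auc = mean(rnx),
       wauc = sum(rnx / Kr) / sum(1 / Kr))
}

#' Cophenetic correlation between two distance matrices
#'
#' Pearson correlation between the strict upper triangles of the two
#' pairwise-distance matrices.
#'
#' @inheritParams coranking
#' @return Scalar in \[-1, 1\].
#' @export
cophenetic_correlation <- function(D_high, D_low) {
  if (inherits(D_high, "dist")) D_high <- as.matrix(D_high)
  if (inherits(D_low, "dist")) D_low <- as.matrix(D_low)
  D_high <- .check_distance_matrix(D_high, "D_high")
  D_low <- .check_distance_matrix(D_low, "D_low")
  if (!all(dim(D_high) == dim(D_low))) stop("shapes must match")
  a <- D_high[upper.tri(D_high)]
  b <- D_low[upper.tri(D_low)]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero variance in a distance triangle; correlation undefined")
  stats::cor(a, b)
}

#' Cluster-separation scores of an embedding
#'
#' Silhouette coefficient (Euclidean; singletons score 0 and are flagged),
#' Calinski-Harabasz index, and Davies-Bouldin index of the labelled
#' embedding coordinates (for spherical embeddings, typically the
#' hyperspherical angles). Two clusters with coincident centroids make the
#' Davies-Bouldin index infinite; it is reported as `Inf`.
#'
#' @param Y Numeric n x p embedding coordinates.
#' @param labels Cluster labels, length n, at least two distinct values.
#' @return List with `sc`, `chi`, `dbi`, and `singleton` (logical: any
#'   singleton cluster present).
#' @export
cluster_scores <- function(Y, labels) {
  Y <- as.matrix(Y)
  labels <- as.factor(labels)
  if (nrow(Y) != length(labels)) stop("'labels' must have one entry per row")
  labels <- droplevels(labels)
  k <- nlevels(labels)
  if (k < 2L) stop("need at least two clusters")
  n <- nrow(Y)
  sizes <- table(labels)
  singleton <- any(sizes == 1L)
  sil <- cluster::silhouette(as.integer(labels), stats::dist(Y))
  sc <- mean(sil[, "sil_width"])
  mu <- colMeans(Y)
  centroids <- rowsum(Y, labels) / as.vector(sizes)
  between <- sum(as.vector(sizes) * rowSums(sweep(centroids, 2L, mu)^2))
  within_by <- rowsum(rowSums((Y - centroids[as.integer(labels), , drop = FALSE])^2),
                      labels)
  within <- sum(within_by)
  chi <- if (within == 0) Inf else (between / (k - 1)) / (within / (n - k))
  scatter <- sqrt(as.vector(within_by) / as.vector(sizes))
  Dc <- as.matrix(stats::dist(centroids))
  ratios <- outer(scatter, scatter, `+`) / ifelse(Dc > 0, Dc, NA)
  diag(ratios) <- NA
  worst <- apply(ratios, 1L, function(r) {
    if (all(is.na(r))) Inf else max(r, na.rm = FALSE)
  })
  worst[is.na(worst)] <- Inf  # coincident centroids: zero separation
  dbi <- mean(worst)
  list(sc = sc, chi = chi, dbi = dbi, singleton = singleton)
}

#' Circular rank correlation
#'
#' Association between two circular variables, invariant to rotation and
#' reflection of either circle: both samples are rank-transformed to uniform
#' angles and the larger of the mean resultant lengths of the angle
#' differences and sums is returned. Any monotone circular map scores 1;
#' independent angles score near 0.
#'
#' @param a,b Numeric vectors of angles (radians), same length.
#' @return Scalar in \[0, 1\].
#' @export
circular_rank_cor <- function(a, b) {
  if (length(a) != length(b)) stop("'a' and 'b' must have the same length")
  n <- length(a)
  if (n < 3L) stop("need at least 3 observations")
  ra <- 2 * pi * rank(a, ties.method = "average") / n
  rb <- 2 * pi * rank(b, ties.method = "average") / n
  r_plus <- Mod(mean(exp(1i * (ra - rb))))
  r_minus <- Mod(mean(exp(1i * (ra + rb))))
  max(r_plus, r_minus)
}

#' Check that labelled arcs appear in a given cyclic order
#'
#' Computes the circular mean angle of each label group and tests whether
#' the groups occur in the requested cyclic order around the circle, in
#' either direction (a reflection of the embedding is order-preserving).
#'
#' @param angles Numeric vector of angles (radians).
#' @param labels Group labels, one per angle.
#' @param order Character vector giving the expected cyclic order of the
#'   labels.
#' @return `TRUE` if the circular means respect the cyclic order.
#' @export
cyclic_order_preserved <- function(angles, labels, order) {
  labels <- as.character(labels)
  if (!setequal(unique(labels), order)) stop("'order' must list exactly the labels present")
  means <- vapply(order, function(g) {
    Arg(mean(exp(1i * angles[labels == g])))
  }, numeric(1))
  pos <- rank(means)  # positions around the circle in [1..k]
  k <- length(order)
  step <- diff(c(pos, pos[1L]))
  step <- ((step %% k) + k) %% k
  all(step == 1) || all(step == k - 1)
}
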