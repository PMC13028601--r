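# Linear and two-step spherical baselines: PCA reconstruction and SPCA
# (PCA subspace followed by a closed-form algebraic sphere fit).

#' PCA reconstruction at a given retained dimension
#'
#' Projects the data onto the best d'-dimensional affine subspace (top d'
#' principal axes through the mean), \eqn{\hat x_i = \bar x + V V^T (x_i -
#' \bar x)}, and reports the mean squared reconstruction error, which equals
#' the sum of the discarded covariance eigenvalues (up to the n-1
#' normalization of the sample covariance).
#'
#' @param X Numeric n x d matrix.
#' @param retained_dim Plane dimension d', 1 <= d' < d.
#' @return List with `model` (`mean`, orthonormal `basis` d x d'),
#'   `reconstructed`, and `mse`.
#' @export
pca_reduce <- function(X, retained_dim) {
  X <- .as_data_matrix(X)
  d <- ncol(X)
  retained_dim <- as.integer(retained_dim)
  if (retained_dim < 1L || retained_dim >= d)
    stop("'retained_dim' must satisfy 1 <= d' < d")
  e <- .pca_eigen(X)
  V <- e$vectors[, seq_len(retained_dim), drop = FALSE]
  xbar <- colMeans(X)
  Xc <- sweep(X, 2L, xbar)
  Xhat <- sweep(Xc %*% V %*% t(V), 2L, xbar, `+`)
  list(model = list(mean = xbar, basis = V),
       reconstructed = Xhat,
       mse = mean(rowSums((X - Xhat)^2)))
}

#' Algebraic (least-squares) sphere fit
#'
#' Minimizes \eqn{\sum_i (\|y_i - c\|^2 - r^2)^2} through the linear
#' parameterization \eqn{\|y_i\|^2 = 2 y_i^T c + (r^2 - \|c\|^2)}, solved in
#' closed form; exact for points lying exactly on a sphere. A rank-deficient
#' normal system (e.g. collinear points) yields the minimum-norm solution
#' with a warning.
#'
#' @param Y Numeric m x p matrix, m >= p + 1, of points in the subspace.
#' @return List with `center` (p-vector) and `radius`.
#' @export
algebraic_sphere_fit <- function(Y) {
  Y <- as.matrix(Y)
  p <- ncol(Y)
  if (nrow(Y) < p + 1L) stop("need at least p + 1 points for the sphere fit")
  if (max(apply(Y, 2L, function(col) diff(range(col)))) == 0)
    stop("all points coincide; sphere fit is undefined")
  A <- cbind(2 * Y, 1)
  b <- rowSums(Y^2)
  qrA <- qr(A)
  if (qrA$rank < ncol(A)) {
    warning("rank-deficient sphere system; returning the minimum-norm solution")
    sv <- svd(A)
    pos <- sv$d > max(sv$d) * 1e-12
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], b)) / sv$d[pos])
    beta <- drop(beta)
  } else {
    beta <- qr.coef(qrA, b)
  }
  center <- beta[seq_len(p)]
  r2 <- beta[p + 1L] + sum(center^2)
  if (r2 <= 0) {
    warning("non-positive squared radius in the algebraic fit; flooring")
    r2 <- .Machine$double.eps
  }
  list(center = unname(center), radius = sqrt(r2))
}

#' Two-step spherical PCA baseline
#'
#' Step 1: the (d'+1)-dimensional PCA affine subspace (mean plus top d'+1
#' eigenvectors), with the data projected into subspace coordinates. Step 2:
#' a closed-form [algebraic_sphere_fit()] in those coordinates. The
#' reconstruction projects each point radially onto the fitted sphere inside
#' the subspace and maps back to the ambient space; the reported `mse` is
#' the mean squared Euclidean distance to the reconstruction.
#'
#' @param X Numeric n x d matrix, n >= d' + 2.
#' @param retained_dim Intrinsic sphere dimension d'.
#' @return List with `model` (`mean`, orthonormal `basis` d x (d'+1),
#'   in-subspace `center`, `radius`), `reconstructed`, and `mse`.
#' @export
spca_fit <- function(X, retained_dim) {
  X <- .as_data_matrix(X)
  d <- ncol(X)
  retained_dim <- as.integer(retained_dim)
  if (retained_dim < 1L || retained_dim >= d)
    stop("'retained_dim' must satisfy 1 <= d' < d")
  if (nrow(X) < retained_dim + 2L) stop("need at least d' + 2 rows")
  p <- retained_dim + 1L
  e <- .pca_eigen(X)
  B <- e$vectors[, seq_len(p), drop = FALSE]
  xbar <- colMeans(X)
  Yc <- sweep(X, 2L, xbar) %*% B                 # subspace coordinates
  sph <- algebraic_sphere_fit(Yc)
  Dc <- sweep(Yc, 2L, sph$center)
  den <- sqrt(rowSums(Dc^2))
  degenerate <- den == 0
  scale <- ifelse(degenerate, 0, sph$radius / pmax(den, .Machine$double.xmin))
  Yhat <- sweep(Dc * scale, 2L, sph$center, `+`)
  if (any(degenerate)) Yhat[degenerate, 1L] <- sph$center[1L] + sph$radius
  Xhat <- sweep(Yhat %*% t(B), 2L, xbar, `+`)
  list(model = list(mean = xbar, basis = B, center = sph$center,
                    radius = sph$radius),
       reconstructed = Xhat,
       mse = mean(rowSums((X - Xhat)^2)),
       degenerate = degenerate)
}
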