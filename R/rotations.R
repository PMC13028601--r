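# Orthogonal rotations used by the rotate step: PCA (default), the orthomax
# family (varimax, quartimax, equamax, parsimax, user gamma), and fixed-point
# ICA. Every function returns a full d x d orthogonal matrix; factor rotations
# act only on the top-m principal axes (the block that affects the sphere fit),
# leaving the complement untouched.

.rotation_methods <- c("pca", "varimax", "quartimax", "equamax", "parsimax",
                       "orthomax", "ica", "identity")

# Run `expr` under a temporary RNG state seeded with `seed`.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Eigen-decomposition of the sample covariance with the package's sign and
# tie conventions: eigenvalues descending (ties keep original order), each
# eigenvector's largest-magnitude entry positive.
.pca_eigen <- function(X) {
  X <- .as_data_matrix(X)
  if (nrow(X) < 2L) stop("PCA rotation needs at least 2 rows")
  S <- stats::cov(X)
  e <- eigen(S, symmetric = TRUE)
  V <- e$vectors
  for (k in seq_len(ncol(V))) {
    j <- which.max(abs(V[, k]))
    if (V[j, k] < 0) V[, k] <- -V[, k]
  }
  list(values = e$values, vectors = V, total = sum(diag(S)))
}

#' PCA rotation
#'
#' Returns the d x d orthogonal matrix whose columns are the unit
#' eigenvectors of the sample covariance of `X`, ordered by descending
#' eigenvalue, with each column's largest-magnitude entry made positive.
#' Constant data (zero covariance) yields the identity with a warning.
#'
#' @param X Numeric n x d matrix, n >= 2.
#' @return Orthogonal d x d matrix.
#' @export
pca_rotation <- function(X) {
  e <- .pca_eigen(X)
  if (e$total <= .Machine$double.eps * ncol(X)) {
    warning("constant data: covariance is zero, returning identity rotation")
    return(diag(ncol(as.matrix(X))))
  }
  e$vectors
}

# Orthomax criterion for a loading matrix L (d x m):
#   sum(L^4) - (gamma/d) * sum_k (sum_j L_jk^2)^2
.orthomax_criterion <- function(L, gamma) {
  sum(L^4) - (gamma / nrow(L)) * sum(colSums(L^2)^2)
}

# Maximize the orthomax criterion over m x m orthogonal rotations of L by
# classic pairwise (Jacobi-style) angle sweeps. Returns the rotation T.
.orthomax_rotate <- function(L, gamma, max_sweeps = 100L, tol = 1e-10) {
  m <- ncol(L)
  d <- nrow(L)
  Tm <- diag(m)
  if (m < 2L) return(Tm)
  for (sweep_i in seq_len(max_sweeps)) {
    total_angle <- 0
    for (a in seq_len(m - 1L)) for (b in (a + 1L):m) {
      x <- L[, a]; y <- L[, b]
      u <- x^2 - y^2
      v <- 2 * x * y
      A <- sum(u); B <- sum(v)
      C <- sum(u^2 - v^2); D <- sum(2 * u * v)
      num <- D - 2 * A * B * gamma / d
      den <- C - (A^2 - B^2) * gamma / d
      phi <- atan2(num, den) / 4
      if (abs(phi) > 1e-12) {
        cp <- cos(phi); sp <- sin(phi)
        L[, a] <- cp * x + sp * y
        L[, b] <- -sp * x + cp * y
        ta <- Tm[, a]; tb <- Tm[, b]
        Tm[, a] <- cp * ta + sp * tb
        Tm[, b] <- -sp * ta + cp * tb
        total_angle <- total_angle + abs(phi)
      }
    }
    if (total_angle < tol) return(Tm)
  }
  warning("orthomax rotation did not converge; returning best iterate")
  Tm
}

#' Orthomax-family rotation
#'
#' Rotates the top-m principal axes of `X` to maximize the orthomax
#' simplicity criterion of the corresponding loading matrix
#' (eigenvectors scaled by the square roots of their eigenvalues),
#' \eqn{\sum_{jk} \lambda_{jk}^4 - (\gamma/d) \sum_k (\sum_j \lambda_{jk}^2)^2},
#' and embeds the rotated block into a full d x d orthogonal matrix with the
#' remaining principal axes untouched. The criterion weight is
#' quartimax \eqn{\gamma = 0}, varimax \eqn{\gamma = 1}, equamax
#' \eqn{\gamma = m/2}, parsimax \eqn{\gamma = d(m-1)/(d+m-2)}, or a user
#' value for `method = "orthomax"`.
#'
#' @param X Numeric n x d matrix.
#' @param m Number of leading principal axes to rotate (typically d' + 1).
#' @param method One of `"varimax"`, `"quartimax"`, `"equamax"`,
#'   `"parsimax"`, `"orthomax"`.
#' @param gamma Criterion weight, used only for `method = "orthomax"`.
#' @return Orthogonal d x d matrix.
#' @export
orthomax_rotation <- function(X, m, method = "varimax", gamma = NULL) {
  X <- .as_data_matrix(X)
  d <- ncol(X)
  m <- as.integer(m)
  if (m > d) stop("'m' must not exceed the number of columns")
  if (m < 1L) stop("'m' must be at least 1")
  gamma <- switch(method,
    quartimax = 0,
    varimax = 1,
    equamax = m / 2,
    parsimax = d * (m - 1) / (d + m - 2),
    orthomax = {
      if (is.null(gamma) || gamma < 0) stop("method 'orthomax' needs gamma >= 0")
      gamma
    },
    stop("unknown orthomax method: ", method))
  e <- .pca_eigen(X)
  V <- e$vectors
  if (m == 1L) return(V)
  L <- V[, seq_len(m), drop = FALSE] %*% diag(sqrt(pmax(e$values[seq_len(m)], 0)), m)
  Tm <- .orthomax_rotate(L, gamma)
  R <- V
  R[, seq_len(m)] <- V[, seq_len(m), drop = FALSE] %*% Tm
  R
}

# Polar orthonormalization: nearest orthogonal matrix in Frobenius norm.
.polar_orthonormalize <- function(M) {
  s <- svd(M)
  s$u %*% t(s$v)
}

#' ICA rotation
#'
#' Whitens `X` in its principal-axis basis, runs symmetric fixed-point ICA
#' with the log-cosh contrast on the whitened data, and composes the
#' orthogonal unmixing rotation with the eigenbasis, giving an orthogonal
#' d x d rotation (polar-orthonormalized as a safeguard). Deterministic for a
#' given `seed`; on non-convergence it falls back to [pca_rotation()] with a
#' warning.
#'
#' @param X Numeric n x d matrix.
#' @param seed Integer seed for the random initial unmixing matrix.
#' @param max_iters Fixed-point iteration cap.
#' @param tol Convergence tolerance on the unmixing update.
#' @return Orthogonal d x d matrix.
#' @export
ica_rotation <- function(X, seed = 0L, max_iters = 500L, tol = 1e-6) {
  X <- .as_data_matrix(X)
  d <- ncol(X)
  e <- .pca_eigen(X)
  vals <- pmax(e$values, 0)
  if (min(vals) <= max(vals) * 1e-12) {
    warning("degenerate covariance: falling back to PCA rotation")
    return(pca_rotation(X))
  }
  Xc <- sweep(X, 2L, colMeans(X))
  Y <- Xc %*% e$vectors %*% diag(1 / sqrt(vals), d)   # whitened, n x d
  n <- nrow(Y)
  U <- .with_seed(seed, matrix(stats::rnorm(d * d), d, d))
  U <- .polar_orthonormalize(U)
  converged <- FALSE
  for (it in seq_len(max_iters)) {
    G <- tanh(Y %*% U)            # n x d, log-cosh nonlinearity derivative
    gprime <- colMeans(1 - G^2)
    U_new <- crossprod(Y, G) / n - U %*% diag(gprime, d)
    U_new <- .polar_orthonormalize(U_new)
    delta <- max(abs(abs(colSums(U_new * U)) - 1))
    U <- U_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("ICA did not converge; falling back to PCA rotation")
    return(pca_rotation(X))
  }
  .polar_orthonormalize(e$vectors %*% U)
}

#' Build the rotation for the rotate step
#'
#' Dispatcher over the supported rotation methods. `m` (the number of
#' leading principal axes the orthomax family acts on) defaults to d' + 1
#' when called from [srca_fit()].
#'
#' @param X Numeric n x d matrix.
#' @param method One of `r paste0('"', .rotation_methods, '"', collapse = ", ")`.
#' @param m Rotated block size for the orthomax family.
#' @param gamma Orthomax criterion weight (method `"orthomax"` only).
#' @param seed Seed for `"ica"`.
#' @return Orthogonal d x d matrix.
#' @export
rotation_matrix <- function(X, method = "pca", m = NULL, gamma = NULL, seed = 0L) {
  method <- match.arg(method, .rotation_methods)
  d <- ncol(as.matrix(X))
  switch(method,
    identity = diag(d),
    pca = pca_rotation(X),
    ica = ica_rotation(X, seed = seed),
    orthomax_rotation(X, m = if (is.null(m)) d else m, method = method,
                      gamma = gamma))
}
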