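# Core geometry: weighted point-to-sphere distance, geometric loss, sphere
# projection, hyperspherical coordinates, frame changes.

# Module tolerances; overridable via options(srca.tol.<name> = ...).
.srca_tol <- function(name, default) getOption(paste0("srca.tol.", name), default)

#' @keywords internal
.as_data_matrix <- function(X, arg = "X") {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop(sprintf("'%s' must be a numeric matrix", arg))
  if (!all(is.finite(X))) stop(sprintf("'%s' contains non-finite entries", arg))
  if (nrow(X) < 1L || ncol(X) < 2L)
    stop(sprintf("'%s' must have at least 1 row and 2 columns", arg))
  X
}

#' @keywords internal
.check_index_set <- function(index_set, d) {
  idx <- as.integer(index_set)
  if (length(idx) < 1L || anyNA(idx)) stop("index set must be a non-empty integer vector")
  if (any(idx < 1L) || any(idx > d)) stop("index set entries must lie in 1..d")
  if (is.unsorted(idx, strictly = TRUE)) stop("index set must be strictly increasing (no duplicates)")
  idx
}

#' @keywords internal
.check_weight <- function(weight, d) {
  if (is.null(weight)) return(NULL)
  W <- as.matrix(weight)
  if (nrow(W) != d || ncol(W) != d) stop("weight matrix must be d x d")
  if (max(abs(W - t(W))) > .srca_tol("symmetric", 1e-10))
    stop("weight matrix must be symmetric")
  ev <- eigen(W, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -.srca_tol("psd", 1e-10) * max(1, max(abs(ev))))
    stop("weight matrix must be positive semidefinite")
  if (max(abs(W - diag(d))) < 1e-15) return(NULL)  # identity fast path
  W
}

#' @keywords internal
.check_rotation <- function(R, tol = .srca_tol("orthogonality", 1e-8)) {
  R <- as.matrix(R)
  if (nrow(R) != ncol(R)) stop("rotation must be a square matrix")
  if (max(abs(crossprod(R) - diag(ncol(R)))) > tol)
    stop("rotation matrix is not orthogonal")
  R
}

# Vectorised squared point-to-sphere distances for the rows of X;
# weight = NULL means the identity. Computed in the decomposed form
# (off-subspace part) + (in-subspace distance - r)^2, which is algebraically
# identical to quad + r^2 - 2 r sqrt(radical) but immune to the catastrophic
# cancellation of r^2 - 2 r sqrt(radical) for large radii (near-planar fits).
.sphere_sqdist_rows <- function(X, center, radius, index_set, weight = NULL) {
  Xc <- sweep(X, 2L, center)
  if (is.null(weight)) {
    comp <- setdiff(seq_len(ncol(X)), index_set)
    off <- if (length(comp) > 0L) rowSums(Xc[, comp, drop = FALSE]^2) else 0
    radical <- sqrt(rowSums(Xc[, index_set, drop = FALSE]^2))
  } else {
    B <- Xc %*% weight
    # W - W^T I_I W, the residual quadratic form off the selected subspace
    # (indefinite for general W, so no clamping here)
    M <- weight - crossprod(weight[index_set, , drop = FALSE])
    off <- rowSums((Xc %*% M) * Xc)
    radical <- sqrt(rowSums(B[, index_set, drop = FALSE]^2))
  }
  off + (radical - radius)^2
}

#' Squared distance from a point to an axis-aligned sub-sphere
#'
#' Computes \eqn{(x-c)^T W (x-c) + r^2 - 2r\sqrt{(x-c)^T W^T I_I W (x-c)}},
#' the (optionally weighted) squared distance from `x` to the sphere of radius
#' `r` centred at `c` living in the coordinate subspace selected by
#' `index_set` (coordinates outside the index set are pinned at the centre).
#' With the identity weight this is exactly the squared Euclidean distance to
#' the nearest point of the embedded sphere.
#'
#' @param x Numeric d-vector.
#' @param center Numeric d-vector, sphere centre.
#' @param radius Positive scalar.
#' @param index_set Strictly increasing integers in 1..d selecting the
#'   coordinates that span the sphere's subspace.
#' @param weight Optional symmetric positive-semidefinite d x d matrix
#'   (`NULL` means identity).
#' @return Non-negative scalar.
#' @export
#' @examples
#' point_to_sphere_sqdist(c(2, 0, 0), c(0, 0, 0), 1, c(1L, 2L))  # 1
point_to_sphere_sqdist <- function(x, center, radius, index_set, weight = NULL) {
  x <- as.numeric(x); center <- as.numeric(center)
  d <- length(x)
  if (length(center) != d) stop("'x' and 'center' must have the same length")
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop("'radius' must be a positive scalar")
  idx <- .check_index_set(index_set, d)
  W <- .check_weight(weight, d)
  drop(.sphere_sqdist_rows(matrix(x, 1L), center, radius, idx, W))
}

#' Geometric loss of a sphere on a data matrix
#'
#' Sum of squared point-to-sphere distances over the rows of `X`:
#' \eqn{L(c, r, I | X, W) = \sum_i d^2(x_i, S_I(c, r))}.
#'
#' @param X Numeric n x d matrix.
#' @inheritParams point_to_sphere_sqdist
#' @return Scalar loss.
#' @export
geometric_loss <- function(X, center, radius, index_set, weight = NULL) {
  X <- .as_data_matrix(X)
  d <- ncol(X)
  if (length(center) != d) stop("'center' must have length ncol(X)")
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop("'radius' must be a positive scalar")
  idx <- .check_index_set(index_set, d)
  W <- .check_weight(weight, d)
  sum(.sphere_sqdist_rows(X, as.numeric(center), radius, idx, W))
}

#' Project points onto an axis-aligned sub-sphere
#'
#' For each row z, coordinates in the index set are projected radially onto
#' the sphere, \eqn{\hat z_j = c_j + r (z_j - c_j) / \|(z - c)_I\|}, and the
#' remaining coordinates are set to the centre, \eqn{\hat z_j = c_j}. The
#' output attains the point-to-sphere distance (identity weight). Rows whose
#' in-subspace part coincides with the centre have no nearest point; they are
#' mapped deterministically to `center + radius * e_min(index_set)` and
#' flagged in the `"degenerate"` attribute.
#'
#' @param Z Numeric n x d matrix (rotated frame).
#' @inheritParams point_to_sphere_sqdist
#' @return n x d matrix with logical attribute `"degenerate"` (length n).
#' @export
project_to_sphere <- function(Z, center, radius, index_set) {
  Z <- .as_data_matrix(Z, "Z")
  d <- ncol(Z)
  center <- as.numeric(center)
  if (length(center) != d) stop("'center' must have length ncol(Z)")
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop("'radius' must be a positive scalar")
  idx <- .check_index_set(index_set, d)
  Zc <- sweep(Z[, idx, drop = FALSE], 2L, center[idx])
  den <- sqrt(rowSums(Zc^2))
  degenerate <- den == 0
  out <- matrix(rep(center, each = nrow(Z)), nrow(Z), d)
  scale <- ifelse(degenerate, 0, radius / pmax(den, .Machine$double.xmin))
  out[, idx] <- sweep(Zc * scale, 2L, center[idx], `+`)
  if (any(degenerate)) out[degenerate, idx[1L]] <- center[idx[1L]] + radius
  dimnames(out) <- dimnames(Z)
  attr(out, "degenerate") <- degenerate
  out
}

#' Hyperspherical angles of unit vectors
#'
#' Maps each unit row of `U` (n x (d'+1)) to d' angles. For a circle (two
#' columns) the single angle is `atan2(u2, u1)` in (-pi, pi]. For a sphere
#' (three columns) the angles are geographic: longitude `atan2(u2, u1)` in
#' (-pi, pi] and latitude `asin(u3)` in [-pi/2, pi/2]. Higher dimensions use
#' the standard hyperspherical recursion (leading angles in [0, pi], final
#' angle in (-pi, pi]). At poles the undetermined angle is 0.
#'
#' @param U Numeric matrix with unit-norm rows.
#' @param tol Tolerance for the unit-norm check.
#' @return n x (ncol(U) - 1) matrix of angles in radians.
#' @seealso [from_hyperspherical()] for the inverse map.
#' @export
to_hyperspherical <- function(U, tol = 1e-8) {
  U <- as.matrix(U)
  p <- ncol(U)
  if (p < 2L) stop("'U' must have at least 2 columns")
  nrm <- sqrt(rowSums(U^2))
  if (any(abs(nrm - 1) > tol)) stop("rows of 'U' must have unit norm")
  n <- nrow(U)
  if (p == 2L) {
    A <- matrix(atan2(U[, 2L], U[, 1L]), n, 1L)
  } else if (p == 3L) {
    A <- cbind(atan2(U[, 2L], U[, 1L]), asin(pmin(1, pmax(-1, U[, 3L]))))
    A[abs(U[, 1L]) + abs(U[, 2L]) == 0, 1L] <- 0  # pole tie-break
  } else {
    A <- matrix(0, n, p - 1L)
    # tail norms: t_k = ||u_{k+1..p}||
    for (k in seq_len(p - 2L)) {
      tail_norm <- sqrt(rowSums(U[, (k + 1L):p, drop = FALSE]^2))
      A[, k] <- atan2(tail_norm, U[, k])
    }
    A[, p - 1L] <- atan2(U[, p], U[, p - 1L])
  }
  A
}

#' Unit vectors from hyperspherical angles
#'
#' Inverse of [to_hyperspherical()]: rebuilds unit vectors in
#' \eqn{R^{d'+1}} from an n x d' angle matrix under the same conventions.
#'
#' @param A Numeric n x d' matrix of angles (radians).
#' @return n x (d'+1) matrix with unit rows.
#' @export
from_hyperspherical <- function(A) {
  A <- as.matrix(A)
  q <- ncol(A)
  n <- nrow(A)
  if (q == 1L) {
    cbind(cos(A[, 1L]), sin(A[, 1L]))
  } else if (q == 2L) {
    cbind(cos(A[, 2L]) * cos(A[, 1L]), cos(A[, 2L]) * sin(A[, 1L]), sin(A[, 2L]))
  } else {
    p <- q + 1L
    U <- matrix(0, n, p)
    running <- rep(1, n)  # prod of sines so far
    for (k in seq_len(q - 1L)) {
      U[, k] <- running * cos(A[, k])
      running <- running * sin(A[, k])
    }
    U[, p - 1L] <- running * cos(A[, q])
    U[, p] <- running * sin(A[, q])
    U
  }
}

#' Map rotated-frame points back to the original frame
#'
#' Inverse of the rotate step `Z = (X - xbar) R`: returns `Z %*% t(R)`
#' with the mean added back, so rotate-then-reconstruct is the identity.
#'
#' @param Z Numeric n x d matrix in the rotated frame.
#' @param rotation Orthogonal d x d matrix.
#' @param mean Numeric d-vector subtracted before rotation.
#' @return n x d matrix in the original frame.
#' @export
reconstruct_original_frame <- function(Z, rotation, mean) {
  Z <- as.matrix(Z)
  R <- .check_rotation(rotation)
  if (ncol(Z) != ncol(R)) stop("ncol(Z) must match the rotation dimension")
  mean <- as.numeric(mean)
  if (length(mean) != ncol(Z)) stop("'mean' must have length ncol(Z)")
  sweep(Z %*% t(R), 2L, mean, `+`)
}
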