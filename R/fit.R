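# The rotate-optimize-project pipeline.

#' Spherical rotation component analysis
#'
#' Fits a d'-dimensional sphere to the data by (1) centring and rotating,
#' `Z = (X - xbar) R`, with a data-driven orthogonal rotation; (2) selecting
#' the d'+1 rotated coordinates and the sphere centre/radius minimizing the
#' geometric point-to-sphere loss (exhaustive subset search or l1
#' relaxation); (3) projecting every point onto the fitted sphere and mapping
#' back to the original frame.
#'
#' @param X Numeric n x d matrix (rows = samples) or a data frame of numeric
#'   columns.
#' @param retained_dim Intrinsic dimension d' of the fitted sphere
#'   (1 <= d' <= d-1); a circle is d' = 1.
#' @param rotation Rotation method (see [rotation_matrix()]) or a d x d
#'   orthogonal matrix supplied directly.
#' @param weight Optional symmetric PSD d x d weight matrix; `NULL` means the
#'   identity (plain Euclidean loss).
#' @param options An [fit_options()] list.
#' @param gamma Orthomax criterion weight (rotation `"orthomax"` only).
#' @param standardize Z-score the columns before fitting (recommended for
#'   mixed-unit features). The reported reconstruction is on the
#'   standardized scale.
#' @return Object of class `srca`: list with `model` ([srca_model]),
#'   `embedding` (reconstruction, unit coordinates, hyperspherical angles,
#'   per-point squared distances), `mse` (`total_loss / n`), and `search`
#'   (policy, subsets evaluated, convergence, loss trace).
#' @seealso [srca_transform()] to embed new data with a fitted model.
#' @export
#' @examples
#' ds <- sample_subsphere(100, d = 4, index_set = c(1L, 2L), center = rep(0, 4),
#'                        radius = 2, noise_sd = 0.05, seed = 1)
#' fit <- srca_fit(ds$X, retained_dim = 1)
#' fit$mse
srca_fit <- function(X, retained_dim, rotation = "pca", weight = NULL,
                     options = fit_options(), gamma = NULL,
                     standardize = FALSE) {
  X <- .as_data_matrix(X)
  n <- nrow(X); d <- ncol(X)
  retained_dim <- as.integer(retained_dim)
  if (retained_dim < 1L || retained_dim >= d)
    stop("'retained_dim' must satisfy 1 <= d' <= d - 1")
  if (standardize) {
    sds <- apply(X, 2L, stats::sd)
    if (any(sds == 0)) stop("cannot standardize constant columns")
    X <- scale(X)[, , drop = FALSE]
    attr(X, "scaled:center") <- NULL; attr(X, "scaled:scale") <- NULL
  }
  W <- .check_weight(weight, d)
  xbar <- colMeans(X)
  R <- if (is.matrix(rotation)) .check_rotation(rotation)
       else rotation_matrix(X, method = rotation, m = retained_dim + 1L,
                            gamma = gamma, seed = options$seed)
  Z <- sweep(X, 2L, xbar) %*% R
  policy <- switch(options$search,
                   auto = auto_search_policy(d, retained_dim, options$combo_budget),
                   options$search)
  sr <- if (policy == "exhaustive")
    exhaustive_search(Z, retained_dim, W, options)
  else
    l1_search(Z, retained_dim, W, options)
  model <- srca_model(rotation = R, mean = xbar, index_set = sr$index_set,
                      center = sr$center, radius = sr$radius,
                      retained_dim = retained_dim, weight = W,
                      seed = options$seed)
  embedding <- .embed_rotated(Z, model)
  structure(
    list(model = model, embedding = embedding,
         mse = embedding$total_loss / n,
         search = list(policy = policy,
                       n_subsets_evaluated = sr$n_subsets_evaluated,
                       loss = sr$loss, trace = sr$trace,
                       converged = sr$converged),
         standardized = standardize, n = n),
    class = "srca")
}

#' @export
print.srca <- function(x, ...) {
  cat("Spherical rotation component analysis fit\n")
  cat(sprintf("  n = %d, d = %d, d' = %d\n", x$n, ncol(x$model$rotation),
              x$model$retained_dim))
  cat(sprintf("  search: %s (%d subset(s) evaluated), converged: %s\n",
              x$search$policy, x$search$n_subsets_evaluated,
              x$search$converged))
  cat(sprintf("  index set {%s}, radius %.6g\n",
              paste(x$model$index_set, collapse = ", "), x$model$radius))
  cat(sprintf("  MSE (geometric loss / n): %.6g\n", x$mse))
  invisible(x)
}

#' Embed new data with a fitted spherical model
#'
#' Applies the stored centring and rotation, projects onto the stored
#' sphere, and maps back; no refitting takes place.
#'
#' @param model An `srca` fit or an [srca_model] object.
#' @param X_new Numeric matrix with the same number of columns as the
#'   training data (a single row is allowed).
#' @return An `srca_embedding` (same components as the training embedding).
#' @export
srca_transform <- function(model, X_new) {
  if (inherits(model, "srca")) model <- model$model
  stopifnot(inherits(model, "srca_model"))
  X_new <- as.matrix(X_new)
  if (!is.numeric(X_new) || !all(is.finite(X_new)))
    stop("'X_new' must be a finite numeric matrix")
  d <- ncol(model$rotation)
  if (ncol(X_new) != d)
    stop(sprintf("'X_new' has %d columns but the model expects %d",
                 ncol(X_new), d))
  Z <- sweep(X_new, 2L, model$mean) %*% model$rotation
  .embed_rotated(Z, model)
}

#' @export
predict.srca <- function(object, newdata, ...) srca_transform(object, newdata)
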