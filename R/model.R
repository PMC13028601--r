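# Fitted-model and embedding containers plus text serialization.

#' Construct a fitted sphere model
#'
#' Bundles the components of a fitted spherical reduction: the orthogonal
#' rotation `R` and column mean defining the rotated frame `Z = (X - xbar) R`,
#' the index set of the d'+1 rotated coordinates carrying the sphere, and the
#' sphere centre/radius (rotated frame) with the optional weight matrix.
#'
#' @param rotation Orthogonal d x d matrix.
#' @param mean Numeric d-vector (original frame).
#' @param index_set Strictly increasing integers in 1..d of length
#'   `retained_dim + 1`.
#' @param center Numeric d-vector (rotated frame).
#' @param radius Positive scalar.
#' @param retained_dim Intrinsic dimension d' of the fitted sphere.
#' @param weight Optional symmetric PSD d x d weight matrix (`NULL` =
#'   identity).
#' @param seed Integer seed recorded for provenance (may be `NA`).
#' @return Object of class `srca_model`.
#' @export
srca_model <- function(rotation, mean, index_set, center, radius,
                       retained_dim, weight = NULL, seed = NA_integer_) {
  R <- .check_rotation(rotation)
  d <- ncol(R)
  mean <- as.numeric(mean); center <- as.numeric(center)
  if (length(mean) != d || length(center) != d)
    stop("'mean' and 'center' must have length d")
  idx <- .check_index_set(index_set, d)
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop("'radius' must be a positive scalar")
  retained_dim <- as.integer(retained_dim)
  if (retained_dim < 1L || retained_dim + 1L > d)
    stop("'retained_dim' must satisfy 1 <= d' <= d - 1")
  if (length(idx) != retained_dim + 1L)
    stop("index set must have d' + 1 elements")
  W <- .check_weight(weight, d)
  structure(
    list(rotation = R, mean = mean, index_set = idx, center = center,
         radius = radius, retained_dim = retained_dim, weight = W,
         seed = seed,
         version = as.character(utils::packageVersion("srca"))),
    class = "srca_model")
}

#' @export
print.srca_model <- function(x, ...) {
  cat("Spherical rotation model\n")
  cat(sprintf("  ambient dimension d = %d, retained dimension d' = %d\n",
              ncol(x$rotation), x$retained_dim))
  cat(sprintf("  index set: {%s}\n", paste(x$index_set, collapse = ", ")))
  cat(sprintf("  radius: %.6g\n", x$radius))
  cat(sprintf("  centre (retained coords): %s\n",
              paste(signif(x$center[x$index_set], 6), collapse = ", ")))
  cat(sprintf("  weight: %s\n", if (is.null(x$weight)) "identity" else "general"))
  invisible(x)
}

#' Save a sphere model as JSON
#'
#' Writes all model components (rotation, mean, 1-based index set, centre,
#' radius, weight, retained dimension, software version, seed) to a JSON
#' document with full double precision; [read_srca_model()] restores it
#' losslessly.
#'
#' @param model `srca_model` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_srca_model <- function(model, path) {
  stopifnot(inherits(model, "srca_model"))
  doc <- list(
    schema = "srca-model/1",
    version = model$version,
    seed = model$seed,
    retained_dim = model$retained_dim,
    index_set = model$index_set,
    radius = model$radius,
    mean = model$mean,
    center = model$center,
    rotation = model$rotation,
    weight = if (is.null(model$weight)) "identity" else model$weight)
  # I(17) = 17 significant digits: doubles survive the round trip exactly
  jsonlite::write_json(doc, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Load a sphere model saved by [write_srca_model()]
#'
#' @param path JSON file path.
#' @return `srca_model` object.
#' @export
read_srca_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, "srca-model/1"))
    stop("not an srca model file (schema mismatch): ", path)
  weight <- if (identical(doc$weight, "identity")) NULL else as.matrix(doc$weight)
  m <- srca_model(rotation = as.matrix(doc$rotation), mean = doc$mean,
                  index_set = as.integer(doc$index_set), center = doc$center,
                  radius = doc$radius, retained_dim = doc$retained_dim,
                  weight = weight,
                  seed = if (is.null(doc$seed)) NA_integer_ else doc$seed)
  m$version <- doc$version
  m
}

# Build the embedding (reconstruction, unit coordinates, angles, per-point
# squared distances) of rotated-frame data Z under a fitted model.
.embed_rotated <- function(Z, model) {
  idx <- model$index_set
  proj <- project_to_sphere(Z, model$center, model$radius, idx)
  degenerate <- attr(proj, "degenerate")
  U <- sweep(proj[, idx, drop = FALSE], 2L, model$center[idx]) / model$radius
  sqd <- .sphere_sqdist_rows(Z, model$center, model$radius, idx, model$weight)
  sqd <- pmax(sqd, 0)
  reconstructed <- reconstruct_original_frame(proj, model$rotation, model$mean)
  structure(
    list(reconstructed = reconstructed,
         unit_coords = U,
         angles = to_hyperspherical(U),
         per_point_sqdist = sqd,
         total_loss = sum(sqd),
         degenerate = degenerate),
    class = "srca_embedding")
}

#' @export
print.srca_embedding <- function(x, ...) {
  cat(sprintf("srca embedding: %d points, %d angle column(s), total loss %.6g\n",
              nrow(x$reconstructed), ncol(x$angles), x$total_loss))
  if (any(x$degenerate))
    cat(sprintf("  %d degenerate row(s) mapped to the fallback pole\n",
                sum(x$degenerate)))
  invisible(x)
}
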