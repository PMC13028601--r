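# Seeded generators of datasets with known ground truth: planted noisy
# sub-spheres, tori, planes, and cell-cycle-like cyclic data. Every generator
# is a pure function of its parameters and seed.

.new_dataset <- function(X, truth = NULL, labels = NULL, noise_sd = 0,
                         seed = NA_integer_, generator, params = list()) {
  structure(list(X = X, truth = truth, labels = labels, noise_sd = noise_sd,
                 seed = seed, generator = generator, params = params),
            class = "srca_dataset")
}

#' @export
print.srca_dataset <- function(x, ...) {
  cat(sprintf("srca synthetic dataset '%s': n = %d, d = %d, noise sd = %g, seed = %s\n",
              x$generator, nrow(x$X), ncol(x$X), x$noise_sd, x$seed))
  invisible(x)
}

# Additive noise: isotropic Gaussian, or scaled Student-t for a heavy tail.
.noise_matrix <- function(n, d, sd, df = Inf) {
  if (sd == 0) return(matrix(0, n, d))
  if (is.finite(df)) {
    matrix(stats::rt(n * d, df = df) * sd, n, d)
  } else {
    matrix(stats::rnorm(n * d, sd = sd), n, d)
  }
}

#' Sample a planted noisy sub-sphere
#'
#' Draws points uniformly on the (|index_set|-1)-sphere of the given centre
#' and radius in the coordinates of `index_set` (normalized Gaussian draws),
#' pins the complement coordinates at the centre, adds isotropic noise, and
#' optionally applies a rigid motion (orthogonal `rotation` and `shift`).
#' The planted truth is recorded for parameter-recovery tests.
#'
#' @param n Number of points.
#' @param d Ambient dimension.
#' @param index_set Coordinates spanning the sphere's subspace (>= 2).
#' @param center d-vector, sphere centre in the truth frame.
#' @param radius Positive radius.
#' @param noise_sd Isotropic noise standard deviation (>= 0).
#' @param rotation Optional orthogonal d x d matrix applied to the points.
#' @param shift Optional d-vector added after rotation.
#' @param noise_df Degrees of freedom for Student-t noise (`Inf` =
#'   Gaussian).
#' @param seed Integer seed.
#' @return `srca_dataset` with `truth` = list(index_set, center, radius,
#'   rotation, shift).
#' @export
sample_subsphere <- function(n, d, index_set, center = rep(0, d), radius = 1,
                             noise_sd = 0, rotation = NULL, shift = NULL,
                             noise_df = Inf, seed = 0L) {
  idx <- .check_index_set(index_set, d)
  if (length(idx) < 2L) stop("the index set must have at least 2 coordinates")
  if (radius <= 0) stop("'radius' must be positive")
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  center <- as.numeric(center)
  if (length(center) != d) stop("'center' must have length d")
  if (!is.null(rotation)) rotation <- .check_rotation(rotation)
  .with_seed(seed, {
    G <- matrix(stats::rnorm(n * length(idx)), n, length(idx))
    U <- G / sqrt(rowSums(G^2))
    Z <- matrix(rep(center, each = n), n, d)
    Z[, idx] <- sweep(U * radius, 2L, center[idx], `+`)
    X <- Z + .noise_matrix(n, d, noise_sd, noise_df)
    if (!is.null(rotation)) X <- X %*% t(rotation)
    if (!is.null(shift)) X <- sweep(X, 2L, as.numeric(shift), `+`)
    .new_dataset(X,
                 truth = list(index_set = idx, center = center, radius = radius,
                              rotation = rotation, shift = shift),
                 noise_sd = noise_sd, seed = seed, generator = "subsphere",
                 params = list(n = n, d = d, radius = radius,
                               noise_df = noise_df))
  })
}

#' Sample a noisy torus
#'
#' Standard torus embedding in the first three coordinates,
#' \eqn{((R + r\cos v)\cos u, (R + r\cos v)\sin u, r\sin v)} with uniform
#' angles, zeros in the remaining coordinates, plus isotropic noise. Labels
#' are the quartile of the major angle u.
#'
#' @param n Number of points.
#' @param R_major,r_minor Major and minor radii, `R_major > r_minor > 0`.
#' @param d Ambient dimension (>= 3).
#' @param noise_sd Isotropic noise sd.
#' @param seed Integer seed.
#' @return `srca_dataset` with `truth` = list(R_major, r_minor) and angle
#'   labels.
#' @export
sample_torus <- function(n, R_major = 2, r_minor = 0.5, d = 3, noise_sd = 0,
                         seed = 0L) {
  if (d < 3L) stop("'d' must be at least 3")
  if (!(R_major > r_minor && r_minor > 0)) stop("need R_major > r_minor > 0")
  .with_seed(seed, {
    u <- stats::runif(n, -pi, pi)
    v <- stats::runif(n, -pi, pi)
    X <- matrix(0, n, d)
    X[, 1L] <- (R_major + r_minor * cos(v)) * cos(u)
    X[, 2L] <- (R_major + r_minor * cos(v)) * sin(u)
    X[, 3L] <- r_minor * sin(v)
    X <- X + .noise_matrix(n, d, noise_sd)
    labels <- cut(u, breaks = seq(-pi, pi, length.out = 5L),
                  labels = paste0("Q", 1:4), include.lowest = TRUE)
    .new_dataset(X, truth = list(R_major = R_major, r_minor = r_minor,
                                 major_angle = u, minor_angle = v),
                 labels = labels, noise_sd = noise_sd, seed = seed,
                 generator = "torus", params = list(n = n, d = d))
  })
}

#' Sample a noisy plane patch
#'
#' Uniform box in a seeded random d'-dimensional affine subspace of
#' \eqn{R^d}, plus isotropic noise. The plane basis and offset are recorded.
#'
#' @param n Number of points.
#' @param retained_dim Plane dimension d' < d.
#' @param d Ambient dimension.
#' @param extent Half-width of the uniform box.
#' @param noise_sd Isotropic noise sd.
#' @param seed Integer seed.
#' @return `srca_dataset` with `truth` = list(basis, offset).
#' @export
sample_plane <- function(n, retained_dim, d, extent = 1, noise_sd = 0,
                         seed = 0L) {
  if (retained_dim >= d) stop("'retained_dim' must be less than d")
  .with_seed(seed, {
    B <- qr.Q(qr(matrix(stats::rnorm(d * retained_dim), d, retained_dim)))
    offset <- stats::rnorm(d)
    U <- matrix(stats::runif(n * retained_dim, -extent, extent), n, retained_dim)
    X <- sweep(U %*% t(B), 2L, offset, `+`) + .noise_matrix(n, d, noise_sd)
    .new_dataset(X, truth = list(basis = B, offset = offset),
                 noise_sd = noise_sd, seed = seed, generator = "plane",
                 params = list(n = n, d = d, retained_dim = retained_dim,
                               extent = extent))
  })
}

#' Sample cell-cycle-like cyclic data
#'
#' Emulates an asynchronous proliferating cell population: phase angles are
#' drawn from contiguous arcs in the cyclic order G1 -> S -> G2 -> M on a
#' circle of fixed radius embedded in a seeded random 2-dimensional subspace
#' of \eqn{R^d}, with phase-dependent isotropic dispersion. The defaults
#' mimic a population rich in G1 with the loosest G1 cluster (cells in G1
#' have the most freedom in size and expression), the tightest S cluster,
#' and intermediate G2/M, at a signal-to-noise ratio (radius over largest
#' dispersion sd) of about 8.
#'
#' @param n Number of cells.
#' @param d Ambient dimension.
#' @param phase_fractions Length-4 fractions (G1, S, G2, M) summing to 1.
#' @param phase_dispersions Length-4 positive per-phase noise sds.
#' @param radius Circle radius.
#' @param seed Integer seed.
#' @return `srca_dataset` with phase `labels` and `truth` = list(basis,
#'   offset, radius, angle, arcs).
#' @export
sample_cell_cycle_like <- function(n, d,
                                   phase_fractions = c(G1 = 0.5, S = 0.2,
                                                       G2 = 0.2, M = 0.1),
                                   phase_dispersions = c(G1 = 0.12, S = 0.04,
                                                         G2 = 0.08, M = 0.08),
                                   radius = 1, seed = 0L) {
  if (length(phase_fractions) != 4L || length(phase_dispersions) != 4L)
    stop("phase fractions and dispersions must have length 4 (G1, S, G2, M)")
  if (abs(sum(phase_fractions) - 1) > 1e-8) stop("phase fractions must sum to 1")
  if (any(phase_dispersions <= 0)) stop("dispersions must be positive")
  phases <- c("G1", "S", "G2", "M")
  breaks <- c(0, cumsum(phase_fractions)) * 2 * pi
  .with_seed(seed, {
    counts <- as.vector(stats::rmultinom(1L, n, phase_fractions))
    labels <- factor(rep(phases, counts), levels = phases)
    angle <- numeric(n)
    pos <- 1L
    for (p in 1:4) {
      if (counts[p] == 0L) next
      span <- pos:(pos + counts[p] - 1L)
      angle[span] <- stats::runif(counts[p], breaks[p], breaks[p + 1L])
      pos <- pos + counts[p]
    }
    perm <- sample.int(n)
    angle <- angle[perm]; labels <- labels[perm]
    B <- qr.Q(qr(matrix(stats::rnorm(d * 2L), d, 2L)))
    offset <- stats::rnorm(d, sd = 0.5)
    signal <- cbind(cos(angle), sin(angle)) * radius
    X <- sweep(signal %*% t(B), 2L, offset, `+`)
    sd_row <- phase_dispersions[as.integer(labels)]
    X <- X + matrix(stats::rnorm(n * d), n, d) * sd_row
    .new_dataset(X, truth = list(basis = B, offset = offset, radius = radius,
                                 angle = angle, arcs = breaks),
                 labels = labels,
                 noise_sd = max(phase_dispersions), seed = seed,
                 generator = "cell_cycle",
                 params = list(n = n, d = d,
                               phase_fractions = phase_fractions,
                               phase_dispersions = phase_dispersions,
                               radius = radius))
  })
}

#' Benchmark battery of synthetic datasets
#'
#' Twenty seeded datasets spanning noisy sub-spheres (rotated and shifted),
#' tori, planes, clustered pairs of spheres, heavy-tailed noise, and
#' cell-cycle-like circles, each with the retained dimension to use. Sized
#' for quick MSE comparisons of the spherical fit against the PCA and
#' two-step spherical-PCA baselines.
#'
#' @param seed Integer master seed; each dataset derives its own seed.
#' @return List of 20 elements, each `list(data = srca_dataset,
#'   retained_dim)`.
#' @export
srca_benchmark_battery <- function(seed = 0L) {
  seeds <- seed * 1000L + seq_len(40L)
  out <- list()
  add <- function(data, retained_dim) {
    out[[length(out) + 1L]] <<- list(data = data, retained_dim = retained_dim)
  }
  rot <- function(d, s) .with_seed(s, qr.Q(qr(matrix(stats::rnorm(d * d), d, d))))
  # 6 noisy sub-spheres, varying dimension/noise, rigid motion applied
  specs <- list(list(d = 4, k = 2, ns = 0.05), list(d = 5, k = 3, ns = 0.1),
                list(d = 6, k = 3, ns = 0.2), list(d = 8, k = 2, ns = 0.1),
                list(d = 10, k = 3, ns = 0.15), list(d = 7, k = 2, ns = 0.3))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    add(sample_subsphere(300, sp$d, seq_len(sp$k), center = rep(0.5, sp$d),
                         radius = 2, noise_sd = sp$ns,
                         rotation = rot(sp$d, seeds[20L + i]),
                         shift = rep(1, sp$d), seed = seeds[i]),
        sp$k - 1L)
  }
  # 4 tori
  for (i in 1:4) {
    add(sample_torus(250, R_major = 2, r_minor = 0.6, d = 2 + i,
                     noise_sd = 0.05 * i, seed = seeds[6L + i]), 2L)
  }
  # 4 planes
  pl <- list(list(k = 1, d = 5), list(k = 2, d = 6), list(k = 2, d = 8),
             list(k = 1, d = 10))
  for (i in 1:4) {
    add(sample_plane(250, pl[[i]]$k, pl[[i]]$d, noise_sd = 0.05,
                     seed = seeds[10L + i]), pl[[i]]$k)
  }
  # 2 clustered: union of two shifted spheres
  for (i in 1:2) {
    a <- sample_subsphere(150, 6, 1:3, center = rep(0, 6), radius = 1,
                          noise_sd = 0.05, seed = seeds[14L + i])
    b <- sample_subsphere(150, 6, 1:3, center = c(4, 0, 0, 0, 0, 0),
                          radius = 1, noise_sd = 0.05, seed = seeds[16L + i])
    X <- rbind(a$X, b$X)
    add(.new_dataset(X, labels = rep(c("A", "B"), each = 150L),
                     noise_sd = 0.05, seed = seeds[14L + i],
                     generator = "clustered_spheres"), 2L)
  }
  # 2 heavy-tailed sub-spheres (Student-t noise, df = 3)
  for (i in 1:2) {
    add(sample_subsphere(300, 6, 1:3, center = rep(0, 6), radius = 2,
                         noise_sd = 0.1, noise_df = 3,
                         seed = seeds[18L + i]), 2L)
  }
  # 2 cell-cycle-like circles
  for (i in 1:2) {
    add(sample_cell_cycle_like(400, d = 4 * i + 2, seed = seeds[26L + i]), 1L)
  }
  out
}
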