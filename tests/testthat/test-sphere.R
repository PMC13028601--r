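# Core geometry: point-to-sphere distance, loss, projection, angles.

test_that("point-to-sphere squared distance matches hand-worked cases", {
  expect_equal(point_to_sphere_sqdist(c(2, 0, 0), rep(0, 3), 1, 1:2), 1.0)
  expect_equal(point_to_sphere_sqdist(c(0, 0, 1), rep(0, 3), 1, 1:2), 2.0)
  # weighted: (x-c)'W(x-c) = 16, radical^2 = 64 -> 16 + 1 - 2*8 = 1
  expect_equal(
    point_to_sphere_sqdist(c(2, 0, 0), rep(0, 3), 1, 1:2, diag(c(4, 1, 1))),
    1.0)
  expect_error(point_to_sphere_sqdist(c(1, 2), rep(0, 3), 1, 1:2), "length")
  expect_error(point_to_sphere_sqdist(c(1, 2, 3), rep(0, 3), -1, 1:2), "positive")
  expect_error(point_to_sphere_sqdist(c(1, 2, 3), rep(0, 3), 1, c(1L, 5L)), "1..d")
})

test_that("distance agrees with a dense minimization oracle on d <= 3", {
  set.seed(42)
  for (case in 1:8) {
    idx <- if (case %% 2 == 0) 1:2 else 1:3
    cen <- rnorm(3)
    r <- runif(1, 0.5, 2)
    x <- rnorm(3, sd = 2)
    got <- point_to_sphere_sqdist(x, cen, r, idx)
    want <- oracle_sphere_sqdist(x, cen, r, idx)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("geometric loss is additive and permutation invariant", {
  X <- matrix(c(1, 0, 0, -1, 0, 0, 0, 1, 0), 3, 3, byrow = TRUE)
  expect_equal(geometric_loss(X, rep(0, 3), 1, 1:3), 0)
  X2 <- rbind(c(2, 0, 0), c(0, 0, 1))
  expect_equal(geometric_loss(X2, rep(0, 3), 1, 1:2), 3.0)
  set.seed(7)
  X <- matrix(rnorm(100), 20, 5)
  cen <- rnorm(5); r <- 1.3; idx <- c(2L, 4L)
  per_point <- vapply(seq_len(20), function(i)
    point_to_sphere_sqdist(X[i, ], cen, r, idx), numeric(1))
  expect_equal(geometric_loss(X, cen, r, idx), sum(per_point),
               tolerance = 1e-12)
  perm <- sample(20)
  expect_equal(geometric_loss(X[perm, ], cen, r, idx),
               geometric_loss(X, cen, r, idx))
})

test_that("projection lands on the sphere, attains the distance, idempotent", {
  p <- project_to_sphere(matrix(c(2, 0, 5), 1), rep(0, 3), 1, 1:2)
  expect_equal(as.numeric(p), c(1, 0, 0))
  p2 <- project_to_sphere(matrix(c(3, 4, 0), 1), rep(0, 3), 5, 1:2)
  expect_equal(as.numeric(p2), c(3, 4, 0))
  set.seed(11)
  Z <- matrix(rnorm(60, sd = 2), 20, 3)
  cen <- c(0.3, -1, 2); r <- 1.7; idx <- c(1L, 3L)
  P <- project_to_sphere(Z, cen, r, idx)
  expect_equal(sqrt(rowSums(sweep(P[, idx], 2, cen[idx])^2)), rep(r, 20),
               tolerance = 1e-8)
  attained <- rowSums((Z - P)^2)
  direct <- vapply(seq_len(20), function(i)
    point_to_sphere_sqdist(Z[i, ], cen, r, idx), numeric(1))
  expect_equal(attained, direct, tolerance = 1e-8)
  P2 <- project_to_sphere(P, cen, r, idx)
  expect_equal(unclass(P2), unclass(P), ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("degenerate rows are mapped deterministically and flagged", {
  Z <- rbind(c(0, 0, 7), c(1, 0, 0))
  P <- project_to_sphere(Z, rep(0, 3), 2, 1:2)
  expect_identical(attr(P, "degenerate"), c(TRUE, FALSE))
  expect_equal(P[1, ], c(2, 0, 0))  # centre + r * e_min(I)
})

test_that("hyperspherical angles use the stated conventions and round-trip", {
  A <- to_hyperspherical(rbind(c(1, 0, 0), c(0, 0, 1)))
  expect_equal(A[1, ], c(0, 0))
  expect_equal(A[2, ], c(0, pi / 2))  # pole: longitude tie-break 0
  set.seed(3)
  for (p in 2:5) {
    U <- matrix(rnorm(40 * p), 40, p)
    U <- U / sqrt(rowSums(U^2))
    A <- to_hyperspherical(U)
    expect_equal(ncol(A), p - 1L)
    expect_equal(from_hyperspherical(A), U, tolerance = 1e-10)
  }
  expect_error(to_hyperspherical(matrix(c(1, 1), 1)), "unit")
})

test_that("frame reconstruction inverts the rotate step", {
  set.seed(5)
  X <- matrix(rnorm(50), 10, 5)
  R <- random_orthogonal(5, 9)
  xbar <- colMeans(X)
  Z <- sweep(X, 2, xbar) %*% R
  expect_equal(reconstruct_original_frame(Z, R, xbar), X, tolerance = 1e-10)
  expect_equal(reconstruct_original_frame(X, diag(5), rep(0, 5)), X)
  expect_error(reconstruct_original_frame(Z, matrix(1, 5, 5), xbar),
               "orthogonal")
})

test_that("model serialization round-trips losslessly", {
  R <- random_orthogonal(4, 2)
  m <- srca_model(rotation = R, mean = rnorm(4), index_set = c(1L, 3L),
                  center = rnorm(4), radius = exp(1), retained_dim = 1L,
                  seed = 7L)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_srca_model(m, path)
  m2 <- read_srca_model(path)
  expect_identical(m2$index_set, m$index_set)
  expect_equal(m2$rotation, m$rotation, tolerance = 1e-15)
  expect_equal(m2$center, m$center, tolerance = 1e-15)
  expect_identical(m2$radius, m$radius)
  expect_identical(m2$seed, 7L)
})
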