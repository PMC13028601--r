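# Sphere estimation: radius/centre updates, fixed-subset fit, subset search,
# and the full rotate-optimize-project pipeline.

test_that("radius update is the mean of in-subspace distances and exact on spheres", {
  X <- rbind(c(2, 0, 5), c(0, 4, -1))
  expect_equal(update_radius(X, rep(0, 3), 1:2), 3)  # distances 2 and 4
  ds <- sample_subsphere(50, 4, 1:3, center = c(1, 2, 3, 4), radius = 2.5,
                         noise_sd = 0, seed = 1)
  expect_equal(update_radius(ds$X, ds$truth$center, 1:3), 2.5,
               tolerance = 1e-12)
  expect_error(update_radius(matrix(1, 5, 3), c(1, 1, 1), 1:2), "collapsed")
})

test_that("radius update beats a dense 1-d grid in loss", {
  set.seed(2)
  for (case in 1:5) {
    X <- matrix(rnorm(40 * 4, sd = 2), 40, 4)
    cen <- rnorm(4); idx <- c(1L, 3L)
    r_hat <- update_radius(X, cen, idx)
    loss_hat <- geometric_loss(X, cen, r_hat, idx)
    dmax <- max(sqrt(rowSums(sweep(X[, idx], 2, cen[idx])^2)))
    grid <- seq(1e-9, 2 * dmax, length.out = 10001L)
    grid_losses <- vapply(grid, function(r) geometric_loss(X, cen, r, idx),
                          numeric(1))
    expect_lte(loss_hat, min(grid_losses) + 1e-12)
  }
})

test_that("centre update honours the closed form off the subset and symmetry on it", {
  ds <- sample_subsphere(200, 4, 1:2, center = rep(0, 4), radius = 1,
                         noise_sd = 0, seed = 3)
  X <- ds$X
  c_out <- update_center(X, 1, 1:2, center_init = c(0.1, -0.1, 0.5, 0.5))
  expect_equal(c_out[3:4], colMeans(X[, 3:4]))   # exact closed form
  expect_lt(sqrt(sum(c_out[1:2]^2)), 1e-6)        # symmetry forces the centre
})

test_that("centre update beats a 2-d grid oracle", {
  set.seed(4)
  X <- matrix(rnorm(20), 10, 2)
  r <- 1.5
  c_hat <- update_center(X, r, 1:2, center_init = colMeans(X))
  loss_hat <- geometric_loss(X, c_hat, r, 1:2)
  mu <- colMeans(X)
  grid <- seq(-1, 1, length.out = 101L)
  for (dx in grid) {
    losses <- vapply(grid, function(dy)
      geometric_loss(X, mu + c(dx, dy), r, 1:2), numeric(1))
    expect_lte(loss_hat, min(losses) + 1e-8)
  }
})

test_that("fixed-subset fit recovers planted spheres exactly and descends monotonically", {
  ds <- sample_subsphere(100, 5, c(2L, 3L, 5L), center = c(1, -1, 2, 0, 3),
                         radius = 1.8, noise_sd = 0, seed = 5)
  f <- fit_fixed_subset(ds$X, c(2L, 3L, 5L))
  expect_lt(f$loss, 1e-12)
  expect_lt(sqrt(sum((f$center - ds$truth$center)^2)), 1e-6)
  expect_lt(abs(f$radius - 1.8), 1e-6)
  for (s in 1:10) {
    set.seed(s)
    X <- matrix(rnorm(30 * 4, sd = 2), 30, 4)
    f <- fit_fixed_subset(X, c(1L, 2L, 4L))
    expect_true(all(diff(f$trace) <= 1e-12))
  }
})

test_that("fixed-subset fit matches a 3-d brute-force grid oracle", {
  set.seed(6)
  X <- matrix(rnorm(15 * 3), 15, 3)
  f <- fit_fixed_subset(X, 1:2)
  # grid + refinement over (c1, c2, r)
  mu <- colMeans(X)
  obj <- function(p) geometric_loss(X, c(p[1], p[2], mu[3]), max(p[3], 1e-9), 1:2)
  g <- seq(-1.5, 1.5, length.out = 21L)
  rr <- seq(0.1, 4, length.out = 21L)
  best <- Inf; best_p <- NULL
  for (a in g) for (b in g) for (r in rr) {
    v <- obj(c(mu[1] + a, mu[2] + b, r))
    if (v < best) { best <- v; best_p <- c(mu[1] + a, mu[2] + b, r) }
  }
  ref <- stats::optim(best_p, obj, control = list(reltol = 1e-14, maxit = 5000))
  expect_equal(f$loss, ref$value, tolerance = 1e-4)
})

test_that("fixed-subset fit supports a general weight matrix", {
  ds <- sample_subsphere(80, 3, 1:2, center = c(0, 0, 1), radius = 1,
                         noise_sd = 0.05, seed = 7)
  W <- diag(c(1, 0.8, 0.5))  # eigenvalues <= 1 keep the weighted loss bounded
  f <- fit_fixed_subset(ds$X, 1:2, weight = W)
  expect_true(all(diff(f$trace) <= 1e-10))
  expect_lt(sqrt(sum((f$center[1:2] - ds$truth$center[1:2])^2)), 0.1)
})

test_that("exhaustive search finds the planted subset and obeys the tie rule", {
  ds <- sample_subsphere(100, 4, 1:2, radius = 1.5, noise_sd = 0.01, seed = 8)
  sr <- exhaustive_search(ds$X, 1)
  expect_identical(sr$index_set, 1:2)
  expect_identical(sr$n_subsets_evaluated, 6L)
  # duplicated coordinate: subsets {1,2} and {1,3} tie; lexicographic winner
  set.seed(9)
  ang <- runif(60, -pi, pi)
  X <- cbind(cos(ang), sin(ang), sin(ang), rnorm(60, sd = 1e-3))
  sr2 <- exhaustive_search(X, 1)
  expect_identical(sr2$index_set, 1:2)
  # d' + 1 = d: single subset, identical to the fixed-subset fit
  set.seed(10)
  Y <- matrix(rnorm(40 * 3), 40, 3)
  sr3 <- exhaustive_search(Y, 2)
  f3 <- fit_fixed_subset(Y, 1:3)
  expect_identical(sr3$n_subsets_evaluated, 1L)
  expect_equal(sr3$loss, f3$loss)
  # budget guard
  expect_error(
    exhaustive_search(matrix(rnorm(600), 30, 20), 2,
                      options = fit_options(combo_budget = 100L)),
    "l1")
})

test_that("the l1 relaxation matches exhaustive search on planted spheres", {
  set.seed(11)
  idx0 <- c(2L, 5L, 9L)
  ds <- sample_subsphere(150, 10, idx0, center = rnorm(10), radius = 1.5,
                         noise_sd = 0, seed = 11)
  ex <- exhaustive_search(ds$X, 2)
  l1 <- l1_search(ds$X, 2, options = fit_options(seed = 1))
  expect_identical(l1$index_set, ex$index_set)
  expect_lt(abs(l1$loss - ex$loss), 1e-6)
  expect_gte(l1$loss, ex$loss - 1e-9)  # exhaustive is optimal over subsets
  l1b <- l1_search(ds$X, 2, options = fit_options(seed = 1))
  expect_identical(l1$index_set, l1b$index_set)
  expect_identical(l1$loss, l1b$loss)   # same seed, same answer
})

test_that("the automatic policy switches on the subset budget", {
  expect_identical(auto_search_policy(10, 2, 500L), "exhaustive")  # C(10,3)=120
  expect_identical(auto_search_policy(40, 2, 500L), "l1")          # C(40,3)=9880
  expect_identical(auto_search_policy(5, 4, 500L), "exhaustive")   # one subset
})

test_that("capped-simplex projection satisfies its constraints and fixed points", {
  set.seed(12)
  for (i in 1:20) {
    w <- rnorm(8, sd = 2)
    s <- sample(1:6, 1)
    v <- srca:::.project_capped_simplex(w, s)
    expect_true(all(v >= -1e-12 & v <= 1 + 1e-12))
    expect_lte(sum(v), s + 1e-8)
  }
  v0 <- c(0.2, 0.3, 0.1)
  expect_equal(srca:::.project_capped_simplex(v0, 2), v0)  # already feasible
})

test_that("the full pipeline recovers rotated planted spheres and is equivariant", {
  Q <- random_orthogonal(5, 14)
  ds <- sample_subsphere(150, 5, 1:3, radius = 2, noise_sd = 0,
                         rotation = Q, shift = rep(1, 5), seed = 14)
  fit <- srca_fit(ds$X, 2)
  expect_lt(fit$mse, 1e-10)
  expect_lt(abs(fit$model$radius - 2), 1e-6)
  # rigid motion leaves the MSE unchanged (PCA rotation re-aligns it)
  ds2 <- sample_subsphere(150, 5, 1:3, radius = 2, noise_sd = 0.1, seed = 15)
  fit_a <- srca_fit(ds2$X, 2)
  Q2 <- random_orthogonal(5, 16)
  fit_b <- srca_fit(sweep(ds2$X %*% t(Q2), 2, c(1, -2, 0, 3, 5), `+`), 2)
  expect_lt(abs(fit_a$mse - fit_b$mse), 1e-8)
})

test_that("feature permutation permutes the index set under the identity rotation", {
  ds <- sample_subsphere(120, 5, c(1L, 2L, 3L), radius = 1.5, noise_sd = 0.05,
                         seed = 17)
  opts <- fit_options()
  f1 <- srca_fit(ds$X, 2, rotation = "identity", options = opts)
  perm <- c(4L, 1L, 5L, 3L, 2L)  # column j of new matrix = old column perm[j]
  f2 <- srca_fit(ds$X[, perm], 2, rotation = "identity", options = opts)
  mapped <- sort(match(f1$model$index_set, perm))
  expect_identical(f2$model$index_set, as.integer(mapped))
  expect_equal(f2$search$loss, f1$search$loss, tolerance = 1e-8)
})

test_that("transform reproduces the training embedding and handles new points", {
  ds <- sample_subsphere(80, 4, 1:3, radius = 1.2, noise_sd = 0.1, seed = 18)
  fit <- srca_fit(ds$X, 2)
  tr <- srca_transform(fit, ds$X)
  expect_equal(tr$reconstructed, fit$embedding$reconstructed, tolerance = 1e-12)
  expect_equal(tr$total_loss, fit$embedding$total_loss, tolerance = 1e-12)
  one <- srca_transform(fit, ds$X[1, , drop = FALSE])
  expect_equal(nrow(one$reconstructed), 1L)
  # a point on the fitted sphere (rotated frame) has zero distance
  m <- fit$model
  z <- m$center
  z[m$index_set] <- z[m$index_set] + c(m$radius, 0, 0)
  x_on <- reconstruct_original_frame(matrix(z, 1), m$rotation, m$mean)
  expect_lt(srca_transform(fit, x_on)$total_loss, 1e-16)
  expect_error(srca_transform(fit, matrix(0, 2, 3)), "columns")
})

test_that("search result traces are non-increasing", {
  set.seed(19)
  for (case in 1:5) {
    X <- matrix(rnorm(50 * 4, sd = 1.5), 50, 4)
    sr <- exhaustive_search(X, 1)
    expect_true(all(diff(sr$trace) <= 1e-12))
  }
})
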