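# Embedding-quality metrics.

test_that("reconstruction MSE matches hand values and the fitted loss", {
  X <- matrix(rnorm(20), 5, 4)
  expect_equal(reconstruction_mse(X, X), 0)
  expect_equal(reconstruction_mse(matrix(c(0, 0), 1), matrix(c(3, 4), 1)), 25)
  expect_error(reconstruction_mse(X, X[1:3, ]), "shape")
  ds <- sample_subsphere(100, 4, 1:3, radius = 1.5, noise_sd = 0.1, seed = 1)
  fit <- srca_fit(ds$X, 2)
  expect_equal(reconstruction_mse(ds$X, fit$embedding$reconstructed), fit$mse,
               tolerance = 1e-8)
})

test_that("coranking matches the brute-force double loop exactly", {
  set.seed(2)
  for (case in 1:6) {
    n <- sample(5:30, 1)
    Xh <- matrix(rnorm(n * 3), n, 3)
    Xl <- matrix(rnorm(n * 2), n, 2)
    Dh <- as.matrix(dist(Xh)); Dl <- as.matrix(dist(Xl))
    Q <- coranking(Dh, Dl)
    expect_identical(unclass(Q)[seq_len(n - 1), seq_len(n - 1)],
                     matrix(as.integer(coranking_bruteforce(Dh, Dl)), n - 1),
                     ignore_attr = TRUE)
    expect_true(all(rowSums(Q) == n))
    expect_true(all(colSums(Q) == n))
    expect_identical(sum(Q), as.integer(n * (n - 1)))
  }
})

test_that("identical and reversed embeddings give diagonal and anti-diagonal corankings", {
  set.seed(3)
  X <- matrix(rnorm(12 * 2), 12, 2)
  D <- as.matrix(dist(X))
  Q <- coranking(D, D)
  expect_equal(unclass(Q), diag(12, 11), ignore_attr = TRUE)
  # a strictly decreasing transform reverses every ranking
  Drev <- max(D) * 1.5 - D
  diag(Drev) <- 0
  Qr <- coranking(D, Drev)
  expect_identical(unclass(Qr)[, 11:1], unclass(Q), ignore_attr = TRUE)
})

test_that("perfect embeddings score R_NX = 1 and AUC = WAUC = 1", {
  set.seed(4)
  X <- matrix(rnorm(20 * 3), 20, 3)
  D <- as.matrix(dist(X))
  r <- rnx_scores(coranking(D, D))
  expect_true(all(abs(r$rnx - 1) < 1e-12))
  expect_equal(r$auc, 1)
  expect_equal(r$wauc, 1)
  expect_true(all(r$qnx >= 0 & r$qnx <= 1))
})

test_that("independent rankings give R_NX near zero", {
  set.seed(5)
  aucs <- replicate(40, {
    Xh <- matrix(rnorm(50 * 3), 50, 3)
    Xl <- matrix(rnorm(50 * 3), 50, 3)
    rnx_scores(coranking(as.matrix(dist(Xh)), as.matrix(dist(Xl))))$auc
  })
  se <- sd(aucs) / sqrt(length(aucs))
  expect_lt(abs(mean(aucs)), 3 * se + 0.02)
})

test_that("AUC is invariant to monotone transforms of either distance matrix", {
  set.seed(6)
  Xh <- matrix(rnorm(25 * 3), 25, 3)
  Xl <- matrix(rnorm(25 * 2), 25, 2)
  Dh <- as.matrix(dist(Xh)); Dl <- as.matrix(dist(Xl))
  r1 <- rnx_scores(coranking(Dh, Dl))
  r2 <- rnx_scores(coranking(sqrt(Dh), Dl^2))
  expect_identical(r1$auc, r2$auc)
  expect_identical(r1$wauc, r2$wauc)
})

test_that("cophenetic correlation is affine invariant and matches a hand case", {
  set.seed(7)
  X <- matrix(rnorm(10 * 3), 10, 3)
  D <- as.matrix(dist(X))
  expect_equal(cophenetic_correlation(D, D), 1)
  expect_equal(cophenetic_correlation(D, 2.5 * D + 1 - diag(diag(2.5 * D + 1))),
               1, tolerance = 1e-12)
  D4 <- matrix(0, 4, 4)
  D4[upper.tri(D4)] <- c(1, 2, 3, 4, 5, 6)
  D4 <- D4 + t(D4)
  E4 <- matrix(0, 4, 4)
  E4[upper.tri(E4)] <- c(2, 1, 3, 5, 4, 6)
  E4 <- E4 + t(E4)
  expect_equal(cophenetic_correlation(D4, E4),
               cor(c(1, 2, 3, 4, 5, 6), c(2, 1, 3, 5, 4, 6)))
})

test_that("cluster scores match hand-worked silhouettes and flag degeneracies", {
  Y <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  lab <- c("A", "A", "B", "B")
  cs <- cluster_scores(Y, lab)
  b <- (10 + sqrt(101)) / 2
  expect_equal(cs$sc, 1 - 1 / b, tolerance = 1e-4)  # ~0.9003
  expect_false(cs$singleton)
  # translation invariance of the variance-ratio index
  cs2 <- cluster_scores(Y + 100, lab)
  expect_equal(cs2$chi, cs$chi, tolerance = 1e-9)
  # coincident clusters: zero separation blows up the Davies-Bouldin index
  Yc <- rbind(c(0, 0), c(0, 1), c(0, 0), c(0, 1))
  expect_identical(cluster_scores(Yc, lab)$dbi, Inf)
  expect_error(cluster_scores(Y, rep("A", 4)), "two clusters")
})

test_that("circular rank correlation detects monotone circular maps", {
  set.seed(8)
  a <- runif(200, -pi, pi)
  expect_equal(circular_rank_cor(a, a + 1), 1, tolerance = 1e-10)
  expect_equal(circular_rank_cor(a, -a + 0.5), 1, tolerance = 1e-10)  # reflection
  b <- runif(200, -pi, pi)
  expect_lt(circular_rank_cor(a, b), 0.3)
})

test_that("cyclic order detection respects rotation and reflection", {
  set.seed(9)
  n <- 400
  lab <- rep(c("G1", "S", "G2", "M"), each = n / 4)
  ang <- c(runif(100, 0, 1), runif(100, 1, 2), runif(100, 2, 3),
           runif(100, 3, 4)) + 2  # rotated arcs, wrap around pi
  ang <- Arg(exp(1i * ang))
  expect_true(cyclic_order_preserved(ang, lab, c("G1", "S", "G2", "M")))
  expect_true(cyclic_order_preserved(-ang, lab, c("G1", "S", "G2", "M")))
  expect_false(cyclic_order_preserved(ang, lab, c("G1", "G2", "S", "M")))
})
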