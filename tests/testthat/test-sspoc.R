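test_that("standardization centers, scales, and zeroes degenerate columns", {
  set.seed(2)
  x <- cbind(matrix(rnorm(200, 5, 2), 50, 4), rep(3, 50))
  st <- standardize(x)
  expect_equal(colMeans(st$z[, 1:4]), numeric(4), tolerance = 1e-12)
  expect_equal(apply(st$z[, 1:4], 2, sd), rep(1, 4), tolerance = 1e-12)
  expect_true(all(st$z[, 5] == 0))
  expect_true(st$degenerate[5])
  expect_equal(apply_standardize(x, st), st$z)
})

test_that("the PCA basis is orthonormal with non-increasing variances", {
  set.seed(3)
  x <- matrix(rnorm(600), 30, 20) %*% diag(seq(3, 0.5, length.out = 20))
  st <- standardize(x)
  pb <- pca_basis(st$z, 5)
  expect_equal(crossprod(pb$Psi), diag(5), tolerance = 1e-10)
  expect_true(all(diff(pb$sdev) <= 1e-12))
  # deterministic sign: largest loading positive
  for (j in 1:5) expect_gt(pb$Psi[which.max(abs(pb$Psi[, j])), j], 0)
})

test_that("rank-deficient data yield a reduced basis with a warning", {
  line <- outer(seq_len(20), c(1, -2, 0.5))   # exact rank one
  expect_warning(pb <- pca_basis(line, 3), "components")
  expect_equal(pb$k, 1L)
  expect_equal(abs(sum(pb$Psi[, 1] * c(1, -2, 0.5) / sqrt(5.25))), 1,
               tolerance = 1e-10)
})

test_that("the Fisher direction recovers the separating axis", {
  set.seed(4)
  x <- rbind(matrix(rnorm(300, 0, 0.2), 100, 3),
             matrix(rnorm(300, 0, 0.2), 100, 3))
  x[101:200, 1] <- x[101:200, 1] + 5
  labels <- rep(c("a", "b"), each = 100)
  w <- lda_direction(x, labels)
  expect_equal(abs(w[1]), 1, tolerance = 1e-2)
  expect_equal(sqrt(sum(w^2)), 1, tolerance = 1e-12)
  # orientation: positive class projects positive
  expect_gt(mean(x[101:200, ] %*% w), mean(x[1:100, ] %*% w))
  # swapping class labels reverses the oriented direction
  w2 <- lda_direction(x, rep(c("b", "a"), each = 100))
  expect_equal(w2, -w, tolerance = 1e-10)
  expect_warning(lda_direction(rbind(x[1:100, ], x[1:100, ]), labels),
                 "identical class means")
})

test_that("the Fisher direction agrees with the reference LDA implementation", {
  skip_if_not_installed("MASS")
  set.seed(5)
  x <- rbind(matrix(rnorm(240, 0, 1), 80, 3),
             sweep(matrix(rnorm(240, 0, 1), 80, 3), 2, c(1, -0.5, 2), "+"))
  labels <- rep(c("a", "b"), each = 80)
  w <- lda_direction(x, labels)
  ref <- MASS::lda(x, grouping = labels)$scaling[, 1]
  ref <- ref / sqrt(sum(ref^2))
  expect_equal(abs(sum(w * ref)), 1, tolerance = 1e-4)
})

test_that("the constrained elastic net satisfies its feasibility contract", {
  set.seed(6)
  n <- 40
  Psi <- diag(n)[, 1:3]
  w <- c(0.5, -1.2, 0.3)
  s <- elastic_net_sensors(Psi, w, lam = 0.9)
  expect_equal(s[1:3], w, tolerance = 1e-8)
  expect_equal(s[4:n], numeric(n - 3), tolerance = 1e-8)
  # lam = 0 closed form: least-norm solution Psi w for orthonormal Psi
  Q <- qr.Q(qr(matrix(rnorm(n * 3), n, 3)))
  w2 <- c(1, 0.2, -0.7)
  s0 <- elastic_net_sensors(Q, w2, lam = 0)
  expect_equal(s0, as.numeric(Q %*% w2), tolerance = 1e-6)
  s9 <- elastic_net_sensors(Q, w2, lam = 0.9)
  expect_lt(max(abs(crossprod(Q, s9) - w2)), 1e-6)
  # sparsity: the l1-weighted solution has no more active entries
  nnz <- function(v) sum(abs(v) > 1e-6 * max(abs(v)))
  expect_lte(nnz(s9), nnz(s0))
})

test_that("top-k selection is deterministic with stable tie-breaks", {
  s <- c(0.9, -0.8, 0.01, numeric(7))
  ss <- select_top_k(s, 2)
  expect_identical(ss$selected, c(1L, 2L))
  expect_warning(z <- select_top_k(numeric(5), 3), "degenerate")
  expect_identical(z$selected, 1:3)
  all10 <- select_top_k(s, 10)
  expect_setequal(all10$selected, 1:10)
  # ties resolve toward the lower node index
  tied <- select_top_k(c(0.5, 0.7, 0.5, 0.2), 2)
  expect_identical(tied$selected, c(2L, 1L))
})

test_that("placement ranks a strongly informative node first across seeds", {
  # Per-node standardization equalizes second moments, so a basis from
  # pooled-variance PCA only sees a single informative node if the
  # subspace is large enough to cover it; the ranking guarantee is
  # therefore tested with a basis spanning the data.
  hits <- 0
  for (seed in 1:20) {
    fx <- make_fixture("separable-spikes", seed = seed, n_trials = 50,
                       n_nodes = 30, shift = 5, sd = 0.5)
    train <- rbind(fx$x0, fx$x1)
    labels <- rep(c("flap", "rotation"), each = 50)
    ss <- sspoc_place(train, labels,
                      sspoc_params(n_sensors = 3, n_basis = 29))
    hits <- hits + (ss$selected[1] == fx$informative_node)
  }
  expect_gte(hits / 20, 0.95)
})
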