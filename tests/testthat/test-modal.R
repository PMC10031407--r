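fake_strain <- function(eps, dt = 2e-4) {
  # minimal strain_field-like object over one wingbeat
  structure(
    list(eps = eps, times = dt * seq_len(ncol(eps)),
         wingbeat_window = seq_len(ncol(eps)), dt = dt,
         provenance = list(kin = kinematics())),
    class = "strain_field")
}

test_that("a rank-one field concentrates all energy in one mode", {
  u <- sin(seq(0, pi, length.out = 24))
  v <- cos(seq(0, 4 * pi, length.out = 50))
  s <- fake_strain(outer(u, v))
  dc <- pod_decompose(s)
  expect_equal(dc$eigenvalues[1], 1, tolerance = 1e-12)
  expect_equal(sum(dc$eigenvalues), 1, tolerance = 1e-12)
  expect_equal(reconstruct_k(dc, 1), s$eps, tolerance = 1e-10)
})

test_that("eigenvalues are scale invariant, normalized and non-increasing", {
  set.seed(11)
  eps <- matrix(rnorm(24 * 50), 24, 50)
  d1 <- pod_decompose(fake_strain(eps))
  d2 <- pod_decompose(fake_strain(10 * eps))
  expect_equal(d1$eigenvalues, d2$eigenvalues, tolerance = 1e-12)
  expect_equal(d1$spatial_modes, d2$spatial_modes, tolerance = 1e-9)
  expect_equal(sum(d1$eigenvalues), 1, tolerance = 1e-12)
  expect_true(all(diff(d1$eigenvalues) <= 1e-12))
  expect_equal(crossprod(d1$spatial_modes), diag(d1$n_modes),
               tolerance = 1e-10)
  # cumulative energy capture is monotone and complete
  expect_true(all(diff(cumsum(d1$eigenvalues)) >= 0))
})

test_that("full-rank reconstruction recovers the field to numerical precision", {
  pair <- tiny_pair()
  dc <- pod_decompose(pair$s0)
  A <- pair$s0$eps[, pair$s0$wingbeat_window]
  R <- reconstruct_k(dc, dc$n_modes)
  expect_lt(norm(R - A, "F") / norm(A, "F"), 1e-10)
  # Frobenius reconstruction error is non-increasing in k
  errs <- vapply(seq_len(min(8, dc$n_modes)), function(k)
    norm(reconstruct_k(dc, k) - A, "F"), numeric(1))
  expect_true(all(diff(errs) <= 1e-10))
  expect_error(reconstruct_k(dc, 0), "invalid parameter")
  expect_error(reconstruct_k(dc, dc$n_modes + 1), "invalid parameter")
})

test_that("projection onto the flap-only basis is idempotent and exact at full rank", {
  pair <- tiny_pair()
  dc <- pod_decompose(pair$s0)
  p1 <- project_onto_modes(pair$s1, dc, dc$n_modes)
  p2 <- project_onto_modes(p1, dc, dc$n_modes)
  expect_equal(p1$eps, p2$eps, tolerance = 1e-10)
  # the flap-only field itself lies in its own basis
  p0 <- project_onto_modes(pair$s0, dc, dc$n_modes)
  A <- pair$s0$eps[, pair$s0$wingbeat_window]
  expect_equal(p0$eps[, pair$s0$wingbeat_window], A, tolerance = 1e-8)
})

test_that("mean-centered decomposition stores and restores the mean", {
  pair <- tiny_pair()
  dc <- pod_decompose(pair$s0, center = TRUE)
  A <- pair$s0$eps[, pair$s0$wingbeat_window]
  expect_equal(dc$mean, rowMeans(A))
  expect_lt(norm(reconstruct_k(dc, dc$n_modes) - A, "F") /
              norm(A, "F"), 1e-10)
})

test_that("an all-zero field yields an empty decomposition with a warning", {
  s <- fake_strain(matrix(0, 10, 20))
  expect_warning(dc <- pod_decompose(s), "degenerate")
  expect_equal(dc$n_modes, 0L)
})

test_that("accuracy-vs-modes returns bounded accuracies for every k", {
  pair <- tiny_pair()
  res <- accuracy_vs_modes(pair$s0, pair$s1, k_max = 2,
                           enc = encoding_params(n_trials = 20),
                           sp = sspoc_params(n_iterations = 2,
                                             n_sensors = 4),
                           seed = 17)
  expect_equal(sort(unique(res$k)), 1:2)
  expect_true(all(res$accuracy >= 0 & res$accuracy <= 1))
  agg <- attr(res, "summary")
  expect_equal(nrow(agg), 2)
  expect_true(all(agg$sem >= 0))
})
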