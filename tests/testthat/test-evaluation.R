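test_that("train/test splits are reproducible and guard against empty classes", {
  s1 <- split_trials(100, 100, 0.9, 5)
  s2 <- split_trials(100, 100, 0.9, 5)
  expect_identical(s1, s2)
  expect_length(s1$train0, 90)
  expect_length(s1$test1, 10)
  expect_length(intersect(s1$train0, s1$test0), 0)
  expect_error(split_trials(3, 3, 0.99, 1), "invalid split")
})

test_that("separable spike data classify perfectly with the midpoint boundary", {
  fx <- make_fixture("separable-spikes", seed = 1, n_trials = 50,
                     n_nodes = 20, shift = 6, sd = 0.3)
  split <- split_trials(50, 50, 0.9, 2)
  ev <- train_eval(fx$x0, fx$x1, fx$informative_node, split)
  expect_equal(ev$accuracy, 1.0)
  expect_equal(ev$boundary, mean(ev$class_centroids))
  expect_gt(ev$class_centroids["rotation"], ev$class_centroids["flap"])
})

test_that("statistically identical classes sit at chance accuracy", {
  accs <- vapply(1:25, function(seed) {
    fx <- make_fixture("synthetic-spikes", seed = seed, n_trials = 40,
                       n_nodes = 15, mu0 = 10, mu1 = 10, sd = 1)
    split <- split_trials(40, 40, 0.9, seed + 100)
    train_eval(fx$x0, fx$x1, 1:10, split)$accuracy
  }, numeric(1))
  expect_gt(mean(accs), 0.35)
  expect_lt(mean(accs), 0.65)
})

test_that("placement sensitivity has the documented endpoints", {
  expect_equal(placement_sensitivity(1.0, 0.5), 1.0)
  expect_equal(placement_sensitivity(0.7, 0.7), 0.0)
  expect_equal(placement_sensitivity(0.9, 0.6), 0.5)
  expect_error(placement_sensitivity(0.9, 0), "undefined sensitivity")
})

test_that("spanwise location summary maps base to 0 and tip to 1", {
  mk <- function(X) {
    structure(list(selected = seq_along(X), weights = rep(1, length(X)),
                   locations = data.frame(node = seq_along(X), X = X,
                                          Y = 0)),
              class = "sensor_set")
  }
  span <- 0.05
  expect_equal(spanwise_location_summary(list(mk(rep(0, 5))), span)$mean, 0)
  expect_equal(spanwise_location_summary(list(mk(rep(span, 5))), span)$mean, 1)
  spread <- spanwise_location_summary(
    list(mk(seq(0, span, length.out = 11)), mk(seq(0, span, length.out = 11))),
    span)
  expect_equal(spread$mean, 0.5, tolerance = 1e-10)
  expect_equal(spread$sem, 0)
})

test_that("detection evaluation is deterministic given its seeds", {
  pair <- tiny_pair()
  enc <- encoding_params(n_trials = 30)
  sp <- sspoc_params(n_iterations = 2, n_sensors = 5)
  d1 <- evaluate_detection(pair$s0, pair$s1, enc, sp, seed = 9)
  d2 <- evaluate_detection(pair$s0, pair$s1, enc, sp, seed = 9)
  expect_identical(d1$results, d2$results)
  expect_identical(d1$sensor_sets[[1]]$selected, d2$sensor_sets[[1]]$selected)
  expect_true(all(d1$results$accuracy >= 0 & d1$results$accuracy <= 1))
})

test_that("label permutation drives accuracy to chance", {
  pair <- tiny_pair()
  enc <- encoding_params(n_trials = 30)
  # encode the same (flap) field twice with different RNG streams: the
  # two "classes" then differ only by spike noise
  a <- encode_strain(pair$s0, enc, seed = 101)
  b <- encode_strain(pair$s0, enc, seed = 202)
  accs <- vapply(1:10, function(i) {
    split <- split_trials(30, 30, 0.9, i)
    train <- rbind(a$first_spike[split$train0, ], b$first_spike[split$train1, ])
    labels <- rep(c("flap", "rotation"), each = length(split$train0))
    ss <- sspoc_place(train, labels, sspoc_params(n_sensors = 5))
    train_eval(a$first_spike, b$first_spike, ss, split)$accuracy
  }, numeric(1))
  expect_gte(mean(accs), 0.3)
  expect_lte(mean(accs), 0.7)
})

test_that("a one-cell sweep reproduces the direct pipeline", {
  enc <- encoding_params(n_trials = 20)
  sp <- sspoc_params(n_iterations = 2, n_sensors = 4)
  sw <- suppressWarnings(
    run_sweep(E_mean_values = 3e9, gradients = "gradient", zetas = 2,
              axes = "yaw", enc = enc, sp = sp, seed = 3, n_cycles = 8,
              nx = 10, ny = 5))
  expect_null(sw$failures)
  expect_equal(nrow(sw$results), 2)
  spec <- wing_spec(gradient = "gradient", E_mean = 3e9, zeta = 2)
  s0 <- suppressWarnings(simulate_strain(spec, kinematics(rotation_axis = "none"),
                                         n_cycles = 8, nx = 10, ny = 5))
  s1 <- suppressWarnings(simulate_strain(spec, kinematics(rotation_axis = "yaw"),
                                         n_cycles = 8, nx = 10, ny = 5))
  det <- evaluate_detection(s0, s1, enc, sp, seed = 3 + 1000L)
  expect_equal(sw$results$accuracy, det$results$accuracy)
  # errors in a cell are recorded, not fatal
  sw_bad <- suppressWarnings(
    run_sweep(E_mean_values = c(-1, 3e9), gradients = "gradient", zetas = 2,
              axes = "yaw", enc = enc, sp = sp, seed = 3, n_cycles = 8,
              nx = 10, ny = 5))
  expect_equal(nrow(sw_bad$failures), 1)
  expect_match(sw_bad$failures$message, "E_mean")
})
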