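#' Reproducible per-class train/test split
#'
#' @param n0,n1 trials per class.
#' @param frac training fraction.
#' @param seed split RNG seed.
#' @return list with train/test index vectors for each class.
#' @export
split_trials <- function(n0, n1, frac, seed) {
  set.seed(seed)
  tr0 <- sort(sample.int(n0, round(frac * n0)))
  tr1 <- sort(sample.int(n1, round(frac * n1)))
  if (length(tr0) == n0 || length(tr1) == n1)
    stop("invalid split: empty test set for one class")
  list(train0 = tr0, test0 = setdiff(seq_len(n0), tr0),
       train1 = tr1, test1 = setdiff(seq_len(n1), tr1))
}

#' Train and evaluate the rotation classifier on selected sensors
#'
#' Fits the 1-D Fisher discriminant on the *non-standardized* training
#' first-spike times restricted to the selected sensors, draws the
#' decision boundary at the midpoint of the two projected class
#' centroids, and classifies the held-out test trials.
#'
#' @param spikes0,spikes1 `spike_data` for the flap-only and rotation
#'   classes (or plain trials x nodes matrices).
#' @param sensors a `sensor_set` (or integer vector of node indices).
#' @param split a [split_trials()] result (sensors must have been chosen
#'   on its training half).
#' @return object of class `eval_result`: `accuracy`, per-test-trial
#'   `projection`, `boundary`, `class_centroids` and the sensors used.
#' @export
train_eval <- function(spikes0, spikes1, sensors, split) {
  x0 <- if (inherits(spikes0, "spike_data")) spikes0$first_spike else spikes0
  x1 <- if (inherits(spikes1, "spike_data")) spikes1$first_spike else spikes1
  sel <- if (inherits(sensors, "sensor_set")) sensors$selected else sensors
  tr <- rbind(x0[split$train0, sel, drop = FALSE],
              x1[split$train1, sel, drop = FALSE])
  tr_lab <- rep(c("flap", "rotation"),
                c(length(split$train0), length(split$train1)))
  te <- rbind(x0[split$test0, sel, drop = FALSE],
              x1[split$test1, sel, drop = FALSE])
  te_lab <- rep(c("flap", "rotation"),
                c(length(split$test0), length(split$test1)))
  w_c <- lda_direction(tr, tr_lab)
  proj_tr <- as.numeric(tr %*% w_c)
  cent <- c(flap = mean(proj_tr[tr_lab == "flap"]),
            rotation = mean(proj_tr[tr_lab == "rotation"]))
  boundary <- mean(cent)
  proj_te <- as.numeric(te %*% w_c)
  pred <- ifelse(proj_te > boundary, "rotation", "flap")
  structure(
    list(accuracy = mean(pred == te_lab), projection = proj_te,
         test_labels = te_lab, boundary = boundary,
         class_centroids = cent, w_c = w_c, sensors = sel),
    class = "eval_result"
  )
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> accuracy %.3f on %d test trials, boundary %.3g\n",
              x$accuracy, length(x$projection), x$boundary))
  invisible(x)
}

#' Placement sensitivity
#'
#' `acc_opt / acc_rand - 1`: 0 when random sensors do as well as
#' optimized ones, 1 when optimized sensors are perfect while random
#' sensors sit at two-class chance.
#'
#' @param acc_opt accuracy of optimized sensors.
#' @param acc_rand mean accuracy of randomly placed sensors (> 0).
#' @return sensitivity value.
#' @export
placement_sensitivity <- function(acc_opt, acc_rand) {
  stopifnot(acc_opt >= 0, acc_opt <= 1, acc_rand <= 1)
  if (acc_rand <= 0)
    stop("undefined sensitivity: random-placement accuracy is zero")
  acc_opt / acc_rand - 1
}

#' Mean spanwise location of selected sensors
#'
#' Mean spanwise position (0 = wing base, 1 = tip) of the selected
#' sensors pooled over iterations, with the SEM across iterations.
#'
#' @param sensor_sets list of `sensor_set` objects (one per iteration).
#' @param span wing span in metres.
#' @return list with `mean`, `sem` and the per-iteration means.
#' @export
spanwise_location_summary <- function(sensor_sets, span) {
  stopifnot(length(sensor_sets) >= 1)
  per_iter <- vapply(sensor_sets, function(ss) {
    mean(ss$locations$X) / span
  }, numeric(1))
  sem <- if (length(per_iter) > 1)
    stats::sd(per_iter) / sqrt(length(per_iter)) else 0
  list(mean = mean(per_iter), sem = sem, per_iteration = per_iter)
}

#' Rotation-detection evaluation over optimization iterations
#'
#' Runs the encode -> place -> evaluate chain `n_iterations` times on a
#' fixed pair of simulated strain fields.  Each iteration redraws the
#' stochastic spike responses and the 90/10 split (strain is
#' deterministic given the wing, so it is shared), optimizes sensors on
#' the training half, and reports held-out accuracy.  Optionally
#' evaluates `n_random` random placements per iteration for the
#' placement-sensitivity denominator.
#'
#' @param strain0,strain1 `strain_field`s for flap-only and
#'   flap+rotation.
#' @param enc an [encoding_params()].
#' @param sp an [sspoc_params()].
#' @param seed base seed; iteration i uses `seed + i` for spikes and
#'   `seed + 10000 + i` for the split.
#' @param n_random random placements per iteration (0 to skip).
#' @return object of class `detection_result`: tidy `results` data frame
#'   (iteration, accuracy, mean spanwise location, random accuracy),
#'   the per-iteration `sensor_sets`, and summary statistics.
#' @export
evaluate_detection <- function(strain0, strain1, enc = encoding_params(),
                               sp = sspoc_params(), seed = sp$seed,
                               n_random = 0) {
  n_iter <- sp$n_iterations
  acc <- numeric(n_iter)
  acc_rand <- rep(NA_real_, n_iter)
  sets <- vector("list", n_iter)
  span <- strain0$provenance$spec$span
  for (i in seq_len(n_iter)) {
    sd0 <- encode_strain(strain0, enc, seed = seed + 2L * i)
    sd1 <- encode_strain(strain1, enc, seed = seed + 2L * i + 1L)
    split <- split_trials(nrow(sd0$first_spike), nrow(sd1$first_spike),
                          sp$train_frac, seed + 10000L + i)
    train <- rbind(sd0$first_spike[split$train0, , drop = FALSE],
                   sd1$first_spike[split$train1, , drop = FALSE])
    labels <- rep(c("flap", "rotation"),
                  c(length(split$train0), length(split$train1)))
    sets[[i]] <- sspoc_place(train, labels, sp, sd0$node_X, sd0$node_Y)
    acc[i] <- train_eval(sd0, sd1, sets[[i]], split)$accuracy
    if (n_random > 0) {
      set.seed(seed + 20000L + i)
      racc <- vapply(seq_len(n_random), function(r) {
        rsel <- sample.int(ncol(sd0$first_spike), sp$n_sensors)
        train_eval(sd0, sd1, rsel, split)$accuracy
      }, numeric(1))
      acc_rand[i] <- mean(racc)
    }
  }
  loc <- spanwise_location_summary(sets, span)
  res <- data.frame(iteration = seq_len(n_iter), accuracy = acc,
                    spanwise_location = loc$per_iteration,
                    random_accuracy = acc_rand)
  structure(
    list(results = res, sensor_sets = sets,
         mean_accuracy = mean(acc),
         sem_accuracy = if (n_iter > 1) stats::sd(acc) / sqrt(n_iter) else 0,
         mean_random_accuracy = if (n_random > 0) mean(acc_rand) else NA_real_,
         sensitivity = if (n_random > 0)
           placement_sensitivity(mean(acc), mean(acc_rand)) else NA_real_,
         spanwise = loc),
    class = "detection_result"
  )
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf(
    "<detection_result> accuracy %.1f%% +/- %.1f%% (SEM, %d iterations)",
    100 * x$mean_accuracy, 100 * x$sem_accuracy, nrow(x$results)))
  if (!is.na(x$mean_random_accuracy))
    cat(sprintf("; random %.1f%%, sensitivity %.2f",
                100 * x$mean_random_accuracy, x$sensitivity))
  cat("\n")
  invisible(x)
}

#' Sweep wing configurations
#'
#' Executes simulate -> encode -> place -> evaluate for every
#' combination of mean stiffness, stiffness profile, damping ratio and
#' rotation axis, and returns one tidy row per cell and iteration.
#' Failed cells are recorded and skipped rather than aborting the sweep.
#'
#' @param E_mean_values numeric vector of mean stiffness values (Pa).
#' @param gradients character vector from `c("uniform", "gradient")`.
#' @param zetas numeric damping ratios.
#' @param axes character rotation axes from `c("roll", "pitch", "yaw")`.
#' @param enc,sp encoding and placement parameters.
#' @param n_random random placements per iteration (for sensitivity).
#' @param seed base seed.
#' @param n_cycles,nx,ny simulation controls passed to
#'   [simulate_strain()].
#' @return list with tidy `results` data frame and any `failures`.
#' @export
run_sweep <- function(E_mean_values = 3e9, gradients = "gradient",
                      zetas = 2, axes = "yaw",
                      enc = encoding_params(), sp = sspoc_params(),
                      n_random = 0, seed = 1L, n_cycles = 8,
                      nx = 50, ny = 25) {
  grid <- expand.grid(E_mean = E_mean_values, gradient = gradients,
                      zeta = zetas, axis = axes,
                      stringsAsFactors = FALSE)
  rows <- list()
  failures <- list()
  for (g in seq_len(nrow(grid))) {
    cell <- grid[g, ]
    out <- tryCatch({
      spec <- wing_spec(gradient = cell$gradient, E_mean = cell$E_mean,
                        zeta = cell$zeta)
      s0 <- simulate_strain(spec, kinematics(rotation_axis = "none"),
                            n_cycles = n_cycles, nx = nx, ny = ny)
      s1 <- simulate_strain(spec,
                            kinematics(rotation_axis = cell$axis),
                            n_cycles = n_cycles, nx = nx, ny = ny)
      det <- evaluate_detection(s0, s1, enc, sp,
                                seed = seed + 1000L * g,
                                n_random = n_random)
      cbind(cell, det$results, row.names = NULL)
    }, error = function(e) e)
    if (inherits(out, "error")) {
      failures[[length(failures) + 1]] <-
        data.frame(cell, message = conditionMessage(out))
    } else {
      rows[[length(rows) + 1]] <- out
    }
  }
  list(results = do.call(rbind, rows),
       failures = if (length(failures)) do.call(rbind, failures) else NULL)
}
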