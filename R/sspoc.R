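#' SSPOC optimization parameters
#'
#' @param n_basis dimension `m` of the PCA subspace.
#' @param lam elastic-net mixing weight in `[0, 1]` (1 = pure lasso).
#' @param n_sensors number of sensors kept (largest weights).
#' @param train_frac fraction of trials per class used for training.
#' @param n_iterations number of optimization iterations (independent
#'   train/test splits and spike redraws) in evaluations.
#' @param seed RNG seed for splits.
#' @return object of class `sspoc_params`.
#' @export
sspoc_params <- function(n_basis = 3, lam = 0.9, n_sensors = 10,
                         train_frac = 0.9, n_iterations = 20, seed = 1L) {
  stopifnot(lam >= 0, lam <= 1, n_basis >= 1, n_sensors >= 1,
            train_frac > 0, train_frac < 1, n_iterations >= 1)
  structure(
    list(n_basis = as.integer(n_basis), lam = lam,
         n_sensors = as.integer(n_sensors), train_frac = train_frac,
         n_iterations = as.integer(n_iterations), seed = as.integer(seed)),
    class = "sspoc_params"
  )
}

#' Per-feature standardization of a training matrix
#'
#' Zero mean, unit variance per column; columns with (near-)zero
#' variance are mapped to zero rather than dropped, so node indexing
#' stays stable (a node that never spikes is uninformative but keeps its
#' place).
#'
#' @param x trials x features matrix.
#' @return list with the standardized matrix `z` and the transform
#'   (`center`, `scale`, logical `degenerate`).
#' @export
standardize <- function(x) {
  center <- colMeans(x)
  sdev <- apply(x, 2, stats::sd)
  degenerate <- !is.finite(sdev) | sdev < .Machine$double.eps^0.5
  scale <- ifelse(degenerate, 1, sdev)
  z <- sweep(sweep(x, 2, center), 2, scale, "/")
  z[, degenerate] <- 0
  list(z = z, center = center, scale = scale, degenerate = degenerate)
}

#' Apply a stored standardization transform
#' @param x trials x features matrix.
#' @param transform result of [standardize()].
#' @return standardized matrix.
#' @export
apply_standardize <- function(x, transform) {
  z <- sweep(sweep(x, 2, transform$center), 2, transform$scale, "/")
  z[, transform$degenerate] <- 0
  z
}

#' Principal component basis of the pooled training data
#'
#' Top `n_basis` principal directions of the standardized training
#' matrix (both classes pooled), orthonormal and ordered by explained
#' variance, with a deterministic sign convention (the largest-magnitude
#' loading of each column is positive).
#'
#' @param z standardized trials x features matrix.
#' @param n_basis requested subspace dimension.
#' @return list with `Psi` (features x k), `sdev` (component standard
#'   deviations) and `k` (effective dimension; may be below `n_basis`
#'   for degenerate data, with a warning).
#' @export
pca_basis <- function(z, n_basis) {
  stopifnot(n_basis >= 1)
  sv <- svd(z, nu = 0, nv = min(n_basis, ncol(z)))
  pos <- sv$d > max(sv$d[1], .Machine$double.eps) * 1e-10
  k <- min(n_basis, sum(pos))
  if (k < n_basis)
    warning(sprintf("data support only %d of %d requested components", k,
                    n_basis))
  Psi <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(Psi[, j]))
    if (Psi[i, j] < 0) Psi[, j] <- -Psi[, j]
  }
  list(Psi = Psi, sdev = sv$d[seq_len(k)] / sqrt(max(1, nrow(z) - 1)), k = k)
}

#' Two-class Fisher discriminant direction
#'
#' Direction maximizing between- over within-class scatter, with a small
#' trace-scaled ridge on the within-class scatter for invertibility.
#' The result has unit norm and is oriented so the second class (the
#' rotation class, by convention) projects positive.
#'
#' @param x trials x dims matrix (projected data).
#' @param labels two-level factor or vector; the second level is the
#'   positive class.
#' @param ridge ridge fraction of the average within-class variance.
#' @return unit-norm numeric vector `w`.
#' @export
lda_direction <- function(x, labels, ridge = 1e-6) {
  f <- factor(labels)
  stopifnot(nlevels(f) == 2, all(table(f) >= 2))
  x <- as.matrix(x)
  mu <- lapply(levels(f), function(l) colMeans(x[f == l, , drop = FALSE]))
  Sw <- matrix(0, ncol(x), ncol(x))
  for (l in seq_along(levels(f))) {
    xc <- sweep(x[f == levels(f)[l], , drop = FALSE], 2, mu[[l]])
    Sw <- Sw + crossprod(xc)
  }
  Sw <- Sw + ridge * (sum(diag(Sw)) / ncol(x) + .Machine$double.eps) *
    diag(ncol(x))
  dmu <- mu[[2]] - mu[[1]]
  if (sqrt(sum(dmu^2)) < .Machine$double.eps^0.5 * (1 + sqrt(sum(mu[[1]]^2))))
    warning("identical class means: discriminant direction is degenerate")
  w <- solve(Sw, dmu)
  nw <- sqrt(sum(w^2))
  if (nw == 0) return(w)
  w <- w / nw
  if (sum(w * dmu) < 0) w <- -w
  w
}

#' Sparse sensor weights by the constrained elastic net
#'
#' Solves `min_s lam * ||s||_1 + (1 - lam) * ||s||_2^2` subject to
#' `Psi^T s = w` by ADMM: the quadratic-plus-equality subproblem has a
#' closed-form KKT solution and the l1 subproblem is soft thresholding.
#' The returned point is projected onto the constraint set, so the
#' feasibility residual `||Psi^T s - w||` is at solver precision.
#'
#' @param Psi features x m orthonormal basis.
#' @param w length-m discriminant direction.
#' @param lam elastic-net mixing weight in `[0, 1]`.
#' @param rho ADMM penalty parameter.
#' @param max_iter,tol iteration cap and primal/dual stopping tolerance.
#' @return numeric weight vector `s` (length = number of features).
#' @export
elastic_net_sensors <- function(Psi, w, lam, rho = 1, max_iter = 5000,
                                tol = 1e-10) {
  Psi <- as.matrix(Psi)
  w <- as.numeric(w)
  stopifnot(ncol(Psi) == length(w), lam >= 0, lam <= 1)
  G <- crossprod(Psi)                    # m x m, identity for orthonormal Psi
  if (rcond(G) < 1e-12)
    stop("optimization failed: basis is rank deficient, constraint infeasible")
  n <- nrow(Psi)
  kap <- 2 * (1 - lam) + rho
  # KKT solve helper: min (1-lam)||s||^2 + rho/2 ||s - q||^2  s.t. Psi's = w
  Ginv_fac <- chol(G)
  kkt <- function(q) {
    rhs <- crossprod(Psi, q) - (kap / rho) * w
    nu <- backsolve(Ginv_fac, forwardsolve(t(Ginv_fac), rhs))
    q - Psi %*% nu
  }
  z <- numeric(n)
  u <- numeric(n)
  s <- numeric(n)
  thr <- lam / rho
  for (it in seq_len(max_iter)) {
    s <- as.numeric((rho / kap) * kkt(z - u))
    sz <- s + u
    z_new <- sign(sz) * pmax(abs(sz) - thr, 0)
    r_dual <- sqrt(sum((z_new - z)^2))
    z <- z_new
    u <- u + s - z
    r_prim <- sqrt(sum((s - z)^2))
    if (r_prim <= tol * (1 + sqrt(sum(s^2))) &&
        r_dual <= tol * (1 + sqrt(sum(z^2))))
      break
  }
  # exact projection onto the affine constraint
  resid <- crossprod(Psi, s) - w
  s <- as.numeric(s - Psi %*% solve(G, resid))
  s
}

#' Select the top-k sensors from a weight vector
#'
#' Indices of the `n_sensors` largest-magnitude weights, in decreasing
#' order of magnitude; ties break deterministically toward the lower
#' node index.  An all-zero weight vector yields the first `n_sensors`
#' indices with a warning.
#'
#' @param s numeric sensor weight vector.
#' @param n_sensors number of sensors to keep.
#' @param node_X,node_Y optional node coordinates carried along.
#' @return object of class `sensor_set`: `selected`, `weights` (full
#'   vector) and selected node locations.
#' @export
select_top_k <- function(s, n_sensors, node_X = NULL, node_Y = NULL) {
  stopifnot(length(s) >= n_sensors)
  if (all(s == 0))
    warning("degenerate solution: all sensor weights are zero")
  ord <- order(-abs(s), seq_along(s))
  sel <- ord[seq_len(n_sensors)]
  structure(
    list(selected = sel, weights = s,
         locations = if (!is.null(node_X))
           data.frame(node = sel, X = node_X[sel], Y = node_Y[sel])
         else NULL),
    class = "sensor_set"
  )
}

#' @export
print.sensor_set <- function(x, ...) {
  cat(sprintf("<sensor_set> %d sensors of %d nodes; |w| in [%.3g, %.3g]\n",
              length(x$selected), length(x$weights),
              min(abs(x$weights[x$selected])),
              max(abs(x$weights[x$selected]))))
  invisible(x)
}

#' SSPOC sensor placement on a training set
#'
#' The full placement pass: standardize the training first-spike matrix,
#' compute the pooled PCA basis, find the LDA direction in that
#' subspace, solve the constrained elastic net for sparse weights, and
#' keep the top sensors.
#'
#' @param train trials x nodes matrix of first-spike times (training split).
#' @param labels class labels aligned with rows of `train`.
#' @param params an [sspoc_params()].
#' @param node_X,node_Y optional node coordinates.
#' @return a `sensor_set`.
#' @export
sspoc_place <- function(train, labels, params = sspoc_params(),
                        node_X = NULL, node_Y = NULL) {
  st <- standardize(train)
  pb <- pca_basis(st$z, params$n_basis)
  proj <- st$z %*% pb$Psi
  w <- lda_direction(proj, labels)
  s <- elastic_net_sensors(pb$Psi, w, params$lam)
  select_top_k(s, params$n_sensors, node_X, node_Y)
}
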