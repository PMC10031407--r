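#' Proper orthogonal decomposition of a strain field
#'
#' Singular value decomposition of the node x time strain matrix of the
#' analysis wingbeat.  Eigenvalues are the squared singular values
#' normalized to sum to one, so they read as the fraction of strain
#' energy captured by each mode.  The temporal mean per node is retained
#' by default (spiking depends on absolute strain); set `center = TRUE`
#' to subtract it before decomposing.
#'
#' @param strain a `strain_field`.
#' @param center subtract the per-node temporal mean first?
#' @return object of class `modal_decomposition`: orthonormal
#'   `spatial_modes` (node x k), `temporal_modes` (time x k, unit norm),
#'   singular values `d`, normalized `eigenvalues`, `n_modes`, and the
#'   retained `mean` field.  Mode signs follow the largest-magnitude
#'   spatial loading.
#' @export
pod_decompose <- function(strain, center = FALSE) {
  A <- strain$eps[, strain$wingbeat_window, drop = FALSE]
  mu <- if (center) rowMeans(A) else numeric(nrow(A))
  A <- A - mu
  if (max(abs(A)) == 0) {
    warning("degenerate strain field: all zero, empty decomposition")
    return(structure(list(spatial_modes = matrix(0, nrow(A), 0),
                          temporal_modes = matrix(0, ncol(A), 0),
                          d = numeric(0), eigenvalues = numeric(0),
                          n_modes = 0L, mean = mu, center = center,
                          times = strain$times[strain$wingbeat_window]),
                     class = "modal_decomposition"))
  }
  sv <- svd(A)
  keep <- sv$d > sv$d[1] * 1e-12
  U <- sv$u[, keep, drop = FALSE]
  V <- sv$v[, keep, drop = FALSE]
  d <- sv$d[keep]
  for (j in seq_len(ncol(U))) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) {
      U[, j] <- -U[, j]
      V[, j] <- -V[, j]
    }
  }
  structure(
    list(spatial_modes = U, temporal_modes = V, d = d,
         eigenvalues = d^2 / sum(d^2), n_modes = ncol(U), mean = mu,
         center = center, times = strain$times[strain$wingbeat_window]),
    class = "modal_decomposition"
  )
}

#' @export
print.modal_decomposition <- function(x, ...) {
  cat(sprintf("<modal_decomposition> %d modes; leading eigenvalues: %s\n",
              x$n_modes,
              paste(signif(utils::head(x$eigenvalues, 4), 3),
                    collapse = ", ")))
  invisible(x)
}

#' Rank-k reconstruction of the decomposed wingbeat
#'
#' @param decomp a [pod_decompose()] result.
#' @param k number of leading modes retained (1 to `n_modes`).
#' @return node x time matrix of the reconstructed analysis wingbeat.
#' @export
reconstruct_k <- function(decomp, k) {
  if (!(k >= 1 && k <= decomp$n_modes))
    stop(sprintf("invalid parameter: k must be in 1..%d", decomp$n_modes))
  idx <- seq_len(k)
  decomp$spatial_modes[, idx, drop = FALSE] %*%
    (decomp$d[idx] * t(decomp$temporal_modes[, idx, drop = FALSE])) +
    decomp$mean
}

#' Project a strain field onto a truncated spatial basis
#'
#' Replaces the strain at every time step by its projection onto the
#' first `k` spatial modes of `decomp` (plus the retained mean), leaving
#' all other bookkeeping intact.  Used to express both motion conditions
#' in the flap-only basis when measuring accuracy as a function of the
#' number of modes.
#'
#' @param strain a `strain_field`.
#' @param decomp a [pod_decompose()] result (typically of the flap-only
#'   condition).
#' @param k number of spatial modes retained.
#' @return a `strain_field` with truncated strain.
#' @export
project_onto_modes <- function(strain, decomp, k) {
  if (!(k >= 1 && k <= decomp$n_modes))
    stop(sprintf("invalid parameter: k must be in 1..%d", decomp$n_modes))
  U <- decomp$spatial_modes[, seq_len(k), drop = FALSE]
  out <- strain
  A <- strain$eps - decomp$mean
  out$eps <- U %*% crossprod(U, A) + decomp$mean
  out$condition <- strain$condition
  out
}

#' Detection accuracy as a function of retained strain modes
#'
#' For `k = 1..k_max`, projects both motion conditions onto the leading
#' `k` spatial modes of the flap-only field and runs the full
#' encode -> place -> evaluate chain.
#'
#' @param strain0,strain1 `strain_field`s (flap-only and rotation).
#' @param k_max largest number of modes.
#' @param enc,sp encoding and placement parameters.
#' @param seed base seed.
#' @param center mean-centering choice passed to [pod_decompose()].
#' @return data frame with one row per (k, iteration) plus a summary
#'   attribute `summary` (mean and SEM per k).
#' @export
accuracy_vs_modes <- function(strain0, strain1, k_max = 6,
                              enc = encoding_params(), sp = sspoc_params(),
                              seed = sp$seed, center = FALSE) {
  decomp <- pod_decompose(strain0, center = center)
  k_max <- min(k_max, decomp$n_modes)
  rows <- lapply(seq_len(k_max), function(k) {
    p0 <- project_onto_modes(strain0, decomp, k)
    p1 <- project_onto_modes(strain1, decomp, k)
    det <- evaluate_detection(p0, p1, enc, sp, seed = seed + 100000L * k)
    cbind(k = k, det$results)
  })
  res <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(res, res$k), function(d) {
    data.frame(k = d$k[1], mean_accuracy = mean(d$accuracy),
               sem = if (nrow(d) > 1)
                 stats::sd(d$accuracy) / sqrt(nrow(d)) else 0)
  }))
  attr(res, "summary") <- agg
  res
}
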