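#' Parameters of the linear-nonlinear spiking sensor
#'
#' Each grid node carries a model mechanosensory neuron: strain is
#' convolved with a decaying-sinusoid temporal feature, passed through a
#' steep sigmoid to a per-bin firing probability, and spikes are drawn
#' per 0.1 ms bin against independent uniform variates with an absolute
#' refractory period.
#'
#' @param omega filter frequency in 1/ms (default `1/(2*pi)`).
#' @param tau time offset of the filter peak, ms.
#' @param delta filter decay time, ms.
#' @param alpha sigmoid slope (per unit filtered strain).
#' @param beta sigmoid half-maximum threshold (filtered-strain units).
#' @param refractory absolute refractory period, ms.
#' @param bin encoding resolution, ms (spike times are quantized to it).
#' @param n_trials number of stochastic spiking repetitions.
#' @param seed master RNG seed for spike generation.
#' @param gain global multiplier applied to strain before filtering
#'   (sensitivity analyses only; 1 leaves strain in natural units).
#' @return object of class `encoding_params`.
#' @export
encoding_params <- function(omega = 1 / (2 * pi), tau = 5, delta = 4,
                            alpha = 5e5, beta = 1e-4, refractory = 15,
                            bin = 0.1, n_trials = 100, seed = 1L,
                            gain = 1) {
  stopifnot(omega > 0, tau > 0, delta > 0, alpha > 0, beta > 0,
            refractory > 0, bin > 0,
            "bin must not exceed the refractory period" = bin <= refractory,
            n_trials >= 1)
  structure(
    list(omega = omega, tau = tau, delta = delta, alpha = alpha,
         beta = beta, refractory = refractory, bin = bin,
         n_trials = as.integer(n_trials), seed = as.integer(seed),
         gain = gain),
    class = "encoding_params"
  )
}

#' Temporal strain feature (sensor filter)
#'
#' The decaying sinusoid `cos(2 pi omega u) * exp(-u^2 / delta^2)`
#' sampled on the encoding bin grid, shifted to a causal kernel of
#' length `tau + 4 delta` so that peak sensitivity lags strain by
#' `tau`: tap `j` weights strain `(j - 1) * bin` ms in the past, and the
#' peak value 1 sits at lag `tau`.
#'
#' @param params an [encoding_params()].
#' @return list with `kernel` (numeric taps) and `lags` (ms).
#' @export
make_filter <- function(params) {
  lags <- seq(0, params$tau + 4 * params$delta, by = params$bin)
  u <- lags - params$tau
  list(kernel = cos(2 * pi * params$omega * u) * exp(-u^2 / params$delta^2),
       lags = lags)
}

#' Causal convolution of strain with the sensor filter
#'
#' `g[t] = sum_j kernel[j] * strain[t - j + 1]`: the filtered signal at a
#' time depends only on strain at earlier or equal times.  Strain before
#' the first sample is taken as zero (the wing starts at rest).
#'
#' @param strain numeric vector (one node) or node x time matrix, on the
#'   encoding bin grid.
#' @param filter a [make_filter()] result.
#' @return filtered signal, same shape as `strain`.
#' @export
filter_strain <- function(strain, filter) {
  k <- filter$kernel
  vec <- is.null(dim(strain))
  m <- if (vec) matrix(strain, nrow = 1) else strain
  if (ncol(m) < length(k))
    stop("insufficient data: strain series shorter than the filter support")
  nt <- ncol(m)
  nfft <- 2^ceiling(log2(nt + length(k)))
  kf <- stats::fft(c(k, numeric(nfft - length(k))))
  xf <- stats::mvfft(t(cbind(m, matrix(0, nrow(m), nfft - nt))))
  g <- Re(stats::mvfft(xf * kf, inverse = TRUE)) / nfft
  g <- t(g[seq_len(nt), , drop = FALSE])
  if (vec) as.numeric(g) else g
}

#' Firing probability from filtered strain
#'
#' Elementwise sigmoid `1 / (1 + exp(-alpha (g - beta)))`; reaches half
#' maximum where the filtered strain crosses the threshold `beta`.
#'
#' @param g filtered strain (any shape).
#' @param params an [encoding_params()].
#' @return probabilities in (0, 1), same shape as `g`.
#' @export
firing_probability <- function(g, params) {
  p <- stats::plogis(params$alpha * (g - params$beta))
  if (!is.null(dim(g))) dim(p) <- dim(g)
  p
}

#' Generate spike trains from a probability series (one node)
#'
#' Reference per-node generator: one uniform draw per bin and trial; a
#' spike is emitted when the probability exceeds the draw and at least
#' the refractory period has elapsed since the previous spike.
#'
#' @param prob probability per encoding bin.
#' @param params an [encoding_params()]; `n_trials` repetitions.
#' @param seed RNG seed (defaults to `params$seed`).
#' @return list of length `n_trials`; each element the spike times in ms
#'   (bin-end convention: a spike in bin `k` has time `k * bin`).
#' @export
generate_spikes <- function(prob, params, seed = params$seed) {
  stopifnot(all(prob >= 0), all(prob <= 1))
  refr_bins <- ceiling(params$refractory / params$bin)
  set.seed(seed)
  lapply(seq_len(params$n_trials), function(tr) {
    u <- stats::runif(length(prob))
    cand <- which(prob > u)
    out <- integer(0)
    while (length(cand)) {
      out <- c(out, cand[1])
      cand <- cand[cand >= cand[1] + refr_bins]
    }
    out * params$bin
  })
}

#' First-spike time within a wingbeat
#'
#' Earliest spike time within the half-open wingbeat window
#' `[start, end)`, measured from the wingbeat start; 0 when the wingbeat
#' elicits no spike.  A spike exactly on the start boundary belongs to
#' this wingbeat and reports the smallest representable latency (one
#' bin), so that 0 uniquely encodes silence.
#'
#' @param spikes list of per-trial spike-time vectors (ms), or a single
#'   numeric vector.
#' @param window `c(start, end)` of the wingbeat in the same time base, ms.
#' @param bin encoding resolution in ms.
#' @return numeric vector of per-trial first-spike times (ms).
#' @export
first_spike_times <- function(spikes, window, bin = 0.1) {
  if (is.numeric(spikes)) spikes <- list(spikes)
  vapply(spikes, function(s) {
    s <- s[s >= window[1] & s < window[2]]
    if (length(s)) max(min(s) - window[1], bin) else 0
  }, numeric(1))
}

#' Encode a simulated strain field into first-spike times
#'
#' Full encoding pass over every grid node: resamples strain to the
#' encoding bin grid, convolves with the temporal feature, maps to
#' firing probabilities, draws `n_trials` stochastic spike responses and
#' reduces each to the time of the first spike within the analysis
#' wingbeat (0 when no spike occurs).  Spikes are generated over the two
#' final wingbeats so that refractoriness carries physically across the
#' wingbeat boundary into the analysis wingbeat.
#'
#' @param strain a `strain_field` from [simulate_strain()].
#' @param params an [encoding_params()].
#' @param seed RNG seed for the stochastic spike draws (defaults to
#'   `params$seed`).
#' @return object of class `spike_data`: `first_spike` (n_trials x
#'   n_nodes matrix, ms), `wingbeat_period` (ms), `class_label`, node
#'   coordinates and parameters.
#' @export
encode_strain <- function(strain, params = encoding_params(),
                          seed = params$seed) {
  bin_s <- params$bin * 1e-3
  r <- strain$dt / bin_s
  if (abs(r - round(r)) > 1e-9)
    stop("solver step must be an integer multiple of the encoding bin")
  r <- round(r)
  nt <- ncol(strain$eps)
  # upsample to the bin grid by linear interpolation between solver steps
  # (solver sample s sits at time s * dt; strain at t = 0 is zero)
  n_bins <- nt * r
  wts <- (seq_len(r)) / r
  E <- matrix(0, nrow(strain$eps), n_bins)
  prev <- cbind(0, strain$eps[, -nt, drop = FALSE])
  for (q in seq_len(r)) {
    E[, seq(q, n_bins, by = r)] <- (1 - wts[q]) * prev + wts[q] * strain$eps
  }
  filt <- make_filter(params)
  g <- filter_strain(params$gain * E, filt)
  p <- firing_probability(g, params)

  per_wb <- round((1 / strain$provenance$kin$f1) / bin_s)
  stopifnot(n_bins >= 2 * per_wb)
  win <- (n_bins - 2 * per_wb + 1):n_bins    # last two wingbeats
  p <- p[, win, drop = FALSE]
  n_nodes <- nrow(p)
  n_trials <- params$n_trials
  refr_bins <- ceiling(params$refractory / params$bin)

  set.seed(seed)
  next_ok <- matrix(1L, n_trials, n_nodes)
  fs <- matrix(0, n_trials, n_nodes)
  analysis_start <- per_wb  # bins per_wb+1 .. 2*per_wb are the analysis wingbeat
  for (k in seq_len(2L * per_wb)) {
    pk <- p[, k]
    if (max(pk) < 1e-12) next
    u <- matrix(stats::runif(n_trials * n_nodes), n_trials, n_nodes)
    fire <- (u < matrix(pk, n_trials, n_nodes, byrow = TRUE)) & (next_ok <= k)
    if (any(fire)) {
      next_ok[fire] <- k + refr_bins
      if (k > analysis_start) {
        new_first <- fire & fs == 0
        fs[new_first] <- (k - analysis_start) * params$bin
      }
    }
  }
  structure(
    list(first_spike = fs,
         wingbeat_period = per_wb * params$bin,
         class_label = if (strain$condition == "flap") "flap" else "rotation",
         condition = strain$condition,
         node_X = strain$node_X, node_Y = strain$node_Y,
         params = params, seed = seed),
    class = "spike_data"
  )
}

#' @export
print.spike_data <- function(x, ...) {
  cat(sprintf(
    "<spike_data> %s: %d trials x %d nodes, %.0f%% wingbeats spiking, period %g ms\n",
    x$class_label, nrow(x$first_spike), ncol(x$first_spike),
    100 * mean(x$first_spike > 0), x$wingbeat_period))
  invisible(x)
}
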