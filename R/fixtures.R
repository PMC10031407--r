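#' Synthetic test fixtures
#'
#' Small, fully in-code inputs that let every downstream stage be
#' exercised without a plate simulation:
#'
#' * `"tiny-plate"`: a wing specification with a coarse 10 x 5 element
#'   mesh for fast solver tests.
#' * `"synthetic-spikes"`: per-class first-spike matrices drawn from
#'   Gaussians (class means `mu0`, `mu1` ms, common `sd`), quantized to
#'   the 0.1 ms grid -- statistically featureless when `mu0 == mu1`.
#' * `"separable-spikes"`: all nodes pure noise except one informative
#'   node whose first-spike time shifts by `shift` ms between classes
#'   (`shift >> sd`), so placement must rank that node first.
#'
#' @param kind fixture kind.
#' @param seed RNG seed; a fixed seed reproduces the fixture exactly.
#' @param n_trials,n_nodes dimensions of the spike fixtures.
#' @param mu0,mu1,sd,shift Gaussian parameters in ms.
#' @param informative_node index of the informative node.
#' @return `"tiny-plate"`: list with `spec`, `nx`, `ny`.  Spike kinds:
#'   list with matrices `x0`, `x1` (trials x nodes), `labels`
#'   convention, and the generating parameters.
#' @export
make_fixture <- function(kind = c("tiny-plate", "synthetic-spikes",
                                  "separable-spikes"),
                         seed = 1L, n_trials = 100, n_nodes = 30,
                         mu0 = 10, mu1 = 10, sd = 1, shift = 5,
                         informative_node = ceiling(n_nodes / 2)) {
  kind <- match.arg(kind)
  q <- function(x) pmax(round(x, 1), 0.1)  # quantize, keep strictly positive
  if (kind == "tiny-plate") {
    return(list(spec = wing_spec(zeta = 2), nx = 10, ny = 5))
  }
  set.seed(seed)
  if (kind == "synthetic-spikes") {
    x0 <- matrix(q(stats::rnorm(n_trials * n_nodes, mu0, sd)),
                 n_trials, n_nodes)
    x1 <- matrix(q(stats::rnorm(n_trials * n_nodes, mu1, sd)),
                 n_trials, n_nodes)
    return(list(x0 = x0, x1 = x1, mu0 = mu0, mu1 = mu1, sd = sd,
                seed = seed))
  }
  x0 <- matrix(q(stats::rnorm(n_trials * n_nodes, mu0, sd)),
               n_trials, n_nodes)
  x1 <- matrix(q(stats::rnorm(n_trials * n_nodes, mu0, sd)),
               n_trials, n_nodes)
  x1[, informative_node] <- q(stats::rnorm(n_trials, mu0 + shift, sd))
  list(x0 = x0, x1 = x1, informative_node = informative_node,
       shift = shift, sd = sd, seed = seed)
}
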