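#' Default experiment configuration
#'
#' Nested list of every tunable parameter with its default value:
#' wing geometry and material, flapping/rotation kinematics, solver
#' controls, sensor encoding, SSPOC optimization and the sweep grid.
#' The stiffness sweep covers two orders of magnitude around 3 GPa on a
#' log-spaced grid.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    wing = list(span = 0.05, chord = 0.025, thickness = 127e-6,
                density = 1180, poisson = 0.35, E_mean = 3e9,
                gradient = "gradient", decline_x = 26.67,
                decline_y = 26.67, zeta = 2),
    kinematics = list(A1 = pi / 12, A2 = pi / 60, f1 = 25, f2 = 50,
                      rotation_axis = "yaw", rotation_rate = 1.0,
                      ramp_cycles = 1),
    simulation = list(dt = 2e-4, n_cycles = 8, nx = 50, ny = 25,
                      include_geometric = TRUE),
    encoding = list(omega = 1 / (2 * pi), tau = 5, delta = 4,
                    alpha = 5e5, beta = 1e-4, refractory = 15,
                    bin = 0.1, n_trials = 100, seed = 1, gain = 1),
    sspoc = list(n_basis = 3, lam = 0.9, n_sensors = 10,
                 train_frac = 0.9, n_iterations = 20, seed = 1),
    sweep = list(E_mean_values = 10^seq(log10(0.3e9), log10(30e9),
                                        length.out = 9),
                 gradients = c("uniform", "gradient"),
                 zetas = c(0.2, 1, 2),
                 axes = c("roll", "pitch", "yaw"),
                 n_random = 20)
  )
}

.merge_config <- function(defaults, user, path = "") {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown configuration key%s: %s",
                 if (length(unknown) > 1) "s" else "",
                 paste0(path, unknown, collapse = ", ")))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      if (!is.list(user[[k]]))
        stop(sprintf("configuration key %s%s must be a mapping", path, k))
      defaults[[k]] <- .merge_config(defaults[[k]], user[[k]],
                                     paste0(path, k, "."))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Load and validate an experiment configuration
#'
#' Reads a YAML file, fills unset keys from [default_config()], rejects
#' unknown keys, and validates every block by constructing the
#' corresponding parameter objects.  An empty (or missing) file yields
#' the defaults.
#'
#' @param path path to a YAML file, or `NULL` for pure defaults.
#' @return validated nested configuration list (class
#'   `experiment_config`), with the constructed parameter objects in
#'   attribute `"objects"`.
#' @export
load_config <- function(path = NULL) {
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("configuration file not found: ", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  cfg <- .merge_config(default_config(), user)
  objects <- config_objects(cfg)   # constructors validate every field
  structure(cfg, class = "experiment_config", objects = objects)
}

#' Construct parameter objects from a configuration
#'
#' @param cfg configuration list (as from [load_config()]).
#' @return list with `spec` ([wing_spec()]), `kin` ([kinematics()]),
#'   `enc` ([encoding_params()]), `sp` ([sspoc_params()]) and the raw
#'   `simulation` and `sweep` blocks.
#' @export
config_objects <- function(cfg) {
  w <- cfg$wing
  k <- cfg$kinematics
  e <- cfg$encoding
  s <- cfg$sspoc
  sim <- cfg$simulation
  stopifnot(sim$dt > 0, sim$n_cycles >= 3, sim$nx >= 2, sim$ny >= 2)
  list(
    spec = wing_spec(span = w$span, chord = w$chord,
                     thickness = w$thickness, density = w$density,
                     poisson = w$poisson, E_mean = w$E_mean,
                     gradient = w$gradient, decline_x = w$decline_x,
                     decline_y = w$decline_y, zeta = w$zeta),
    kin = kinematics(A1 = k$A1, A2 = k$A2, f1 = k$f1, f2 = k$f2,
                     rotation_axis = k$rotation_axis,
                     rotation_rate = k$rotation_rate,
                     ramp_cycles = k$ramp_cycles),
    enc = encoding_params(omega = e$omega, tau = e$tau, delta = e$delta,
                          alpha = e$alpha, beta = e$beta,
                          refractory = e$refractory, bin = e$bin,
                          n_trials = e$n_trials, seed = e$seed,
                          gain = e$gain),
    sp = sspoc_params(n_basis = s$n_basis, lam = s$lam,
                      n_sensors = s$n_sensors, train_frac = s$train_frac,
                      n_iterations = s$n_iterations, seed = s$seed),
    simulation = sim,
    sweep = cfg$sweep
  )
}

#' Write a configuration to YAML
#'
#' @param cfg configuration list.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}
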