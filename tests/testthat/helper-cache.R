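# Shared lazily-computed simulations so expensive plate runs are done
# once per test session.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache))
    assign(key, expr, envir = .sim_cache)
  get(key, envir = .sim_cache)
}

# coarse-mesh wing pair (flap / flap+yaw) for fast pipeline tests
tiny_pair <- function() {
  cached("tiny_pair", {
    fx <- make_fixture("tiny-plate")
    s0 <- suppressWarnings(simulate_strain(fx$spec,
                                           kinematics(rotation_axis = "none"),
                                           n_cycles = 8, nx = fx$nx,
                                           ny = fx$ny))
    s1 <- suppressWarnings(simulate_strain(fx$spec,
                                           kinematics(rotation_axis = "yaw"),
                                           n_cycles = 8, nx = fx$nx,
                                           ny = fx$ny))
    list(s0 = s0, s1 = s1)
  })
}

# production-mesh gradient wing pair at the headline configuration
# (E_mean = 3 GPa, zeta = 2, yaw at 1 rad/s)
headline_pair <- function() {
  cached("headline_pair", {
    spec <- wing_spec(gradient = "gradient", E_mean = 3e9, zeta = 2)
    s0 <- simulate_strain(spec, kinematics(rotation_axis = "none"),
                          n_cycles = 8)
    s1 <- simulate_strain(spec, kinematics(rotation_axis = "yaw",
                                           rotation_rate = 1),
                          n_cycles = 8)
    list(s0 = s0, s1 = s1)
  })
}
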