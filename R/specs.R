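#' Wing specification
#'
#' Geometry, material constants, stiffness-gradient parameters and damping
#' ratio of the rectangular plate wing.  Defaults describe a hawkmoth-scale
#' wing: a 25 mm x 50 mm plate, 127 um thick, density 1180 kg/m^3,
#' Poisson ratio 0.35 and a mean Young's modulus of 3 GPa.
#'
#' For `gradient = "gradient"` wings the Young's modulus decays
#' log-linearly from the leading-edge base corner (stiffest, at X = Y = 0)
#' to the trailing-edge tip corner, with log10 decline rates `decline_x`
#' and `decline_y` (per metre) along span and chord.  The default rate of
#' 26.67 in both directions yields two orders of magnitude between the
#' stiffest and most compliant corners.
#'
#' @param span spanwise length in metres (clamped base at X = 0).
#' @param chord chordwise length in metres (leading edge at Y = 0).
#' @param thickness plate thickness in metres.
#' @param density material density, kg/m^3.
#' @param poisson Poisson ratio, in (0, 0.5).
#' @param E_mean mean Young's modulus in Pa.
#' @param gradient `"uniform"` or `"gradient"`.
#' @param decline_x,decline_y log10 decline rates (1/m); ignored (treated
#'   as zero) for uniform wings.
#' @param zeta damping ratio (0.2 underdamped, 1 critical, 2 overdamped).
#' @return An object of class `wing_spec`.
#' @export
wing_spec <- function(span = 0.05, chord = 0.025, thickness = 127e-6,
                      density = 1180, poisson = 0.35, E_mean = 3e9,
                      gradient = c("gradient", "uniform"),
                      decline_x = 26.67, decline_y = 26.67, zeta = 2) {
  gradient <- match.arg(gradient)
  stopifnot(
    "lengths must be strictly positive" =
      span > 0 && chord > 0 && thickness > 0,
    "density must be strictly positive" = density > 0,
    "E_mean must be strictly positive" = is.finite(E_mean) && E_mean > 0,
    "poisson must lie in (0, 0.5)" = poisson > 0 && poisson < 0.5,
    "zeta must be non-negative" = zeta >= 0
  )
  if (gradient == "uniform") {
    decline_x <- 0
    decline_y <- 0
  }
  structure(
    list(span = span, chord = chord, thickness = thickness,
         density = density, poisson = poisson, E_mean = E_mean,
         gradient = gradient, decline_x = decline_x, decline_y = decline_y,
         zeta = zeta),
    class = "wing_spec"
  )
}

#' @export
print.wing_spec <- function(x, ...) {
  cat(sprintf(
    "<wing_spec> %g x %g mm plate, h = %g um, E_mean = %g GPa (%s), zeta = %g\n",
    x$span * 1e3, x$chord * 1e3, x$thickness * 1e6, x$E_mean / 1e9,
    x$gradient, x$zeta))
  invisible(x)
}

#' Flapping and rotation kinematics
#'
#' The flapping angle is the sum of two harmonics,
#' `phi(t) = A1 sin(2 pi f1 t) + A2 sin(2 pi f2 t)`, giving a 40 ms
#' wingbeat at the default 25 Hz fundamental.  An optional constant-rate
#' body rotation about the roll, pitch or yaw axis is ramped in smoothly
#' over `ramp_cycles` wingbeats.
#'
#' @param A1,A2 harmonic amplitudes in radians.
#' @param f1,f2 harmonic frequencies in Hz (`f2 = 2 f1` keeps the stroke
#'   periodic in one wingbeat).
#' @param rotation_axis one of `"none"`, `"roll"`, `"pitch"`, `"yaw"`.
#' @param rotation_rate body rotation rate in rad/s.
#' @param ramp_cycles number of wingbeats over which the rotation rate is
#'   ramped from zero to `rotation_rate` (half-cosine ramp).
#' @return An object of class `kinematics`.
#' @export
kinematics <- function(A1 = pi / 12, A2 = pi / 60, f1 = 25, f2 = 50,
                       rotation_axis = c("none", "roll", "pitch", "yaw"),
                       rotation_rate = 1.0, ramp_cycles = 1) {
  rotation_axis <- match.arg(rotation_axis)
  stopifnot(
    "frequencies must be positive" = f1 > 0 && f2 > 0,
    "rotation_rate must be non-negative" = rotation_rate >= 0,
    "ramp_cycles must be >= 1" = ramp_cycles >= 1
  )
  structure(
    list(A1 = A1, A2 = A2, f1 = f1, f2 = f2,
         rotation_axis = rotation_axis,
         rotation_rate = if (rotation_axis == "none") 0 else rotation_rate,
         ramp_cycles = ramp_cycles,
         period = 1 / f1),
    class = "kinematics"
  )
}

#' @export
print.kinematics <- function(x, ...) {
  cat(sprintf(
    "<kinematics> A1 = %.4f rad @ %g Hz, A2 = %.4f rad @ %g Hz, rotation %s",
    x$A1, x$f1, x$A2, x$f2, x$rotation_axis))
  if (x$rotation_axis != "none")
    cat(sprintf(" @ %g rad/s (ramp %g cycle)", x$rotation_rate, x$ramp_cycles))
  cat("\n")
  invisible(x)
}

#' Flapping angle and its time derivatives
#'
#' @param t time in seconds (vectorized).
#' @param kin a [kinematics()] object.
#' @param deriv 0 for the angle, 1 or 2 for its analytic time derivatives.
#' @return angle (rad), angular velocity (rad/s) or acceleration (rad/s^2).
#' @export
flap_angle <- function(t, kin, deriv = 0) {
  stopifnot(all(t >= 0), deriv %in% 0:2)
  w1 <- 2 * pi * kin$f1
  w2 <- 2 * pi * kin$f2
  switch(as.character(deriv),
    "0" = kin$A1 * sin(w1 * t) + kin$A2 * sin(w2 * t),
    "1" = kin$A1 * w1 * cos(w1 * t) + kin$A2 * w2 * cos(w2 * t),
    "2" = -kin$A1 * w1^2 * sin(w1 * t) - kin$A2 * w2^2 * sin(w2 * t)
  )
}

#' Body rotation rate profile (half-cosine ramp)
#'
#' Rotation rate and angular acceleration of the ramped body rotation at
#' time `t`.  The rate rises from 0 to `rotation_rate` over
#' `ramp_cycles` wingbeats along a half-cosine, which keeps the angular
#' acceleration continuous at both ends of the ramp.
#'
#' @inheritParams flap_angle
#' @return list with vectors `rate` (rad/s) and `accel` (rad/s^2).
#' @export
rotation_profile <- function(t, kin) {
  Tr <- kin$ramp_cycles * kin$period
  Om <- kin$rotation_rate
  ramp <- ifelse(t < Tr, 0.5 * (1 - cos(pi * t / Tr)), 1)
  dramp <- ifelse(t < Tr, 0.5 * pi / Tr * sin(pi * t / Tr), 0)
  list(rate = Om * ramp, accel = Om * dramp)
}
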