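## Rigid-frame kinematics of the flapping, rotating wing.
##
## Wing frame: x spanwise (clamped base at x = 0), y chordwise, z normal.
## Body frame: x_b forward (roll axis), y_b lateral (pitch axis), z_b up
## (yaw axis).  At zero flap angle the span lies along y_b and the chord
## along -x_b; flapping is a rotation about the body roll axis x_b, so
## the flap axis expressed in the wing frame is -e_y at all times.
## All inertial loads are evaluated in the wing frame, where the plate
## is at rest up to its elastic deflection.

.axis_vec <- function(axis) {
  switch(axis,
         roll  = c(1, 0, 0),
         pitch = c(0, 1, 0),
         yaw   = c(0, 0, 1),
         none  = c(0, 0, 0))
}

.rot_x <- function(phi) {
  c_ <- cos(phi); s_ <- sin(phi)
  matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3)
}

# constant permutation: columns are the wing basis vectors in body coords
.P_wb <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)

#' Angular velocity and acceleration of the wing frame
#'
#' Total angular velocity and acceleration of the wing-attached frame
#' (flapping plus ramped body rotation), expressed in wing coordinates,
#' together with the coefficients of the rigid-body acceleration field
#' at a material point `(X, Y, 0)` of the undeformed plate:
#' transverse `a_z = cX * X + cY * Y` and in-plane
#' `a_x = axx * X + axy * Y`, `a_y = ayx * X + ayy * Y`.
#'
#' @param t time in seconds (scalar).
#' @param kin a [kinematics()] object.
#' @return list with `omega`, `alpha` (length-3, wing frame) and load
#'   coefficients `cX`, `cY`, `axx`, `axy`, `ayx`, `ayy` (SI units).
#' @export
frame_rates <- function(t, kin) {
  phi <- flap_angle(t, kin, 0)
  dphi <- flap_angle(t, kin, 1)
  ddphi <- flap_angle(t, kin, 2)
  rot <- rotation_profile(t, kin)
  ea <- .axis_vec(kin$rotation_axis)
  xb <- c(1, 0, 0)
  omega_b <- rot$rate * ea + dphi * xb
  alpha_b <- rot$accel * ea + ddphi * xb +
    rot$rate * dphi * c(0, ea[3], -ea[2])     # rate * (ea x xb)
  R_bw <- .rot_x(phi) %*% .P_wb
  omega <- as.numeric(crossprod(R_bw, omega_b))
  alpha <- as.numeric(crossprod(R_bw, alpha_b))
  list(
    omega = omega, alpha = alpha,
    cX = -alpha[2] + omega[3] * omega[1],
    cY =  alpha[1] + omega[3] * omega[2],
    axx = -(omega[2]^2 + omega[3]^2),
    axy = -alpha[3] + omega[1] * omega[2],
    ayx =  alpha[3] + omega[1] * omega[2],
    ayy = -(omega[1]^2 + omega[3]^2)
  )
}
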