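## Quasi-static plane-stress membrane companion problem.
##
## The in-plane inertial body forces of the prescribed motion (and the
## Coriolis force on the transverse elastic velocity) load the wing in
## its own plane.  Membrane natural frequencies sit far above the
## flapping band, so the in-plane response is solved quasi-statically at
## each step with bilinear quadrilateral elements, clamped along the
## wing base.  The resulting stress resultants N_x, N_y, N_xy feed the
## transverse geometric coupling load in the plate integrator.

.q4_unit_stiffness <- function(a, b, poisson) {
  # plane-stress Q4 stiffness for E = 1, unit thickness; DOFs
  # (u1,v1,...,u4,v4), nodes (0,0),(a,0),(a,b),(0,b)
  D <- matrix(c(1, poisson, 0, poisson, 1, 0, 0, 0, (1 - poisson) / 2),
              3, 3) / (1 - poisson^2)
  gp <- c(-1, 1) / sqrt(3)
  K <- matrix(0, 8, 8)
  for (xi in gp) for (eta in gp) {
    # shape derivatives on [-1,1]^2 mapped to a x b
    dNdxi <- c(-(1 - eta), (1 - eta), (1 + eta), -(1 + eta)) / 4
    dNdeta <- c(-(1 - xi), -(1 + xi), (1 + xi), (1 - xi)) / 4
    dNdx <- dNdxi * 2 / a
    dNdy <- dNdeta * 2 / b
    B <- matrix(0, 3, 8)
    B[1, seq(1, 8, 2)] <- dNdx
    B[2, seq(2, 8, 2)] <- dNdy
    B[3, seq(1, 8, 2)] <- dNdy
    B[3, seq(2, 8, 2)] <- dNdx
    K <- K + (a * b / 4) * crossprod(B, D %*% B)
  }
  K
}

#' Assemble the clamped membrane (in-plane) system
#'
#' Plane-stress stiffness of the wing on the same mesh and stiffness
#' field as the plate problem, with `u = v = 0` along the wing base.
#'
#' @param stiffness a `stiffness_field`.
#' @return list with the free-DOF sparse stiffness, index bookkeeping
#'   and nodal area weights.
#' @keywords internal
assemble_membrane <- function(stiffness) {
  mesh <- stiffness$mesh
  spec <- stiffness$spec
  Ku <- .q4_unit_stiffness(mesh$dx, mesh$dy, spec$poisson) * spec$thickness
  nxn <- mesh$nx + 1
  ei <- rep(seq_len(mesh$nx), times = mesh$ny)
  ej <- rep(seq_len(mesh$ny), each = mesh$nx)
  n1 <- (ej - 1) * nxn + ei
  nodes4 <- cbind(n1, n1 + 1, n1 + nxn + 1, n1 + nxn)
  edof <- matrix(0L, nrow = length(n1), ncol = 8)
  for (k in 1:4) {
    edof[, 2 * k - 1] <- 2L * (nodes4[, k] - 1L) + 1L
    edof[, 2 * k]     <- 2L * (nodes4[, k] - 1L) + 2L
  }
  ii <- rep(seq_len(8), times = 8)
  jj <- rep(seq_len(8), each = 8)
  n_dof <- 2L * mesh$n_nodes
  K <- Matrix::sparseMatrix(i = as.vector(t(edof[, ii])),
                            j = as.vector(t(edof[, jj])),
                            x = as.vector(outer(as.vector(Ku),
                                                stiffness$E_elem)),
                            dims = c(n_dof, n_dof))
  clamped_nodes <- which(mesh$X == 0)
  clamped <- as.vector(vapply(clamped_nodes,
                              function(n) 2L * (n - 1L) + 1:2, integer(2)))
  free <- setdiff(seq_len(n_dof), clamped)
  area <- rep(mesh$dx * mesh$dy, mesh$n_nodes)
  gi <- ((seq_len(mesh$n_nodes) - 1) %% nxn) + 1
  gj <- ((seq_len(mesh$n_nodes) - 1) %/% nxn) + 1
  area[gi == 1 | gi == nxn] <- area[gi == 1 | gi == nxn] / 2
  area[gj == 1 | gj == mesh$ny + 1] <- area[gj == 1 | gj == mesh$ny + 1] / 2
  list(K = Matrix::forceSymmetric(K[free, free]), free = free,
       n_dof = n_dof, area = area)
}

#' Membrane stress resultants for a nodal in-plane force field
#'
#' Solves the quasi-static membrane problem for body force per area
#' `(fx, fy)` given at the nodes and returns nodal stress resultants
#' (N/m) by finite differences of the displacement field.
#'
#' @param mem an [assemble_membrane()] result (with Cholesky factor
#'   attached as `chol`).
#' @param stiffness the `stiffness_field`.
#' @param fx,fy nodal force-per-area grids ((nx+1) x (ny+1) matrices).
#' @return list of (nx+1) x (ny+1) matrices `Nx`, `Ny`, `Nxy`.
#' @keywords internal
membrane_resultants <- function(mem, stiffness, fx, fy) {
  mesh <- stiffness$mesh
  F <- numeric(mem$n_dof)
  idx_u <- seq(1, mem$n_dof, by = 2)
  F[idx_u] <- as.vector(fx) * mem$area
  F[idx_u + 1] <- as.vector(fy) * mem$area
  sol <- numeric(mem$n_dof)
  sol[mem$free] <- as.numeric(Matrix::solve(mem$chol, F[mem$free]))
  nxn <- mesh$nx + 1
  nyn <- mesh$ny + 1
  u <- matrix(sol[idx_u], nxn, nyn)
  v <- matrix(sol[idx_u + 1], nxn, nyn)
  exx <- .ddx(u, mesh$dx)
  eyy <- .ddy(v, mesh$dy)
  gxy <- .ddy(u, mesh$dy) + .ddx(v, mesh$dx)
  spec <- stiffness$spec
  Emat <- matrix(stiffness$E, nxn, nyn)
  fac <- spec$thickness * Emat / (1 - spec$poisson^2)
  list(Nx = fac * (exx + spec$poisson * eyy),
       Ny = fac * (eyy + spec$poisson * exx),
       Nxy = fac * (1 - spec$poisson) / 2 * gxy)
}
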