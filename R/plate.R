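## Kirchhoff-Love plate bending discretized with the classic 12-DOF
## non-conforming rectangular element (ACM).  DOFs per node: (w, dw/dx,
## dw/dy).  All elements of a mesh share one unit stiffness/mass matrix;
## per-element flexural rigidity scales the stiffness entries, so
## variable-stiffness plates assemble as cheaply as uniform ones.

# monomial exponents of the 12-term ACM polynomial basis
.acm_pows <- cbind(
  px = c(0, 1, 0, 2, 1, 0, 3, 2, 1, 0, 3, 1),
  py = c(0, 0, 1, 0, 1, 2, 0, 1, 2, 3, 1, 3)
)

.poly_eval <- function(x, y, dx = 0, dy = 0) {
  # value of d^(dx+dy) basis / dx^dx dy^dy at (x, y), all 12 monomials
  px <- .acm_pows[, 1]
  py <- .acm_pows[, 2]
  cx <- ifelse(px >= dx, choose(px, dx) * factorial(dx), 0)
  cy <- ifelse(py >= dy, choose(py, dy) * factorial(dy), 0)
  ex <- pmax(px - dx, 0)
  ey <- pmax(py - dy, 0)
  cx * cy * x^ex * y^ey
}

.gauss_legendre <- function(n, a, b) {
  # nodes/weights on [a, b]; Golub-Welsch on the Jacobi matrix
  i <- seq_len(n - 1)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- beta
  J[cbind(i + 1, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  list(x = (b - a) / 2 * x + (a + b) / 2, w = (b - a) / 2 * w)
}

#' Unit element matrices of the ACM plate bending element
#'
#' Stiffness for unit flexural rigidity and mass for unit surface density
#' on an `a` x `b` rectangle, by Gauss quadrature of the 12 cubic shape
#' functions.  DOF order: node-major, (w, wx, wy) per node, nodes at
#' (0,0), (a,0), (a,b), (0,b).
#'
#' @param a,b element side lengths (m), span- and chordwise.
#' @param poisson Poisson ratio.
#' @return list with 12 x 12 matrices `K` (per unit rigidity D) and `M`
#'   (per unit rho*h).
#' @keywords internal
acm_element <- function(a, b, poisson) {
  corners <- rbind(c(0, 0), c(a, 0), c(a, b), c(0, b))
  A <- matrix(0, 12, 12)
  for (k in 1:4) {
    A[3 * k - 2, ] <- .poly_eval(corners[k, 1], corners[k, 2], 0, 0)
    A[3 * k - 1, ] <- .poly_eval(corners[k, 1], corners[k, 2], 1, 0)
    A[3 * k, ]     <- .poly_eval(corners[k, 1], corners[k, 2], 0, 1)
  }
  Cinv <- solve(A)  # columns map polynomial coeffs -> DOFs; N = p %*% Cinv
  gx <- .gauss_legendre(5, 0, a)
  gy <- .gauss_legendre(5, 0, b)
  Dhat <- matrix(c(1, poisson, 0, poisson, 1, 0, 0, 0, (1 - poisson) / 2),
                 3, 3)
  K <- matrix(0, 12, 12)
  M <- matrix(0, 12, 12)
  for (ix in seq_along(gx$x)) {
    for (iy in seq_along(gy$x)) {
      wq <- gx$w[ix] * gy$w[iy]
      x <- gx$x[ix]; y <- gy$x[iy]
      N <- .poly_eval(x, y, 0, 0) %*% Cinv
      B <- rbind(.poly_eval(x, y, 2, 0) %*% Cinv,
                 .poly_eval(x, y, 0, 2) %*% Cinv,
                 2 * (.poly_eval(x, y, 1, 1) %*% Cinv))
      K <- K + wq * crossprod(B, Dhat %*% B)
      M <- M + wq * crossprod(N)
    }
  }
  list(K = K, M = M)
}

#' Assemble the clamped plate system
#'
#' Builds sparse stiffness and consistent mass matrices for the wing
#' plate on the mesh of a [build_stiffness_field()], with the wing-base
#' edge (X = 0) fully clamped and the other three edges free.
#'
#' @param stiffness a `stiffness_field`.
#' @return list with free-DOF sparse matrices `K`, `M`, index bookkeeping
#'   (`free`, `n_dof`), and unit element matrices.
#' @export
assemble_plate <- function(stiffness) {
  mesh <- stiffness$mesh
  spec <- stiffness$spec
  elem <- acm_element(mesh$dx, mesh$dy, spec$poisson)
  h <- spec$thickness
  D_el <- stiffness$E_elem * h^3 / (12 * (1 - spec$poisson^2))
  rho_h <- spec$density * h

  nxn <- mesh$nx + 1
  # element -> 4 corner node ids (ccw from lower-left), span-fastest order
  ei <- rep(seq_len(mesh$nx), times = mesh$ny)
  ej <- rep(seq_len(mesh$ny), each = mesh$nx)
  n1 <- (ej - 1) * nxn + ei
  nodes4 <- cbind(n1, n1 + 1, n1 + nxn + 1, n1 + nxn)
  # DOF indices, 12 per element
  edof <- matrix(0L, nrow = length(n1), ncol = 12)
  for (k in 1:4) {
    edof[, 3 * k - 2] <- 3L * (nodes4[, k] - 1L) + 1L
    edof[, 3 * k - 1] <- 3L * (nodes4[, k] - 1L) + 2L
    edof[, 3 * k]     <- 3L * (nodes4[, k] - 1L) + 3L
  }
  ii <- rep(seq_len(12), times = 12)
  jj <- rep(seq_len(12), each = 12)
  rows <- as.vector(t(edof[, ii]))
  cols <- as.vector(t(edof[, jj]))
  # triplets are element-major with the 144 (ii, jj) entries fastest,
  # matching the layout of rows/cols above
  kvals <- as.vector(outer(as.vector(elem$K), D_el))
  mvals <- rep(as.vector(elem$M) * rho_h, times = length(n1))
  n_dof <- 3L * mesh$n_nodes
  K <- Matrix::sparseMatrix(i = rows, j = cols, x = kvals,
                            dims = c(n_dof, n_dof))
  M <- Matrix::sparseMatrix(i = rows, j = cols, x = mvals,
                            dims = c(n_dof, n_dof))
  clamped_nodes <- which(mesh$X == 0)
  clamped <- as.vector(vapply(clamped_nodes,
                              function(n) 3L * (n - 1L) + 1:3, integer(3)))
  free <- setdiff(seq_len(n_dof), clamped)
  list(K = Matrix::forceSymmetric(K[free, free]),
       M = Matrix::forceSymmetric(M[free, free]),
       free = free, n_dof = n_dof, mesh = mesh, spec = spec,
       elem = elem)
}

#' First structural eigenfrequency and mode shape
#'
#' Smallest eigenfrequency of the undamped clamped-free plate, by inverse
#' power iteration on the generalized problem `K v = lambda M v` using a
#' sparse Cholesky factor of `K`.
#'
#' @param spec a [wing_spec()].
#' @param stiffness optional `stiffness_field` (built from `spec` if missing).
#' @param nx,ny mesh used when `stiffness` is missing.
#' @param tol relative convergence tolerance on the eigenvalue.
#' @return list with `omega_n` (rad/s), `freq` (Hz), and the full-grid
#'   deflection `mode` (one value per node, unit max amplitude).
#' @export
eigenfrequency <- function(spec, stiffness = NULL, nx = 50, ny = 25,
                           tol = 1e-10) {
  if (is.null(stiffness))
    stiffness <- build_stiffness_field(spec, plate_mesh(spec, nx, ny))
  sys <- assemble_plate(stiffness)
  ch <- tryCatch(Matrix::Cholesky(sys$K, LDL = FALSE),
                 error = function(e)
                   stop("numerical assembly error: stiffness matrix is not SPD: ",
                        conditionMessage(e)))
  x <- rep(1, nrow(sys$K))
  lam_old <- Inf
  for (it in 1:200) {
    y <- as.numeric(Matrix::solve(ch, sys$M %*% x))
    mu <- sqrt(sum(y * as.numeric(sys$M %*% y)))
    x <- y / mu
    lam <- sum(x * as.numeric(sys$K %*% x)) / sum(x * as.numeric(sys$M %*% x))
    if (is.finite(lam_old) && abs(lam - lam_old) <= tol * lam) break
    lam_old <- lam
  }
  omega_n <- sqrt(lam)
  mode_full <- numeric(sys$n_dof)
  mode_full[sys$free] <- x
  w_node <- mode_full[seq(1, sys$n_dof, by = 3)]
  w_node <- w_node / max(abs(w_node))
  list(omega_n = omega_n, freq = omega_n / (2 * pi), mode = w_node,
       iterations = it)
}

#' Damping specification
#'
#' Total viscous damping coefficient `c = 2 zeta m omega_n`, with the
#' plate mass `m = span * chord * thickness * density`.  In the time
#' integrator the total is distributed over the plate proportionally to
#' local mass (mass-proportional damping `C = (c / m) M`), so the summed
#' damping force on any rigid-body velocity `V` is exactly `-c V`.
#'
#' @param zeta damping ratio.
#' @param mass plate mass in kg.
#' @param omega_n first natural frequency in rad/s.
#' @return object of class `damping_spec` with fields `c`, `zeta`,
#'   `mass`, `omega_n`.
#' @export
damping_coefficient <- function(zeta, mass, omega_n) {
  stopifnot(zeta >= 0, mass >= 0, omega_n >= 0)
  structure(
    list(c = 2 * zeta * mass * omega_n, zeta = zeta, mass = mass,
         omega_n = omega_n),
    class = "damping_spec"
  )
}

#' Plate mass from a wing specification
#' @param spec a [wing_spec()].
#' @return mass in kg.
#' @export
wing_mass <- function(spec) {
  spec$span * spec$chord * spec$thickness * spec$density
}
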