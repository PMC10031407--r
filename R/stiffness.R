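#' Node grid of the wing plate
#'
#' Regular node grid of a `nx` x `ny` element mesh of the plate
#' (`nx` elements along the span, `ny` along the chord), so
#' `(nx + 1) * (ny + 1)` nodes.  With the default 50 x 25 mesh the nodes
#' fall every 1 mm and coincide with the candidate sensor sites.
#' Nodes are ordered span-fastest: node `(i, j)` (span index `i`,
#' chord index `j`) has linear index `(j - 1) * (nx + 1) + i`.
#'
#' @param spec a [wing_spec()].
#' @param nx,ny number of elements along span and chord.
#' @return list with node coordinates `X`, `Y` (length-n vectors, metres),
#'   mesh sizes and index helpers.
#' @export
plate_mesh <- function(spec, nx = 50, ny = 25) {
  stopifnot(nx >= 2, ny >= 2)
  xs <- seq(0, spec$span, length.out = nx + 1)
  ys <- seq(0, spec$chord, length.out = ny + 1)
  X <- rep(xs, times = ny + 1)
  Y <- rep(ys, each = nx + 1)
  list(nx = nx, ny = ny, dx = spec$span / nx, dy = spec$chord / ny,
       xs = xs, ys = ys, X = X, Y = Y,
       n_nodes = (nx + 1) * (ny + 1))
}

#' Spatial Young's modulus field
#'
#' Evaluates the stiffness field on the node grid.  Gradient wings follow
#' a log-linear decay `E(X, Y) = E_mean * 10^(-mx X) 10^(-my Y) / Z`
#' where the normalizer `Z` is the discrete mean of
#' `10^(-mx x) 10^(-my y)` over the grid, so the discrete mean of `E`
#' equals `E_mean` exactly.  The maximum sits at the leading-edge base
#' corner (X = Y = 0) and the minimum at the trailing-edge tip corner.
#'
#' @param spec a [wing_spec()].
#' @param mesh a [plate_mesh()]; defaults to the 50 x 25 element mesh.
#' @return object of class `stiffness_field`: node values `E` (Pa), the
#'   element-centroid values `E_elem` used for assembly, and the mesh.
#' @export
build_stiffness_field <- function(spec, mesh = plate_mesh(spec)) {
  if (!is.finite(spec$E_mean) || spec$E_mean <= 0)
    stop("invalid parameter: E_mean must be positive and finite")
  shape <- function(X, Y) 10^(-spec$decline_x * X - spec$decline_y * Y)
  raw <- shape(mesh$X, mesh$Y)
  Z <- mean(raw)
  E <- spec$E_mean * raw / Z
  # element centroid values share the node-grid normalizer so that the
  # assembled plate represents the same field
  xc <- (mesh$xs[-1] + mesh$xs[-(mesh$nx + 1)]) / 2
  yc <- (mesh$ys[-1] + mesh$ys[-(mesh$ny + 1)]) / 2
  E_elem <- spec$E_mean * shape(rep(xc, times = mesh$ny),
                                rep(yc, each = mesh$nx)) / Z
  structure(
    list(E = E, E_elem = E_elem, mesh = mesh, spec = spec),
    class = "stiffness_field"
  )
}

#' @export
print.stiffness_field <- function(x, ...) {
  cat(sprintf(
    "<stiffness_field> %d nodes, E in [%.3g, %.3g] Pa, mean %.4g Pa\n",
    length(x$E), min(x$E), max(x$E), mean(x$E)))
  invisible(x)
}
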