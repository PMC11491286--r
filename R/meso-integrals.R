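#' Column connection-density integrals
#'
#' Evaluates the two cylindrical integrals that split an area's local synapses
#' into those with presynaptic neuron inside the simulated column
#' (`rho_internal`) and those with presynaptic neuron in the remainder of the
#' area (`rho_external`). The spatial connection probability is an isotropic
#' 3D exponential with decay constant `lambda_conn`; the column is a cylinder
#' of surface `column_area`, the area a concentric cylinder of surface
#' `area_surface`, both of height `h`. After analytic reduction of the
#' azimuthal and vertical difference coordinates the integrals are
#'
#' \deqn{\rho \propto 4 \int dr_1 \int_0^{r_{col}} dr_2\, r_1 r_2
#'   \int_0^{2\pi} d\phi (2\pi - \phi) \int_0^h dz (h - z)
#'   e^{-d(r_1, r_2, \phi, z)/\lambda},}
#'
#' with \eqn{d = \sqrt{r_1^2 - 2 r_1 r_2 \cos\phi + r_2^2 + z^2}}, the outer
#' radial coordinate running over \eqn{[0, r_{col}]} for `rho_internal` and
#' over \eqn{[r_{col}, r_{area}]} for `rho_external`. They are evaluated by
#' panelled Gauss-Legendre quadrature (panels concentrated within a few decay
#' lengths of the kernel peak) with a node-refinement convergence check.
#' Both values share one proportionality constant, so only their ratio is
#' meaningful; it feeds the internal/external synapse split.
#'
#' @param h column height (total cortical thickness), mm; must be positive.
#' @param area_surface area surface, mm^2 (>= `column_area`).
#' @param lambda_conn exponential decay constant, mm.
#' @param column_area column surface, mm^2.
#' @param rel_tol relative convergence tolerance of the refinement check.
#' @return A list with `rho_internal` and `rho_external` (unnormalized).
#' @export
#' @examples
#' column_density_integrals(2, 1000, 0.16, 1)
column_density_integrals <- function(h, area_surface, lambda_conn = 0.160,
                                     column_area = 1.0, rel_tol = 1e-3) {
  if (h <= 0) stop("column height h must be positive")
  if (lambda_conn <= 0) stop("lambda_conn must be positive")
  if (area_surface < column_area) {
    stop("area_surface must be at least column_area")
  }
  r_col <- sqrt(column_area / pi)
  r_area <- sqrt(area_surface / pi)

  eval_pair <- function(refine) {
    # the kernel has a ridge of width ~lambda along r1 = r2: radial node
    # counts must grow when lambda << r_col
    nr <- ceiling(min(120, max(24, 3 * r_col / lambda_conn)) * refine)
    nphi <- ceiling(16 * refine)
    nz <- ceiling(20 * refine)
    r2_full <- gl_panels(c(0, r_col), nr)
    # concentrate panels near phi = 0 and 2*pi (cos is symmetric) and z = 0
    phi_scale <- min(pi / 2, max(lambda_conn / r_col, 0.05))
    phi <- gl_panels(sort(unique(pmin(pmax(
      c(0, phi_scale, 6 * phi_scale, pi,
        2 * pi - 6 * phi_scale, 2 * pi - phi_scale, 2 * pi), 0), 2 * pi))),
      nphi)
    z <- gl_panels(sort(unique(pmin(
      c(0, 5 * lambda_conn, 25 * lambda_conn, h), h))), nz)
    rho_i <- quad_cell(r2_full, r2_full, phi, z, h, lambda_conn)
    if (r_area > r_col) {
      r1_ext <- gl_panels(sort(unique(pmin(
        r_col + c(0, 5 * lambda_conn, 25 * lambda_conn, r_area - r_col),
        r_area))), ceiling(24 * refine))
      # for the external domain only r2 near the column boundary contributes
      r2_ext <- gl_panels(sort(unique(pmax(
        r_col - c(r_col, 25 * lambda_conn, 5 * lambda_conn, 0), 0))),
        ceiling(24 * refine))
      rho_e <- quad_cell(r1_ext, r2_ext, phi, z, h, lambda_conn)
    } else {
      rho_e <- 0
    }
    c(rho_i, rho_e)
  }

  coarse <- eval_pair(1)
  fine <- eval_pair(1.5)
  err <- abs(fine - coarse) / pmax(abs(fine), .Machine$double.xmin)
  # rho_external may be relatively tiny; judge it against the pair scale too
  err_ok <- (err <= rel_tol) | (abs(fine - coarse) <= rel_tol * max(abs(fine)))
  if (!all(err_ok)) {
    stop(sprintf(
      "column density quadrature did not converge: achieved relative error %.2e (tolerance %.0e)",
      max(err), rel_tol
    ))
  }
  list(rho_internal = fine[1], rho_external = fine[2])
}

# Gauss-Legendre nodes/weights over a panelled interval. `breaks` is a sorted
# vector of panel edges; zero-width panels are dropped.
gl_panels <- function(breaks, n_per_panel) {
  nodes <- numeric(0)
  weights <- numeric(0)
  for (i in seq_len(length(breaks) - 1L)) {
    a <- breaks[i]
    b <- breaks[i + 1L]
    if (b - a <= 0) next
    gl <- pracma::gaussLegendre(n_per_panel, a, b)
    nodes <- c(nodes, gl$x)
    weights <- c(weights, gl$w)
  }
  list(x = nodes, w = weights)
}

# Weighted sum of the reduced 4D kernel over a tensor grid (compiled kernel).
quad_cell <- function(r1, r2, phi, z, h, lambda) {
  cpp_quad_kernel(r1$x, r1$w, r2$x, r2$w, phi$x, phi$w, z$x, z$w, h, lambda)
}
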