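#' Mesh specification for the axisymmetric indentation model
#'
#' Structured mesh of the soft-tissue cylinder (radius and height
#' `r_c_mm = 110` mm) as solved in the axisymmetric plane: `10 N` quadratic
#' elements in the radial and `5 N` in the axial direction, graded with a
#' density bias of 1.1 towards the center (finer near the axis) and 0.8
#' towards the top (finer under the contact surface). At the reference
#' refinement `N = 3` this gives the 30 x 15 quadratic-element layout used
#' throughout the parameter identification.
#'
#' @param N Mesh refinement factor (>= 1).
#' @param r_c_mm Cylinder radius = tip radius + 100 mm.
#' @param height_mm Cylinder height.
#' @param bias_radial Mesh density bias towards the center: the ratio of
#'   successive radial element widths (outward) of the reference 30 x 15
#'   layout. Other refinements subdivide the same grading.
#' @param bias_axial Mesh density bias towards the top: the ratio of
#'   successive axial element heights (upward) of the reference layout;
#'   values < 1 refine towards the contact surface.
#' @return A list of class `mesh_spec`.
#' @export
mesh_spec <- function(N = 3L, r_c_mm = 110, height_mm = 110,
                      bias_radial = 1.1, bias_axial = 0.8) {
  assert_that(N >= 1, "refinement factor must be >= 1")
  structure(
    list(N = as.integer(N), r_c_mm = r_c_mm, height_mm = height_mm,
         n_radial = 10L * as.integer(N), n_axial = 5L * as.integer(N),
         bias_radial = bias_radial, bias_axial = bias_axial),
    class = "mesh_spec"
  )
}

# graded 1D partition: n geometric widths with total last/first size ratio
# `total_ratio`, summing to L. Keeping the total ratio fixed across n means
# every refinement subdivides the same grading function, which is what a
# mesh-convergence family requires.
graded_breaks <- function(L, n, total_ratio) {
  r <- if (n > 1L) total_ratio^(1 / (n - 1L)) else 1
  w <- r^(seq_len(n) - 1L)
  w <- w / sum(w) * L
  assert_that(all(w > 0), "bias produced inverted elements")
  c(0, cumsum(w))
}

#' Build the structured axisymmetric Q8 mesh
#'
#' Generates nodes, 8-node serendipity quadrilateral connectivity and the
#' node sets of the indentation model: `axis` (radial constraint), `bottom`
#' (vertical constraint), `top` (contact surface) and the ordered top-edge
#' nodes used by the surface objective.
#'
#' @param spec A [mesh_spec()].
#' @return A list of class `fe_mesh`: `nodes` (n x 2 matrix, columns R and
#'   Z), `conn` (n_el x 8, 1-based), `sets` (node index vectors), and
#'   `top_edges` (3-column matrix of edge node triples along the top
#'   surface, ordered inner to outer).
#' @export
#' @examples
#' m <- build_mesh(mesh_spec(N = 3))
#' nrow(m$conn) # 450 elements
build_mesh <- function(spec = mesh_spec()) {
  stopifnot(inherits(spec, "mesh_spec"))
  nr <- spec$n_radial; nz <- spec$n_axial
  # the density biases are per-element size ratios of the reference 30 x 15
  # layout (N = 3); refinements subdivide that same grading, so the total
  # first-to-last ratio is what stays fixed across N
  rb <- graded_breaks(spec$r_c_mm, nr, spec$bias_radial^29)
  zb <- graded_breaks(spec$height_mm, nz, spec$bias_axial^14)
  # lattice including midside positions
  rl <- numeric(2L * nr + 1L); zl <- numeric(2L * nz + 1L)
  rl[2L * (0:nr) + 1L] <- rb
  rl[2L * seq_len(nr)] <- (rb[-1] + rb[-length(rb)]) / 2
  zl[2L * (0:nz) + 1L] <- zb
  zl[2L * seq_len(nz)] <- (zb[-1] + zb[-length(zb)]) / 2
  ni <- 2L * nr + 1L; nj <- 2L * nz + 1L
  # serendipity lattice: drop element-center positions (both indices odd,
  # 0-based), number the rest
  idx <- matrix(0L, ni, nj)
  count <- 0L
  for (j in seq_len(nj)) {
    for (i in seq_len(ni)) {
      if ((i %% 2L == 0L) && (j %% 2L == 0L)) next  # 0-based odd,odd
      count <- count + 1L
      idx[i, j] <- count
    }
  }
  nodes <- matrix(0, count, 2L)
  for (j in seq_len(nj)) for (i in seq_len(ni)) {
    k <- idx[i, j]
    if (k > 0L) { nodes[k, 1L] <- rl[i]; nodes[k, 2L] <- zl[j] }
  }
  conn <- matrix(0L, nr * nz, 8L)
  e <- 0L
  for (ej in seq_len(nz)) {
    for (ei in seq_len(nr)) {
      e <- e + 1L
      i0 <- 2L * (ei - 1L) + 1L; j0 <- 2L * (ej - 1L) + 1L
      conn[e, ] <- c(idx[i0, j0], idx[i0 + 2L, j0], idx[i0 + 2L, j0 + 2L],
                     idx[i0, j0 + 2L], idx[i0 + 1L, j0], idx[i0 + 2L, j0 + 1L],
                     idx[i0 + 1L, j0 + 2L], idx[i0, j0 + 1L])
    }
  }
  jt <- nj
  top <- idx[, jt][idx[, jt] > 0L]
  top <- top[order(nodes[top, 1L])]
  top_edges <- t(vapply(seq_len(nr), function(ei) {
    i0 <- 2L * (ei - 1L) + 1L
    c(idx[i0, jt], idx[i0 + 1L, jt], idx[i0 + 2L, jt])
  }, integer(3L)))
  sets <- list(
    axis = idx[1L, ][idx[1L, ] > 0L],
    bottom = idx[, 1L][idx[, 1L] > 0L],
    top = top
  )
  structure(
    list(nodes = nodes, conn = conn, sets = sets, top_edges = top_edges,
         spec = spec),
    class = "fe_mesh"
  )
}

#' @export
print.fe_mesh <- function(x, ...) {
  cat(sprintf(
    "<fe_mesh> N = %d: %d x %d Q8 elements (%d), %d nodes, r_C = %g mm\n",
    x$spec$N, x$spec$n_radial, x$spec$n_axial, nrow(x$conn), nrow(x$nodes),
    x$spec$r_c_mm))
  invisible(x)
}

#' First-order Ogden material parameters
#'
#' Parameter set `p = (c, m)` of the uncoupled first-order Ogden strain
#' energy density
#' `Psi = (c/m^2) * sum_i (lambda_tilde_i^m - 1) + (kappa/2) * ln(J)^2`,
#' with deviatoric principal stretches `lambda_tilde_i`, volume ratio `J`
#' and the bulk-like modulus `kappa = 2e3 * c` enforcing nearly isochoric
#' deformation unless overridden.
#'
#' @param c_kpa Stress-like parameter `c` in kPa (> 0).
#' @param m Dimensionless nonlinearity exponent (>= 1).
#' @param kappa_kpa Bulk-like modulus in kPa; default `2000 * c_kpa`.
#' @return An object of class `ogden_params`.
#' @export
ogden_params <- function(c_kpa, m, kappa_kpa = 2000 * c_kpa) {
  assert_that(c_kpa > 0, "c must be positive")
  assert_that(m >= 1, "m must be >= 1")
  structure(list(c_kpa = c_kpa, m = m, kappa_kpa = kappa_kpa),
            class = "ogden_params")
}

#' @export
print.ogden_params <- function(x, ...) {
  cat(sprintf("<ogden_params> c = %g kPa, m = %g, kappa = %g kPa\n",
              x$c_kpa, x$m, x$kappa_kpa))
  invisible(x)
}

#' Ogden Cauchy stress at a material point
#'
#' Evaluates the Cauchy stress, Kirchhoff principal stresses and strain
#' energy density of the uncoupled first-order Ogden model for an arbitrary
#' deformation gradient. Intended for material-point verification and
#' small-strain calibration; the FE solver evaluates the same routine at
#' its integration points.
#'
#' @param params An [ogden_params()].
#' @param F 3x3 deformation gradient with positive determinant.
#' @return A list: `sigma` (3x3 Cauchy stress, kPa), `tau` (principal
#'   Kirchhoff stresses), `psi` (strain energy density, kPa), `J`.
#' @export
ogden_stress <- function(params, F) {
  stopifnot(inherits(params, "ogden_params"))
  F <- as.matrix(F)
  assert_that(all(dim(F) == c(3, 3)), "F must be 3x3")
  assert_that(det(F) > 0, "det(F) must be positive")
  ogden_stress_cpp(F, params$c_kpa, params$m, params$kappa_kpa)
}

#' Small-strain elastic constants of an Ogden parameter set
#'
#' Numerically measures the small-strain shear modulus by probing
#' [ogden_stress()] with an infinitesimal simple shear, and derives the
#' effective Poisson ratio and indentation modulus `E* = E / (1 - nu^2)`
#' from it together with the bulk-like modulus. Used by the Hertzian
#' contact cross-check of the forward model.
#'
#' @param params An [ogden_params()].
#' @param gamma Probe shear strain.
#' @return A list: `mu_kpa`, `nu`, `e_kpa`, `e_star_kpa`.
#' @export
small_strain_moduli <- function(params, gamma = 1e-6) {
  F <- diag(3); F[1, 2] <- gamma
  s <- ogden_stress(params, F)
  mu <- s$sigma[1, 2] / gamma
  k <- params$kappa_kpa
  nu <- (3 * k - 2 * mu) / (2 * (3 * k + mu))
  e <- 2 * mu * (1 + nu)
  list(mu_kpa = mu, nu = nu, e_kpa = e, e_star_kpa = e / (1 - nu^2))
}
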