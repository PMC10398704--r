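# Brute-force validation oracles.
#
# Two independent routes to the same interaction energy: direct 4-D
# quadrature of the primitive double-surface integral (no angular reduction,
# no hypergeometric kernel), and a pairwise sum over discrete atomistic
# lattices.  Both are deliberately slow and are meant for small geometries
# only.

#' Four-dimensional quadrature of the primitive surface integral
#'
#' Evaluates the continuum interaction energy directly as
#' \deqn{E = \eta_C \eta_w\, b_1 b_2 \int_0^L\!\!\int_{-d}^{d}\!\!\int_0^{2\pi}\!\!\int_0^{2\pi}
#'   \left(-\frac{A_{cw}}{\rho^6} + \frac{B_{cw}}{\rho^{12}}\right)
#'   d\theta_1\, d\theta_2\, dz_2\, dz_1,}
#' with \eqn{\rho} computed from the raw cylindrical coordinates.  The two
#' axial integrals use nested adaptive quadrature; the two angular integrals
#' use the trapezoidal rule on the periodic torus, refined until converged
#' (spectrally accurate for this smooth periodic integrand).  Nothing is
#' shared with the hypergeometric reduction, so agreement with
#' [total_energy()] validates the whole analytic chain.
#'
#' @inheritParams cyl_integral_i
#' @param rel_tol Relative tolerance of the axial quadratures (default 1e-7).
#' @param n_theta Initial number of angular nodes per dimension (doubled
#'   once and checked for convergence).
#' @return Energy in kcal/mol.
#' @export
#' @examples
#' \donttest{
#' sys <- tube_system(b1 = 6, L = 20)
#' cl <- cluster_cylinder(3, 5, eps_co = 0.040)
#' quad4d_energy(sys, cl, Z = 10)
#' total_energy(sys, cl, Z = 10)
#' }
quad4d_energy <- function(system, cluster, Z, rel_tol = 1e-7, n_theta = 48) {
  stopifnot(inherits(system, "tube_system"), inherits(cluster, "cluster_cylinder"))
  if (system$L > 60)
    stop("quad4d_energy is an oracle for small geometries (L <= 60 A)")
  b1 <- system$b1; b2 <- cluster$b2; L <- system$L; d <- cluster$d
  m <- cluster$medium
  theta_mat <- function(N) {
    th <- 2 * pi * (seq_len(N) - 1) / N
    b1^2 + b2^2 - 2 * b1 * b2 * cos(outer(th, th, `-`))
  }
  # angular double integral of the LJ kernel at squared axial offset w2
  ang <- function(C, w2) {
    r2 <- C + w2
    (2 * pi / nrow(C))^2 * sum(-m$A_cw / r2^3 + m$B_cw / r2^6)
  }
  C1 <- theta_mat(n_theta); C2 <- theta_mat(2L * n_theta)
  # convergence check at the most demanding (smallest-gap) offset
  a1 <- ang(C1, 0.01); a2 <- ang(C2, 0.01)
  C <- if (abs(a1 - a2) <= 1e-9 * abs(a2)) C1 else C2
  inner <- function(z2) {
    f <- function(z1) vapply(z1, function(z) ang(C, (z - z2 - Z)^2), 0)
    stats::integrate(f, 0, L, rel.tol = rel_tol, abs.tol = 1e-13)$value
  }
  val <- stats::integrate(function(z2v) vapply(z2v, inner, 0), -d, d,
                          rel.tol = rel_tol, abs.tol = 1e-13)$value
  system$eta_c * m$eta_w * b1 * b2 * val
}

#' Deterministic atomistic lattice on a cylinder surface
#'
#' Generates a near-uniform point set on the surface of a cylinder at a
#' requested surface density.  `"rings"` places equally spaced rings of
#' equally spaced atoms (every radial distance exactly equal to `radius`);
#' `"fibonacci"` winds a golden-angle helix.  Both are deterministic.
#'
#' @param radius Cylinder radius (A).
#' @param length Cylinder length (A); the lattice spans `z` in
#'   `[0, length]`.
#' @param density Target surface density (atoms/A^2).
#' @param pattern `"rings"` or `"fibonacci"`.
#' @return Object of class `atom_lattice`: list with `coordinates` (N x 3
#'   matrix), `target_density`, `achieved_density`, `radius`, `length`,
#'   `pattern`.
#' @export
#' @examples
#' lat <- make_lattice(13.56, 20, 0.3812)
#' lat$achieved_density
make_lattice <- function(radius, length, density,
                         pattern = c("rings", "fibonacci")) {
  stopifnot(radius > 0, length > 0, density > 0)
  pattern <- match.arg(pattern)
  area <- 2 * pi * radius * length
  if (pattern == "rings") {
    s <- 1 / sqrt(density)                  # nominal lattice spacing
    n_rows <- max(1L, round(length / s))
    n_ring <- max(3L, round(2 * pi * radius / s))
    z <- (seq_len(n_rows) - 0.5) * length / n_rows
    th <- 2 * pi * (seq_len(n_ring) - 1) / n_ring
    coords <- cbind(
      x = radius * rep(cos(th), times = n_rows),
      y = radius * rep(sin(th), times = n_rows),
      z = rep(z, each = n_ring))
  } else {
    n <- max(3L, round(density * area))
    k <- seq_len(n)
    th <- (2 * pi * (sqrt(5) - 1) / 2) * k
    z <- (k - 0.5) * length / n
    coords <- cbind(x = radius * cos(th), y = radius * sin(th), z = z)
  }
  structure(list(coordinates = coords, target_density = density,
                 achieved_density = nrow(coords) / area,
                 radius = radius, length = length, pattern = pattern),
            class = "atom_lattice")
}

#' Pairwise Lennard-Jones sum over two lattices
#'
#' \eqn{\sum_{i,j} (-A/\rho_{ij}^6 + B/\rho_{ij}^{12})} over all atom pairs
#' between two disjoint lattices.  Normalised by the per-atom surface
#' densities this Riemann sum converges to the continuum surface integral as
#' the lattice spacing shrinks.
#'
#' @param lattice_a,lattice_b `atom_lattice` objects (or N x 3 coordinate
#'   matrices).
#' @param A,B Attractive and repulsive constants (kcal A^6/mol,
#'   kcal A^12/mol).
#' @param min_dist Minimum allowed inter-set distance (default 0.5 A); a
#'   closer pair indicates a fixture bug (the repulsive term blows up) and
#'   raises an error.
#' @return Energy in kcal/mol (per pair of discrete structures).
#' @export
pairwise_sum <- function(lattice_a, lattice_b, A, B, min_dist = 0.5) {
  pa <- if (inherits(lattice_a, "atom_lattice")) lattice_a$coordinates else lattice_a
  pb <- if (inherits(lattice_b, "atom_lattice")) lattice_b$coordinates else lattice_b
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), `+`) - 2 * tcrossprod(pa, pb)
  d2[d2 < 0] <- 0
  if (min(d2) < min_dist^2)
    stop(sprintf("lattices approach within %.3f A (< %g A): near-contact pair",
                 sqrt(min(d2)), min_dist))
  sum(-A / d2^3 + B / d2^6)
}

#' Write a lattice in XYZ format
#'
#' Standard XYZ text format: atom count, comment line, then one
#' `element x y z` row per atom.
#'
#' @param lattice An `atom_lattice`.
#' @param path Output file path.
#' @param element Element symbol for the atom column (default `"C"`).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(lattice, path, element = "C") {
  co <- lattice$coordinates
  lines <- c(
    nrow(co),
    sprintf("cylinder lattice r=%g L=%g density=%g pattern=%s",
            lattice$radius, lattice$length, lattice$achieved_density,
            lattice$pattern),
    sprintf("%s %.6f %.6f %.6f", element, co[, 1], co[, 2], co[, 3]))
  writeLines(lines, path)
  invisible(path)
}
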