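# Continuum interaction energy between the tube and the cluster.
#
# After the angular reduction (kernel_j), the remaining work is the double
# axial integral
#
#   I_n(Z) = 4 pi^2 b1 b2 int_{-d}^{d} int_0^{L}
#              (alpha + beta)^(-n) 2F1(n, 1/2; 1; beta/(alpha+beta)) dz1 dz2,
#
# evaluated by nested adaptive Gauss-Kronrod quadrature (z1 inner, z2 outer).
# The inner integrand depends on z1 only through w = z1 - z2 - Z and decays
# like |w|^(-2n+1), so the inner range is split at w = 0 whenever the peak
# lies inside it.

#' Axial surface integral of the inverse-power kernel
#'
#' Evaluates \eqn{I_n(Z)}, the cylinder-cylinder surface integral of
#' \eqn{\rho^{-2n}} with both angular dimensions reduced to the closed
#' hypergeometric kernel ([kernel_j()]), by nested adaptive quadrature over
#' the two axial coordinates.
#'
#' @param system A [tube_system()].
#' @param cluster A [cluster_cylinder()].
#' @param Z Axial position of the cluster centre (A).
#' @param n Inverse-power index, 3 or 6.
#' @param rel_tol Relative quadrature tolerance (default 1e-8, absolute
#'   floor 1e-14).
#' @return The value of \eqn{I_n} in A^(4-2n).
#' @export
#' @examples
#' sys <- tube_system(b1 = 6, L = 20)
#' cl <- cluster_cylinder(3, 5, eps_co = 0.040)
#' cyl_integral_i(sys, cl, Z = 10, n = 3)
cyl_integral_i <- function(system, cluster, Z, n, rel_tol = 1e-8) {
  stopifnot(inherits(system, "tube_system"), inherits(cluster, "cluster_cylinder"))
  check_clearance(system, cluster)
  b1 <- system$b1; b2 <- cluster$b2; L <- system$L; d <- cluster$d
  beta <- 4 * b1 * b2
  gap2 <- (b1 - b2)^2
  kern <- function(w) kernel_j(gap2 + w^2, beta, n)
  quad <- function(f, lo, hi) {
    r <- stats::integrate(f, lo, hi, rel.tol = rel_tol, abs.tol = 1e-14,
                          stop.on.error = FALSE)
    if (r$message != "OK")
      stop(sprintf("axial quadrature failed (%s); abs.error %.3e",
                   r$message, r$abs.error))
    r$value
  }
  inner <- function(z2) {            # integrate z1 over [0, L]
    lo <- -z2 - Z; hi <- L - z2 - Z  # in w = z1 - z2 - Z
    if (lo < 0 && hi > 0) quad(kern, lo, 0) + quad(kern, 0, hi)
    else quad(kern, lo, hi)
  }
  outer_val <- quad(function(z2v) vapply(z2v, inner, 0), -d, d)
  # kernel_j carries the 2*pi of the reduced angle; the trivially integrated
  # second angle contributes the remaining 2*pi
  2 * pi * b1 * b2 * outer_val
}

#' Continuum interaction energy of the nested cylinders
#'
#' Total Lennard-Jones interaction energy between the carbon nanotube and the
#' water cluster centred at axial position `Z`,
#' \deqn{E(Z) = \eta_C\,\eta_{H_2O}\,(-A_{cw} I_3(Z) + B_{cw} I_6(Z)),}
#' with the composite carbon-water constants of the cluster's
#' [water_medium()].
#'
#' @inheritParams cyl_integral_i
#' @return Energy in kcal/mol (negative when attraction dominates).
#' @export
#' @examples
#' sys <- tube_system()
#' cl <- cluster_cylinder(10.40, 15, eps_co = 0.040)
#' total_energy(sys, cl, Z = 250)
total_energy <- function(system, cluster, Z, rel_tol = 1e-8) {
  m <- cluster$medium
  system$eta_c * m$eta_w *
    (-m$A_cw * cyl_integral_i(system, cluster, Z, 3L, rel_tol) +
       m$B_cw * cyl_integral_i(system, cluster, Z, 6L, rel_tol))
}

#' Energy profile along the tube axis
#'
#' Evaluates [total_energy()] on a grid of cluster-centre positions.
#'
#' @inheritParams cyl_integral_i
#' @param Z_grid Monotone numeric vector of centre positions (A).
#' @return A data frame of class `energy_profile` with columns `Z` (A) and
#'   `E` (kcal/mol).
#' @export
energy_profile <- function(system, cluster, Z_grid, rel_tol = 1e-8) {
  if (is.unsorted(Z_grid) && is.unsorted(rev(Z_grid)))
    stop("'Z_grid' must be monotone")
  E <- vapply(Z_grid, function(z) total_energy(system, cluster, z, rel_tol), 0)
  structure(data.frame(Z = Z_grid, E = E),
            class = c("energy_profile", "data.frame"),
            system = system, cluster = cluster)
}

#' Write or read an energy profile as CSV
#'
#' The on-disk contract is a two-column CSV with header
#' `Z_angstrom,E_kcal_per_mol`.
#'
#' @param profile An `energy_profile`.
#' @param path File path.
#' @return `write_energy_profile` returns `path` invisibly;
#'   `read_energy_profile` returns an `energy_profile`.
#' @export
write_energy_profile <- function(profile, path) {
  df <- data.frame(Z_angstrom = profile$Z, E_kcal_per_mol = profile$E)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_energy_profile
#' @export
read_energy_profile <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(identical(names(df), c("Z_angstrom", "E_kcal_per_mol")))
  structure(data.frame(Z = df$Z_angstrom, E = df$E_kcal_per_mol),
            class = c("energy_profile", "data.frame"))
}
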