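# Physical constants and unit conversions.
#
# Internal unit system: lengths in angstrom (A), times in femtosecond (fs),
# energies in kcal/mol.  Dynamics converts forces to newton and masses to kg;
# 1 A/fs = 1e5 m/s.

#' Unit conversion constants
#'
#' Conversion factors used throughout the package: the thermochemical calorie
#' (1 kcal = 4184 J), the Avogadro constant, the force conversion
#' 1 (kcal/mol)/A = 6.9477e-11 N, and the velocity conversion
#' 1 A/fs = 1e5 m/s.
#'
#' @format A named list with elements `kcal_J` (J per kcal), `avogadro`
#'   (1/mol), `force_si_per_model` (N per (kcal/mol)/A), `energy_si_per_model`
#'   (J per kcal/mol), `velocity_si_per_model` (m/s per A/fs), and
#'   `water_density` (g/cm^3).
#' @export
#' @examples
#' cnt_units$force_si_per_model # 6.9477e-11
cnt_units <- local({
  kcal_J <- 4184
  avogadro <- 6.02214076e23
  list(
    kcal_J = kcal_J,
    avogadro = avogadro,
    energy_si_per_model = kcal_J / avogadro,          # J per kcal/mol
    force_si_per_model = 6.9477e-11,                  # N per (kcal/mol)/A
    velocity_si_per_model = 1e5,                      # m/s per A/fs
    water_density = 1                                  # g/cm^3
  )
})

#' Lennard-Jones atom-pair constants
#'
#' Builds a Lennard-Jones pair from the well depth \eqn{\epsilon} and the van
#' der Waals diameter \eqn{\sigma}, with the attractive and repulsive
#' constants \eqn{A = 2\epsilon\sigma^6} and \eqn{B = \epsilon\sigma^{12}}.
#' With these constants the pair potential \eqn{-A/\rho^6 + B/\rho^{12}} has
#' its minimum at \eqn{\rho = \sigma} with depth \eqn{-\epsilon}.
#'
#' @param epsilon Well depth in kcal/mol (> 0).
#' @param sigma Van der Waals diameter in angstrom (> 0).
#' @return An object of class `lj_pair`: a list with fields `epsilon`,
#'   `sigma`, `A` (kcal A^6/mol), `B` (kcal A^12/mol).
#' @export
#' @examples
#' lj_pair(0.07937, 3.6755) # carbon-oxygen
lj_pair <- function(epsilon, sigma) {
  if (!is.finite(epsilon) || epsilon <= 0)
    stop("'epsilon' must be a positive finite number")
  if (!is.finite(sigma) || sigma <= 0)
    stop("'sigma' must be a positive finite number")
  structure(
    list(epsilon = epsilon, sigma = sigma,
         A = 2 * epsilon * sigma^6, B = epsilon * sigma^12),
    class = "lj_pair"
  )
}

#' @export
print.lj_pair <- function(x, ...) {
  cat(sprintf(
    "Lennard-Jones pair: epsilon = %g kcal/mol, sigma = %g A\n  A = %g kcal A^6/mol, B = %g kcal A^12/mol\n",
    x$epsilon, x$sigma, x$A, x$B))
  invisible(x)
}

#' Lorentz-Berthelot mixing of two Lennard-Jones pairs
#'
#' Combines two like-atom pairs into a cross pair with the standard mixing
#' rules: geometric mean of the well depths,
#' \eqn{\epsilon_{12} = \sqrt{\epsilon_1\epsilon_2}}, and arithmetic mean of
#' the diameters, \eqn{\sigma_{12} = (\sigma_1 + \sigma_2)/2}.
#'
#' @param pair_a,pair_b Objects of class `lj_pair`.
#' @return An `lj_pair` for the mixed interaction.
#' @export
#' @examples
#' lj_mix(lj_pair(1, 2), lj_pair(4, 4)) # epsilon 2, sigma 3
lj_mix <- function(pair_a, pair_b) {
  stopifnot(inherits(pair_a, "lj_pair"), inherits(pair_b, "lj_pair"))
  lj_pair(sqrt(pair_a$epsilon * pair_b$epsilon),
          (pair_a$sigma + pair_b$sigma) / 2)
}

#' Mean atomic surface density of a spherical molecule
#'
#' Number of atoms divided by the surface area of the sphere,
#' `n_atoms / (4 pi radius^2)`.  Modelling one water molecule as a sphere of
#' radius equal to the O-H bond length (0.9584 A) carrying its three atoms
#' gives the water surface density 0.2599 atom/A^2.
#'
#' @param radius Sphere radius in angstrom (> 0).
#' @param n_atoms Number of atoms on the sphere (>= 1).
#' @return Surface density in atoms/A^2.
#' @export
#' @examples
#' sphere_density(0.9584, 3) # ~ 0.2599
sphere_density <- function(radius, n_atoms = 3) {
  if (!is.finite(radius) || radius <= 0) stop("'radius' must be positive")
  if (n_atoms < 1) stop("'n_atoms' must be >= 1")
  n_atoms / (4 * pi * radius^2)
}

#' Composite water-medium interaction constants
#'
#' A water molecule carries two hydrogen and one oxygen atom, so the
#' effective carbon-water attractive and repulsive constants are the
#' number-weighted means \eqn{A_{cw} = (2 A_{C-H} + A_{C-O})/3} and likewise
#' for \eqn{B_{cw}}.  The weights act on `A` and `B` directly (not on
#' \eqn{\epsilon,\sigma}) because the continuum energy is linear in `A` and
#' `B`, and the water surface density already counts three atoms per
#' molecule.
#'
#' @param pair_ch `lj_pair` for carbon-hydrogen.
#' @param pair_co `lj_pair` for carbon-oxygen.
#' @param eta_w Water surface density in atoms/A^2; defaults to the
#'   three-atom sphere value of [sphere_density()].
#' @return An object of class `water_medium`: list with `A_cw`, `B_cw`
#'   (kcal A^6/mol, kcal A^12/mol), `eta_w`, `h_fraction`, `o_fraction`.
#' @export
#' @examples
#' water_medium(lj_pair(0.06797, 3.3685), lj_pair(0.07937, 3.6755))
water_medium <- function(pair_ch, pair_co, eta_w = sphere_density(0.9584, 3)) {
  stopifnot(inherits(pair_ch, "lj_pair"), inherits(pair_co, "lj_pair"))
  if (eta_w <= 0) stop("'eta_w' must be positive")
  structure(
    list(A_cw = (2 * pair_ch$A + pair_co$A) / 3,
         B_cw = (2 * pair_ch$B + pair_co$B) / 3,
         eta_w = eta_w, h_fraction = 2 / 3, o_fraction = 1 / 3),
    class = "water_medium"
  )
}

#' @export
print.water_medium <- function(x, ...) {
  cat(sprintf(
    "Water medium: A_cw = %g kcal A^6/mol, B_cw = %g kcal A^12/mol, eta_w = %g atom/A^2\n",
    x$A_cw, x$B_cw, x$eta_w))
  invisible(x)
}

#' Mass of a cylindrical water cluster
#'
#' Mass of a solid cylinder of radius `b2` and length `2 d` at the bulk water
#' density, in kilograms.
#'
#' @param b2 Cluster radius in angstrom.
#' @param d Cluster half-length in angstrom.
#' @param density Mass density in g/cm^3 (default 1, bulk water).
#' @return Mass in kg.
#' @export
#' @examples
#' cluster_mass(10.40, 15) # ~ 1.0193e-23 kg
cluster_mass <- function(b2, d, density = cnt_units$water_density) {
  stopifnot(b2 > 0, d > 0, density > 0)
  # A^3 -> cm^3 is 1e-24; g -> kg is 1e-3
  density * pi * b2^2 * (2 * d) * 1e-27
}

#' Convert a model-unit force to SI
#'
#' Multiplies a force in (kcal/mol)/A by 6.9477e-11 to obtain newtons.
#'
#' @param f_model Force in (kcal/mol)/A.
#' @return Force in N.
#' @export
force_to_si <- function(f_model) f_model * cnt_units$force_si_per_model

#' Default interaction constants of the water/carbon-nanotube system
#'
#' Reads the shipped constants file (`extdata/constants.yaml`) holding the
#' carbon-hydrogen and carbon-oxygen Lennard-Jones parameters, the carbon and
#' water surface densities, and the default tube geometry, then assembles the
#' derived pairs and composite water medium.  The carbon-oxygen well depth
#' `eps_co` is the wettability knob of the model: when it is varied every
#' other constant (including \eqn{\sigma_{C-O}} and both surface densities)
#' stays fixed.
#'
#' @param eps_co Carbon-oxygen well depth in kcal/mol.  Defaults to the
#'   tabulated force-field value 0.07937; the wettability studies vary it
#'   over 0.04-0.16.
#' @return A list with `pair_ch`, `pair_co` (`lj_pair`), `medium`
#'   (`water_medium`), `eta_c` (atoms/A^2), `eps_co`, and the default tube
#'   geometry `b1`, `L` (A).
#' @export
#' @examples
#' cnt_constants(eps_co = 0.040)$medium
cnt_constants <- function(eps_co = NULL) {
  path <- system.file("extdata", "constants.yaml", package = "cntflow")
  cfg <- yaml::read_yaml(path)
  if (is.null(eps_co)) eps_co <- cfg$pairs$CO$epsilon
  pair_ch <- lj_pair(cfg$pairs$CH$epsilon, cfg$pairs$CH$sigma)
  pair_co <- lj_pair(eps_co, cfg$pairs$CO$sigma)
  eta_w <- sphere_density(cfg$water$sphere_radius, cfg$water$atoms_per_molecule)
  list(pair_ch = pair_ch, pair_co = pair_co,
       medium = water_medium(pair_ch, pair_co, eta_w),
       eta_c = cfg$densities$eta_c, eps_co = eps_co,
       b1 = cfg$tube$b1, L = cfg$tube$L)
}
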