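# Suction energy, optimal cluster radii, and the axial force.

#' Suction energy of the cluster
#'
#' Total work done by the van der Waals force on the cluster as it moves from
#' far outside the tube to the tube centre, \eqn{W = E(\mathrm{outside}) -
#' E(\mathrm{centred})}.  Because the energy is normalised to zero at
#' infinite separation and the tube (L = 500 A) is much longer than the
#' cluster, the interior energy is flat and \eqn{W = -E(L/2)} is the
#' numerically stable equivalent of the limit definition.  A positive `W`
#' means the cluster is spontaneously sucked into the tube.
#'
#' @inheritParams cyl_integral_i
#' @return Suction energy in kcal/mol.
#' @export
#' @examples
#' suction_energy(tube_system(), cluster_cylinder(10.40, 15, eps_co = 0.040))
suction_energy <- function(system, cluster, rel_tol = 1e-8) {
  -total_energy(system, cluster, system$L / 2, rel_tol)
}

# W as a function of b2, everything else fixed
suction_of_b2 <- function(system, d, eps_co, rel_tol = 1e-8) {
  medium <- cnt_constants(eps_co)$medium
  function(b2) suction_energy(system, cluster_cylinder(b2, d, medium), rel_tol)
}

#' Largest encapsulatable cluster radius
#'
#' Finds \eqn{b_2^\circ}, the root of \eqn{W(b_2) = 0}: the largest cluster
#' radius that the tube can still take up (clusters with larger radii have
#' negative suction energy and will not enter).
#'
#' @param system A [tube_system()].
#' @param d Cluster half-length (A).
#' @param eps_co Carbon-oxygen well depth (kcal/mol).
#' @param bracket Search interval for `b2`; default `(0.5 b1, b1 - 1)`.
#' @param tol Root tolerance in A (default 1e-3).
#' @return \eqn{b_2^\circ} in angstrom.
#' @export
#' @examples
#' \donttest{find_b2_zero(tube_system(), d = 15, eps_co = 0.040) # ~ 10.90}
find_b2_zero <- function(system, d, eps_co,
                         bracket = c(0.5 * system$b1, system$b1 - 1),
                         tol = 1e-3) {
  W <- suction_of_b2(system, d, eps_co)
  w_lo <- W(bracket[1]); w_hi <- W(bracket[2])
  if (sign(w_lo) == sign(w_hi))
    stop(sprintf("no sign change of W on [%g, %g]: W = %.4g and %.4g",
                 bracket[1], bracket[2], w_lo, w_hi))
  stats::uniroot(W, bracket, f.lower = w_lo, f.upper = w_hi, tol = tol)$root
}

#' Suction-optimal cluster radius
#'
#' Finds \eqn{b_2^*}, the cluster radius maximising the suction energy (and
#' hence the transport velocity), by golden-section search after a coarse
#' scan verifying that `W` is unimodal on the bracket.
#'
#' @inheritParams find_b2_zero
#' @param n_scan Number of coarse-scan points used for the unimodality check.
#' @return A list with `b2_star` (A) and `W_max` (kcal/mol).
#' @export
#' @examples
#' \donttest{find_b2_star(tube_system(), d = 15, eps_co = 0.040) # ~ 10.47}
find_b2_star <- function(system, d, eps_co,
                         bracket = c(0.5 * system$b1, system$b1 - 1),
                         tol = 1e-3, n_scan = 17) {
  W <- suction_of_b2(system, d, eps_co)
  grid <- seq(bracket[1], bracket[2], length.out = n_scan)
  wg <- vapply(grid, W, 0)
  peaks <- which(diff(sign(diff(wg))) == -2) + 1
  if (length(peaks) > 1)
    stop("W(b2) is not unimodal on the bracket; local maxima near b2 = ",
         paste(sprintf("%.3f", grid[peaks]), collapse = ", "))
  k <- which.max(wg)
  lo <- grid[max(1, k - 1)]; hi <- grid[min(n_scan, k + 1)]
  opt <- stats::optimize(W, c(lo, hi), maximum = TRUE, tol = tol)
  list(b2_star = opt$maximum, W_max = opt$objective)
}

#' Suction-energy scan over the cluster radius
#'
#' Convenience wrapper producing the `W(b2)` curve together with the two
#' characteristic radii and wall gaps
#' \eqn{\delta_0 = b_1 - b_2^\circ}, \eqn{\delta_{max} = b_1 - b_2^*}.
#'
#' @inheritParams find_b2_zero
#' @param b2_grid Radii to scan (A).
#' @return A list of class `suction_result`: `scan` (data frame `b2`, `W`),
#'   `b2_zero`, `b2_star`, `W_max`, `delta0`, `delta_max`.
#' @export
suction_scan <- function(system, d, eps_co,
                         b2_grid = seq(0.5 * system$b1, system$b1 - 1,
                                       length.out = 25)) {
  W <- suction_of_b2(system, d, eps_co)
  scan <- data.frame(b2 = b2_grid, W = vapply(b2_grid, W, 0))
  b2_zero <- find_b2_zero(system, d, eps_co)
  star <- find_b2_star(system, d, eps_co)
  structure(list(scan = scan, b2_zero = b2_zero, b2_star = star$b2_star,
                 W_max = star$W_max, delta0 = system$b1 - b2_zero,
                 delta_max = system$b1 - star$b2_star),
            class = "suction_result")
}

#' @export
print.suction_result <- function(x, ...) {
  cat(sprintf(
    "Suction scan: b2_zero = %.3f A (delta0 = %.2f), b2_star = %.3f A (delta_max = %.2f), W_max = %.2f kcal/mol\n",
    x$b2_zero, x$delta0, x$b2_star, x$delta_max, x$W_max))
  invisible(x)
}

#' Axial force profile
#'
#' Central-difference derivative \eqn{F_z(Z) = -\partial E/\partial Z} of an
#' energy profile.  The force vanishes in the tube interior and is
#' concentrated in windows of width `2 d` around the two tube mouths, where
#' it pulls the cluster towards the centre.
#'
#' @param system A [tube_system()].
#' @param cluster A [cluster_cylinder()].
#' @param Z_grid Monotone increasing grid of centre positions (A); spacing
#'   near the tube mouths should be at most 0.5 A.
#' @param rel_tol Quadrature tolerance passed to [total_energy()].
#' @return A data frame of class `force_profile` with columns `Z` (A) and
#'   `F` ((kcal/mol)/A), and attribute `F0` = max |F|.
#' @export
force_profile <- function(system, cluster, Z_grid, rel_tol = 1e-8) {
  d <- cluster$d; L <- system$L
  near_mouth <- (Z_grid > -2 * d & Z_grid < 2 * d) |
    (Z_grid > L - 2 * d & Z_grid < L + 2 * d)
  h <- diff(Z_grid)
  if (any(h[near_mouth[-length(Z_grid)]] > 0.5 + 1e-9))
    warning("grid spacing exceeds 0.5 A near the tube mouths; the force peak may be under-resolved")
  prof <- energy_profile(system, cluster, Z_grid, rel_tol)
  n <- nrow(prof)
  Fz <- numeric(n)
  Fz[2:(n - 1)] <- -(prof$E[3:n] - prof$E[1:(n - 2)]) /
    (Z_grid[3:n] - Z_grid[1:(n - 2)])
  Fz[1] <- -(prof$E[2] - prof$E[1]) / h[1]
  Fz[n] <- -(prof$E[n] - prof$E[n - 1]) / h[n - 1]
  structure(data.frame(Z = Z_grid, F = Fz),
            class = c("force_profile", "data.frame"),
            F0 = max(abs(Fz)), energy = prof)
}

#' Step-function model of the axial force
#'
#' Heaviside approximation of the axial force: the mouth forces are idealised
#' as constant pulls of strength `F0` acting while the cluster straddles a
#' mouth,
#' \deqn{F_z(Z) = F_0\,[H(Z+d) - H(Z-d)] - F_0\,[H(Z-L+d) - H(Z-L-d)],}
#' i.e. `+F0` on the entry window \eqn{Z \in (-d, d)}, `-F0` on the exit
#' window \eqn{Z \in (L-d, L+d)} and zero elsewhere (cluster-centre
#' convention).  With the impulse-matched strength `F0 = W/(2 d)` the work
#' done over a full window equals the suction energy exactly.
#'
#' @param Z Cluster-centre position(s) in A; vectorised.
#' @param F0 Force strength in (kcal/mol)/A (> 0).
#' @param L Tube length (A).
#' @param d Cluster half-length (A).
#' @return Force in (kcal/mol)/A, antisymmetric about `Z = L/2`.
#' @export
#' @examples
#' heaviside_force(c(0, 250, 500), F0 = 14.9, L = 500, d = 15)
heaviside_force <- function(Z, F0, L, d) {
  stopifnot(F0 > 0, L > 0, d > 0)
  step_force(Z, F0, L, d)
}

# signed variant used internally: F0 < 0 (negative suction energy) makes the
# mouth forces repel, which is the correct dynamics for a cluster too wide to
# be taken up
step_force <- function(Z, F0, L, d) {
  # symmetric convention H(0) = 1/2 keeps the force antisymmetric about
  # Z = L/2 including the window edges (and non-zero for a cluster at rest
  # exactly at an edge)
  H <- function(x) 0.5 * (sign(x) + 1)
  F0 * (H(Z + d) - H(Z - d)) - F0 * (H(Z - (L - d)) - H(Z - (L + d)))
}
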