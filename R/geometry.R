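# Geometry containers: the fixed outer tube and the mobile inner cluster.
#
# Coordinate convention used by every public function: the tube occupies
# z in [0, L]; Z is the position of the cluster CENTRE, so the cluster
# occupies [Z - d, Z + d].

#' Carbon nanotube (outer cylinder)
#'
#' @param b1 Tube radius in angstrom (default 13.56, a (20,20) nanotube).
#' @param L Tube length in angstrom (default 500).
#' @param eta_c Atomic surface density in atoms/A^2 (default 0.3812).
#' @return Object of class `tube_system`.
#' @export
#' @examples
#' tube_system()
tube_system <- function(b1 = 13.56, L = 500, eta_c = 0.3812) {
  stopifnot(b1 > 0, L > 0, eta_c > 0)
  structure(list(b1 = b1, L = L, eta_c = eta_c), class = "tube_system")
}

#' @export
print.tube_system <- function(x, ...) {
  cat(sprintf("Carbon nanotube: b1 = %g A, L = %g A, eta_c = %g atom/A^2\n",
              x$b1, x$L, x$eta_c))
  invisible(x)
}

#' Cylindrical water cluster (inner cylinder)
#'
#' @param b2 Cluster radius in angstrom.
#' @param d Cluster half-length in angstrom (full length `2 d`).
#' @param medium A `water_medium` from [water_medium()]; defaults to the
#'   shipped constants with `eps_co` overriding the carbon-oxygen well depth.
#' @param eps_co Optional carbon-oxygen well depth (kcal/mol) used to build
#'   the default medium; ignored when `medium` is supplied.
#' @return Object of class `cluster_cylinder`.
#' @export
#' @examples
#' cluster_cylinder(10.40, 15, eps_co = 0.040)
cluster_cylinder <- function(b2, d, medium = NULL, eps_co = NULL) {
  stopifnot(b2 > 0, d > 0)
  if (is.null(medium)) medium <- cnt_constants(eps_co)$medium
  stopifnot(inherits(medium, "water_medium"))
  structure(list(b2 = b2, d = d, medium = medium), class = "cluster_cylinder")
}

#' @export
print.cluster_cylinder <- function(x, ...) {
  cat(sprintf("Water cluster: b2 = %g A, half-length d = %g A (2d = %g A)\n",
              x$b2, x$d, 2 * x$d))
  invisible(x)
}

# Guard shared by all energy entry points: alpha -> 0 on contact, and the
# repulsive wall dominates physically long before that.
check_clearance <- function(system, cluster, min_gap = 0.5) {
  if (cluster$b2 >= system$b1 - min_gap)
    stop(sprintf(
      "cluster radius b2 = %g is within %g A of the tube wall (b1 = %g); the surface integral is singular on contact",
      cluster$b2, min_gap, system$b1))
  invisible(TRUE)
}
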