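# Wall friction and velocity-Verlet transport dynamics.

#' Interfacial friction coefficient
#'
#' Friction coefficient of the sliding water-carbon interface,
#' \deqn{\lambda(b_2, \epsilon_{C-O}) = \lambda_0\,
#'   (\epsilon_{C-O}/\epsilon_{ref})^2\, (b_2/b_{2,ref}),}
#' in N s/m^3.  The quadratic dependence on the carbon-oxygen well depth
#' follows linear-response friction theory (the wall corrugation felt by the
#' water is proportional to \eqn{\epsilon_{C-O}}, and friction scales with
#' the squared corrugation), and the linear growth with radius reflects the
#' curvature effect: flatter walls (larger radii) bind the first water layer
#' more effectively and exert more friction.  The amplitude
#' \eqn{\lambda_0 = 2600} N s/m^3 at the reference state
#' (\eqn{b_2 = 10.40} A, \eqn{\epsilon_{C-O} = 0.040} kcal/mol) is calibrated
#' so that the reference transport run (2d = 30 A cluster in the 13.56 A,
#' 500 A tube) reproduces the published peak and arrival velocities.
#'
#' @param b2 Cluster radius (A).
#' @param eps_co Carbon-oxygen well depth (kcal/mol).
#' @return Friction coefficient in N s/m^3.
#' @export
#' @examples
#' friction_coefficient(10.40, 0.040) # 2600
friction_coefficient <- function(b2, eps_co) {
  stopifnot(b2 > 0, eps_co > 0)
  cfg <- yaml::read_yaml(system.file("extdata", "constants.yaml",
                                     package = "cntflow"))$friction
  if (eps_co < 0.02 || eps_co > 0.5)
    warning("eps_co outside the studied wettability range [0.02, 0.5] kcal/mol")
  cfg$lambda0 * (eps_co / cfg$eps_ref)^2 * (b2 / cfg$b2_ref)
}

#' Friction model of a cluster-tube contact
#'
#' Bundles the friction coefficient with the contact area
#' \eqn{A_{inter} = 4\pi b_2 d} (the full lateral area of the cluster).
#'
#' @param b2 Cluster radius (A).
#' @param d Cluster half-length (A).
#' @param eps_co Carbon-oxygen well depth (kcal/mol).
#' @return Object of class `friction_model` with `lam` (N s/m^3),
#'   `A_inter` (A^2) and `A_inter_m2` (m^2).
#' @export
friction_model <- function(b2, d, eps_co) {
  A <- 4 * pi * b2 * d
  structure(list(lam = friction_coefficient(b2, eps_co),
                 A_inter = A, A_inter_m2 = A * 1e-20,
                 b2 = b2, d = d, eps_co = eps_co),
            class = "friction_model")
}

#' Frictional force on the moving cluster
#'
#' \eqn{F_f = -\lambda A_{inter} V}, evaluated in SI and returned in model
#' units ((kcal/mol)/A), signed to oppose the motion.
#'
#' @param V Cluster velocity in A/fs.
#' @param model A [friction_model()].
#' @param contact_fraction Fraction of the lateral area in contact with the
#'   tube (1 when the cluster is fully inside).
#' @return Force in (kcal/mol)/A.
#' @export
friction_force <- function(V, model, contact_fraction = 1) {
  f_si <- -model$lam * model$A_inter_m2 * contact_fraction *
    (V * cnt_units$velocity_si_per_model)
  f_si / cnt_units$force_si_per_model
}

#' One velocity-Verlet step
#'
#' Synchronised position/velocity update
#' \deqn{Z' = Z + V\Delta t + \tfrac12 a \Delta t^2, \qquad
#'       V' = V + \tfrac12 (a + a')\Delta t,}
#' with acceleration `a = F/M`.  The force is re-evaluated at the new
#' position (and, for velocity-dependent forces, at the predicted velocity)
#' for the second half of the velocity update.
#'
#' @param Z Position (A).
#' @param V Velocity (A/fs).
#' @param force Function `force(Z, V)` returning the total force in
#'   (kcal/mol)/A.
#' @param M Mass in kg.
#' @param dt Time step in fs.
#' @return List with `Z`, `V`, and the acceleration `a` at the new state
#'   (A/fs^2).
#' @export
verlet_step <- function(Z, V, force, M, dt) {
  stopifnot(dt > 0, M > 0)
  # (kcal/mol)/A -> N -> m/s^2 -> A/fs^2 (1 m/s^2 = 1e-20 A/fs^2)
  acc_scale <- cnt_units$force_si_per_model / M * 1e-20
  a <- force(Z, V) * acc_scale
  Znew <- Z + V * dt + 0.5 * a * dt^2
  a_pred <- force(Znew, V + a * dt) * acc_scale
  Vnew <- V + 0.5 * (a + a_pred) * dt
  a_new <- force(Znew, Vnew) * acc_scale
  list(Z = Znew, V = Vnew, a = a_new)
}

#' Configuration of a transport simulation
#'
#' @param dt Time step in fs (default 1).
#' @param t_max Maximum simulated time in fs (default 2e5 = 200 ps).
#' @param Z0 Initial cluster-centre position in A.  The default 0 places the
#'   centre at the entry mouth (the cluster half-submerged), the convention
#'   under which the reference run reproduces the published peak velocity and
#'   peak time.
#' @param V0 Initial velocity in A/fs (default 0, starting from rest).
#' @param friction_on Apply the wall friction force (default `TRUE`).
#' @param force_mode `"heaviside"` (step-function axial force with
#'   impulse-matched strength `F0 = W/(2d)`, the default) or `"profile"`
#'   (interpolated derivative of the computed energy profile).
#' @param partial_contact Scale the friction by the instantaneous overlap
#'   fraction between cluster and tube during entry/exit (default `TRUE`);
#'   `FALSE` applies full-contact friction whenever any overlap exists.
#' @param record_every Store every k-th step in the returned trajectory
#'   (default 10, i.e. every 10 fs at the default step).
#' @return A list of class `transport_config`.
#' @export
transport_config <- function(dt = 1, t_max = 2e5, Z0 = 0, V0 = 0,
                             friction_on = TRUE,
                             force_mode = c("heaviside", "profile"),
                             partial_contact = TRUE, record_every = 10) {
  stopifnot(dt > 0, t_max > dt)
  structure(list(dt = dt, t_max = t_max, Z0 = Z0, V0 = V0,
                 friction_on = friction_on,
                 force_mode = match.arg(force_mode),
                 partial_contact = partial_contact,
                 record_every = as.integer(record_every)),
            class = "transport_config")
}

# axial force function for the chosen mode, in (kcal/mol)/A
axial_force_fn <- function(system, cluster, config, W = NULL, rel_tol = 1e-8) {
  L <- system$L; d <- cluster$d
  if (is.null(W)) W <- suction_energy(system, cluster, rel_tol)
  if (config$force_mode == "heaviside") {
    F0 <- W / (2 * d)
    list(force = function(Z) step_force(Z, F0, L, d), W = W, F0 = F0)
  } else {
    # resolve the entry peak once; the exit side follows by antisymmetry
    Zg <- seq(-2 * d - 5, 2 * d + 5, by = 0.25)
    fp <- force_profile(system, cluster, Zg, rel_tol)
    f_entry <- stats::approxfun(fp$Z, fp$F, yleft = 0, yright = 0)
    list(force = function(Z) {
      ifelse(Z < L / 2, f_entry(Z), -f_entry(L - Z))
    }, W = W, F0 = attr(fp, "F0"))
  }
}

#' Simulate water-cluster transport through the tube
#'
#' Velocity-Verlet integration of the cluster centre under the axial mouth
#' force and (optionally) the interfacial friction force.  The axial force
#' defaults to the Heaviside step model with impulse-matched strength
#' `F0 = W/(2 d)`, where `W` is the suction energy computed from the
#' continuum model; the friction force is
#' \eqn{-\lambda A_{inter} V} scaled by the instantaneous contact fraction.
#' Integration stops when the cluster leaves the far mouth entirely
#' (`Z >= L + d`) or `t_max` is reached.
#'
#' @param system A [tube_system()].
#' @param cluster A [cluster_cylinder()].
#' @param config A [transport_config()].
#' @param eps_co Carbon-oxygen well depth used for the friction coefficient;
#'   must match the wettability of the cluster's medium.
#' @param W Optional precomputed suction energy (kcal/mol); computed from
#'   the continuum model when missing.
#' @return A data frame of class `cnt_trajectory` with columns `t` (fs),
#'   `Z` (A), `V` (A/fs), and attributes `diagnostics` (see
#'   [analyze_trajectory()]), `W`, `F0`, `M_kg`, and `never_enters` (`TRUE`
#'   with a warning when `W < 0`).
#' @export
#' @examples
#' \donttest{
#' sys <- tube_system()
#' cl <- cluster_cylinder(10.40, 15, eps_co = 0.040)
#' traj <- simulate_transport(sys, cl, transport_config(t_max = 2e4), eps_co = 0.040)
#' attr(traj, "diagnostics")
#' }
simulate_transport <- function(system, cluster, config = transport_config(),
                               eps_co, W = NULL) {
  stopifnot(inherits(config, "transport_config"))
  ax <- axial_force_fn(system, cluster, config, W)
  W <- ax$W
  never_enters <- W < 0
  if (never_enters)
    warning("suction energy is negative: the cluster is not drawn into the tube")
  M <- cluster_mass(cluster$b2, cluster$d)
  fric <- friction_model(cluster$b2, cluster$d, eps_co)
  L <- system$L; d <- cluster$d
  dt <- config$dt
  n <- ceiling(config$t_max / dt)
  acc_scale <- cnt_units$force_si_per_model / M * 1e-20
  fric_scale <- -fric$lam * fric$A_inter_m2 * cnt_units$velocity_si_per_model /
    cnt_units$force_si_per_model   # (kcal/mol)/A per (A/fs), full contact
  axf <- ax$force
  contact <- if (config$partial_contact) {
    function(Z) max(0, min(Z + d, L) - max(Z - d, 0)) / (2 * d)
  } else {
    function(Z) as.numeric(min(Z + d, L) > max(Z - d, 0))
  }
  force <- if (config$friction_on) {
    function(Z, V) axf(Z) + fric_scale * contact(Z) * V
  } else {
    function(Z, V) axf(Z)
  }

  keep <- config$record_every
  m <- n %/% keep + 1L
  ts <- numeric(m); Zs <- numeric(m); Vs <- numeric(m)
  Z <- config$Z0; V <- config$V0
  ts[1] <- 0; Zs[1] <- Z; Vs[1] <- V
  j <- 1L
  Vmax <- V; t_peak <- 0
  t_exit <- NA_real_; V_exit <- NA_real_
  a <- force(Z, V) * acc_scale
  for (k in seq_len(n)) {
    Znew <- Z + V * dt + 0.5 * a * dt^2
    a_pred <- force(Znew, V + a * dt) * acc_scale
    Vnew <- V + 0.5 * (a + a_pred) * dt
    Z <- Znew
    V <- Vnew
    a <- force(Z, V) * acc_scale
    if (V > Vmax) { Vmax <- V; t_peak <- k * dt }
    if (is.na(t_exit) && Z >= L - d) { t_exit <- k * dt; V_exit <- V }
    if (k %% keep == 0L) {
      j <- j + 1L
      ts[j] <- k * dt; Zs[j] <- Z; Vs[j] <- V
    }
    if (Z >= L + d) break
  }
  traj <- data.frame(t = ts[1:j], Z = Zs[1:j], V = Vs[1:j])
  diagnostics <- list(
    V_max_m_s = Vmax * cnt_units$velocity_si_per_model,
    t_peak_ps = t_peak / 1000,
    t_exit_ps = t_exit / 1000,
    V_exit_m_s = if (is.na(V_exit)) NA_real_ else
      V_exit * cnt_units$velocity_si_per_model,
    reached_far_end = !is.na(t_exit))
  structure(traj, class = c("cnt_trajectory", "data.frame"),
            diagnostics = diagnostics, W = W, F0 = ax$F0, M_kg = M,
            never_enters = never_enters)
}

#' Trajectory diagnostics
#'
#' Peak velocity and its time, and the arrival state at the far end of the
#' tube, extracted from a trajectory's recorded series.  Arrival is defined
#' as the first passage of the cluster centre beyond `Z = L - d`, i.e. the
#' moment the cluster's front face reaches the far mouth (having traversed
#' the whole channel interior); with friction on, the cluster arrives slower
#' than the escape speed and cannot climb the exit barrier, so this is the
#' natural end point of a traversal.
#'
#' @param traj A `cnt_trajectory` from [simulate_transport()].
#' @param L Tube length (A); defaults to 500.
#' @param d Cluster half-length (A); recovered from the run geometry when
#'   available.
#' @return List with `V_max_m_s`, `t_peak_ps`, `t_exit_ps`, `V_exit_m_s`,
#'   `reached_far_end`.  Exit fields are `NA` when the far end is not
#'   reached within the simulated time.
#' @export
analyze_trajectory <- function(traj, L = 500, d = NULL) {
  stopifnot(nrow(traj) > 0)
  if (is.null(d)) d <- 0
  i_max <- which.max(traj$V)
  arrived <- which(traj$Z >= L - d)
  list(
    V_max_m_s = traj$V[i_max] * cnt_units$velocity_si_per_model,
    t_peak_ps = traj$t[i_max] / 1000,
    t_exit_ps = if (length(arrived)) traj$t[arrived[1]] / 1000 else NA_real_,
    V_exit_m_s = if (length(arrived))
      traj$V[arrived[1]] * cnt_units$velocity_si_per_model else NA_real_,
    reached_far_end = length(arrived) > 0)
}
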