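# Batch runner: execute analysis stages described in a YAML config file.

stage_field <- function(stage, name, default = NULL, where = "") {
  if (!is.null(stage[[name]])) return(stage[[name]])
  if (!is.null(default)) return(default)
  stop(sprintf("config field missing: %s%s", where, name))
}

#' Run a bundle of analysis stages from a config file
#'
#' Executes any combination of `energy_profile`, `force_profile`,
#' `suction_scan`, `dynamics` and `sweep` stages described in a YAML file
#' and writes their CSV/JSON outputs plus a run log (parameters, package
#' version, seed) to the output directory.  Every stage is deterministic, so
#' a rerun of the same config reproduces the same files.
#'
#' A minimal config:
#' \preformatted{
#' output_dir: out
#' seed: 1
#' tube: {b1: 13.56, L: 500}
#' stages:
#'   - {type: dynamics, b2: 10.40, d: 15, eps_co: 0.040, t_max: 150000}
#'   - {type: sweep, lengths: [30, 60, 120], eps_min: 0.04,
#'      eps_max: 0.16, eps_step: 0.01}
#' }
#'
#' @param config_file Path to the YAML config.
#' @return Invisibly, a character vector of the files written.
#' @export
run_config <- function(config_file) {
  cfg <- yaml::read_yaml(config_file)
  out_dir <- if (is.null(cfg$output_dir)) "." else cfg$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  set.seed(seed)
  tube <- cfg$tube
  system <- tube_system(
    b1 = if (is.null(tube$b1)) 13.56 else tube$b1,
    L = if (is.null(tube$L)) 500 else tube$L)
  written <- character(0)
  log <- c(sprintf("cntflow %s", as.character(utils::packageVersion("cntflow"))),
           sprintf("seed: %d", seed),
           sprintf("tube: b1 = %g, L = %g", system$b1, system$L))
  stages <- if (is.null(cfg$stages)) list() else cfg$stages
  for (i in seq_along(stages)) {
    st <- stages[[i]]
    where <- sprintf("stages[%d].", i)
    type <- stage_field(st, "type", where = where)
    log <- c(log, sprintf("stage %d: %s", i, type))
    if (type %in% c("energy_profile", "force_profile")) {
      b2 <- stage_field(st, "b2", where = where)
      d <- stage_field(st, "d", where = where)
      eps <- stage_field(st, "eps_co", where = where)
      z_min <- stage_field(st, "z_min", -2 * d - 10, where)
      z_max <- stage_field(st, "z_max", system$L + 2 * d + 10, where)
      n <- stage_field(st, "n", 400, where)
      cl <- cluster_cylinder(b2, d, eps_co = eps)
      grid <- seq(z_min, z_max, length.out = n)
      path <- file.path(out_dir, sprintf("%s_%d.csv", type, i))
      if (type == "energy_profile") {
        write_energy_profile(energy_profile(system, cl, grid), path)
      } else {
        fp <- force_profile(system, cl, grid)
        utils::write.csv(
          data.frame(Z_angstrom = fp$Z, F_kcal_per_mol_per_angstrom = fp$F),
          path, row.names = FALSE, quote = FALSE)
      }
      written <- c(written, path)
    } else if (type == "suction_scan") {
      d <- stage_field(st, "d", where = where)
      eps <- stage_field(st, "eps_co", where = where)
      res <- suction_scan(system, d, eps)
      path <- file.path(out_dir, sprintf("suction_scan_%d.csv", i))
      utils::write.csv(res$scan, path, row.names = FALSE, quote = FALSE)
      spath <- file.path(out_dir, sprintf("suction_summary_%d.json", i))
      jsonlite::write_json(
        res[c("b2_zero", "b2_star", "W_max", "delta0", "delta_max")],
        spath, auto_unbox = TRUE, digits = NA)
      written <- c(written, path, spath)
    } else if (type == "dynamics") {
      b2 <- stage_field(st, "b2", where = where)
      d <- stage_field(st, "d", where = where)
      eps <- stage_field(st, "eps_co", where = where)
      config <- transport_config(
        dt = stage_field(st, "dt", 1, where),
        t_max = stage_field(st, "t_max", 2e5, where),
        friction_on = !isTRUE(st$no_friction))
      cl <- cluster_cylinder(b2, d, eps_co = eps)
      traj <- simulate_transport(system, cl, config, eps_co = eps)
      path <- file.path(out_dir, sprintf("dynamics_%d.csv", i))
      utils::write.csv(
        data.frame(t_fs = traj$t, Z_angstrom = traj$Z,
                   V_angstrom_per_fs = traj$V),
        path, row.names = FALSE, quote = FALSE)
      dpath <- file.path(out_dir, sprintf("dynamics_%d.json", i))
      jsonlite::write_json(attr(traj, "diagnostics"), dpath,
                           auto_unbox = TRUE, digits = NA, na = "null")
      written <- c(written, path, dpath)
    } else if (type == "sweep") {
      lengths <- unlist(stage_field(st, "lengths", c(30, 60, 120), where))
      eps_grid <- seq(stage_field(st, "eps_min", 0.04, where),
                      stage_field(st, "eps_max", 0.16, where),
                      by = stage_field(st, "eps_step", 0.01, where))
      cs <- critical_sweep(lengths, eps_grid, system)
      path <- file.path(out_dir, sprintf("sweep_%d.csv", i))
      utils::write.csv(cs$sweep, path, row.names = FALSE, quote = FALSE)
      fpath <- file.path(out_dir, sprintf("fits_%d.json", i))
      fits <- lapply(names(cs$fits), function(nm) {
        f <- cs$fits[[nm]]
        cp <- cs$critical[cs$critical$length_2d == as.numeric(nm), ]
        list(length_2d = as.numeric(nm), coefficients = f$coefficients,
             r_squared = f$r_squared, eps_star = cp$eps_star,
             v_star = cp$v_star, stationary = cp$stationary)
      })
      jsonlite::write_json(fits, fpath, auto_unbox = TRUE, digits = NA)
      written <- c(written, path, fpath)
    } else {
      stop(sprintf("%stype: unknown stage type '%s'", where, type))
    }
  }
  log_path <- file.path(out_dir, "run_log.txt")
  writeLines(log, log_path)
  invisible(c(written, log_path))
}
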