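# Wettability sweeps, the quartic fit of V*(eps), and critical points.

#' Peak-velocity sweep over wettability and cluster length
#'
#' For each carbon-oxygen well depth in `eps_grid`, the suction-optimal
#' cluster radius \eqn{b_2^*(\epsilon)} is recomputed (it is independent of
#' the cluster length), the suction energy is evaluated per length, and a
#' transport simulation yields the peak velocity.  Failed runs are recorded
#' with their reason and the sweep continues.
#'
#' @param lengths Full cluster lengths `2 d` in A (default 30, 60, 120).
#' @param eps_grid Carbon-oxygen well depths in kcal/mol (default 0.04-0.16
#'   in steps of 0.01).
#' @param system A [tube_system()].
#' @param config A [transport_config()]; the default stops each run at 60 ps,
#'   well past the velocity peak of every studied length.
#' @param refresh_b2 Recompute `b2 = b2_star(eps)` at every grid point (the
#'   default).  `FALSE` holds `b2` at `fixed_b2` instead, reproducing the
#'   fixed-radius variant of the reference dynamics runs.
#' @param fixed_b2 Radius used when `refresh_b2 = FALSE` (default 10.40 A).
#' @return A data frame of class `sweep_result` with columns `length_2d`,
#'   `eps_co`, `b2`, `W`, `V_max_m_s`, `t_peak_ps`, and `failed`/`reason`.
#' @export
#' @examples
#' \donttest{
#' vmax_sweep(lengths = 30, eps_grid = c(0.04, 0.08), system = tube_system())
#' }
vmax_sweep <- function(lengths = c(30, 60, 120),
                       eps_grid = seq(0.04, 0.16, by = 0.01),
                       system = tube_system(),
                       config = transport_config(t_max = 6e4),
                       refresh_b2 = TRUE, fixed_b2 = 10.40) {
  eps_grid <- sort(eps_grid)
  b2_of_eps <- vapply(eps_grid, function(e) {
    if (!refresh_b2) return(fixed_b2)
    # b2* does not depend on the cluster length; locate it once per eps.
    # A failure here (e.g. nonsensical eps) is deferred to the per-run
    # error capture below.
    tryCatch(find_b2_star(system, d = 15, eps_co = e)$b2_star,
             error = function(err) NA_real_)
  }, 0)
  rows <- list()
  for (len in lengths) {
    d <- len / 2
    for (i in seq_along(eps_grid)) {
      e <- eps_grid[i]; b2 <- b2_of_eps[i]
      row <- data.frame(length_2d = len, eps_co = e, b2 = b2, W = NA_real_,
                        V_max_m_s = NA_real_, t_peak_ps = NA_real_,
                        failed = FALSE, reason = "")
      res <- tryCatch({
        if (is.na(b2))   # surface the deferred b2* failure for this eps
          b2 <- find_b2_star(system, d = 15, eps_co = e)$b2_star
        row$b2 <- b2
        medium <- cnt_constants(e)$medium
        cl <- cluster_cylinder(b2, d, medium)
        W <- suction_energy(system, cl)
        traj <- simulate_transport(system, cl, config, eps_co = e, W = W)
        diag <- attr(traj, "diagnostics")
        row$W <- W
        row$V_max_m_s <- diag$V_max_m_s
        row$t_peak_ps <- diag$t_peak_ps
        row
      }, error = function(err) {
        row$failed <- TRUE
        row$reason <- conditionMessage(err)
        row
      })
      rows[[length(rows) + 1L]] <- res
    }
  }
  structure(do.call(rbind, rows), class = c("sweep_result", "data.frame"))
}

#' Quartic fit of the peak velocity against wettability
#'
#' Ordinary least-squares fit of a degree-4 polynomial
#' \eqn{V^*(\epsilon) = c_0 + c_1\epsilon + \dots + c_4\epsilon^4} to a
#' sweep series.
#'
#' @param eps_grid Well depths (kcal/mol), at least 6 points.
#' @param vmax_series Peak velocities (m/s), same length.
#' @return Object of class `quartic_fit`: list with `coefficients`
#'   (ascending powers), `r_squared`, and the input data.
#' @export
#' @examples
#' f <- fit_quartic(seq(0.04, 0.16, 0.01), 500 + 100 * seq(0.04, 0.16, 0.01))
#' f$r_squared
fit_quartic <- function(eps_grid, vmax_series) {
  ok <- is.finite(eps_grid) & is.finite(vmax_series)
  eps_grid <- eps_grid[ok]; vmax_series <- vmax_series[ok]
  if (length(eps_grid) < 6)
    stop("need at least 6 grid points for a stable quartic fit")
  X <- outer(eps_grid, 0:4, `^`)
  if (qr(X)$rank < 5) stop("rank-deficient design: too few distinct eps values")
  fit <- stats::lm.fit(X, vmax_series)
  co <- unname(fit$coefficients)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((vmax_series - mean(vmax_series))^2)
  structure(list(coefficients = co,
                 r_squared = 1 - ss_res / ss_tot,
                 eps = eps_grid, vmax = vmax_series),
            class = "quartic_fit")
}

#' Evaluate a quartic fit
#'
#' @param object A `quartic_fit`.
#' @param newdata Well depths at which to evaluate (kcal/mol).
#' @param ... Unused.
#' @return Fitted velocities (m/s).
#' @export
predict.quartic_fit <- function(object, newdata, ...) {
  drop(outer(newdata, 0:4, `^`) %*% object$coefficients)
}

#' @export
print.quartic_fit <- function(x, ...) {
  cat("Quartic fit V*(eps):", sprintf("%.6g", x$coefficients),
      sprintf("\n  R^2 = %.5f on %d points\n", x$r_squared, length(x$eps)))
  invisible(x)
}

#' Critical wettability of a fitted quartic
#'
#' Stationary maximum of the fitted polynomial: the real roots of the cubic
#' derivative inside `interval` with negative second derivative.  Among
#' several interior maxima the one with the largest polynomial value is
#' returned, ties broken towards smaller \eqn{\epsilon}.  When the
#' polynomial has no interior stationary maximum the search fails with a
#' message reporting the derivative signs at the interval endpoints;
#' `boundary = TRUE` instead falls back to the constrained maximiser on the
#' interval (flagged in the result), which is the honest summary of a fit
#' that is still rising at the search boundary.
#'
#' @param fit A [fit_quartic()] result.
#' @param interval Search interval in kcal/mol (default `c(0.02, 0.5)`;
#'   critical points of short clusters lie beyond the sampled wettability
#'   range, so values found there are extrapolations of the fit).
#' @param boundary Fall back to the constrained maximiser instead of
#'   erroring when no interior stationary maximum exists.
#' @return List with `eps_star` (kcal/mol), `v_star` (m/s), and
#'   `stationary` (`FALSE` when the boundary fallback was taken).
#' @export
#' @examples
#' f <- fit_quartic(seq(0.04, 0.16, 0.01),
#'                  700 - 5000 * (seq(0.04, 0.16, 0.01) - 0.1)^2)
#' critical_point(f) # ~ (0.1, 700)
critical_point <- function(fit, interval = c(0.02, 0.5), boundary = FALSE) {
  stopifnot(inherits(fit, "quartic_fit"))
  co <- fit$coefficients
  dco <- co[2:5] * (1:4)                      # derivative, ascending powers
  dval <- function(x) drop(outer(x, 0:3, `^`) %*% dco)
  roots <- polyroot(dco)
  real <- Re(roots[abs(Im(roots)) < 1e-8])
  real <- real[real > interval[1] & real < interval[2]]
  d2co <- dco[2:4] * (1:3)
  curv <- function(x) drop(outer(x, 0:2, `^`) %*% d2co)
  maxima <- real[curv(real) < 0]
  if (length(maxima) == 0) {
    msg <- sprintf(
      "no interior stationary maximum in [%g, %g]; derivative is %.4g at the left and %.4g at the right endpoint",
      interval[1], interval[2], dval(interval[1]), dval(interval[2]))
    if (!boundary) stop(msg)
    cand <- c(interval, real)
    vals <- predict(fit, cand)
    k <- which.max(vals)
    return(list(eps_star = cand[k], v_star = vals[k], stationary = FALSE))
  }
  vals <- predict(fit, maxima)
  best <- vals == max(vals)
  eps_star <- min(maxima[best])
  list(eps_star = eps_star, v_star = predict(fit, eps_star), stationary = TRUE)
}

#' Sweep, fit, and extract critical points in one call
#'
#' Runs [vmax_sweep()], fits the quartic per cluster length, and extracts
#' each critical point (with the boundary fallback, flagged in the output).
#'
#' @inheritParams vmax_sweep
#' @param interval Search interval passed to [critical_point()].
#' @return List with `sweep` (the [vmax_sweep()] table), `fits` (one
#'   [fit_quartic()] per length) and `critical` (data frame `length_2d`,
#'   `eps_star`, `v_star`, `r_squared`, `stationary`).
#' @export
critical_sweep <- function(lengths = c(30, 60, 120),
                           eps_grid = seq(0.04, 0.16, by = 0.01),
                           system = tube_system(),
                           config = transport_config(t_max = 6e4),
                           interval = c(0.02, 0.5)) {
  sw <- vmax_sweep(lengths, eps_grid, system, config)
  fits <- list(); crit <- list()
  for (len in lengths) {
    sub <- sw[sw$length_2d == len & !sw$failed, ]
    fit <- fit_quartic(sub$eps_co, sub$V_max_m_s)
    cp <- critical_point(fit, interval, boundary = TRUE)
    fits[[as.character(len)]] <- fit
    crit[[as.character(len)]] <- data.frame(
      length_2d = len, eps_star = cp$eps_star, v_star = cp$v_star,
      r_squared = fit$r_squared, stationary = cp$stationary)
  }
  list(sweep = sw, fits = fits, critical = do.call(rbind, crit))
}
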