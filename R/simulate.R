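#' Simulate a cantilever-fiber stretching experiment
#'
#' Integrates the quasi-static force-balance dynamics of a fiber (active
#' standard linear solid) pulled transversally at its midpoint by a
#' cantilever mounted on a moving stage. At every instant the cantilever
#' force balances the projected segment tensions,
#' `k_clv (delta_s(t) - e) = 2 (T0 + k1 delta + T_m) sin(theta)`,
#' while the Maxwell-branch tension `T_m` evolves by [maxwell_rate()] with
#' `delta_dot = sin(theta) * de/dt`. Differentiating the constraint in time
#' yields an explicit ODE for `e` which is integrated with an adaptive
#' Runge-Kutta scheme (compiled right-hand side, deSolve); the ramp and hold
#' phases are integrated as separate legs so the stage-velocity
#' discontinuity at the halt falls on a leg boundary.
#'
#' @param geometry A [fiber_geometry()].
#' @param probe A [cantilever_probe()].
#' @param params A [mechanical_params()].
#' @param protocol A [stage_protocol()].
#' @param solver A [solver_config()].
#' @param times Optional output time grid, s. Defaults to the protocol's
#'   uniform grid over `[0, t_star + t_hold]` at `sample_rate`, augmented
#'   with `t_star` itself.
#' @return A `sim_trace`: a data.frame with columns `t`, `delta_s`, `e`,
#'   `delta_clv`, `F_clv`, `delta`, `T`, `T_m` (units s, um, nN) and the
#'   inputs stored as attributes. Invariants held at every sample:
#'   `delta_clv = delta_s - e`, `F_clv = k_clv * delta_clv`, and the force
#'   balance residual below solver tolerance.
#' @examples
#' tr <- forward_simulate(fiber_geometry(28.4), cantilever_probe(3),
#'                        mechanical_params(7.44, 3.23, 10.94, 7.85),
#'                        stage_protocol(5, 20, 10, 50))
#' head(tr)
#' @export
forward_simulate <- function(geometry, probe, params, protocol,
                             solver = solver_config(), times = NULL) {
  stopifnot(inherits(geometry, "fiber_geometry"),
            inherits(probe, "cantilever_probe"),
            inherits(params, "mechanical_params"),
            inherits(protocol, "stage_protocol"),
            inherits(solver, "solver_config"))
  t_star <- protocol$t_star
  t_end <- t_star + protocol$t_hold
  if (is.null(times)) {
    times <- seq(0, t_end, by = 1 / protocol$sample_rate)
    if (!any(abs(times - t_star) < 1e-12)) times <- sort(c(times, t_star))
  }
  times <- sort(unique(as.numeric(times)))
  if (times[1] < 0 || times[length(times)] > t_end + 1e-9) {
    stop("output times must lie within [0, t_star + t_hold]")
  }

  kr <- if (is.infinite(params$eta)) 0 else params$k2 / params$eta
  base_parms <- c(d = geometry$d, kclv = probe$k_clv, T0 = params$T0,
                  k1 = params$k1, k2 = params$k2, kr = kr)

  run_leg <- function(y0, leg_times, a, b) {
    if (length(leg_times) < 2) {
      return(cbind(time = leg_times,
                   matrix(y0, nrow = length(leg_times), ncol = 2,
                          byrow = TRUE, dimnames = list(NULL, c("e", "Tm"))),
                   residual = NA_real_))
    }
    out <- tryCatch(
      deSolve::ode(y = c(e = y0[1], Tm = y0[2]), times = leg_times,
                   func = "sls_derivs", parms = c(base_parms, a = a, b = b),
                   dllname = "fiberSLS", initfunc = "sls_initmod",
                   nout = 1, outnames = "residual",
                   method = solver$method, rtol = solver$rtol,
                   atol = solver$atol),
      error = function(e) e)
    if (inherits(out, "error") || nrow(out) < length(leg_times) ||
        anyNA(out[, "e"])) {
      last <- if (inherits(out, "error")) y0 else out[nrow(out), c("e", "Tm")]
      stop(sprintf(paste0("ODE solver failed to cover the requested interval ",
                          "(last valid state e = %.6g um, T_m = %.6g nN); ",
                          "check for sin(theta) -> 1 pathologies"),
                   last[1], last[2]), call. = FALSE)
    }
    out
  }

  # ramp leg [0, t_star], hold leg [t_star, t_end]; t_star bridges the two
  ramp_cap <- min(t_star, times[length(times)])
  ramp_times <- sort(unique(c(0, times[times < ramp_cap - 1e-12], ramp_cap)))
  out1 <- run_leg(c(0, 0), ramp_times, a = 0, b = protocol$v0)
  y <- as.numeric(out1[nrow(out1), c("e", "Tm")])
  pieces <- list(ramp = out1)
  if (times[length(times)] > t_star + 1e-12) {
    hold_times <- sort(unique(c(t_star, times[times > t_star + 1e-12])))
    out2 <- run_leg(y, hold_times, a = protocol$delta_s_star, b = 0)
    pieces$hold <- out2[-1, , drop = FALSE]
  }
  out <- do.call(rbind, pieces)
  keep <- vapply(out[, "time"], function(tt) any(abs(times - tt) < 1e-12), logical(1))
  out <- out[keep, , drop = FALSE]

  t <- out[, "time"]
  e <- out[, "e"]
  T_m <- out[, "Tm"]
  delta_s <- stage_displacement(protocol, t)
  delta <- as.numeric(transverse_to_elongation(geometry, pmax(e, 0)))
  Tension <- constitutive_tension(params, delta, T_m)
  trace <- data.frame(t = t, delta_s = delta_s, e = e,
                      delta_clv = delta_s - e,
                      F_clv = probe$k_clv * (delta_s - e),
                      delta = delta, T = Tension, T_m = T_m,
                      row.names = NULL)
  structure(trace,
            geometry = geometry, probe = probe, params = params,
            protocol = protocol, solver = solver,
            max_residual = max(abs(out[, "residual"]), na.rm = TRUE),
            class = c("sim_trace", "data.frame"))
}

#' Algebraic transverse displacement of a pure-elastic fiber
#'
#' For an elastic fiber (Maxwell branch inert, `T_m = 0`) the quasi-static
#' balance is purely algebraic:
#' `k_clv (delta_s - e) = 2 (T0 + k1 delta(e)) sin(theta(e))`.
#' This solves it per stage position by root bracketing, providing the
#' closed-solution reference for the elastic limit of [forward_simulate()].
#'
#' @inheritParams forward_simulate
#' @param delta_s Stage displacement(s), um (>= 0).
#' @param tol Root tolerance on `e`, um.
#' @return Numeric vector of equilibrium transverse displacements `e`, um.
#' @export
elastic_equilibrium <- function(geometry, probe, params, delta_s, tol = 1e-12) {
  stopifnot(inherits(geometry, "fiber_geometry"),
            inherits(probe, "cantilever_probe"),
            inherits(params, "mechanical_params"))
  vapply(delta_s, function(ds) {
    if (ds <= 0) return(0)
    f <- function(e) {
      probe$k_clv * (ds - e) -
        2 * constitutive_tension(params,
                                 as.numeric(transverse_to_elongation(geometry, e)),
                                 0) * projection_sine(geometry, e)
    }
    stats::uniroot(f, c(0, ds), tol = tol)$root
  }, numeric(1))
}
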