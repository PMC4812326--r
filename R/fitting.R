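#' Construct an experiment trace
#'
#' The unit of analysis: sampled stage displacement and cantilever
#' deflection versus time, with the per-experiment metadata needed for the
#' force-balance analysis. The derived kinematics `e = delta_s - delta_clv`
#' (transverse fiber displacement) and `F_clv = k_clv * delta_clv`
#' (cantilever force) are computed once at construction and cached as
#' columns.
#'
#' @param t Time, s; strictly increasing, mean sampling rate >= 10 Hz.
#' @param delta_s Stage displacement, um.
#' @param delta_clv Cantilever deflection, um.
#' @param d Fiber half-length, um.
#' @param k_clv Cantilever spring constant, nN/um.
#' @param condition Optional condition label (e.g. `"CTRL"`, `"Y27632"`).
#' @param seed Optional provenance seed.
#' @param truth Optional list of ground-truth parameters (synthetic traces).
#' @return An `experiment_trace`: data.frame `t, delta_s, delta_clv, e,
#'   F_clv` with `geometry`, `probe`, `condition`, `seed`, `truth`
#'   attributes.
#' @export
experiment_trace <- function(t, delta_s, delta_clv, d, k_clv,
                             condition = "CTRL", seed = NA_integer_,
                             truth = NULL) {
  n <- length(t)
  if (length(delta_s) != n || length(delta_clv) != n) {
    stop("t, delta_s and delta_clv must have equal length")
  }
  if (n < 2 || any(diff(t) <= 0)) stop("t must be strictly increasing")
  if (1 / median(diff(t)) < 10 - 1e-9) {
    stop("sampling rate must be >= 10 Hz for a 5 um/s protocol")
  }
  geometry <- fiber_geometry(d)
  probe <- cantilever_probe(k_clv)
  df <- data.frame(t = as.numeric(t), delta_s = as.numeric(delta_s),
                   delta_clv = as.numeric(delta_clv))
  df$e <- df$delta_s - df$delta_clv
  df$F_clv <- probe$k_clv * df$delta_clv
  structure(df, geometry = geometry, probe = probe,
            condition = condition, seed = seed, truth = truth,
            class = c("experiment_trace", "data.frame"))
}

#' Derived kinematics of a trace
#'
#' Transverse fiber displacement and cantilever force from the two measured
#' displacement channels: `e = delta_s - delta_clv`,
#' `F_clv = k_clv * delta_clv`.
#'
#' @param trace An [experiment_trace()].
#' @return data.frame with columns `t`, `e`, `F_clv`.
#' @export
derive_kinematics <- function(trace) {
  stopifnot(inherits(trace, "experiment_trace"))
  data.frame(t = trace$t, e = trace$e, F_clv = trace$F_clv)
}

#' Detect the stage halt
#'
#' Finds the moment `t_star` when the stage stops: the first sample from
#' which the finite-difference stage speed (median-smoothed over 5 samples)
#' stays below 10 percent of the ramp speed for at least 3 consecutive
#' intervals. The ramp speed is taken from metadata if supplied, otherwise
#' estimated as the maximum smoothed speed.
#'
#' @param trace An [experiment_trace()].
#' @param v0 Optional known nominal stage speed, um/s.
#' @return List with `t_star` (s), `e_star` (um), `delta_s_star` (um,
#'   median stage position during the hold), `index` (sample index of the
#'   halt) and `v0_hat` (um/s).
#' @export
detect_halt <- function(trace, v0 = NULL) {
  stopifnot(inherits(trace, "experiment_trace"))
  t <- trace$t
  speed <- diff(trace$delta_s) / diff(t)
  sm <- if (length(speed) >= 5) stats::runmed(speed, 5) else speed
  v0_est <- if (is.null(v0)) max(sm) else v0
  if (v0_est < 1e-12) {            # stage never moved: hold from t = 0
    return(list(t_star = t[1], e_star = trace$e[1],
                delta_s_star = median(trace$delta_s), index = 1L,
                v0_hat = 0))
  }
  low <- sm < 0.1 * v0_est
  sustained <- which(low & c(low[-1], FALSE) & c(low[-(1:2)], FALSE, FALSE))
  if (length(sustained) == 0) {
    stop(paste("no stage halt detected (speed never fell below 10% of the",
               "ramp speed for 3 consecutive intervals); supply t_star manually"))
  }
  i <- sustained[1]
  t_star <- t[i]
  ds_star <- median(trace$delta_s[t >= t_star])
  list(t_star = t_star, e_star = trace$e[i], delta_s_star = ds_star,
       index = i, v0_hat = if (t_star > 0) ds_star / t_star else 0)
}

#' Tension-deformation curve of the loading phase
#'
#' Converts loading-phase samples to a tension-versus-elongation curve via
#' [transverse_to_elongation()] and [tension_from_force()]. Samples with
#' `e < e_min` are excluded (the symmetric force-balance formula amplifies
#' noise without bound as `e -> 0`); samples after the halt are excluded.
#'
#' @param trace An [experiment_trace()].
#' @param t_star Halt time, s; detected with [detect_halt()] if missing.
#' @param e_min Minimum transverse displacement, um (default 1).
#' @param monotone If `TRUE`, additionally keep only samples where `delta`
#'   is non-decreasing along the curve.
#' @return A `tension_curve`: data.frame with columns `delta` (um) and
#'   `T` (nN), plus a `retained` logical attribute over the full trace.
#' @export
tension_deformation_curve <- function(trace, t_star = NULL, e_min = 1.0,
                                      monotone = FALSE) {
  stopifnot(inherits(trace, "experiment_trace"))
  if (is.null(t_star)) t_star <- detect_halt(trace)$t_star
  geometry <- attr(trace, "geometry")
  retained <- trace$t <= t_star & trace$e >= e_min
  if (sum(retained) < 5) {
    stop("fewer than 5 loading-phase samples with e >= e_min; cannot build a tension curve")
  }
  e <- trace$e[retained]
  delta <- as.numeric(transverse_to_elongation(geometry, e))
  Tension <- tension_from_force(trace$F_clv[retained], geometry, e, e_min = e_min)
  if (monotone) {
    keep <- delta >= cummax(c(-Inf, delta[-length(delta)]))
    delta <- delta[keep]; Tension <- Tension[keep]
    retained[retained] <- keep
  }
  structure(data.frame(delta = delta, T = Tension),
            retained = retained, class = c("tension_curve", "data.frame"))
}

#' Extract pre-tension from the tension-curve intercept
#'
#' The pre-tension `T0` is the fiber tension extrapolated to zero
#' elongation. The plain estimator is the y-intercept of an ordinary
#' least-squares line through the whole loading-phase `(delta, T)` curve;
#' with a viscous fiber the loading curve lies above the elastic line
#' `T0 + k1 delta`, so that intercept is biased upward (the overestimation
#' the viscous term causes). Because the viscous contribution vanishes as
#' `delta -> 0`, the default estimator instead fits the line on nested
#' early-`delta` windows and extrapolates the intercept linearly to window
#' size zero, which removes the leading-order viscous bias at the cost of
#' some variance. `window_fracs = 1` recovers the plain full-range OLS
#' intercept.
#'
#' @param curve A `tension_curve` from [tension_deformation_curve()].
#' @param window_fracs Fractions of the elongation range used as nested fit
#'   windows (default `c(0.25, 0.5)`); with two fractions the intercept is
#'   linearly extrapolated to a zero-size window, with one it is that
#'   window's intercept. A window with fewer than 5 points falls back to
#'   the full range.
#' @return Estimated `T0` (nN) with attributes `slope` (nN/um, full-range
#'   OLS slope: the pure-elastic upper bound for k1), `intercept_full`
#'   (plain full-range intercept) and `r_squared` (full-range fit). A
#'   negative estimate is returned with a warning.
#' @export
extract_pretension <- function(curve, window_fracs = c(0.25, 0.5)) {
  stopifnot(inherits(curve, "tension_curve"),
            is.numeric(window_fracs), length(window_fracs) %in% c(1L, 2L),
            all(window_fracs > 0), all(window_fracs <= 1))
  if (nrow(curve) < 5) stop("need at least 5 points for the intercept fit")
  if (diff(range(curve$delta)) < 1) {
    stop("tension curve spans < 1 um of elongation; intercept ill-determined")
  }
  full <- lm(T ~ delta, data = curve)
  window_intercept <- function(f) {
    w <- curve$delta <= min(curve$delta) + f * diff(range(curve$delta))
    if (sum(w) < 5) return(unname(coef(full)[1]))
    unname(coef(lm(T ~ delta, data = curve[w, , drop = FALSE]))[1])
  }
  window_fracs <- sort(window_fracs)
  ic <- vapply(window_fracs, window_intercept, numeric(1))
  T0_hat <- if (length(ic) == 2L && diff(window_fracs) > 0) {
    ic[1] - window_fracs[1] * diff(ic) / diff(window_fracs)
  } else {
    ic[length(ic)]
  }
  if (T0_hat < 0) {
    warning(sprintf("negative pre-tension intercept (%.3g nN): unphysical, flagging bad trace",
                    T0_hat))
  }
  ss_tot <- sum((curve$T - mean(curve$T))^2)
  structure(T0_hat, slope = unname(coef(full)[2]),
            intercept_full = unname(coef(full)[1]),
            r_squared = if (ss_tot > 0) 1 - sum(residuals(full)^2) / ss_tot
                        else NA_real_)
}

#' Fit the exponential relaxation of the hold phase
#'
#' After the stage halts, the additional transverse displacement
#' `e' = e - e*` grows as `e'(t') = e_inf * (1 - exp(-t'/tau))` with
#' `t' = t - t_star`. Nonlinear least squares (Levenberg-Marquardt) with
#' starting values from a log-linearization. Fits with `R^2 < 0.9` are
#' flagged; a flat hold phase is flagged degenerate (`tau = NA`), which is
#' how a pure-elastic fiber announces itself.
#'
#' @param trace An [experiment_trace()].
#' @param t_star Halt time, s (from [detect_halt()]).
#' @param t_min Lower edge of the fit window relative to the halt, s
#'   (default 0: from the first sample after the halt to the end of the
#'   hold). A positive value restricts the fit to the tail, where the
#'   relaxation is closest to its asymptotic single-exponential form.
#' @return A `relaxation_fit`: list with `tau` (s), `e_inf` (um),
#'   `r_squared`, `t_star`, `e_star`, `flagged`, `degenerate`.
#' @export
fit_relaxation <- function(trace, t_star, t_min = 0) {
  stopifnot(inherits(trace, "experiment_trace"))
  i_star <- which.min(abs(trace$t - t_star))
  e_star <- trace$e[i_star]
  hold <- trace$t > t_star + max(t_min, 0) + 1e-12
  if (sum(hold) < 10) stop("hold phase has fewer than 10 samples")
  tp <- trace$t[hold] - t_star
  ep <- trace$e[hold] - e_star
  mk <- function(tau, e_inf, r2, flagged, degenerate) {
    structure(list(tau = tau, e_inf = e_inf, r_squared = r2,
                   t_star = t_star, e_star = e_star,
                   flagged = flagged, degenerate = degenerate),
              class = "relaxation_fit")
  }
  if (max(abs(ep)) < 1e-8) {
    return(mk(NA_real_, 0, NA_real_, TRUE, TRUE))
  }
  # starting values: lagged differences of an exponential approach decay as
  # exp(-t/tau), so a log-linear regression on positive differences gives
  # tau without knowing e_inf; works on any sub-window of the hold
  n <- length(tp)
  m <- max(1L, n %/% 10)
  di <- ep[(m + 1):n] - ep[1:(n - m)]
  td <- tp[1:(n - m)]
  pos <- di > 0
  tau0 <- if (sum(pos) >= 3) {
    -1 / unname(coef(lm(log(di[pos]) ~ td[pos]))[2])
  } else NA_real_
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- max(tp) / 3
  e_inf0 <- mean(ep / (1 - exp(-pmax(tp, 1e-9) / tau0)))
  if (!is.finite(e_inf0) || e_inf0 <= 0) e_inf0 <- max(ep)
  fit <- tryCatch(
    minpack.lm::nlsLM(ep ~ e_inf * (1 - exp(-tp / tau)),
                      start = list(e_inf = e_inf0, tau = tau0),
                      lower = c(e_inf = 0, tau = 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(mk(NA_real_, e_inf0, NA_real_, TRUE, TRUE))
  }
  cf <- coef(fit)
  r2 <- 1 - sum(residuals(fit)^2) / sum((ep - mean(ep))^2)
  mk(unname(cf["tau"]), unname(cf["e_inf"]), r2,
     flagged = r2 < 0.9, degenerate = FALSE)
}

#' Viscosity from the Maxwell spring constant and the relaxation time
#'
#' During the hold the projection angle is approximately constant at its
#' end-of-ramp value `theta*` (the additional elongation is small compared
#' to `e*`). Linearizing the coupled fiber-cantilever dynamics at constant
#' `theta*` gives a single exponential with
#' `tau = (eta/k2) * (k_clv + 2 sin^2(theta*) (k1 + k2)) /
#'        (k_clv + 2 sin^2(theta*) k1)`,
#' i.e. the observed time differs from the intrinsic Maxwell time `eta/k2`
#' by geometry and stiffness factors. Inverted for the viscosity:
#' `eta = tau k2 (k_clv + 2 sin^2(theta*) k1) /
#'        (k_clv + 2 sin^2(theta*) (k1 + k2))`.
#'
#' The constant-angle form neglects the geometric stiffness of the rotating
#' tension vector, `G = 2 T d^2 / L^3` (nN/um, with `L = sqrt(d^2 + e^2)`),
#' which enters both brackets of the exact linearization:
#' `tau = (eta/k2) (k_clv + 2 s^2 (k1+k2) + G) / (k_clv + 2 s^2 k1 + G)`.
#' Supplying `geom_stiffness` includes that term; the default 0 is the
#' plain constant-angle formula.
#'
#' @param k1,k2 Spring constants, nN/um.
#' @param tau Observed relaxation time, s.
#' @param sin_theta_star `sin(theta*)` at the end of the ramp, in (0, 1).
#' @param k_clv Cantilever spring constant, nN/um.
#' @param geom_stiffness Geometric stiffness `2 T d^2 / L^3` at the
#'   linearization state, nN/um (default 0).
#' @return Viscosity `eta`, nN.s/um.
#' @export
eta_from_k2 <- function(k1, k2, tau, sin_theta_star, k_clv,
                        geom_stiffness = 0) {
  stopifnot(k1 >= 0, k2 >= 0, tau > 0, k_clv > 0,
            sin_theta_star > 0, sin_theta_star < 1, geom_stiffness >= 0)
  s2 <- sin_theta_star^2
  tau * k2 * (k_clv + 2 * s2 * k1 + geom_stiffness) /
    (k_clv + 2 * s2 * (k1 + k2) + geom_stiffness)
}

#' Linearized relaxation time of the coupled fiber-cantilever system
#'
#' Linearizing the hold-phase dynamics about the relaxed equilibrium (the
#' elastic equilibrium at the halted stage position, where the Maxwell
#' branch is fully relaxed) gives a single exponential whose time constant
#' is the intrinsic Maxwell time `eta/k2` rescaled by the stiffness budget
#' of the coupled system:
#' `tau = (eta/k2) (k_clv + 2 s^2 (k1+k2) + G) / (k_clv + 2 s^2 k1 + G)`
#' with `s = sin(theta)` and geometric stiffness `G = 2 T d^2/L^3`, all
#' evaluated at the equilibrium state.
#'
#' @param geometry A [fiber_geometry()].
#' @param probe A [cantilever_probe()].
#' @param params A [mechanical_params()] (requires k2 > 0, finite eta).
#' @param delta_s_star Halted stage position, um.
#' @return Predicted relaxation time `tau`, s, with attributes `e_eq`,
#'   `sin_theta` and `geom_stiffness` describing the linearization state.
#' @export
relaxation_time_linearized <- function(geometry, probe, params, delta_s_star) {
  stopifnot(inherits(geometry, "fiber_geometry"),
            inherits(probe, "cantilever_probe"),
            inherits(params, "mechanical_params"))
  if (params$k2 <= 0 || is.infinite(params$eta)) {
    stop("relaxation time undefined for a pure-elastic fiber (k2 = 0 or eta = Inf)")
  }
  e_eq <- elastic_equilibrium(geometry, probe, params, delta_s_star)
  d <- geometry$d
  L <- sqrt(d^2 + e_eq^2)
  s <- e_eq / L
  T_eq <- params$T0 + params$k1 * (L - d)
  G <- 2 * T_eq * d^2 / L^3
  tau <- (params$eta / params$k2) *
    (probe$k_clv + 2 * s^2 * (params$k1 + params$k2) + G) /
    (probe$k_clv + 2 * s^2 * params$k1 + G)
  structure(tau, e_eq = e_eq, sin_theta = s, geom_stiffness = G)
}

#' Normalized misfit between a simulated and a measured trace
#'
#' Root-mean-square of the transverse-displacement residual normalized by
#' the peak measured displacement:
#' `err = sqrt(mean(((e_exp - e_sim)/max|e_exp|)^2))`.
#' Because `F_clv = k_clv (delta_s - e)` with a shared stage trace, the
#' force residual is proportional to the `e` residual; the force RMSE is
#' attached as a diagnostic rather than double-counted.
#'
#' @param sim A `sim_trace` evaluated on the experiment's time grid.
#' @param exp_trace An [experiment_trace()].
#' @return Dimensionless error with attribute `force_rmse` (nN).
#' @export
aggregated_error <- function(sim, exp_trace) {
  stopifnot(inherits(sim, "sim_trace"), inherits(exp_trace, "experiment_trace"))
  if (nrow(sim) != nrow(exp_trace) ||
      max(abs(sim$t - exp_trace$t)) > 1e-8) {
    stop("simulated and experimental traces must share the same time grid")
  }
  scale <- max(abs(exp_trace$e))
  if (scale <= 0) stop("experimental trace has zero displacement throughout")
  res <- (exp_trace$e - sim$e) / scale
  k_clv <- attr(exp_trace, "probe")$k_clv
  structure(sqrt(mean(res^2)),
            force_rmse = sqrt(mean((k_clv * (exp_trace$e - sim$e))^2)))
}

#' Fitting configuration
#'
#' @param coarse_step Coarse grid step for (k1, k2), nN/um (default 2).
#' @param fine_step Fine grid step, nN/um (default 0.1).
#' @param k1_bounds Search bounds for k1; an `NA` upper bound means "use
#'   the slope of the loading-phase tension curve" (pure-elastic reading:
#'   all loading resistance assigned to k1).
#' @param k2_bounds Search bounds for k2 (default `c(0.1, 40)`).
#' @param e_min Minimum `e` for tension-curve samples, um (default 1).
#' @param intercept_windows Window fractions for [extract_pretension()].
#' @param relax_t_min Relaxation-fit window lower edge, s after the halt.
#' @param max_recenter Maximum number of fine-pass re-centerings when the
#'   fine optimum lands on the moving window's edge (default 12).
#' @param solver A [solver_config()] used for grid-search simulations.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(coarse_step = 2, fine_step = 0.1,
                       k1_bounds = c(0, NA), k2_bounds = c(0.1, 40),
                       e_min = 1.0, intercept_windows = c(0.25, 0.5),
                       relax_t_min = 0, max_recenter = 12,
                       solver = solver_config()) {
  stopifnot(coarse_step > 0, fine_step > 0, fine_step <= coarse_step,
            length(k1_bounds) == 2, length(k2_bounds) == 2,
            k2_bounds[1] > 0, k2_bounds[2] > k2_bounds[1],
            max_recenter >= 0, inherits(solver, "solver_config"))
  structure(list(coarse_step = coarse_step, fine_step = fine_step,
                 k1_bounds = k1_bounds, k2_bounds = k2_bounds,
                 e_min = e_min, intercept_windows = intercept_windows,
                 relax_t_min = relax_t_min, max_recenter = max_recenter,
                 solver = solver),
            class = "fit_config")
}

# Reconstruct the idealized ramp-hold protocol implied by a trace's halt.
protocol_from_trace <- function(trace, halt) {
  t <- trace$t
  rate <- 1 / median(diff(t))
  stage_protocol(v0 = halt$v0_hat, delta_s_star = halt$delta_s_star,
                 t_hold = max(t) - halt$t_star, sample_rate = rate)
}

#' Two-stage grid search over (k1, k2)
#'
#' For each candidate pair the viscosity is slaved to the fitted relaxation
#' time via [eta_from_k2()] with the geometric-stiffness term evaluated at
#' the candidate's hold-phase equilibrium, the forward model is integrated
#' on the trace's time grid, and the candidate is scored with
#' [aggregated_error()]. A coarse pass (default step 2 nN/um) over the full
#' bounds is refined by a fine pass (default step 0.1 nN/um) within one
#' coarse step of the coarse optimum; because the (k1, k2) error surface is
#' a shallow curved valley, the fine window re-centers itself while its
#' optimum sits on the window edge, so the refinement can walk along the
#' valley away from a mis-anchored coarse optimum. Scores are memoised, so
#' overlapping windows cost nothing. The k1 upper bound defaults to the
#' loading-curve slope. If the relaxation fit is degenerate (no measurable
#' relaxation) the Maxwell branch is dropped and only k1 is searched.
#'
#' Ties are broken toward the smallest (k1, then k2) and flagged; an
#' optimum on the configured search boundary is flagged.
#'
#' @param trace An [experiment_trace()].
#' @param T0_hat Pre-tension estimate from [extract_pretension()] (its
#'   `slope` attribute, when present, supplies the default k1 upper bound).
#' @param relaxation A `relaxation_fit` from [fit_relaxation()].
#' @param config A [fit_config()].
#' @param halt Optional halt description from [detect_halt()] (recomputed
#'   if missing).
#' @return A `fit_result`: list with `params` ([mechanical_params()]),
#'   `relaxation`, `error`, `T0_hat`, and `diagnostics` (visited grids,
#'   evaluation count, runner-up gap, boundary/tie flags).
#' @export
grid_search <- function(trace, T0_hat, relaxation, config = fit_config(),
                        halt = NULL) {
  stopifnot(inherits(trace, "experiment_trace"),
            inherits(relaxation, "relaxation_fit"),
            inherits(config, "fit_config"))
  geometry <- attr(trace, "geometry")
  probe <- attr(trace, "probe")
  if (is.null(halt)) halt <- detect_halt(trace)
  protocol <- protocol_from_trace(trace, halt)
  T0 <- max(as.numeric(T0_hat), 0)
  sin_star <- projection_sine(geometry, max(halt$e_star, 1e-9))

  k1_lo <- config$k1_bounds[1]
  k1_hi <- config$k1_bounds[2]
  if (is.na(k1_hi)) {
    k1_hi <- attr(T0_hat, "slope")
    if (is.null(k1_hi)) stop("k1 upper bound not configured and T0_hat carries no slope attribute")
  }
  if (k1_hi < k1_lo) k1_hi <- k1_lo
  k2_lo <- config$k2_bounds[1]; k2_hi <- config$k2_bounds[2]
  degenerate <- isTRUE(relaxation$degenerate)

  # geometric stiffness of the hold-phase equilibrium, per candidate k1
  # (T_m relaxed => equilibrium is elastic; independent of k2)
  geom_G <- local({
    memo <- new.env(parent = emptyenv())
    function(k1) {
      key <- sprintf("%.9g", k1)
      if (!is.null(memo[[key]])) return(memo[[key]])
      eq <- elastic_equilibrium(geometry, probe,
                                mechanical_params(T0, k1, 0, 1),
                                halt$delta_s_star)
      L <- sqrt(geometry$d^2 + eq^2)
      G <- 2 * (T0 + k1 * (L - geometry$d)) * geometry$d^2 / L^3
      memo[[key]] <- c(G = G, s = eq / L)
      memo[[key]]
    }
  })

  slave_eta <- function(k1, k2) {
    gs <- geom_G(k1)
    eta_from_k2(k1, k2, relaxation$tau, gs[["s"]], probe$k_clv,
                geom_stiffness = gs[["G"]])
  }

  score_memo <- new.env(parent = emptyenv())
  n_eval <- 0L
  score <- function(k1, k2) {
    key <- sprintf("%.9g_%.9g", k1, k2)
    if (!is.null(score_memo[[key]])) return(score_memo[[key]])
    params <- if (degenerate) mechanical_params(T0, k1, 0, Inf) else
      mechanical_params(T0, k1, k2, max(slave_eta(k1, k2), 1e-9))
    sim <- forward_simulate(geometry, probe, params, protocol,
                            solver = config$solver, times = trace$t)
    err <- as.numeric(aggregated_error(sim, trace))
    n_eval <<- n_eval + 1L
    score_memo[[key]] <- err
    err
  }

  grid_axis <- function(lo, hi, step) {
    g <- seq(lo, hi, by = step)
    if (g[length(g)] < hi - 1e-9) g <- c(g, hi)
    round(g, 9)
  }
  run_pass <- function(k1_grid, k2_grid) {
    pts <- expand.grid(k1 = k1_grid, k2 = k2_grid)
    pts <- pts[order(pts$k1, pts$k2), ]   # tie-break order: smallest k1, then k2
    pts$err <- mapply(score, pts$k1, pts$k2)
    pts
  }
  best_of <- function(pts) pts[which.min(pts$err), ]

  coarse <- run_pass(grid_axis(k1_lo, k1_hi, config$coarse_step),
                     if (degenerate) 0 else grid_axis(k2_lo, k2_hi, config$coarse_step))
  center <- best_of(coarse)

  # fine pass: step fine_step inside a +/- coarse_step window; if the
  # optimum lands on the window edge (not a configured bound), re-center
  # the window there and continue until interior or max_recenter reached
  fine <- NULL
  recenters <- 0L
  repeat {
    win_k1 <- c(max(k1_lo, center$k1 - config$coarse_step),
                min(k1_hi, center$k1 + config$coarse_step))
    win_k2 <- c(max(k2_lo, center$k2 - config$coarse_step),
                min(k2_hi, center$k2 + config$coarse_step))
    pass <- run_pass(grid_axis(win_k1[1], win_k1[2], config$fine_step),
                     if (degenerate) 0 else
                       grid_axis(win_k2[1], win_k2[2], config$fine_step))
    fine <- if (is.null(fine)) pass else {
      both <- rbind(fine, pass)
      both[!duplicated(both[c("k1", "k2")]), ]
    }
    fb <- best_of(fine)
    on_edge <- (abs(fb$k1 - win_k1[1]) < 1e-9 && fb$k1 > k1_lo + 1e-9) ||
      (abs(fb$k1 - win_k1[2]) < 1e-9 && fb$k1 < k1_hi - 1e-9) ||
      (!degenerate &&
         ((abs(fb$k2 - win_k2[1]) < 1e-9 && fb$k2 > k2_lo + 1e-9) ||
          (abs(fb$k2 - win_k2[2]) < 1e-9 && fb$k2 < k2_hi - 1e-9)))
    if (!on_edge || recenters >= config$max_recenter) break
    recenters <- recenters + 1L
    center <- fb
  }
  fb <- best_of(fine)
  tie <- sum(fine$err == fb$err) > 1
  boundary <- abs(fb$k1 - k1_lo) < 1e-9 || abs(fb$k1 - k1_hi) < 1e-9 ||
    (!degenerate && (abs(fb$k2 - k2_lo) < 1e-9 || abs(fb$k2 - k2_hi) < 1e-9))
  runner_up <- if (nrow(fine) > 1) sort(fine$err)[2] - fb$err else NA_real_

  eta_opt <- if (degenerate) Inf else max(slave_eta(fb$k1, fb$k2), 1e-9)
  params <- mechanical_params(T0, fb$k1, if (degenerate) 0 else fb$k2, eta_opt)
  structure(list(params = params, relaxation = relaxation,
                 error = fb$err, T0_hat = T0_hat,
                 halt = halt, sin_theta_star = sin_star,
                 diagnostics = list(coarse = coarse, fine = fine,
                                    n_eval = n_eval, recenters = recenters,
                                    runner_up_gap = runner_up,
                                    boundary = boundary, tie = tie,
                                    degenerate_maxwell = degenerate)),
            class = "fit_result")
}

#' Fit a full experiment trace (staged pipeline)
#'
#' Runs the sequential inference: derive kinematics, detect the stage halt,
#' build the loading-phase tension curve, extract the pre-tension intercept,
#' fit the hold-phase exponential relaxation, then grid-search (k1, k2)
#' with the viscosity slaved to the relaxation time. All intermediate
#' estimates are kept in the result for provenance.
#'
#' @param trace An [experiment_trace()].
#' @param config A [fit_config()].
#' @return A `fit_result` (see [grid_search()]) with an added `stages` list
#'   (halt, tension curve, intercept fit, relaxation fit).
#' @export
fit_experiment <- function(trace, config = fit_config()) {
  stopifnot(inherits(trace, "experiment_trace"))
  halt <- tryCatch(detect_halt(trace),
                   error = function(e) stop("detect_halt: ", conditionMessage(e), call. = FALSE))
  curve <- tryCatch(tension_deformation_curve(trace, t_star = halt$t_star,
                                              e_min = config$e_min),
                    error = function(e) stop("tension_deformation_curve: ",
                                             conditionMessage(e), call. = FALSE))
  T0_hat <- tryCatch(extract_pretension(curve, window_fracs = config$intercept_windows),
                     error = function(e) stop("extract_pretension: ",
                                              conditionMessage(e), call. = FALSE))
  relax <- tryCatch(fit_relaxation(trace, halt$t_star, t_min = config$relax_t_min),
                    error = function(e) stop("fit_relaxation: ",
                                             conditionMessage(e), call. = FALSE))
  res <- grid_search(trace, T0_hat, relax, config, halt = halt)
  res$stages <- list(halt = halt, curve = curve, T0_hat = T0_hat,
                     relaxation = relax)
  res
}

#' Parameter ratios between two conditions
#'
#' Elementwise after/before ratios of the four recovered parameters, the
#' comparison used for paired drug experiments (e.g. ROCK inhibition, where
#' the pre-tension ratio is the readout). Ratios with a near-zero
#' denominator are returned as `NA` and flagged.
#'
#' @param fit_before,fit_after `fit_result` objects for the same fiber.
#' @param tol Denominator threshold below which a ratio is undefined.
#' @return Named numeric vector `c(T0, k1, k2, eta)` of ratios, with
#'   attribute `undefined` naming any guarded entries.
#' @export
compare_conditions <- function(fit_before, fit_after, tol = 1e-9) {
  stopifnot(inherits(fit_before, "fit_result"), inherits(fit_after, "fit_result"))
  pb <- fit_before$params; pa <- fit_after$params
  before <- c(T0 = pb$T0, k1 = pb$k1, k2 = pb$k2, eta = pb$eta)
  after <- c(T0 = pa$T0, k1 = pa$k1, k2 = pa$k2, eta = pa$eta)
  ratios <- after / before
  ratios[is.infinite(before) & is.infinite(after)] <- NA_real_
  undef <- names(before)[abs(before) < tol | is.infinite(before)]
  ratios[names(ratios) %in% undef] <- NA_real_
  structure(ratios, undefined = undef)
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Stress-fiber SLS fit\n")
  print(x$params)
  cat(sprintf("  T0 intercept: %.4g nN (loading slope %.4g nN/um)\n",
              as.numeric(x$T0_hat), attr(x$T0_hat, "slope")))
  if (!is.null(x$relaxation$tau) && !is.na(x$relaxation$tau)) {
    cat(sprintf("  relaxation: tau = %.4g s, e_inf = %.4g um, R^2 = %.4f%s\n",
                x$relaxation$tau, x$relaxation$e_inf, x$relaxation$r_squared,
                if (isTRUE(x$relaxation$flagged)) " [flagged]" else ""))
  } else {
    cat("  relaxation: degenerate (no measurable Maxwell branch)\n")
  }
  cat(sprintf("  normalized misfit: %.4g (%d ODE solves%s%s)\n",
              x$error, x$diagnostics$n_eval,
              if (isTRUE(x$diagnostics$boundary)) ", optimum on boundary" else "",
              if (isTRUE(x$diagnostics$tie)) ", tie" else ""))
  invisible(x)
}
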