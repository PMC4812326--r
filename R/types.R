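#' Fiber geometry
#'
#' Describes the rest geometry of a probed stress fiber: the probe contacts
#' the fiber at its midpoint, so the fiber consists of two segments of rest
#' half-length `d` anchored at focal adhesions.
#'
#' @param d Fiber half-length in micrometers. Must be positive; values
#'   outside the plausible experimental band (10--60 um, cf. measured fibers
#'   of 22--35 um) trigger a warning, not an error.
#' @return An object of class `fiber_geometry`.
#' @examples
#' fiber_geometry(28.4)
#' @export
fiber_geometry <- function(d) {
  stopifnot(is.numeric(d), length(d) == 1L, is.finite(d))
  if (d <= 0) stop("fiber half-length d must be > 0 (um)")
  if (d < 10 || d > 60) {
    warning(sprintf("d = %.3g um is outside the plausible range [10, 60] um", d))
  }
  structure(list(d = as.numeric(d)), class = "fiber_geometry")
}

#' Cantilever probe
#'
#' @param k_clv Cantilever spring constant in nN/um. Must be positive;
#'   values outside [1, 10] nN/um (experimental probes span 1.53--6.25)
#'   trigger a warning.
#' @return An object of class `cantilever_probe`.
#' @examples
#' cantilever_probe(3.0)
#' @export
cantilever_probe <- function(k_clv) {
  stopifnot(is.numeric(k_clv), length(k_clv) == 1L, is.finite(k_clv))
  if (k_clv <= 0) stop("cantilever spring constant k_clv must be > 0 (nN/um)")
  if (k_clv < 1 || k_clv > 10) {
    warning(sprintf("k_clv = %.3g nN/um is outside the plausible range [1, 10] nN/um",
                    k_clv))
  }
  structure(list(k_clv = as.numeric(k_clv)), class = "cantilever_probe")
}

#' Mechanical parameters of the active standard linear solid
#'
#' The fiber's constitutive model has three parallel branches: an active
#' element carrying constant pre-tension `T0`, a primary spring `k1`, and a
#' Maxwell branch (spring `k2` in series with a dashpot `eta`) whose internal
#' tension relaxes with intrinsic time `eta / k2`.
#'
#' `k2 = 0` is admitted as the pure-elastic mode (the Maxwell branch carries
#' no tension); `eta = Inf` freezes the dashpot, which makes the Maxwell
#' spring act as an additional parallel spring.
#'
#' @param T0 Pre-tension, nN (>= 0).
#' @param k1 Primary spring constant, nN/um (>= 0).
#' @param k2 Maxwell spring constant, nN/um (>= 0; 0 means pure-elastic).
#' @param eta Dashpot viscosity, nN.s/um (> 0; may be `Inf`).
#' @return An object of class `mechanical_params`.
#' @examples
#' mechanical_params(T0 = 7.44, k1 = 3.23, k2 = 10.94, eta = 7.85)
#' @export
mechanical_params <- function(T0, k1, k2, eta) {
  vals <- c(T0 = T0, k1 = k1, k2 = k2, eta = eta)
  stopifnot(is.numeric(vals), length(vals) == 4L, !anyNA(vals))
  if (T0 < 0) stop("pre-tension T0 must be >= 0 (nN)")
  if (k1 < 0) stop("spring constant k1 must be >= 0 (nN/um)")
  if (k2 < 0) stop("spring constant k2 must be >= 0 (nN/um)")
  if (eta <= 0) stop("viscosity eta must be > 0 (nN.s/um)")
  structure(list(T0 = as.numeric(T0), k1 = as.numeric(k1),
                 k2 = as.numeric(k2), eta = as.numeric(eta)),
            class = "mechanical_params")
}

#' Stage motion protocol
#'
#' Piecewise-linear stage trajectory: a ramp at speed `v0` until the stage
#' displacement reaches `delta_s_star`, then a hold of duration `t_hold`.
#' The halt time is `t_star = delta_s_star / v0`.
#'
#' @param v0 Nominal stage speed, um/s (> 0; default 5).
#' @param delta_s_star Stage displacement at halt, um (> 0; default 20).
#' @param t_hold Hold duration after the halt, s (>= 0; default 10).
#' @param sample_rate Output sampling rate, Hz (>= 10; default 50).
#' @return An object of class `stage_protocol` with derived field `t_star`.
#' @export
stage_protocol <- function(v0 = 5, delta_s_star = 20, t_hold = 10,
                           sample_rate = 50) {
  stopifnot(is.numeric(v0), is.numeric(delta_s_star), is.numeric(t_hold),
            is.numeric(sample_rate))
  if (v0 <= 0) stop("stage speed v0 must be > 0 (um/s)")
  if (delta_s_star <= 0) stop("delta_s_star must be > 0 (um)")
  if (t_hold < 0) stop("t_hold must be >= 0 (s)")
  if (sample_rate < 10) stop("sample_rate must be >= 10 Hz")
  structure(list(v0 = as.numeric(v0), delta_s_star = as.numeric(delta_s_star),
                 t_hold = as.numeric(t_hold),
                 sample_rate = as.numeric(sample_rate),
                 t_star = as.numeric(delta_s_star) / as.numeric(v0)),
            class = "stage_protocol")
}

#' Stage displacement at time t under a protocol
#'
#' @param protocol A [stage_protocol()].
#' @param t Numeric vector of times, s.
#' @return Stage displacement delta_s(t), um.
#' @export
stage_displacement <- function(protocol, t) {
  pmin(protocol$v0 * t, protocol$delta_s_star)
}

#' ODE solver configuration
#'
#' @param rtol Relative tolerance (default 1e-8, ode45-class accuracy).
#' @param atol Absolute tolerance, um (default 1e-10).
#' @param method deSolve integration method (default `"ode45"`).
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(rtol = 1e-8, atol = 1e-10, method = "ode45") {
  stopifnot(rtol > 0, atol > 0, is.character(method))
  structure(list(rtol = rtol, atol = atol, method = method),
            class = "solver_config")
}

#' @export
print.mechanical_params <- function(x, ...) {
  cat(sprintf("SLS parameters: T0 = %.4g nN, k1 = %.4g nN/um, k2 = %.4g nN/um, eta = %.4g nN.s/um\n",
              x$T0, x$k1, x$k2, x$eta))
  invisible(x)
}

#' @export
print.stage_protocol <- function(x, ...) {
  cat(sprintf("Stage protocol: ramp %.3g um/s to %.3g um (t* = %.3g s), hold %.3g s, %g Hz\n",
              x$v0, x$delta_s_star, x$t_star, x$t_hold, x$sample_rate))
  invisible(x)
}
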