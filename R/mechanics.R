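#' Half-fiber elongation from transverse displacement
#'
#' A fiber of rest half-length `d` pulled transversally at its midpoint by a
#' distance `e` has elongated half-length `sqrt(d^2 + e^2)`; the elongation
#' per half-fiber is `delta = sqrt(d^2 + e^2) - d`.
#'
#' @param geometry A [fiber_geometry()].
#' @param e Transverse midpoint displacement, um (>= 0; vectorized).
#' @return Numeric vector of elongations `delta` (um), with attribute
#'   `strain` = delta / d.
#' @examples
#' transverse_to_elongation(fiber_geometry(28.4), 15)
#' @export
transverse_to_elongation <- function(geometry, e) {
  stopifnot(inherits(geometry, "fiber_geometry"), is.numeric(e))
  if (any(e < 0, na.rm = TRUE)) {
    stop("e must be >= 0 (outward-stretch convention; record probing direction as metadata)")
  }
  d <- geometry$d
  delta <- sqrt(d^2 + e^2) - d
  attr(delta, "strain") <- delta / d
  delta
}

#' Sine of the projection angle
#'
#' `theta` is the angle between the displaced fiber segment and the initial
#' fiber axis; `sin(theta) = e / sqrt(d^2 + e^2)` projects segment tension
#' onto the probe displacement axis.
#'
#' @inheritParams transverse_to_elongation
#' @return `sin(theta)` in [0, 1), vectorized, monotone increasing in `e`.
#' @export
projection_sine <- function(geometry, e) {
  stopifnot(inherits(geometry, "fiber_geometry"), is.numeric(e))
  if (any(e < 0, na.rm = TRUE)) stop("e must be >= 0")
  e / sqrt(geometry$d^2 + e^2)
}

#' Fiber tension from cantilever force
#'
#' Quasi-static balance: the cantilever force is carried by the transverse
#' projections of the tension in the two fiber segments,
#' `F_clv = 2 T sin(theta)`, so `T = F_clv / (2 sin(theta))`.
#'
#' Samples with `e < e_min` are rejected: near zero deflection the 1/sin
#' amplification turns pixel-scale displacement noise into unbounded tension
#' noise, so such samples must be excluded from tension curves.
#'
#' @param F_clv Cantilever force, nN (vectorized with `e`).
#' @param geometry A [fiber_geometry()].
#' @param e Transverse displacement, um.
#' @param e_min Minimum admissible `e`, um (default 1).
#' @return Tension `T`, nN.
#' @examples
#' tension_from_force(18, fiber_geometry(28.4), 15)
#' @export
tension_from_force <- function(F_clv, geometry, e, e_min = 1.0) {
  stopifnot(is.numeric(F_clv), is.numeric(e))
  if (any(e < e_min, na.rm = TRUE)) {
    stop(sprintf("tension undefined for e < e_min = %.3g um (0/0 guard); exclude these samples",
                 e_min))
  }
  F_clv / (2 * projection_sine(geometry, e))
}

#' Constitutive tension of the active standard linear solid
#'
#' Three parallel branches: active pre-tension, primary spring, Maxwell
#' branch. `T = T0 + k1 * delta + T_m`.
#'
#' @param params A [mechanical_params()].
#' @param delta Half-fiber elongation, um (>= 0; vectorized with `T_m`).
#' @param T_m Maxwell-branch tension, nN.
#' @return Total fiber tension, nN.
#' @export
constitutive_tension <- function(params, delta, T_m) {
  stopifnot(inherits(params, "mechanical_params"))
  if (any(delta < 0, na.rm = TRUE)) stop("delta must be >= 0")
  params$T0 + params$k1 * delta + T_m
}

#' Evolution rate of the Maxwell-branch tension
#'
#' The branch spring `k2` in series with dashpot `eta` gives
#' `dT_m/dt = k2 * delta_dot - (k2/eta) * T_m`: at constant elongation rate
#' the branch tension saturates at `eta * delta_dot`; at rest it decays with
#' the intrinsic Maxwell time `eta / k2`.
#'
#' @param params A [mechanical_params()].
#' @param delta_dot Elongation rate of the half-fiber, um/s.
#' @param T_m Current Maxwell-branch tension, nN.
#' @return dT_m/dt, nN/s.
#' @export
maxwell_rate <- function(params, delta_dot, T_m) {
  stopifnot(inherits(params, "mechanical_params"))
  kr <- if (is.infinite(params$eta)) 0 else params$k2 / params$eta
  params$k2 * delta_dot - kr * T_m
}

#' Tension error from off-center probe placement
#'
#' If the probe splits the fiber into rest lengths `d1 : d2 = length_ratio`
#' (with `d1 + d2 = 2 d`) but tension is inferred with the symmetric formula
#' `T = F / (2 sin theta)` using half-length `d`, the inferred tension
#' overestimates the true (equal-in-both-segments) tension. In the
#' small-transverse-displacement limit the relative error is
#' `(d/2) * (1/d1 + 1/d2) - 1`, independent of `d`.
#'
#' @param length_ratio Ratio of the longer to the shorter segment rest
#'   length (>= 1; vectorized).
#' @return Relative tension error (dimensionless); 0 for symmetric
#'   placement, 1/24 (about 4.2 percent) for a 1.5:1 split.
#' @examples
#' asymmetric_tension_error(1.5)  # 1/24
#' @export
asymmetric_tension_error <- function(length_ratio) {
  stopifnot(is.numeric(length_ratio))
  if (any(length_ratio < 1, na.rm = TRUE)) {
    stop("length_ratio must be >= 1 (longer over shorter segment)")
  }
  # d1 = 2d r/(1+r), d2 = 2d/(1+r); (d/2)(1/d1 + 1/d2) - 1
  r <- length_ratio
  (1 + r)^2 / (4 * r) - 1
}
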