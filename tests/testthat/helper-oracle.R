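# Independent reference implementations used to validate the package's
# solvers and closed forms. Deliberately brute-force and structurally
# different from the code under test.

# Fixed-step integration of the probed-fiber dynamics: at every step the
# quasi-static balance k_clv (delta_s - e) = 2 (T0 + k1*delta + T_m) sin(theta)
# is solved for e by bisection (with the current Maxwell tension), then T_m
# is stepped explicitly from the elongation increment. No ODE library, no
# differentiated constraint.
sls_bisection_oracle <- function(geometry, probe, params, protocol,
                                 dt = 1e-4, times = NULL) {
  d <- geometry$d
  kclv <- probe$k_clv
  T0 <- params$T0; k1 <- params$k1; k2 <- params$k2
  kr <- if (is.infinite(params$eta)) 0 else k2 / params$eta
  t_end <- protocol$t_star + protocol$t_hold
  if (is.null(times)) {
    times <- seq(0, t_end, by = 1 / protocol$sample_rate)
  }
  n_steps <- ceiling(t_end / dt)

  balance_root <- function(ds, Tm, lo, hi) {
    f <- function(e) {
      L <- sqrt(d^2 + e^2)
      kclv * (ds - e) - 2 * (T0 + k1 * (L - d) + Tm) * e / L
    }
    if (f(lo) < 0) return(lo)
    while (f(hi) > 0) {              # expand bracket if needed
      lo <- hi
      hi <- min(hi + 1, ds)
      if (hi >= ds) return(ds)
    }
    for (i in 1:40) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }

  e <- 0; Tm <- 0
  delta_prev <- 0
  out_e <- numeric(length(times))
  out_Tm <- numeric(length(times))
  out_i <- 1L
  # record t = 0
  while (out_i <= length(times) && times[out_i] <= 0) {
    out_e[out_i] <- e; out_Tm[out_i] <- Tm; out_i <- out_i + 1L
  }
  for (k in seq_len(n_steps)) {
    t_new <- min(k * dt, t_end)
    ds <- min(protocol$v0 * t_new, protocol$delta_s_star)
    e <- balance_root(ds, Tm, lo = e, hi = min(e + 0.005, ds))
    L <- sqrt(d^2 + e^2)
    delta_new <- L - d
    Tm <- Tm + (t_new - (k - 1) * dt) *
      (k2 * (delta_new - delta_prev) / (t_new - (k - 1) * dt) - kr * Tm)
    delta_prev <- delta_new
    while (out_i <= length(times) && times[out_i] <= t_new + 1e-12) {
      out_e[out_i] <- e; out_Tm[out_i] <- Tm; out_i <- out_i + 1L
    }
  }
  data.frame(t = times, e = out_e, T_m = out_Tm)
}

# Finite-e force balance for an off-center probe: both rest segments carry
# the same tension T_true; the transverse force is T (sin theta1 + sin
# theta2); the symmetric formula infers T_hat = F / (2 sin theta) with
# half-length d. Returns the relative tension error at finite e.
asymmetry_oracle <- function(length_ratio, e, d = 28.4, T_true = 1) {
  d1 <- 2 * d * length_ratio / (1 + length_ratio)
  d2 <- 2 * d / (1 + length_ratio)
  F <- T_true * (e / sqrt(d1^2 + e^2) + e / sqrt(d2^2 + e^2))
  T_hat <- F / (2 * e / sqrt(d^2 + e^2))
  T_hat / T_true - 1
}

# Richardson-style e -> 0 extrapolation of the finite-e asymmetry error.
asymmetry_oracle_limit <- function(length_ratio, d = 28.4,
                                   e_values = c(0.4, 0.2, 0.1, 0.05)) {
  err <- vapply(e_values, function(e) asymmetry_oracle(length_ratio, e, d),
                numeric(1))
  # quadratic in e: fit err ~ e^2 and take the intercept
  unname(coef(lm(err ~ I(e_values^2)))[1])
}

# Shared fixture: Table-1 mean fiber under the default protocol.
default_fiber <- function() {
  list(geometry = fiber_geometry(28.4),
       probe = cantilever_probe(3.0),
       params = mechanical_params(7.44, 3.23, 10.94, 7.85),
       protocol = stage_protocol(5, 20, 10, 50))
}

noise_free_trace <- function(fx = default_fiber()) {
  sim <- forward_simulate(fx$geometry, fx$probe, fx$params, fx$protocol)
  experiment_trace(sim$t, sim$delta_s, sim$delta_clv,
                   d = fx$geometry$d, k_clv = fx$probe$k_clv)
}
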