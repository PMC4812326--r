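fx <- default_fiber()
nf_trace <- noise_free_trace(fx)

test_that("kinematics derivation is the defining linear map", {
  tr <- experiment_trace(c(0, 0.1, 0.2), c(0, 1, 2), c(0, 0.4, 0.8),
                         d = 28.4, k_clv = 2)
  k <- derive_kinematics(tr)
  expect_equal(k$e, c(0, 0.6, 1.2))
  expect_equal(k$F_clv, c(0, 0.8, 1.6))
  # rigid fiber limit: stage and cantilever move together
  trr <- experiment_trace(c(0, 0.1, 0.2), c(0, 1, 2), c(0, 1, 2),
                          d = 28.4, k_clv = 2)
  expect_equal(derive_kinematics(trr)$e, c(0, 0, 0))
  # round-trip against the simulator's own channels
  sim <- forward_simulate(fx$geometry, fx$probe, fx$params, fx$protocol)
  expect_equal(nf_trace$e, sim$e)
  expect_equal(nf_trace$F_clv, sim$F_clv)
  expect_error(experiment_trace(c(0, 1), c(0, 1, 2), c(0, 0, 0), 28.4, 2),
               "equal length")
  expect_error(experiment_trace(c(0, 1, 0.5), c(0, 1, 2), c(0, 0, 0), 28.4, 2),
               "increasing")
})

test_that("the stage halt is detected at the ramp-hold corner", {
  h <- detect_halt(nf_trace)
  expect_equal(h$t_star, 4, tolerance = 1 / 50 + 1e-12)
  expect_equal(h$delta_s_star, 20, tolerance = 1e-9)
  expect_equal(h$v0_hat, 5, tolerance = 1e-6)
  # pure ramp: no halt to find
  t <- seq(0, 4, 0.02)
  ramp <- experiment_trace(t, 5 * t, 0.3 * t, d = 28.4, k_clv = 3)
  expect_error(detect_halt(ramp), "manually")
  # hold from the start
  still <- experiment_trace(t, rep(2, length(t)), rep(0.5, length(t)),
                            d = 28.4, k_clv = 3)
  expect_equal(detect_halt(still)$t_star, 0)
  # noisy trace: within a few sample periods
  set.seed(42)
  noisy <- experiment_trace(nf_trace$t,
                            nf_trace$delta_s + rnorm(nrow(nf_trace), 0, 0.02),
                            nf_trace$delta_clv + rnorm(nrow(nf_trace), 0, 0.05),
                            d = 28.4, k_clv = 3)
  expect_lt(abs(detect_halt(noisy)$t_star - 4), 0.1)
})

test_that("the tension-deformation curve reproduces the constitutive law", {
  # pure elastic: curve is exactly T0 + k1 delta
  mpe <- mechanical_params(7.44, 3.23, 0, 1)
  sime <- forward_simulate(fx$geometry, fx$probe, mpe, fx$protocol)
  tre <- experiment_trace(sime$t, sime$delta_s, sime$delta_clv,
                          d = 28.4, k_clv = 3)
  cve <- tension_deformation_curve(tre, t_star = 4)
  expect_equal(cve$T, 7.44 + 3.23 * cve$delta, tolerance = 1e-7)
  # viscous fiber: loading curve lies above the elastic line
  cv <- tension_deformation_curve(nf_trace, t_star = 4)
  expect_true(all(cv$T > 7.44 + 3.23 * cv$delta - 1e-9))
  # only loading samples with e >= e_min are retained
  expect_true(all(nf_trace$e[attr(cv, "retained")] >= 1))
  expect_lte(max(nf_trace$t[attr(cv, "retained")]), 4)
  # hold-only trace has no loading phase to analyze
  still <- experiment_trace(seq(0, 2, 0.02), rep(2, 101), rep(0.5, 101),
                            d = 28.4, k_clv = 3)
  expect_error(tension_deformation_curve(still), "fewer than 5")
})

test_that("pre-tension extraction is exact on linear curves and de-biased on viscous ones", {
  lin <- structure(data.frame(delta = 1:10, T = 5 + 2 * (1:10)),
                   class = c("tension_curve", "data.frame"))
  T0l <- extract_pretension(lin)
  expect_equal(as.numeric(T0l), 5)
  expect_equal(attr(T0l, "slope"), 2)
  const <- structure(data.frame(delta = seq(0, 3, length.out = 20),
                                T = rep(7.44, 20)),
                     class = c("tension_curve", "data.frame"))
  expect_equal(as.numeric(extract_pretension(const)), 7.44)
  # plain OLS intercept overestimates T0 whenever the fiber is viscous
  for (k1 in c(1, 3.23, 6)) for (eta in c(2, 7.85, 15)) {
    simv <- forward_simulate(fx$geometry, fx$probe,
                             mechanical_params(7.44, k1, 10.94, eta),
                             fx$protocol)
    trv <- experiment_trace(simv$t, simv$delta_s, simv$delta_clv,
                            d = 28.4, k_clv = 3)
    cvv <- tension_deformation_curve(trv, t_star = 4)
    expect_gt(as.numeric(extract_pretension(cvv, window_fracs = 1)), 7.44)
  }
  # the windowed extrapolation removes most of that bias
  cv <- tension_deformation_curve(nf_trace, t_star = 4)
  expect_equal(as.numeric(extract_pretension(cv)), 7.44, tolerance = 0.1)
  expect_gt(attr(extract_pretension(cv), "intercept_full"), 7.44)
})

test_that("relaxation fitting recovers exact exponentials and flags flat holds", {
  t <- seq(0, 14, 0.02)
  e <- ifelse(t <= 4, 10 * t / 4, 10 + 3 * (1 - exp(-(t - 4) / 2)))
  tr <- experiment_trace(t, e, rep(0, length(t)), d = 28.4, k_clv = 3)
  rf <- fit_relaxation(tr, 4)
  expect_equal(rf$tau, 2, tolerance = 1e-6)
  expect_equal(rf$e_inf, 3, tolerance = 1e-6)
  expect_equal(rf$r_squared, 1, tolerance = 1e-9)
  expect_false(rf$flagged)
  # flat hold: degenerate Maxwell branch
  ef <- ifelse(t <= 4, 10 * t / 4, 10)
  trf <- experiment_trace(t, ef, rep(0, length(t)), d = 28.4, k_clv = 3)
  rff <- fit_relaxation(trf, 4)
  expect_true(rff$degenerate)
  expect_true(is.na(rff$tau))
  expect_equal(rff$e_inf, 0)
  # simulated hold: single exponential consistent with the linearization
  rfs <- fit_relaxation(nf_trace, 4)
  tau_lin <- as.numeric(relaxation_time_linearized(fx$geometry, fx$probe,
                                                   fx$params, 20))
  expect_equal(rfs$tau, tau_lin, tolerance = 0.05)
})

test_that("the eta-k2-tau relation obeys its limiting cases", {
  expect_lt(eta_from_k2(3.23, 1e-9, 2.3, 0.47, 3), 1e-8)   # k2 -> 0: eta -> 0
  expect_equal(eta_from_k2(3.23, 10.94, 2.3, 0.47, 1e9), 2.3 * 10.94,
               tolerance = 1e-6)                            # rigid cantilever
  # explicit formula value
  s2 <- 0.47^2
  expect_equal(eta_from_k2(3.23, 10.94, 2.3, 0.47, 3),
               2.3 * 10.94 * (3 + 2 * s2 * 3.23) / (3 + 2 * s2 * (3.23 + 10.94)))
  # the geometric stiffness term raises the inferred viscosity
  expect_gt(eta_from_k2(3.23, 10.94, 2.3, 0.47, 3, geom_stiffness = 1),
            eta_from_k2(3.23, 10.94, 2.3, 0.47, 3))
})

test_that("the linearized relaxation time matches the simulated asymptotic rate", {
  # sweep stiffness ratios, probe angles and cantilever constants; compare
  # the closed-form linearization at the hold equilibrium against the
  # instantaneous relaxation rate measured from the simulated tail
  d <- 28.4; T0 <- 7.44; k1 <- 3
  g <- fiber_geometry(d)
  for (ratio in c(0.5, 3, 10)) for (s_t in c(0.2, 0.5)) for (kclv in c(1.53, 6.25)) {
    mp <- mechanical_params(T0, k1, ratio * k1, 0.72 * ratio * k1)
    p <- cantilever_probe(kclv)
    e_t <- d * s_t / sqrt(1 - s_t^2)
    ds_star <- e_t + 2 * (T0 + k1 * (sqrt(d^2 + e_t^2) - d)) * s_t / kclv
    tau_lin <- relaxation_time_linearized(g, p, mp, ds_star)
    pr <- stage_protocol(5, ds_star, 12 * as.numeric(tau_lin), 50)
    sim <- forward_simulate(g, p, mp, pr)
    hold <- sim[sim$t > pr$t_star + 8 * as.numeric(tau_lin), ]
    e_eq <- attr(tau_lin, "e_eq")
    lam <- diff(hold$e) / diff(hold$t) /
      (e_eq - (head(hold$e, -1) + tail(hold$e, -1)) / 2)
    tau_sim <- 1 / median(lam)
    expect_equal(tau_sim, as.numeric(tau_lin), tolerance = 0.02,
                 label = sprintf("tau (k2/k1=%g, sin=%g, kclv=%g)",
                                 ratio, s_t, kclv))
  }
})

test_that("the aggregated error is a normalized e-residual RMS", {
  sim <- forward_simulate(fx$geometry, fx$probe, fx$params, fx$protocol,
                          times = nf_trace$t)
  expect_equal(as.numeric(aggregated_error(sim, nf_trace)), 0, tolerance = 1e-12)
  # constant offset of c * max|e| scores exactly |c|
  sim2 <- sim
  sim2$e <- sim$e + 0.01 * max(abs(nf_trace$e))
  expect_equal(as.numeric(aggregated_error(sim2, nf_trace)), 0.01,
               tolerance = 1e-12)
  expect_true(is.numeric(attr(aggregated_error(sim, nf_trace), "force_rmse")))
  # one fine grid step in k1 is distinguishable
  simk <- forward_simulate(fx$geometry, fx$probe,
                           mechanical_params(7.44, 3.33, 10.94, 7.85),
                           fx$protocol, times = nf_trace$t)
  expect_gt(as.numeric(aggregated_error(simk, nf_trace)), 0)
  expect_error(aggregated_error(sim[1:10, ], nf_trace), "time grid")
})

test_that("the staged pipeline recovers the generating parameters from a noise-free trace", {
  fit <- fit_experiment(nf_trace)
  expect_s3_class(fit, "fit_result")
  expect_equal(fit$params$k1, 3.23, tolerance = 0.2 / 3.23)
  expect_equal(fit$params$k2, 10.94, tolerance = 1.0 / 10.94)
  expect_equal(fit$params$eta, 7.85, tolerance = 0.15)
  expect_equal(fit$params$T0, 7.44, tolerance = 0.10)
  expect_false(fit$diagnostics$boundary)
  # error-surface sanity: the truth scores no worse than any probed point
  sim_truth <- forward_simulate(fx$geometry, fx$probe, fx$params,
                                fx$protocol, times = nf_trace$t)
  err_truth <- as.numeric(aggregated_error(sim_truth, nf_trace))
  expect_lte(err_truth, min(fit$diagnostics$coarse$err))
  expect_lte(err_truth, min(fit$diagnostics$fine$err))
  # provenance of the staged estimates travels with the result
  expect_named(fit$stages, c("halt", "curve", "T0_hat", "relaxation"))
})

test_that("a pure-elastic trace yields a degenerate Maxwell branch", {
  mpe <- mechanical_params(7.44, 3.23, 0, 1)
  sime <- forward_simulate(fx$geometry, fx$probe, mpe, fx$protocol)
  tre <- experiment_trace(sime$t, sime$delta_s, sime$delta_clv,
                          d = 28.4, k_clv = 3)
  fite <- fit_experiment(tre, fit_config(coarse_step = 2, fine_step = 0.1))
  expect_true(fite$diagnostics$degenerate_maxwell)
  expect_equal(fite$params$k2, 0)
  expect_equal(fite$params$k1, 3.23, tolerance = 0.1 / 3.23)
})

test_that("fitting is deterministic and condition ratios are guarded", {
  cfg <- fit_config(coarse_step = 4, fine_step = 0.5)
  f1 <- fit_experiment(nf_trace, cfg)
  f2 <- fit_experiment(nf_trace, cfg)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$error, f2$error)
  expect_identical(f1$diagnostics$fine, f2$diagnostics$fine)

  r_same <- compare_conditions(f1, f2)
  expect_equal(unname(r_same[c("T0", "k1", "k2", "eta")]), rep(1, 4))
  f3 <- f2
  f3$params <- mechanical_params(f2$params$T0 * 0.58, f2$params$k1,
                                 f2$params$k2, f2$params$eta)
  expect_equal(unname(compare_conditions(f1, f3)["T0"]), 0.58)
  # near-zero denominator is flagged, not divided through
  fz <- f2
  fz$params <- mechanical_params(0, f2$params$k1, f2$params$k2, f2$params$eta)
  rz <- compare_conditions(fz, f1)
  expect_true(is.na(rz["T0"]))
  expect_true("T0" %in% attr(rz, "undefined"))
})
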