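test_that("population sampling honors means, truncation and seeds", {
  pop0 <- population_spec(sd = c(T0 = 0, k1 = 0, k2 = 0, eta = 0), d_sd = 0)
  s0 <- sample_parameters(pop0, 1)
  expect_equal(s0$params$T0, 7.44)
  expect_equal(s0$params$k1, 3.23)
  expect_equal(s0$params$k2, 10.94)
  expect_equal(s0$params$eta, 7.85)
  expect_equal(s0$geometry$d, 28.4)

  pop <- population_spec()
  expect_identical(sample_parameters(pop, 7), sample_parameters(pop, 7))
  draws <- lapply(1:200, function(i) sample_parameters(pop, i))
  d_vals <- vapply(draws, function(x) x$geometry$d, numeric(1))
  expect_true(all(d_vals >= 22 & d_vals <= 35))
  expect_true(all(vapply(draws, function(x) x$params$T0, numeric(1)) >= 0.5))
  expect_true(all(vapply(draws, function(x) x$probe$k_clv, numeric(1)) %in%
                    pop$k_clv_choices))
  expect_error(population_spec(sd = c(T0 = -1, k1 = 0, k2 = 0, eta = 0)),
               ">= 0")
})

test_that("large samples of truncated draws concentrate near the specified means", {
  # truncation at the lower bounds shifts the mean upward slightly, so
  # compare against the closed-form truncated-normal mean
  pop <- population_spec()
  n <- 4000
  draws <- vapply(seq_len(n), function(i) {
    s <- sample_parameters(pop, i)
    c(T0 = s$params$T0, k1 = s$params$k1, k2 = s$params$k2,
      eta = s$params$eta)
  }, numeric(4))
  for (p in c("T0", "k1", "k2", "eta")) {
    mu <- pop$mean[[p]]; sg <- pop$sd[[p]]; lo <- pop$lower[[p]]
    a <- (lo - mu) / sg
    mu_trunc <- mu + sg * dnorm(a) / (1 - pnorm(a))
    x <- draws[p, ]
    expect_lt(abs(mean(x) - mu_trunc), 3 * sd(x) / sqrt(n))
  }
})

test_that("trace generation is exact at zero noise and reproducible under seed", {
  fx <- default_fiber()
  tr0 <- generate_trace(fx$geometry, fx$probe, fx$params, fx$protocol,
                        noise_model(0, 0), seed = 1)
  sim <- forward_simulate(fx$geometry, fx$probe, fx$params, fx$protocol)
  expect_equal(tr0$delta_s, sim$delta_s)
  expect_equal(tr0$delta_clv, sim$delta_clv)
  expect_equal(tr0$e, sim$e)

  tra <- generate_trace(fx$geometry, fx$probe, fx$params, fx$protocol,
                        noise_model(), seed = 5)
  trb <- generate_trace(fx$geometry, fx$probe, fx$params, fx$protocol,
                        noise_model(), seed = 5)
  expect_identical(tra$delta_clv, trb$delta_clv)
  trc <- generate_trace(fx$geometry, fx$probe, fx$params, fx$protocol,
                        noise_model(), seed = 6)
  expect_false(identical(tra$delta_clv, trc$delta_clv))
  # ground truth rides along for recovery scoring
  expect_equal(attr(tra, "truth")$params$T0, 7.44)
})

test_that("cohorts expand scenarios deterministically with shared per-fiber parameters", {
  sc <- scenario_spec(n_fibers = 2, pulls_per_fiber = 2, seed = 11L,
                      protocol = stage_protocol(5, 20, 2, 50))
  c1 <- generate_cohort(sc)
  c2 <- generate_cohort(sc)
  expect_equal(length(c1$traces), 4)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$traces[[1]]$delta_clv, c2$traces[[1]]$delta_clv)
  # pulls of one fiber share parameters; fibers differ
  expect_equal(c1$truth$T0[1], c1$truth$T0[2])
  expect_false(c1$truth$T0[1] == c1$truth$T0[3])

  sct <- scenario_spec(n_fibers = 2, treatment = c(T0 = 0.58), seed = 11L,
                       protocol = stage_protocol(5, 20, 2, 50))
  ct <- generate_cohort(sct)
  expect_equal(length(ct$traces), 4)
  tt <- ct$truth
  for (i in 1:2) {
    expect_equal(tt$T0[tt$fiber == i & tt$condition == "TREAT"],
                 0.58 * tt$T0[tt$fiber == i & tt$condition == "CTRL"])
    expect_equal(tt$k1[tt$fiber == i & tt$condition == "TREAT"],
                 tt$k1[tt$fiber == i & tt$condition == "CTRL"])
  }

  c0 <- generate_cohort(scenario_spec(n_fibers = 0))
  expect_equal(length(c0$traces), 0)
  expect_equal(nrow(c0$truth), 0)
})

test_that("the pipeline recovers parameters from a noisy trace at its stated tolerance", {
  fx <- default_fiber()
  tr <- generate_trace(fx$geometry, fx$probe, fx$params, fx$protocol,
                       noise_model(), seed = 7L)
  fit <- fit_experiment(tr)
  expect_equal(fit$params$T0, 7.44, tolerance = 0.25)
  expect_lt(abs(fit$params$k1 - 3.23), 0.5)
  # registration-scale noise leaves the relaxation fit strong but imperfect
  expect_gt(fit$relaxation$r_squared, 0.9)
  expect_lt(fit$relaxation$r_squared, 1)
})
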