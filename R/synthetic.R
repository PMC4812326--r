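#' Measurement noise model
#'
#' Additive i.i.d. Gaussian noise on the two measured displacement channels
#' (stage and cantilever positions are what image registration tracks;
#' force is derived, so it inherits noise rather than receiving its own).
#' Defaults are pixel-scale guesses and should be treated as configurable,
#' since the real registration noise magnitude is not characterized.
#'
#' @param sigma_stage Stage-channel noise s.d., um (default 0.02).
#' @param sigma_clv Cantilever-channel noise s.d., um (default 0.05).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma_stage = 0.02, sigma_clv = 0.05) {
  stopifnot(sigma_stage >= 0, sigma_clv >= 0)
  structure(list(sigma_stage = sigma_stage, sigma_clv = sigma_clv),
            class = "noise_model")
}

#' Population distribution of fiber parameters
#'
#' Independent truncated-normal distributions per mechanical parameter,
#' defaulting to the control-population statistics of semi-isolated stress
#' fibers (n = 13 fibers): T0 7.44 +/- 5.69 nN, k1 3.23 +/- 2.74 nN/um,
#' k2 10.94 +/- 10.75 nN/um, eta 7.85 +/- 6.74 nN.s/um. The half-length d
#' is 28.4 +/- 3.6 um truncated to the observed range [22, 35] um; the
#' cantilever is drawn from a discrete set spanning the fabricated probes
#' (1.53-6.25 nN/um). No cross-parameter covariance is modeled (none is
#' reported); this is a documented limitation.
#'
#' @param mean Named numeric: `T0`, `k1`, `k2`, `eta` means.
#' @param sd Named numeric: matching standard deviations (>= 0).
#' @param lower Named numeric: truncation lower bounds keeping draws in the
#'   physical regime.
#' @param d_mean,d_sd,d_range Half-length distribution (um).
#' @param k_clv_choices Discrete cantilever spring constants, nN/um.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(mean = c(T0 = 7.44, k1 = 3.23, k2 = 10.94, eta = 7.85),
                            sd = c(T0 = 5.69, k1 = 2.74, k2 = 10.75, eta = 6.74),
                            lower = c(T0 = 0.5, k1 = 0.2, k2 = 0.5, eta = 0.5),
                            d_mean = 28.4, d_sd = 3.6, d_range = c(22, 35),
                            k_clv_choices = c(1.53, 3.0, 4.5, 6.25)) {
  nm <- c("T0", "k1", "k2", "eta")
  stopifnot(all(nm %in% names(mean)), all(nm %in% names(sd)),
            all(nm %in% names(lower)))
  if (any(sd < 0) || d_sd < 0) stop("standard deviations must be >= 0")
  stopifnot(d_range[1] < d_range[2], all(k_clv_choices > 0))
  structure(list(mean = mean[nm], sd = sd[nm], lower = lower[nm],
                 d_mean = d_mean, d_sd = d_sd, d_range = d_range,
                 k_clv_choices = k_clv_choices),
            class = "population_spec")
}

# One truncated-normal draw by rejection; exact at sd = 0 (returns the mean
# clamped into the support).
rtrunc1 <- function(mean, sd, lo, hi = Inf) {
  if (sd == 0) return(min(max(mean, lo), hi))
  for (i in 1:10000) {
    x <- rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  stop("truncated-normal rejection sampling failed (bounds too tight?)")
}

#' Draw one fiber + probe configuration from a population
#'
#' Deterministic under `seed`: the same seed always yields the same fiber.
#'
#' @param pop A [population_spec()].
#' @param seed Integer seed.
#' @return List with `params` ([mechanical_params()]), `geometry`
#'   ([fiber_geometry()]) and `probe` ([cantilever_probe()]).
#' @export
sample_parameters <- function(pop, seed) {
  stopifnot(inherits(pop, "population_spec"))
  set.seed(as.integer(seed))
  draws <- vapply(c("T0", "k1", "k2", "eta"), function(p) {
    rtrunc1(pop$mean[[p]], pop$sd[[p]], pop$lower[[p]])
  }, numeric(1))
  d <- rtrunc1(pop$d_mean, pop$d_sd, pop$d_range[1], pop$d_range[2])
  k_clv <- pop$k_clv_choices[sample.int(length(pop$k_clv_choices), 1)]
  list(params = mechanical_params(draws[["T0"]], draws[["k1"]],
                                  draws[["k2"]], draws[["eta"]]),
       geometry = fiber_geometry(d),
       probe = cantilever_probe(k_clv))
}

#' Generate one synthetic experiment trace
#'
#' Runs [forward_simulate()] and perturbs the two measured channels with
#' the noise model, reproducing what the image-registration measurement
#' delivers. The ground truth is recorded in the trace metadata for
#' recovery scoring.
#'
#' @param geometry,probe,params,protocol As in [forward_simulate()].
#' @param noise A [noise_model()].
#' @param seed Integer seed for the noise realization.
#' @param condition Condition label stored in metadata.
#' @param solver A [solver_config()].
#' @return An [experiment_trace()] whose `truth` attribute holds the
#'   generating parameters and the noise-free simulation.
#' @export
generate_trace <- function(geometry, probe, params,
                           protocol = stage_protocol(),
                           noise = noise_model(), seed = 1L,
                           condition = "CTRL", solver = solver_config()) {
  stopifnot(inherits(noise, "noise_model"))
  sim <- forward_simulate(geometry, probe, params, protocol, solver = solver)
  set.seed(as.integer(seed))
  n <- nrow(sim)
  delta_s <- sim$delta_s + rnorm(n, 0, noise$sigma_stage)
  delta_clv <- sim$delta_clv + rnorm(n, 0, noise$sigma_clv)
  experiment_trace(sim$t, delta_s, delta_clv,
                   d = geometry$d, k_clv = probe$k_clv,
                   condition = condition, seed = as.integer(seed),
                   truth = list(params = params, protocol = protocol,
                                noise = noise))
}

#' Scenario description for a synthetic cohort
#'
#' @param n_fibers Number of fibers.
#' @param pulls_per_fiber Repeated pulls per fiber (1-5; repeated pulls of
#'   a fiber share its parameters and are averaged at analysis time).
#' @param protocol A [stage_protocol()].
#' @param noise A [noise_model()].
#' @param population A [population_spec()].
#' @param treatment Optional named multiplicative factors applied to the
#'   parameters for a paired "after treatment" series (e.g.
#'   `c(T0 = 0.58)` for ROCK inhibition); `NULL` for no treatment arm.
#' @param seed Master seed; per-trace seeds are derived deterministically.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(n_fibers, pulls_per_fiber = 1,
                          protocol = stage_protocol(),
                          noise = noise_model(),
                          population = population_spec(),
                          treatment = NULL, seed = 1L) {
  stopifnot(n_fibers >= 0, pulls_per_fiber >= 1, pulls_per_fiber <= 5,
            inherits(protocol, "stage_protocol"),
            inherits(noise, "noise_model"),
            inherits(population, "population_spec"))
  if (!is.null(treatment)) {
    stopifnot(is.numeric(treatment), !is.null(names(treatment)),
              all(names(treatment) %in% c("T0", "k1", "k2", "eta")))
  }
  structure(list(n_fibers = as.integer(n_fibers),
                 pulls_per_fiber = as.integer(pulls_per_fiber),
                 protocol = protocol, noise = noise,
                 population = population, treatment = treatment,
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

apply_treatment <- function(params, treatment) {
  f <- c(T0 = 1, k1 = 1, k2 = 1, eta = 1)
  f[names(treatment)] <- treatment
  mechanical_params(params$T0 * f[["T0"]], params$k1 * f[["k1"]],
                    params$k2 * f[["k2"]], params$eta * f[["eta"]])
}

#' Generate a synthetic cohort
#'
#' Expands a [scenario_spec()] into per-pull experiment traces plus a truth
#' table. Pure function of the scenario: identical scenarios yield
#' identical cohorts. Per-fiber and per-pull seeds are derived from the
#' master seed (`seed + 1000*fiber + pull`, kept below 2^31). With a
#' treatment, each fiber additionally emits paired "after" pulls with the
#' scaled parameters.
#'
#' @param scenario A [scenario_spec()].
#' @param solver A [solver_config()].
#' @return List with `traces` (list of [experiment_trace()]) and `truth`
#'   (data.frame: fiber, pull, condition, d, k_clv, T0, k1, k2, eta, seed).
#' @export
generate_cohort <- function(scenario, solver = solver_config()) {
  stopifnot(inherits(scenario, "scenario_spec"))
  traces <- list()
  rows <- list()
  for (i in seq_len(scenario$n_fibers)) {
    fiber_seed <- scenario$seed + 1000L * i
    cfg <- sample_parameters(scenario$population, fiber_seed)
    arms <- list(CTRL = cfg$params)
    if (!is.null(scenario$treatment)) {
      arms$TREAT <- apply_treatment(cfg$params, scenario$treatment)
    }
    for (arm in names(arms)) {
      for (p in seq_len(scenario$pulls_per_fiber)) {
        pull_seed <- fiber_seed + p + if (arm == "TREAT") 500L else 0L
        tr <- generate_trace(cfg$geometry, cfg$probe, arms[[arm]],
                             scenario$protocol, scenario$noise,
                             seed = pull_seed, condition = arm,
                             solver = solver)
        traces[[length(traces) + 1L]] <- tr
        pp <- arms[[arm]]
        rows[[length(rows) + 1L]] <- data.frame(
          fiber = i, pull = p, condition = arm,
          d = cfg$geometry$d, k_clv = cfg$probe$k_clv,
          T0 = pp$T0, k1 = pp$k1, k2 = pp$k2, eta = pp$eta,
          seed = pull_seed)
      }
    }
  }
  truth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(fiber = integer(), pull = integer(), condition = character(),
               d = numeric(), k_clv = numeric(), T0 = numeric(),
               k1 = numeric(), k2 = numeric(), eta = numeric(),
               seed = integer())
  list(traces = traces, truth = truth)
}
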