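---
title: "Probing single stress fibers with a soft cantilever: model and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probing single stress fibers with a soft cantilever: model and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fiberSLS)
```

## The experiment and its model

A peripheral stress fiber, isolated from the surrounding cytoplasm but still
anchored at both ends, is a straight contractile bundle of rest half-length
$d$ (tens of micrometers). A calibrated soft cantilever (spring constant
$k_{clv}$, nN/µm) is placed against the fiber midpoint and the microscope
stage is translated perpendicular to the fiber axis: a ramp at nominal speed
$v_0$ up to a stage excursion $\delta_s^*$, then a hold. Image registration
yields two measured channels, the stage displacement $\delta_s(t)$ and the
cantilever deflection $\delta_{clv}(t)$; everything else is derived:

- transverse fiber displacement $e = \delta_s - \delta_{clv}$,
- cantilever force $F_{clv} = k_{clv}\,\delta_{clv}$,
- half-fiber elongation $\delta = \sqrt{d^2 + e^2} - d$ (strain $\delta/d$),
- projection angle $\sin\theta = e/\sqrt{d^2+e^2}$.

The probe is quasi-static (no inertia): at every instant the cantilever force
balances the transverse projections of the tension $T$ carried by the two
fiber segments,

$$ k_{clv}(\delta_s - e) \;=\; 2\,T\,\sin\theta(e). $$

The fiber itself is an *active standard linear solid* — three parallel
branches:

$$ T \;=\; T_0 \;+\; k_1\,\delta \;+\; T_m, \qquad
   \dot T_m \;=\; k_2\,\dot\delta \;-\; \frac{k_2}{\eta}\,T_m, $$

an active element of constant pre-tension $T_0$ (nN, motor activity), a
primary spring $k_1$ (nN/µm, the dominant elastic response), and a Maxwell
branch — spring $k_2$ (nN/µm) in series with a dashpot $\eta$ (nN·s/µm) —
whose internal tension $T_m$ relaxes with intrinsic time $\eta/k_2$. A
Kelvin–Voigt element cannot reproduce the observed combination of small
relaxation amplitudes with seconds-long time courses, because it ties the two
together; the extra series spring decouples them. All quantities are fixed
package-wide in µm, s, nN and combinations thereof; no unit inference.

### State-space form and solver

Differentiating the balance in time and substituting
$\dot\delta = \sin\theta\,\dot e$ gives an explicit ODE in the state
$(e, T_m)$:

$$ \dot e \;=\;
   \frac{k_{clv}\,\dot\delta_s + 2\sin\theta\,\tfrac{k_2}{\eta}\,T_m}
        {k_{clv} + 2(k_1+k_2)\sin^2\theta + G(e)},
   \qquad G(e) = \frac{2\,T\,d^2}{(d^2+e^2)^{3/2}}, $$

with $e(0)=0$, $T_m(0)=0$. $G$ is the *geometric stiffness*: the restoring
effect of the tension vector rotating as $e$ changes. Since the initial
condition satisfies the balance, the ODE preserves it exactly; the residual
$|k_{clv}(\delta_s - e) - 2T\sin\theta|$ is monitored at every output sample
and is reported on the simulated trace.

`forward_simulate()` integrates this system with an adaptive Runge–Kutta
pair (deSolve's `ode45` method, compiled right-hand side) at relative
tolerance $10^{-8}$ and absolute tolerance $10^{-10}$ µm. The stage
trajectory is the idealized piecewise-linear ramp-and-hold with no corner
smoothing; the ramp and hold are integrated as separate legs so the velocity
discontinuity at the halt time $t^* = \delta_s^*/v_0$ falls on a leg
boundary rather than inside an adaptive step. The dashpot ratio $k_2/\eta$
is passed to the compiled code pre-computed, so the pure-elastic mode
($k_2 = 0$, Maxwell branch inert) and the frozen-dashpot limit
($\eta = \infty$, $k_2$ acting as a second parallel spring) are exact
special cases rather than numerical limits. The test suite verifies the
integrator against two independent oracles: the algebraic equilibrium of the
elastic mode (root bracketing per sample) and a fixed-step ($10^{-4}$ s)
integrator that re-solves the nonlinear balance by bisection at every step.

### Conventions and guards

- $\delta$, $k_1$, $k_2$, $\eta$ and $T$ are all per *half-fiber* (rest
  length $d$); strain is $\delta/d$.
- $e$ is the magnitude of the transverse displacement; inward (compressive)
  probing is the same mechanics with the probe on the other side and is
  recorded only as a metadata flag.
- Tension inversion $T = F_{clv}/(2\sin\theta)$ is refused for
  $e < e_{\min} = 1$ µm: as $e \to 0$ the formula amplifies registration
  noise without bound (0/0), and pixel-scale noise dominates below about a
  micrometer. The threshold is configurable.

## The staged inference

`fit_experiment()` reproduces the sequential estimation used to analyze
probing recordings. Each stage feeds the next and all intermediate estimates
are kept in the result:

1. **Halt detection.** $t^*$ is the first sample from which the
   median-smoothed finite-difference stage speed stays below 10 % of the
   ramp speed for three consecutive intervals; a never-halting or
   never-moving trace is diagnosed explicitly.
2. **Pre-tension $T_0$.** The loading-phase tension–elongation curve
   ($e \ge e_{\min}$, $t \le t^*$) is largely linear, and its y-intercept
   estimates $T_0$. Because the viscous branch adds a positive,
   elongation-dependent tension during loading, the plain full-range
   intercept overestimates $T_0$ — under mean-population parameters and the
   default protocol by roughly a fifth, and downstream the $(k_2,\eta)$
   estimates inherit several times that error. Near $\delta = 0$, however,
   the viscous contribution vanishes (the loading curve starts with slope
   $k_1 + k_2$ but unbiased intercept), so the default estimator fits the
   line on two nested early-$\delta$ windows (25 % and 50 % of the
   elongation range) and extrapolates the intercept linearly to zero window
   size. `window_fracs = 1` restores the plain OLS intercept, whose upward
   bias is itself asserted as a property test. The full-range slope is kept
   as the pure-elastic upper bound for $k_1$.
3. **Relaxation time $\tau$.** After the halt, the additional displacement
   $e' = e - e^*$ follows $e'(t') = e_\infty(1 - \mathrm e^{-t'/\tau})$.
   Levenberg–Marquardt least squares, with starting values from a
   log-linear regression on lagged differences (which estimates $\tau$
   without knowing $e_\infty$ and works on any sub-window of the hold).
   Fits with $R^2 < 0.9$ are flagged; a flat hold is flagged *degenerate*
   and routes the fit into the pure-elastic branch.
4. **Slaving $\eta$ to $\tau$.** Linearizing the hold-phase dynamics about
   its relaxed equilibrium (the elastic equilibrium at $\delta_s^*$, where
   $T_m = 0$) gives a single exponential with
   $$ \tau \;=\; \frac{\eta}{k_2}\,
      \frac{k_{clv} + 2\sin^2\theta\,(k_1+k_2) + G}
           {k_{clv} + 2\sin^2\theta\,k_1 + G}, $$
   inverted for $\eta$ given a candidate $(k_1, k_2)$. The constant-angle
   form of this relation (drop $G$) is available via
   `eta_from_k2(..., geom_stiffness = 0)`, but under typical conditions
   ($T \sim 20$ nN, $d \sim 28$ µm) $G \sim 1$ nN/µm is comparable to soft
   cantilever constants and omitting it biases $\eta$ by about 6 %, which
   the grid search then converts into a $k_2$ error of several nN/µm. The
   geometric term is therefore included, evaluated per candidate at its own
   hold equilibrium; a property test sweeps $k_2/k_1 \in \{0.5, 3, 10\}$,
   $\sin\theta^* \in \{0.2, 0.5\}$ and $k_{clv} \in \{1.53, 6.25\}$ nN/µm
   and requires the formula to match the simulated asymptotic relaxation
   rate within 2 %.
5. **Grid search over $(k_1, k_2)$.** Coarse step 2 nN/µm over
   $k_1 \in [0, \text{loading slope}]$ and $k_2 \in (0.1, 40]$ nN/µm
   (bounds sized so the observed population spread fits with margin), then
   a fine step of 0.1 nN/µm inside a ±2 nN/µm window. Each candidate is
   scored by forward simulation on the measured time grid and the
   normalized displacement misfit
   $\mathrm{err} = \sqrt{N^{-1}\sum\left[(e_{exp}-e_{sim})/\max|e_{exp}|\right]^2}$;
   the force residual is proportional to the $e$ residual for a shared
   stage trace ($F_{clv} = k_{clv}(\delta_s - e)$), so it is reported as a
   diagnostic rather than double-counted. The $(k_1,k_2)$ error surface is
   a shallow curved valley, and a single fine window anchored at the coarse
   optimum can sit with the valley floor outside it; the fine window
   therefore re-centers itself (scores memoised) while its optimum lies on
   the moving window edge, stopping at the configured bounds. Exact ties
   break toward the smallest $(k_1, k_2)$ and are flagged, as is an optimum
   on a configured search bound.

The paired-condition comparison (`compare_conditions()`) reports elementwise
after/before parameter ratios with a guard against near-zero denominators —
the readout used for pharmacological interventions such as ROCK inhibition,
modeled as a multiplicative reduction of $T_0$.

## The synthetic-experiment generator

There are no deposited recordings for this kind of experiment, so the
package carries a generator that emulates the protocol end to end and is
itself first-class, tested code:

- **Protocol**: ramp at 5 µm/s to 20 µm, 10 s hold, 50 Hz sampling
  (acquisition must exceed 10 Hz for a 5 µm/s ramp).
- **Population**: independent truncated normals per parameter with the
  control-cohort statistics $T_0 = 7.44 \pm 5.69$ nN,
  $k_1 = 3.23 \pm 2.74$ nN/µm, $k_2 = 10.94 \pm 10.75$ nN/µm,
  $\eta = 7.85 \pm 6.74$ nN·s/µm; half-length $28.4 \pm 3.6$ µm truncated
  to the observed 22–35 µm; cantilever constants drawn from the discrete
  set {1.53, 3.0, 4.5, 6.25} nN/µm spanning the fabricated probes (the
  source reports only the range, so the set is a design choice). Lower
  truncation bounds (0.5 nN, 0.2 nN/µm, 0.5 nN/µm, 0.5 nN·s/µm) keep draws
  in the physically meaningful regime. No cross-parameter covariance is
  modeled because none is reported — a documented limitation.
- **Noise**: additive i.i.d. Gaussian on the two *measured* channels
  ($\sigma_{stage} = 0.02$ µm, $\sigma_{clv} = 0.05$ µm by default) — the
  displacements are what image registration measures, force is derived.
  The real registration noise magnitude is uncharacterized, so these are
  pixel-scale guesses and deliberately configurable.
- **Cohorts**: repeated pulls of a fiber share its parameters (replicates,
  averaged at analysis time, up to 5 per fiber); a treatment arm emits
  paired traces with multiplicative parameter factors (default
  $T_0 \times 0.58$ for the ROCK-inhibition scenario). Everything is a
  pure function of the scenario seed; per-trace seeds are derived
  arithmetically and stay below $2^{31}$.

What passing recovery tests on this generator shows — and what it does not:
the tests demonstrate that the staged inference identifies the model's
parameters from data *generated by the same model* under realistic protocol,
population and noise settings. Real recordings add ingredients the generator
deliberately omits: registration drift and outliers, slightly off-center or
non-perpendicular probe placement, along-fiber heterogeneity, adhesion
compliance, and any force-induced remodeling. Agreement here validates the
software and the identifiability of the method, not the constitutive model
itself.

## Validation scale and numerical choices

The checks are sized to run on a laptop-class machine in minutes: oracle
equivalence over the 14 s default protocol at $10^{-4}$ s steps; noise-free
recovery at the mean-population parameter point; a 3-fiber paired
treatment cohort at default noise; a 12-point linearization sweep; a
single-trace strain excursion to $\delta/d = 0.82$ (stage excursion 90 µm),
where the large-strain fit uses a coarser grid (steps 4 and 0.5 nN/µm) since
only robustness, not resolution, is at stake. Degenerate inputs are handled
explicitly rather than by failure: flat holds (pure-elastic fibers), traces
that never halt or never move, tension curves with too few retained samples,
and negative intercepts all produce typed errors or flags that name the
offending stage.

## Known limitations

- $T_0$ absorbs any passive tension present at the measured rest length; it
  is an upper bound on motor-generated tension, not a decomposition.
- The midpoint-load, two-straight-segment geometry ignores fiber bending
  stiffness, membrane tension, distributed loads and adhesion compliance.
- $k_2$ and $\eta$ are weakly identified when the relaxation amplitude is
  small relative to noise; the fit flags, rather than hides, degenerate and
  boundary solutions.
- The estimator of $T_0$ trades a small variance increase for a large bias
  reduction; on very short or very noisy loading phases the windowed
  extrapolation can be noisier than the plain intercept, which remains
  available.
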