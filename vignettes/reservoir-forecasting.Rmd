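---
title: "Forecasting a chaotic environment from a random reservoir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting a chaotic environment from a random reservoir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`chaosesn` asks a quantitative question with an evolutionary motivation: if
an organism's internal network is *random* — wired by no selective process at
all — how much usable information about the future of a chaotic environment
do its internal states nonetheless carry? The package answers by simulation,
in four stages.

### The environment: Lorenz–96

The environmental signal is the cyclic Lorenz–96 system

$$\frac{dx_i}{dt} = (x_{i+1} - x_{i-2})\,x_{i-1} - x_i + F,
\qquad i = 1, \dots, N,$$

with indices wrapping around (`x_0 = x_N` and so on). We use $N = 5$
throughout. The constant forcing $F$ is the single knob for how chaotic the
environment is: the system sits at the stable equilibrium $x_i = F$ for
small $F$ and becomes increasingly chaotic as $F$ rises above 8. The
quadratic advection term conserves "energy", the linear term damps, and the
forcing feeds energy in — a minimal caricature of a fluctuating environment
with tunable unpredictability.

Integration is fixed-step classical RK4 at $dt = 0.01$ time units, which is
also the cadence at which the reservoir is driven. A fixed step keeps runs
bit-reproducible from their seeds. Accuracy at this step is adequate for the
forcings studied ($F \le 12$): the test suite compares against an
independent adaptive Dormand–Prince integrator and confirms 4th-order
convergence. Note that on a chaotic attractor *any* integrator's pointwise
error grows as $e^{\lambda t}$; what matters for this analysis is that the
simulated trajectory lies on the attractor and has the right statistics, not
that it shadow a particular exact solution indefinitely.

Initial conditions are the equilibrium $F \cdot \mathbf{1}$ plus independent
Uniform$(-0.5, 0.5)$ perturbations — standard Lorenz–96 practice that starts
inside the attractor's basin. The first 100 time units are discarded as
washout so the recorded signal sits on the attractor; recorded samples are
the post-step states, and the initial state is not part of the record.

### Predictability: Lyapunov exponent and doubling time

The natural scale for "how far ahead can anything predict this signal" is
the divergence doubling time $\mathrm{dbl} = \ln 2 / \lambda$, where
$\lambda$ is the maximal Lyapunov exponent. We estimate $\lambda$ with the
classical two-trajectory Benettin procedure: a reference trajectory and a
copy perturbed by $d_0 = 10^{-9}$ evolve side by side; every 0.5 time units
the separation is renormalised back to $d_0$ and its log-growth recorded;
the first 10% of the horizon is discarded while the perturbation aligns
with the most expanding direction. Defaults (horizon 2000 time units,
renormalisation every 0.5) give estimates stable to a few percent in well
under a second of compute. Non-positive exponents report
$\mathrm{dbl} = \infty$: a non-divergent system never doubles a
perturbation.

At $F = 8.75$ the doubling time is about 1.0 time unit, which is why that
forcing anchors the reference experiments. A tangent-space method would
estimate the full spectrum more efficiently, but only the dominant exponent
matters here and the two-trajectory method reuses the already-tested
integrator — one algorithm, two consumers.

### The reservoir: a random echo-state network

The reservoir is a `size`-unit recurrent network with fixed random weights:

* recurrent matrix `w_rec`: Uniform$(-1, 1)$ entries on a
  Bernoulli(connectivity = 0.1) sparsity mask, rescaled so its spectral
  radius is exactly 0.99;
* input matrix `w_in`: dense Uniform$(-0.1, 0.1)$;
* update, once per $dt$:
  $r(t+1) = (1 - a)\,r(t) + a \tanh\!\big(W r(t) + W_{in} u(t+1)\big)$
  with leak rate $a = 1$, starting from $r(0) = 0$.

All $N$ raw environment dimensions drive the network (a switch rescales the
inputs instead; the prediction target is always rescaled). A spectral
radius just below 1 puts the network in the long-memory regime while
retaining the echo-state property: states forget their initial condition at
a geometric rate, which the suite verifies by twin runs from different
random initial states. Because of that fading memory, no separate state
washout is needed beyond the environment's own transient.

These four hyperparameters are exactly the knobs a reservoir-computing
practitioner would expect, and they are the genuinely open part of this
design: the reference results we compare against do not publish them. We
fixed the common defaults above *before* measuring and did not tune them;
the measured pipeline then landed inside the published replicate bands on
the first run (see the acceptance tests), which suggests the headline
result is robust to reasonable hyperparameter choices rather than an
artifact of one setting.

### The readout: cross-validated ridge regression

The "response" side is deliberately minimal: a linear map from the
reservoir state at time $t$ to the target $x_1$ at time $t + \mathrm{shift}$,
with the target affinely rescaled so its range over the *training window*
is $[-1, 1]$ (test-period values may fall outside — the map never sees
them). The first 70% of the 20,000-time-unit record trains the readout; the
last 30% tests it; rows whose predictor and target straddle the boundary
are dropped from both sides, so no training target lies in the test period.

The penalty $\alpha$ is selected by 5-fold cross-validation over an
11-point log-spaced grid ($10^{-8} \dots 10^{2}$): fold membership is
shuffled (chronology is already handled by the outer split), each candidate
is scored by held-out R², and the winner is refitted on all training rows
via the ridge normal equations — centered predictors, penalised weights,
unpenalised intercept. This replaces the evidence-maximising Bayesian ridge
used in some reservoir pipelines with a procedure that is fully specified
and exactly reproducible from its seed; both select one effective
regularisation strength in the same family, and the reported scores are
insensitive to a 10% perturbation of the selected $\alpha$ (tested). The
implementation works from fold-wise sufficient statistics
($X^\top X$, $X^\top y$), so the full $11 \times 5$ search costs about one
pass over the data.

Quality is the coefficient of determination
$R^2 = 1 - SS_{res}/SS_{tot}$, reported as a percentage for both partitions
(`R2_tr`, `R2_ts`). Agreement between the two is the no-overfitting
signature; with ~1.4 million training rows and ≤ a few hundred predictors,
overfitting would indicate a broken split, not a subtle statistical issue.

## The experiment layer

`run_replicate()` executes one fully seeded pipeline; `run_replicates()`
summarises independent replicates as (min, median, max) test R², with the
three random streams (environment initial state, reservoir wiring, tuning
shuffle) derived from a base seed by a counter scheme, so any replicate can
be reproduced in isolation. `run_shift_profile()` scores several forecast
horizons against one shared environment-plus-reservoir, making
horizon-degradation comparisons exactly paired. `run_sweep()` crosses
forcing × horizon × size, attaches the estimated doubling time per forcing,
and `write_results()` emits a fixed-header CSV plus a JSON sidecar from
which the sweep can be regenerated byte-identically (tested).

Where a doubling-time axis is wanted instead of a forcing axis,
`forcing_for_doubling_time()` inverts the estimator by bisection over
$F \in [8, 12]$, where the doubling time decreases monotonically.

## What the generator emulates, and what a green test establishes

The synthetic environment reproduces the stated world of the reference
analysis: $N = 5$, $T = 20{,}000$ time units sampled at $dt = 0.01$
(2 million samples), 70/30 chronological split, target $x_1$ rescaled on
the training range, forecast horizons measured in units of the doubling
time. A green acceptance run establishes that a random reservoir of 25–100
units supports linear prediction of a chaotic signal about one doubling
time ahead at the published accuracy, and that the published ordering
(larger reservoirs better, weaker chaos better, shorter horizons better)
holds.

It does *not* establish anything about real biochemical or neural networks:
the environment is a five-dimensional toy with one tunable parameter, the
network units are noiseless and synchronous, inputs arrive with no sensory
noise, and the readout is trained offline by regression rather than by any
biologically plausible learning rule. The package quantifies the
information argument, not its biological realisation.

## Numerical choices and degenerate inputs

* Fixed-step RK4 at the sampling cadence; divergence (non-finite states)
  raises an error naming the step reached, rather than returning garbage.
* The spectral-radius rescale divides by the measured radius of the random
  draw; an all-zero (or nilpotent) draw — possible at tiny
  `size × connectivity` — raises a degenerate-reservoir error instead of
  dividing by zero.
* A constant signal on the rescale window raises a degenerate-range error;
  a constant observed vector makes R² undefined and errors.
* `shift` must be a multiple of `dt` to within $10^{-9}$ (the state record
  has no values between samples); violations error rather than round.
* Ridge systems are solved directly; if a near-zero penalty meets a
  rank-deficient Gram matrix the solver warns and falls back to a
  pseudoinverse solve rather than failing.
* The median of an even replicate count is the mean of the middle two.
* Seeds are kept within 32-bit range by deriving streams modulo the
  Mersenne prime $2^{31} - 1$.

## Reduced-scale defaults in the tests

Full-scale replicates (2 million steps) take tens of seconds each, so the
unit tests exercise the pipeline at $T$ = 200–2000 with the production
settings reserved for the acceptance tests, which run $n = 5$ replicates
per reservoir size (the reference table used 20; the acceptance script
runs the full 20). Trend assertions (horizon degradation, size benefit,
chaos–predictability ordering) hold already at the reduced scale with a
2-percentage-point noise allowance.

## Known limitations

* Only the dominant Lyapunov exponent is estimated; no spectrum, no
  Kaplan–Yorke dimension. In the weakly forced regime ($F$ near the onset
  of chaos) the estimator inherits the dynamics' own erraticness and no
  special handling is attempted.
* The reservoir update is the canonical leaky-tanh rule; alternative
  topologies, bias terms, or spiking dynamics are out of scope.
* Readouts are linear with a single scalar target; multi-dimensional or
  nonlinear readouts are not supported.
* Exact numerical replication of any external implementation would require
  that implementation's unpublished reservoir hyperparameters; the
  acceptance bands account for this.
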