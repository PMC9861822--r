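---
title: "Modelling and estimating bilayer-membrane memcapacitance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and estimating bilayer-membrane memcapacitance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memcap)
```

## The physical picture

A planar bilayer lipid membrane formed with a residual alkane solvent is not
a fixed capacitor. Under an applied field the solvent redistributes and the
bilayer thins and spreads, so the capacitance grows roughly quadratically
with voltage, `C(U) = C0 (1 + beta U^2)`, with `beta` of order 1-50 V^-2 at
sub-hertz frequencies. These geometric changes are slow (milliseconds to
seconds) and dissipative: the polarization lags the field. Driven by a
periodic triangular command voltage in voltage clamp, the combination of
quadratic capacitance nonlinearity and polarization lag produces two
signatures of a memcapacitive device: pinched hysteresis loops in the
dynamic capacitance-voltage plane, and a *negative insertion conductance* -
a term in the current proportional to `-U` that can make the source's work
per cycle negative.

`memcap` implements the lumped equivalent circuit behind this picture,
its closed-form small-`beta` solutions, an exact ODE reference, a synthetic
trace generator, and the paired-ramp pipeline that recovers the circuit
parameters from recordings.

## The equivalent circuit

Three parallel branches carry the membrane current:

1. **Viscoelastic branch** - a series resistance `r` (standing for the
   viscous resistance to solvent motion) feeding the nonlinear capacitance
   `C1 = (1 - kappa) C0 (1 + beta Utilde^2)`, where `Utilde`, the voltage
   across `C1`, plays the role of the (lagging) electric displacement. Only
   the lag time `tau = (1 - kappa) r C0` enters the solutions, so `tau` is
   the stored parameter and `r` is derived.
2. **Elastic branch** - the fraction `kappa` of the membrane that responds
   instantly, capacitance `kappa C0`. Its own nonlinearity is orders of
   magnitude smaller than the solvent-driven one and is fixed at zero.
3. **Ionic branch** - `i3(U) = g U + gamma U^9`. The ninth-order term is an
   empirical description of the steep conduction increase near +-200 mV; it
   is reported by the estimator as a trend only.

The drive is the symmetric triangle of amplitude `Umax` and frequency `f`;
its slope magnitude `k = 4 Umax f` (the sweep rate) appears throughout. Each
period starts at `-Umax` on the rising ramp. Recorded current is taken
positive for the capacitive charging current on the rising ramp.

Kirchhoff's law for the viscoelastic branch gives a single scalar ODE per
half-period,

    dUtilde/dt = (U(t) - Utilde) / (tau (1 + beta Utilde^2)),

which `integrate_to_steady_state()` solves exactly (see *Numerics*) and
which the closed forms of `utilde_up()`, `total_current_up()` and friends
solve to first order in `beta`.

## What the closed forms say

Expanding to first order in `beta` and matching the half-periods into a
periodic steady state (transient amplitude `2 k tau` at the corner), the
rising-ramp current as a function of voltage is

    I_up(U) = k C0 [1 + beta_exp (U^2 + 5 (k tau)^2)]
              + (g + gamma U^8 - 4 beta_exp k^2 C0 tau) U
              - 2 k C0 (1 - kappa) exp(-(U + Umax)/(k tau)),

with `beta_exp = beta (1 - kappa)` the *effective* nonlinearity. Three
derived quantities organise everything (`derived_params()`):

* apparent zero-voltage capacitance `C_exp0 = C0 (1 + 5 beta_exp (k tau)^2)`;
* zero-hysteresis conductance `g_star = 4 beta_exp k^2 C0 tau`;
* apparent conductance `g_app = g - g_star`.

The half-difference of the rising and time-inverted falling branches
isolates the capacitive parabola; the half-sum isolates the odd conductive
part, whose low-voltage slope is `g_app`. The loop width in the
capacitance-voltage plane is the exact branch difference
`C_up - C_down = 2 * half_sum / k`, i.e. `(2/k) g_app U` away from the
corners: negative slope (pinched, active) for `g < g_star`, closed at
`g = g_star`, reversed for `g > g_star`. A commonly quoted relative-width
expression omits the factor 2 that the exact branch difference carries;
`loop_width()` implements the exact difference and we treat the halved form
as an approximation only. Similarly, the falling-branch corner exponential
must decay away from `U = +Umax` (argument `(Umax - U)/(k tau)`); the
package uses that form consistently.

Where a reference parameter set quotes a nonlinearity without an elastic
fraction, we interpret it as the *effective* coefficient `beta_exp`: with
the regime set (`C0 = 1120 pF`, `tau = 10 ms`, `beta_exp = 15 V^-2`,
200 mV at 2 Hz) this convention reproduces the quoted zero-hysteresis
conductance,

```{r}
refs <- reference_parameter_sets()
zero_hysteresis_conductance(refs$regime_zero$params, refs$regime_zero$drive) * 1e9  # nS
```

exactly (1.72 nS), while interpreting it as the intrinsic coefficient would
not.

### Energy accounting

Integrating `I * U` over one period of the *steady nonlinear response* -
the polynomial part of the closed forms, corner transients excluded - gives

    W = (T / 3) Umax^2 g_app ,

negative exactly when `g < g_star`: the membrane is then an active
memcapacitive element, returning net energy to the source
(`work_per_period()`). The corner-transient terms are not merely a small
correction here: multiplied by the command voltage and integrated they
account for the ohmic dissipation of the lag resistance,

    W_lag = 4 k C0 (1 - kappa) tau (Umax - k tau) + O(beta),

which is positive, grows linearly with `Umax` (hence with `T` at fixed
`k`), and is of the same order as `|W|` whenever `g_app` is dominated by
the insertion term. The two quantities answer different questions - `W`
measures the reversible-versus-insertion balance of the steady response,
`W_lag` the unavoidable viscous loss of dragging the solvent through each
corner - and the package exposes them separately
(`lag_dissipation_per_period()`); the test suite verifies `W_lag` against
the exact ODE energy balance at `beta = 0`.

### The ferroelectric counter-example

Running the same perturbation machinery on a capacitor with the inverse
charge-voltage law (voltage cubic in charge, as in a ferroelectric, instead
of charge cubic in voltage) flips both signatures: the capacitive parabola
inverts (capacitance falls with `|U|`) and the insertion conductance
changes sign to `+4 beta_exp k^2 C0 tau`, so the device dissipates extra
energy and shows no pinched loop (`ferro_current_up()`, validated against
its own ODE oracle with `law = "ferroelectric"`). The coefficients of this
counter-example are derived in-package by the perturbation method, and the
tests check the derivation against the exact ODE, the sign claims, and the
`beta = 0` degeneration.

## The estimation pipeline

`estimate_membrane()` chains the stages; each is exported for use on its
own.

1. **Fold** (`segment_and_fold()`). Align the trace to the drive phase
   (integer-sample search against the command waveform, so arbitrary phase
   offsets are recovered), drop the first `discard_cycles = 2` cycles
   (startup), average the rest pointwise, split into rising and
   time-inverted falling branches, and bin both onto a common 2 mV grid.
   A centered 30 ms moving average (the traditional display smoothing) is
   applied to the binned curves only; the full-resolution time-domain
   branches are kept raw because the transient analysis needs them.
2. **Decompose** (`paired_ramp_decompose()`): exact half-sum and
   half-difference.
3. **Capacitance fit** (`fit_capacitance()`): least squares of
   `half_diff / k = a + b U^2` on `|U| <= 0.6 Umax`. The window default
   keeps the corner exponentials below ~0.5% of `C0` for the reference
   conditions; after the lag time is first estimated, the fit is repeated
   excluding a further `3 k tau` guard band at each sweep end.
4. **Conductance fit** (`fit_apparent_conductance()`): slope through the
   origin of the half-sum on `|U| <= 0.5 Umax` (same guard), below the
   voltages where `gamma U^9` matters.
5. **Transient fit** (`fit_transient()`). The fit runs on the *time-domain
   half-difference*, where the ionic terms of the two branches cancel
   exactly - otherwise the steep `U^9` tail, whose shape near the corner
   mimics an exponential of time constant `Umax / (9 k)`, is collinear with
   the viscoelastic transient. Time constants are profiled (amplitudes and
   a quadratic background enter linearly), giving `tau` and the slow
   amplitude. Two amplitude relations recover the elastic fraction:
   * the instantaneous corner jump between the last falling and first
     rising sample is `2 kappa k C0` - the elastic branch reverses
     instantly while the lagged branch is continuous - and is insensitive
     to the nonlinearity (used when no amplifier model is supplied);
   * with an amplifier in the loop the jump is smeared over `tau_out` and
     the two-exponential amplitudes are used instead, with the slow
     amplitude corrected by `(1 - tau_out/tau)`.
   At finite nonlinearity the slow amplitude is inflated: continuity of
   `Utilde` at the corner plus the quasi-steady lag `k tau (1 + beta
   Utilde^2)` give amplitude `2 (1 - kappa) k C0 (1 + beta Umax^2)`, so the
   estimator subtracts `beta_exp Umax^2` from the relative amplitude. This
   correction matters: at `beta_exp Umax^2 ~ 0.4` the uncorrected relation
   misestimates `kappa` by ~0.2.
6. **Refinement** (`refine = TRUE`). The first-order transient also decays
   at the wrong rate when `beta Utilde^2` is not small (the local time
   constant is `tau (1 + beta Utilde^2)`), which biases a pure
   single-exponential `tau` upward by tens of percent at reference
   conditions. The pipeline therefore refines `(kappa, tau)` by matching
   the raw folded branches against the *exact* circuit ODE, with `C0` and
   `beta` tied to the measured parabola (`C0 = a - 5 b (k tau)^2`,
   `beta = b / (C0 (1 - kappa))`) and the ionic parameters `(g, gamma)`
   profiled linearly at each candidate. When an amplifier model is
   supplied, the model response is passed through the same discrete
   feedback filter as the data. Matching the exact equations rather than
   the first-order curves is a deliberate departure from fitting truncated
   formulas to data: the first-order transient shape is itself the largest
   truncation error at realistic nonlinearity, and fitting data generated
   by the true dynamics with a mis-shaped transient would push the bias
   into `tau` and hence into `g`.
7. **Assembly** (`assemble_parameters()`):
   `C0 = a - 5 b (k tau)^2`, `beta_exp = b / C0`, and
   `g = g_app + 4 beta_exp k^2 C0 tau` (the insertion term added back), so
   the reported parameters satisfy the insertion identity by construction.
   `gamma` is a least-squares trend on the half-sum tails
   (`|U| > 0.75 Umax`), where the corner transients also live - it is
   reported for orientation, not as a calibrated parameter.

Both the transient-stage and refined `kappa`/`tau` are reported
(`glance()` carries the transient values; `tidy()` the final ones).

### What recovery can and cannot achieve

The half-difference and half-sum of *exact* data contain second-order
terms the first-order inversion does not model. The constant of the
parabola is protected (its corrections scale with `(k tau)^2`), so `C0`
recovers to well under 1% at reference conditions; the curvature is not,
so `beta_exp` carries a bias that grows with the expansion parameter
`beta_exp Umax^2` - a few percent at `beta_exp Umax^2 ~ 0.4` and roughly
-15% by `~0.6` (the regime set at 200 mV). The recovered `g` inherits both
that bias (through the insertion term) and the second-order odd content of
the half-sum; with an insertion term of ~0.5 nS the net error is below
0.1 nS. `kappa` and `tau` come from the exact-model refinement and recover
essentially exactly on noiseless data. The property tests pin these claims
on a parameter grid restricted to `beta_exp Umax^2 <= 0.5`, the same
validity domain in which the closed forms track the oracle.

## The synthetic generator

`generate_trace()` emulates the recording protocol: triangular drive of
50-300 mV at 0.01-2 Hz, 1 kHz sampling, 20-30 periods per record
(default 25), optional first-order amplifier filtering, and additive white
Gaussian current noise (default sd 5 pA, the order of the fluctuation
scale visible on nanofarad membranes; the actual noise level of such
recordings is instrument-dependent and the parameter is free). The record
starts from equilibrium at `-Umax` (`Utilde(0) = U(0)`), so the first
cycles carry a genuine startup transient for the pipeline to discard. It
does **not** emulate membrane rupture, amplifier clipping at high
currents, 1/f or mains noise, or electrode drift - so passing recovery
tests here demonstrates correctness of the analysis chain, not robustness
to every experimental pathology.

## Numerics

* **ODE integration**: `lsoda` with `rtol = 1e-9`, `atol = 1e-12` V,
  restarted at every slope reversal (the drive's derivative is
  discontinuous there and an adaptive stepper loses order across an
  undetected corner). Steady state is a Poincare fixed point of the
  branch voltage at the period start (`|dUtilde| < 1e-10` V by default);
  for `T >= 20 tau` this needs at most ~3 periods. `tau = 0` short-circuits
  to the algebraic solution.
* **Amplifier filter**: exact zero-order-hold recursion
  `y[n] = a y[n-1] + (1-a) x[n]`, `a = exp(-dt/tau_out)` - forward Euler
  is badly inaccurate when `tau_out` (0.8 ms on a typical headstage) is
  comparable to the 1 ms sample interval. Discretization error is
  `O(1/(fs tau_out))`.
* **Degenerate inputs**: `tau = 0` (no lag), `kappa = 1` (no viscoelastic
  branch; forces `tau = 0`), `beta = 0` (linear RC) all take exact
  closed-form paths rather than limiting numerics; operations warn when
  `T/2 < 5 tau`, where the steady-ramp assumption behind the closed forms
  degrades.
* **Optimisation**: time constants are always profiled (amplitudes solved
  linearly), and the refinement residual is scaled by `k C_exp0` so
  optimizer tolerances are relative, not absolute in A^2.
* **Problem sizes**: the test suite and the acceptance script use 4-25
  period records at 1 kHz (2.5k-25k samples) and oracle grids of 400-20000
  points per period; these keep every check well inside a minute while
  leaving quadrature and solver error far below the assertion tolerances.

## Conventions and resolved ambiguities

* Internal units are strictly SI; display and file formats use the field's
  customary mV / pF / nS / ms with unit-suffixed keys. The ninth-order
  conductance is the classic trap: `1 nS/mV^8 = 1e15 S/V^8`, so a quoted
  `0.5e-18 nS/mV^8` is `5e-4 S/V^8`.
* Each period starts at `-Umax` on the rising ramp; recorded traces with
  other phases are realigned by the folding stage.
* The transient amplitudes of the branch voltage are fixed by periodic
  matching at zeroth order (`A = +-2 k tau`); first-order corrections to
  the transient are dropped, consistent with the closed-form currents.
  The cost is a residual `O(beta)` mismatch against the exact solution in
  a band of a few `tau` after each corner - which is why oracle
  comparisons quote guard bands and why the refinement stage fits the
  exact equations.

## Limitations

* First-order perturbation: quantitative accuracy degrades beyond
  `beta_exp Umax^2 ~ 0.5`; the oracle is always available for exact work.
* No frequency-dependent parameter models: `beta(f)` and `tau(f)` are
  empirically strong dependencies, and `cmd_sweep()` produces per-cell
  independent estimates, but no parametric law is fitted.
* No access (series electrolyte) resistance, no amplifier saturation, no
  membrane breakdown; triangular drive only.
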