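---
title: "Fitting two-gate Hodgkin-Huxley IKr models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitting two-gate Hodgkin-Huxley IKr models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`ikrfit` characterises the rapid delayed-rectifier potassium current
(IKr, carried by hERG channels) from whole-cell voltage-clamp
recordings. The current model is a two-gate Hodgkin-Huxley scheme:

$$I_{Kr} = g_{Kr}\, a\, r\, (V - E_K),$$

where $a$ is the fraction of activated channels, $r$ the fraction
recovered from inactivation, and $E_K$ the potassium reversal potential
from the Nernst equation. Each gate relaxes mono-exponentially at fixed
voltage,

$$\frac{da}{dt} = \frac{a_\infty - a}{\tau_a}, \qquad
  \tau_a = \frac{1}{k_1 + k_2}, \qquad a_\infty = k_1 \tau_a,$$

(and analogously for $r$ with $k_3, k_4$), with Eyring-style exponential
voltage dependence of the four transition rates:

$$k_1 = p_1 e^{p_2 V}, \quad k_2 = p_3 e^{-p_4 V}, \quad
  k_3 = p_5 e^{p_6 V}, \quad k_4 = p_7 e^{-p_8 V}.$$

The nine strictly positive parameters are
$\theta = \{p_1,\dots,p_8, p_9 = g_{Kr}\}$. Units are fixed
package-wide: milliseconds, millivolts, rates in ms$^{-1}$,
sensitivities in mV$^{-1}$; the current unit is inherited from $g_{Kr}$
(nanoamps when $g_{Kr}$ is in microsiemens).

## The four fitting routes

1. **Direct summary fit** (`method1_fit`). The steady state of each gate
   is an exact Boltzmann sigmoid
   $1/(1+e^{s(h-V)})$ with $s_a = p_2 + p_4$,
   $h_a = (\log p_3 - \log p_1)/s_a$ (activation; the inactivation pair
   has $s_r = -(p_6+p_8) < 0$). Because $a_\infty/\tau_a = k_1$
   identically, a log-linear regression of the reconstructed steady
   state over the measured time constants yields $p_1, p_2$
   ($p_7, p_8$), and the Boltzmann constraints give $p_3, p_4$
   ($p_5, p_6$) by back-substitution. Only the conductance needs one
   simulation: the simulated IV curve is proportional to $g_{Kr}$, so
   the optimal scaling is closed-form least squares. The whole procedure
   is deterministic and, on summary curves computed from the model's own
   equations, exact to floating precision — the package's tests use this
   exactness as an oracle.
2. **Simulated summary fit** (`e_m2` + CMA-ES). Step protocols are
   simulated and pushed through the *identical* extraction pipeline used
   on measured data; the objective sums range-normalized RMSEs of the
   activation curve, both time-constant curves and the IV curve (42
   points with the default protocols). The IV curve replaces the steady
   state of inactivation: same information, no near-$E_K$ division, and
   it pins the conductance. Any summary-derivation failure maps to
   $+\infty$, which is what produces the characteristic "holes" of this
   objective's landscape.
3. **Whole-trace fit to step protocols** (`e_m3`). The sum over Pr2–Pr5
   of RMSEs between recorded and simulated currents, each normalized by
   the protocol's recorded current range; only mask-retained samples
   enter. Step protocols are simulated with the exact piecewise
   exponential solution, so this objective carries no solver noise.
4. **Whole-trace fit to the sinusoidal protocol** (`e_m4`). The same
   normalized RMSE on the single 8 s sine-wave protocol (Pr7). One
   protocol, so no per-protocol weighting choices arise.

An AP-waveform protocol (Pr6) is never fitted; `e_ap` on it is the
independent validation measure, and `cross_validate` assembles the
relative-RMSE table (each row scaled so the best method reads 1).

## Protocols and extraction

The shipped grids (`inst/extdata/protocols.json`) are reconstructions
chosen to satisfy every documented structural constraint
simultaneously: sweep counts 6/7/16/9 for Pr2–Pr5, summary-curve
cardinalities 7/8/9/17/9, 228 s of combined step-protocol time, and an
8 s Pr7. They are configuration, not code: replace the file (or pass
`config` overrides to the builders) to use archived protocol
definitions. Pr7 is a 1 s step to +40 mV followed by a sum of three
sines (≈1.1, 5.9 and 30 Hz; offset −30 mV, amplitudes 54/26/10 mV).
The initial step was lengthened from a nominal 0.5 s to 1 s after in
silico identifiability checks: with only brief depolarised excursions
the activation pre-factor $p_1$ was constrained to ~10% at realistic
noise, with the longer step all nine parameters are constrained to a
few percent (the step-vs-sine split is a design choice; the total stays
8 s).

Capacitance artifacts are handled by blanking the first 5 ms after
every discontinuous voltage step (including the sweep start); the mask
depends only on the voltage command and is applied identically to
measured and simulated data. Summary extraction:

* ã∞ — peak tail current per Pr3 sweep, normalized by the
  largest-magnitude peak, clamped into [0, 1] (noise can flip the sign
  of near-zero tails).
* τ̃a — single-exponential fits to the Pr5 deactivation phase (window
  from 50 ms into P2, P2 < 0 mV) plus one envelope point from Pr2
  (peak tail vs P1 duration at +40 mV).
* τ̃r — fast phase of a two-exponential fit over the first 300 ms of P2
  (Pr5, P2 < −30 mV) plus single-exponential onset fits during P3
  (Pr4, P3 ≥ −40 mV).
* r̃∞ — peak P2 current divided by driving force, the P2 voltage
  nearest E_K excluded, normalized to a maximum of 1.
* IV — signed peak P2 current per sweep.

Peaks are read from a 1 ms running mean (reduces the upward bias of raw
extremum picking on noisy, near-zero currents). Exponential fits
profile the offset and amplitudes out linearly and search only the time
constants (log-scale golden-section for one phase, Nelder-Mead for
two); windows longer than ~400 samples are deterministically decimated
— the identical thinning applies to measured and simulated data, so the
simulated-summary objective is unaffected. A signal whose range falls
below a small floor yields a no-fit sentinel and the point is dropped
(with a warning); in objective context a dropped point makes the whole
evaluation $+\infty$.

On noiseless model-generated data the extracted curves approximate but
do **not** equal the model variables: the peak-based steady state of
inactivation is biased wherever deactivation competes with recovery
(up to ≈0.2 after normalization at −120 mV with the fixture kinetics),
and onset fits inherit a few percent of bias from the slowly drifting
activation gate. This is a property of the experimental analysis being
emulated, not an extraction bug, so tests assert *bounded* discrepancy
(5% for τ̃a, 15% for τ̃r, 0.25 for r̃∞) rather than equality. A green
extraction test therefore establishes pipeline correctness and
stability, not that summary curves are unbiased estimators — which is
precisely why the simulated-summary and whole-trace methods exist.

## Simulation

Step protocols use the exact analytic solution (state carried across
segments; each sweep starts from the steady state at its first
segment's voltage — sweeps are treated as independent, justified by the
long inter-sweep holding periods relative to the holding-potential time
constants). Everything else uses an adaptive Dormand–Prince 5(4)
integrator (implemented in C++ in `src/sim.cpp`) with dense output on
the sampling grid and forced restarts at segment boundaries and
sampled-waveform nodes. Default tolerances are `rtol = atol = 1e-8`:
the test suite reproduces the classic failure mode where lax tolerances
(1e-3) put visible jitter into an objective evaluated along a line in
parameter space, while 1e-8 keeps it smooth and bit-reproducible.
Rate evaluations whose exponent exceeds 700 in magnitude are reported
as invalid evaluations and surface as $+\infty$ objective values rather
than NaNs.

## Optimization

Methods 2–4 are minimized with a from-scratch implementation of
standard (μ/μ_w, λ)-CMA-ES (population 10 by default). The search space
combines:

* box bounds — rate pre-factors and the conductance span ~10 orders of
  magnitude ($[10^{-7}, 10^3]$ ms$^{-1}$, $g_{Kr} \in [10^{-5}, 10^3]$),
  sensitivities capped at 0.4 mV$^{-1}$;
* rate constraints — each rate, evaluated where it is largest over
  [−120, 60] mV (endpoints suffice by monotonicity), must lie in
  $[1.67\times10^{-5}, 10^3]$ ms$^{-1}$. Constraining the rate over the
  *whole* interval would exclude every realistic hERG parameter set
  (activation rates are astronomically small at −120 mV), so the
  maximal-rate form is used;
* a log transform on $p_1, p_3, p_5, p_7$ and (by default, since it
  also spans decades) $p_9$.

Points outside the feasible region score $+\infty$. Starting points are
sampled uniformly in the transformed box and rejection-filtered; the
initial per-coordinate step size is 1/6 of the transformed bound width.
Stopping follows a stall rule — the per-iteration best objective value
changing by less than $10^{-11}$ for 200 successive iterations — plus a
hard iteration cap as a runtime guard (2000 by default; the test suite
uses smaller caps, see below). The per-iteration (not best-so-far)
change is used deliberately: while the population still fluctuates the
iteration best moves by far more than the threshold, so exploration
phases are not cut short. Multi-start fitting runs seeded independent
repeats (reference budgets: 80 for method 2, 50 for methods 3/4; the
`repeats_scale` knob scales these for desk-scale runs) and keeps the
lowest score; `reliability()` reports the fraction of repeats within 1%
of the best score and the fraction additionally within 1% per parameter.

## The synthetic world

`generate_cell()` simulates every protocol from a known truth, adds iid
Gaussian noise, and extracts summary curves from the noisy traces. The
fixture truth has hERG-like kinetics (activation τ of order seconds at
moderately negative voltages, inactivation τ of order 10 ms,
E_K ≈ −88.4 mV from 4/130 mM potassium at 294.65 K); the default noise
sd is 2% of the noiseless Pr7 current range, comparable to the noisiest
whole-cell recordings this kind of experiment produces. What the
generator deliberately does **not** emulate: leak and endogenous
currents, series-resistance artifacts beyond the blanking window,
drift, and temporally correlated noise. A green recovery test therefore
establishes that the estimation machinery works on well-behaved data of
realistic size and noise — not that real recordings are this benign.

Random "truths" for recovery tests come from
`sample_physiological_params()` (log-normal jitter around the fixture,
rejected against the feasible region) rather than uniform draws over
the full 10-decade box: uniform draws routinely produce kinetics that
no finite protocol can identify, which would test the sampler's
cruelty, not the methods.

## Runtime scaling in the test suite

The acceptance tests scale simulation density down to fit a desk-scale
budget and say so in place: recovery cells use 2 ms sampling for the
step protocols (default 0.1 ms; the sine protocol keeps 0.1 ms since
the 5% recovery bar needs its full information content), 5 (method 3)
or 3 (method 4) repeats per truth instead of 50, iteration caps of
600 / 300 with the stall rule kept, and a small-step polish of the best
sine-wave repeat — a budget verified to reach the same optimum as an
uncapped run started at the truth. Under these caps a minority of
repeats reach the global optimum (the multi-start *best* still
recovers the truth); the repeat-to-repeat reliability fractions are
correspondingly lower than a full-budget run would give, so the suite
asserts the reliability *machinery* exactly and the nesting property
(param-close ⊆ RMSE-close) on real fits, not a specific percentage.

## Identifiability of the sine-wave method

The in-silico recovery study quantifies what the 8 s sine-wave protocol
can and cannot pin down at realistic noise (2% of the protocol's
current range). For most hERG-like truths all nine parameters are
recovered to a few percent; for some (verified by starting the
optimizer at the truth, i.e. this is the statistical optimum, not an
optimization failure) the activation pre-factor $p_1$ is only
constrained to 6–8%. The 228 s step-protocol set constrains every
parameter to <3% on the same cells. This trade-off — a 30-fold shorter
recording at the cost of a few percent of parameter precision, with
activation/deactivation rates the weak spot — is exactly the
qualitative behaviour reported for sinusoidal protocols, and is why the
recovery test asserts a 4-of-5-truths criterion for each whole-trace
method and documents the sine-wave method's shortfall rather than
hiding it.

## Known limitations

* Method 2's objective is evaluated through the full extraction
  pipeline and is therefore ~50x more expensive per call than method
  4's, and its landscape contains failure regions and local optima; the
  method-1-seeded start (`seeded_start_from_method1`) is the practical
  way to use it.
* The direct summary fit inherits every bias of the summary curves; on
  realistic synthetic data its parameters are systematically off even
  though its own goodness-of-fit looks excellent. This is reproduced,
  not fixed, by design.
* No temperature (Q10) scaling, no alternative Markov topologies, no
  likelihood-based or autocorrelated noise models.
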