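---
title: "Anti-Hebbian sequence learning in a striatal microcircuit: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anti-Hebbian sequence learning in a striatal microcircuit: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(striatoseq)
```

## The scientific problem

Cortical activity often arrives at the striatum as *sequences* of spikes:
the same set of presynaptic neurons firing in a particular order with
particular delays. A striatal medium spiny neuron (MSN) that learns to fire
only **after the end** of specific ("rewarded") sequences — and to stay
silent both for other sequences and for incomplete fragments of the learned
ones — implements a biologically minimal sequence classifier. striatoseq
simulates this setting with the three ingredients that corticostriatal
physiology actually provides:

1. **anti-Hebbian spike-timing dependent plasticity (STDP)** at the
   cortex→MSN synapses, where a presynaptic spike followed by a postsynaptic
   spike *depresses* the synapse;
2. **spike latency** of MSNs, captured by a quadratic adaptive neuron model;
3. **collateral inhibition** between MSNs.

A non-associative reward signal (reward-LTP) potentiates every synapse that
was active during a rewarded presentation, counteracting the depression so
the cell neither falls silent nor runs away.

## Neuron models

Both models work in mV / ms / nA / nF / MΩ units and are integrated with a
fixed-step Euler scheme, `dt = 0.1` ms by default.

**M1 — leaky integrate-and-fire.** Between spikes

$$\tau \dot V = -(V - V_{eq}) + R\,I(t) + \sqrt{\tau}\,V_{noise}(t),$$

with a spike when $V \ge V_{th}$, reset to $V_r$, and input integration
suspended for $\tau_{refractory} = 10$ ms (Dirac inputs arriving during the
refractory period are discarded, not queued). The defaults in
`m1_params()` are values fitted to whole-cell recordings of mouse
dorsolateral-striatum MSNs: $V_{eq} = -76.72$, $V_{th} = -39.51$,
$V_r = -41.70$ mV, $R = 118.5$ MΩ, $\tau = 11.85$ ms. The white-noise term
is discretised so each Euler step adds a Gaussian increment of standard
deviation $\eta_{noise}\sqrt{dt}$ (mV); with $\eta_{noise} = 0.5$ mV this
noise cannot bridge the ~37 mV gap between rest and threshold on its own,
which is the intended regime — it perturbs timing, not excitability.

**M2 — adaptive quadratic model.** The latency-producing nonlinear model is

$$C \dot V = k (V - V_c)(V - V_{eq}) - U + I(t), \qquad
  \dot U = a\big(b (V - V_{eq}) - U\big),$$

with spike detection at $V \ge V_{th}$, reset $V \gets V_r$ and adaptation
jump $U \gets U + d$. Defaults follow the canonical published MSN
parameterisation of this model family: $C = 0.05$ nF, $V_{eq} = -80$,
$V_{th} = -20$, $V_r = -55$ mV, $a = 0.01$ ms$^{-1}$, $b = -0.02$ nA/mV,
$d = 0.15$ nA, plus the family's standard quadratic gain $k = 1$ nS/mV and
instability parameter $V_c = -25$ mV (the latter two are not constrained by
the MSN recordings, so the canonical values are used and exposed in
`m2_params()`). With $k$ in nS/mV the quadratic current is in pA and is
converted to nA internally. Near rheobase this model fires several
milliseconds after its input — the spike latency that turns out to matter
for sequence learning. M2 has no refractory period and runs noise-free by
default (an optional additive voltage noise is exposed).

**Synaptic input.** Each cortical spike on channel $i$ delivers a current
pulse weighted by $W_i$ (nA), frozen at its pre-update value $W_i(t^-)$.
Three pulse shapes are available (`synapse_kernel()`): Dirac (an
instantaneous voltage jump of $R\,W_i$ mV for M1, $R_{scale} W_i$ mV with
$R_{scale} = 100$ MΩ for M2), and charge-normalised exponential and alpha
kernels

$$\varphi(t) = \tfrac{1}{T_s} e^{-t/T_s}, \qquad
  \varphi(t) = \tfrac{t}{T_s^2} e^{-t/T_s},$$

whose time integral is 1 for every $T_s$, so the shape redistributes a
fixed total charge in time. Continuous kernels are integrated by
per-channel state variables (one linear ODE for the exponential kernel, two
for the alpha kernel), which equals the event-convolution sum up to Euler
error; a test verifies this against direct convolution. External
(non-cortical) spikes use a fixed, non-plastic weight $W_{ext} = 1$ nA.

**Event conventions.** A spike is stamped at the left edge of the Euler
step in which threshold is crossed. Within one step, inputs are processed
before output spike detection; in the two-MSN circuit the inhibiting cell
is examined first, so its spike can veto its target in the same step.

## Plasticity

Pair-based, all-to-all STDP with exponential kernel
($\tau_s = 20$ ms, rate $\varepsilon = 0.02$ nA):

$$\Phi(\Delta t) = A_{post\text{-}pre}\, e^{\Delta t/\tau_s}\ (\Delta t<0),
 \qquad \Phi(\Delta t) = A_{pre\text{-}post}\, e^{-\Delta t/\tau_s}\
 (\Delta t>0),$$

with $\Delta t = t_{post} - t_{pre}$. The four polarity presets are
symmetric LTD $(-1,-1)$, asymmetric Hebbian $(-1,+1)$, asymmetric
anti-Hebbian $(+1,-1)$ and symmetric LTP $(+1,+1)$, ordered
$(A_{post\text{-}pre}, A_{pre\text{-}post})$. At every postsynaptic spike
each channel is updated by $\varepsilon \sum \Phi$ over its previous
presynaptic spikes, and at every presynaptic spike by
$\varepsilon \sum \Phi$ over previous postsynaptic spikes; the engine
evaluates these sums exactly with exponential traces.

Two conventions deserve explanation:

* **Simultaneous pairs.** With Dirac synapses and an instantaneous
  integrate-and-fire cell, the output spike triggered by the final input of
  a sequence lands in the *same* Euler step as that input. Since inputs are
  processed before outputs, the pair is causally ordered pre→post and takes
  the pre-post branch at full amplitude, $\Phi(0) = A_{pre\text{-}post}$
  (the $\Delta t \to 0^+$ limit). Setting $\Phi(0) = 0$ instead would
  exempt exactly the synapse that caused the spike from depression and
  destroy the anti-Hebbian equilibrium described below.
* **Clipping granularity.** Weights are clipped to
  $[w_{min}, w_{max}] = [0, 2]$ nA after the net update of each Euler
  step. Sub-updates inside one step (a reward increment and a depression
  from a same-step output spike) are simultaneous at the integrator's
  resolution; clipping between them would truncate whichever happens to be
  applied first and bias the near-bound dynamics.

**Reward-LTP.** During a rewarded presentation every presynaptic spike adds
$\varepsilon A_{reward}$ to its synapse ($A_{reward} = 0.9$ for task
learning; 0 disables supervision). This deliberately includes background
(noise) spikes — reward is non-associative; a pattern-only mode is
available by running without background noise. Whether external-input
spikes are plastic is a genuinely open choice; here $W_{ext}$ is fixed,
since plasticity is defined for the $P$ cortical channels.

Spike histories (and membrane state) are reset between presentations, and
plasticity is disabled entirely during test sessions.

## The anti-Hebbian equilibrium and its error modes

Presenting one rewarded sequence over and over, a success (MSN fires at the
end) changes the synapse of a neuron firing $\Delta$ before the MSN spike
by $\varepsilon(A_{reward} + A_{pre\text{-}post} e^{-\Delta/\tau_s})$: net
depression within the potentiation window
$T_p = \tau_s \log(-A_{pre\text{-}post}/A_{reward})$ ($\approx 2.1$ ms at
defaults, `potentiation_window()`), net potentiation beyond it. The last
synapse in the sequence is drained by
$\varepsilon|A_{pre\text{-}post} + A_{reward}|$ per success and refilled by
$\varepsilon A_{reward}$ at each missed spike, so at most

$$N = \left\lceil \frac{A_{reward}}{|A_{pre\text{-}post} + A_{reward}|}
 \right\rceil$$

successes fit between two misses (`success_ceiling()`; $N = 9$ at
defaults, bounding accuracy by $1 - 1/N$). The resulting serrated weight
trace and the success/miss alternation are exactly what
`run_error_mode_experiment()` measures. Two closed-form conditions bracket
the regimes: a premature (type 1) spike requires
$base + w_{max}\sum_{k<n} e^{-\delta_k^{n-1}/\tau} \ge V_{th}$, and misses
are certain when $base + w_{max}\sum_{k\le n} e^{-\delta_k^{n}/\tau} \le
V_{th}$ (`type1_possible()`, `type2_certain()`). The conditions are
implemented as printed in their source derivation with the reset potential
$V_r$ as the baseline, plus a `baseline = "V_eq"` switch; because every
simulated trial starts from rest, drivers that must agree with simulation
use the resting-potential baseline. Why the closed form baselines at $V_r$
is left open.

A geometric consequence worth knowing: for the fitted M1 and a 4-spike,
20 ms sequence, the weight headroom available below the premature-spike
bound is smaller than $\varepsilon(A_{reward} + N|A_{pre\text{-}post} +
A_{reward}|)$, so the *fully* unclipped $N$-success cycle does not fit —
at the least-saturated admissible cell (the bound itself, computed at run
time by the error-mode drivers) the measured cycle runs 7 successes per
miss. The tests assert the ceiling as an upper bound, which is what the
theory states.

## Tasks and the synthetic-data generator

All inputs are generated programmatically; there is no external data.
Patterns live in a trial of `t_duration = 50` ms and start at
`t_offset = 10` ms — no canonical onset exists, and 10 ms leaves a wide
post-pattern window for the spike-after-the-end verdict while giving the
membrane time to settle.

* **Task 1** (`gen_task1()`): $n \sim$ Uniform{1..$N_{stim}$} spikes on
  distinct channels in random order, 1 ms apart. Duplicate channel
  sequences are redrawn: duplicates with independently drawn rewards would
  make the task ill-posed. Rewards are i.i.d. Bernoulli(1/2), independent
  of content; a pattern set may by chance be all-rewarded.
* **Task 2** (`gen_task2_nested()`): the nested family (1), (1,2), …,
  (1..P) at 0.5 ms spacing, with all $2^P$ reward assignments enumerated.
* **Task 3** (`jitter_pattern()`): per-presentation uniform jitter of each
  spike; "uniform with standard deviation $\tau_{pattern}$" is realised as
  Uniform$(-\tau_{pattern}\sqrt3, +\tau_{pattern}\sqrt3)$, clipped to the
  trial window.
* **Task 4** (`gen_task4_poisson()`): a 1 kHz Poisson process on a 2 ms
  window scattered uniformly over the channels, rejection-sampled until the
  pattern holds at least two spikes *in total* (the conditioning counts all
  channels together).

Background processes: independent Poisson cortical spikes at
$\lambda_{stim}$ per channel, external spikes at $\lambda_{ext}$, and the
timing jitter above. Training redraws all noise at every presentation.

What this generator does **not** emulate: cortical oscillations,
cross-channel correlations beyond the template, rate modulation, synaptic
failures, or multi-trial temporal continuity (trials are reset,
independent). Passing tests therefore demonstrate the learning mechanics
under idealised input statistics, not performance on recorded cortical
data.

## Protocol, metrics and the fitted object

`run_training()` draws a pattern uniformly (with replacement) each
iteration, applies plasticity with the pattern's reward, resets state
between presentations, and every `test_every` iterations (default $N_p$;
5 for the nested task, which trains for 2000 iterations instead of 500)
runs a frozen-weight, noise-free test session over all patterns. A
rewarded pattern scores $\sigma = 1$ when the first MSN spike is **at or
after** the last template spike — a spike triggered by the final input of
the sequence counts as "after the whole sequence", and firing strictly
earlier is the type 1 error; this inclusive convention is forced by the
Dirac/M1 combination, where the closing spike of a sequence and the output
it causes share a step. The verdict is judged against template spikes
only, never against background spikes. Eq.-style accuracy is
$\frac1{N_p}\sum_k r_k\sigma_k + (1-r_k)(1-\nu_k)$ and `max_accuracy()`
smooths it with a sliding maximum over ±`T_1` = 10 test sessions, because
the anti-Hebbian equilibrium *intrinsically* alternates successes and
failures.

The return value is a classed `striatal_fit` with `print`, `summary`,
`coef` (final weights), `plot` (accuracy curves) and `predict`
(frozen-weight classification of new patterns, used by
`test_subpatterns()` to probe silence on sequence fragments).

For the two-MSN circuit both cells integrate the same cortical events
through their own weight vectors; each MSN2 spike kicks MSN1's voltage by
$R_{scale} J$ mV ($J = -0.5$ nA), the same Dirac convention as excitation.
Under the differential reward scheme MSN2 is rewarded exactly on the
patterns not rewarded for MSN1; accuracy is read out on MSN1 only. A
caveat the package documents honestly: with asymmetric anti-Hebbian STDP
the first spike of *any* cell self-tunes toward latency $T_p$ after its
anchoring input, so a discriminating MSN2 — anchored on a later spike of
the nested pattern — equilibrates slightly later than MSN1, and the veto
is only effective while MSN1 sits in the narrow barely-firing band of the
quadratic model's latency curve; with the default plasticity quantum the
circuit visits that band intermittently rather than settling in it.

## Continuous-kernel weight scaling

Charge-normalised kernels dilute each spike's peak drive as $T_s$ grows
(the quadratic model's effective membrane constant near rest is ~0.9 ms,
so slow input is strongly attenuated); with the Dirac-calibrated bound
$w_{max} = 2$ nA a single spike cannot fire M2 through an alpha synapse
slower than ~3 ms. `run_timescale_sweep()` therefore multiplies all
weight-dimension quantities (initial range, bounds, plasticity rate) by
one common factor $\kappa = 2\,W^*(T_s^{max})/w_{max}$, where
$W^*$ (`min_spiking_weight()`, bisection at run time) is the smallest
weight whose single spike fires the neuron for the slowest kernel in the
sweep. One shared scale keeps the comparison across timescales about the
temporal profile rather than about reachability; the accuracy landscape
still depends on this choice, which is the main caveat attached to any
timescale-optimum readout.

## Numerical choices

* Euler scheme, `dt = 0.1` ms everywhere; events binned to step left
  edges; convergence to the closed-form M1 solution is tested at rate
  $O(dt)$.
* STDP sums via exactly decayed exponential traces (no truncation); the
  engine's updates are verified against a history-based replay of the rule.
* M2 numeric overflow of the quadratic term is treated as a spike in that
  step.
* Weight bounds applied per Euler step (see above); initial weights
  uniform in $[0, 0.05]$ nA.
* Reproducibility: all randomness flows through R's RNG (the compiled
  engine draws its noise from it), so a seed fixes every trajectory
  bit-for-bit; sweeps derive per-cell child seeds from the master seed so
  results are independent of execution order.
* Problem sizes used by the packaged experiments: stationary-drive runs of
  5 s × 20 repetitions; Task-1 trainings of 500 presentations (2000 for
  the nested task) at $P = 10$; direction-of-effect comparisons at 50
  repetitions; timescale sweeps at 10 repetitions per cell. These sizes
  give stable medians and clear t-tests while keeping a full run of the
  suite on a laptop comfortable.

## Known limitations

* The M1 refractory period (10 ms) caps output rates at well under
  100 Hz; saturated-regime rates are refractory-limited and symmetric-LTP
  saturation requires enough drive for initial coincidences to bootstrap
  postsynaptic spiking (pair-based LTP is inert while the cell has never
  spiked). At 10 Hz per channel with subthreshold initial weights the
  symmetric-LTP circuit stays silent indefinitely — a real property of
  pair-based rules, measured and asserted as such.
* The error-mode theory is a single-neuron, noise-free idealisation; with
  background noise the verdicts and weight dynamics acquire stochastic
  components the closed forms do not describe.
* Two MSNs with a single one-way inhibitory collateral are the smallest
  circuit exhibiting nested-pattern discrimination, not a model of striatal
  population dynamics.
* No dopamine dynamics, eligibility traces, triplet/voltage-dependent
  plasticity, or feedforward interneurons: the reward is a bare
  non-associative potentiation.
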